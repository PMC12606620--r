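wavelength_nm	k
600	3.342254e-02
602	3.310713e-02
604	3.279437e-02
606	3.248431e-02
608	3.217697e-02
610	3.187237e-02
612	3.157054e-02
614	3.127150e-02
616	3.097527e-02
618	3.068188e-02
620	3.039133e-02
622	3.010365e-02
624	2.981885e-02
626	2.953694e-02
628	2.925794e-02
630	2.898186e-02
632	2.870871e-02
634	2.843849e-02
636	2.817121e-02
638	2.790689e-02
640	2.764551e-02
642	2.738710e-02
644	2.713165e-02
646	2.687916e-02
648	2.662964e-02
650	2.638308e-02
652	2.613948e-02
654	2.589885e-02
656	2.566117e-02
658	2.542645e-02
660	2.519468e-02
662	2.496586e-02
664	2.473999e-02
666	2.451704e-02
668	2.429703e-02
670	2.407993e-02
672	2.386575e-02
674	2.365448e-02
676	2.344610e-02
678	2.324061e-02
680	2.303799e-02
682	2.283824e-02
684	2.264135e-02
686	2.244730e-02
688	2.225608e-02
690	2.206769e-02
692	2.188210e-02
694	2.169932e-02
696	2.151931e-02
698	2.134208e-02
700	2.116761e-02
702	2.099586e-02
704	2.082673e-02
706	2.066008e-02
708	2.049580e-02
710	2.033375e-02
712	2.017383e-02
714	2.001592e-02
716	1.985990e-02
718	1.970567e-02
720	1.955312e-02
722	1.940215e-02
724	1.925266e-02
726	1.910456e-02
728	1.895774e-02
730	1.881212e-02
732	1.866760e-02
734	1.852411e-02
736	1.838155e-02
738	1.823985e-02
740	1.809892e-02
742	1.795869e-02
744	1.781908e-02
746	1.768002e-02
748	1.754144e-02
750	1.740327e-02
752	1.726545e-02
754	1.712792e-02
756	1.699060e-02
758	1.685345e-02
760	1.671640e-02
762	1.657940e-02
764	1.644240e-02
766	1.630535e-02
768	1.616820e-02
770	1.603090e-02
772	1.589341e-02
774	1.575569e-02
776	1.561769e-02
778	1.547939e-02
780	1.534074e-02
782	1.520171e-02
784	1.506228e-02
786	1.492240e-02
788	1.478212e-02
790	1.464150e-02
792	1.450062e-02
794	1.435955e-02
796	1.421836e-02
798	1.407712e-02
800	1.393590e-02
802	1.379477e-02
804	1.365378e-02
806	1.351300e-02
808	1.337249e-02
810	1.323231e-02
812	1.309251e-02
814	1.295314e-02
816	1.281427e-02
818	1.267594e-02
820	1.253820e-02
822	1.240110e-02
824	1.226469e-02
826	1.212899e-02
828	1.199407e-02
830	1.185996e-02
832	1.172669e-02
834	1.159431e-02
836	1.146285e-02
838	1.133234e-02
840	1.120282e-02
842	1.107432e-02
844	1.094686e-02
846	1.082047e-02
848	1.069518e-02
850	1.057101e-02
852	1.044799e-02
854	1.032614e-02
856	1.020548e-02
858	1.008602e-02
860	9.967790e-03
862	9.850802e-03
864	9.735071e-03
866	9.620612e-03
868	9.507438e-03
870	9.395560e-03
872	9.284991e-03
874	9.175739e-03
876	9.067813e-03
878	8.961222e-03
880	8.855972e-03
882	8.752069e-03
884	8.649519e-03
886	8.548326e-03
888	8.448493e-03
890	8.350024e-03
892	8.252920e-03
894	8.157182e-03
896	8.062811e-03
898	7.969807e-03
900	7.878170e-03
902	7.787896e-03
904	7.698973e-03
906	7.611391e-03
908	7.525134e-03
910	7.440190e-03
912	7.356546e-03
914	7.274188e-03
916	7.193105e-03
918	7.113282e-03
920	7.034707e-03
922	6.957367e-03
924	6.881248e-03
926	6.806339e-03
928	6.732625e-03
930	6.660095e-03
932	6.588735e-03
934	6.518534e-03
936	6.449477e-03
938	6.381554e-03
940	6.314751e-03
942	6.249056e-03
944	6.184457e-03
946	6.120942e-03
948	6.058499e-03
950	5.997115e-03
952	5.936780e-03
954	5.877481e-03
956	5.819207e-03
958	5.761946e-03
960	5.705687e-03
962	5.650419e-03
964	5.596130e-03
966	5.542810e-03
968	5.490448e-03
970	5.439033e-03
972	5.388555e-03
974	5.339003e-03
976	5.290367e-03
978	5.242637e-03
980	5.195803e-03
982	5.149855e-03
984	5.104783e-03
986	5.060578e-03
988	5.017230e-03
990	4.974731e-03
992	4.933071e-03
994	4.892241e-03
996	4.852233e-03
998	4.813039e-03
1000	4.774648e-03
1002	4.737054e-03
1004	4.700243e-03
1006	4.664205e-03
1008	4.628926e-03
1010	4.594396e-03
1012	4.560604e-03
1014	4.527537e-03
1016	4.495187e-03
1018	4.463542e-03
1020	4.432591e-03
1022	4.402327e-03
1024	4.372737e-03
1026	4.343814e-03
1028	4.315548e-03
1030	4.287930e-03
1032	4.260952e-03
1034	4.234605e-03
1036	4.208881e-03
1038	4.183771e-03
1040	4.159269e-03
1042	4.135367e-03
1044	4.112057e-03
1046	4.089332e-03
1048	4.067185e-03
1050	4.045611e-03
1052	4.024601e-03
1054	4.004151e-03
1056	3.984254e-03
1058	3.964903e-03
1060	3.946094e-03
1062	3.927821e-03
1064	3.910078e-03
1066	3.892861e-03
1068	3.876165e-03
1070	3.859984e-03
1072	3.844314e-03
1074	3.829151e-03
1076	3.814491e-03
1078	3.800330e-03
1080	3.786663e-03
1082	3.773487e-03
1084	3.760799e-03
1086	3.748595e-03
1088	3.736872e-03
1090	3.725627e-03
1092	3.714858e-03
1094	3.704560e-03
1096	3.694733e-03
1098	3.685373e-03
1100	3.676479e-03
1102	3.668047e-03
1104	3.660067e-03
1106	3.652528e-03
1108	3.645420e-03
1110	3.638733e-03
1112	3.632455e-03
1114	3.626577e-03
1116	3.621089e-03
1118	3.615982e-03
1120	3.611245e-03
1122	3.606870e-03
1124	3.602847e-03
1126	3.599167e-03
1128	3.595821e-03
1130	3.592800e-03
1132	3.590095e-03
1134	3.587699e-03
1136	3.585602e-03
1138	3.583796e-03
1140	3.582273e-03
1142	3.581024e-03
1144	3.580041e-03
1146	3.579316e-03
1148	3.578842e-03
1150	3.578609e-03
1152	3.578611e-03
1154	3.578839e-03
1156	3.579285e-03
1158	3.579942e-03
1160	3.580802e-03
1162	3.581856e-03
1164	3.583099e-03
1166	3.584520e-03
1168	3.586114e-03
1170	3.587872e-03
1172	3.589787e-03
1174	3.591851e-03
1176	3.594056e-03
1178	3.596394e-03
1180	3.598859e-03
1182	3.601441e-03
1184	3.604135e-03
1186	3.606931e-03
1188	3.609822e-03
1190	3.612801e-03
1192	3.615859e-03
1194	3.618989e-03
1196	3.622183e-03
1198	3.625434e-03
1200	3.628733e-03
1202	3.632073e-03
1204	3.635453e-03
1206	3.638872e-03
1208	3.642329e-03
1210	3.645824e-03
1212	3.649354e-03
1214	3.652920e-03
1216	3.656521e-03
1218	3.660156e-03
1220	3.663824e-03
1222	3.667524e-03
1224	3.671256e-03
1226	3.675018e-03
1228	3.678810e-03
1230	3.682631e-03
1232	3.686480e-03
1234	3.690356e-03
1236	3.694258e-03
1238	3.698186e-03
1240	3.702138e-03
1242	3.706114e-03
1244	3.710113e-03
1246	3.714133e-03
1248	3.718175e-03
1250	3.722237e-03
1252	3.726319e-03
1254	3.730418e-03
1256	3.734536e-03
1258	3.738669e-03
1260	3.742819e-03
1262	3.746983e-03
1264	3.751162e-03
1266	3.755353e-03
1268	3.759556e-03
1270	3.763770e-03
1272	3.767995e-03
1274	3.772229e-03
1276	3.776471e-03
1278	3.780720e-03
1280	3.784976e-03
1282	3.789238e-03
1284	3.793503e-03
1286	3.797773e-03
1288	3.802045e-03
1290	3.806319e-03
1292	3.810593e-03
1294	3.814867e-03
1296	3.819139e-03
1298	3.823409e-03
1300	3.827676e-03
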