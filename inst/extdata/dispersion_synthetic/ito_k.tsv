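wavelength_nm	k
600	5.000000e-03
602	5.022374e-03
604	5.044771e-03
606	5.067212e-03
608	5.089720e-03
610	5.112316e-03
612	5.135024e-03
614	5.157865e-03
616	5.180861e-03
618	5.204035e-03
620	5.227410e-03
622	5.251006e-03
624	5.274847e-03
626	5.298954e-03
628	5.323350e-03
630	5.348057e-03
632	5.373098e-03
634	5.398494e-03
636	5.424267e-03
638	5.450441e-03
640	5.477037e-03
642	5.504077e-03
644	5.531583e-03
646	5.559579e-03
648	5.588085e-03
650	5.617125e-03
652	5.646720e-03
654	5.676893e-03
656	5.707666e-03
658	5.739060e-03
660	5.771099e-03
662	5.803805e-03
664	5.837199e-03
666	5.871305e-03
668	5.906143e-03
670	5.941737e-03
672	5.978109e-03
674	6.015280e-03
676	6.053273e-03
678	6.092111e-03
680	6.131815e-03
682	6.172408e-03
684	6.213912e-03
686	6.256349e-03
688	6.299741e-03
690	6.344111e-03
692	6.389481e-03
694	6.435873e-03
696	6.483309e-03
698	6.531811e-03
700	6.581402e-03
702	6.632104e-03
704	6.683939e-03
706	6.736929e-03
708	6.791097e-03
710	6.846465e-03
712	6.903055e-03
714	6.960888e-03
716	7.019989e-03
718	7.080378e-03
720	7.142077e-03
722	7.205110e-03
724	7.269498e-03
726	7.335264e-03
728	7.402429e-03
730	7.471016e-03
732	7.541048e-03
734	7.612545e-03
736	7.685532e-03
738	7.760029e-03
740	7.836059e-03
742	7.913644e-03
744	7.992807e-03
746	8.073570e-03
748	8.155954e-03
750	8.239983e-03
752	8.325678e-03
754	8.413061e-03
756	8.502155e-03
758	8.592982e-03
760	8.685565e-03
762	8.779925e-03
764	8.876084e-03
766	8.974065e-03
768	9.073891e-03
770	9.175582e-03
772	9.279162e-03
774	9.384653e-03
776	9.492077e-03
778	9.601456e-03
780	9.712812e-03
782	9.826168e-03
784	9.941546e-03
786	1.005897e-02
788	1.017844e-02
790	1.029996e-02
792	1.042353e-02
794	1.054913e-02
796	1.067677e-02
798	1.080643e-02
800	1.093813e-02
802	1.107184e-02
804	1.120756e-02
806	1.134530e-02
808	1.148504e-02
810	1.162679e-02
812	1.177053e-02
814	1.191626e-02
816	1.206398e-02
818	1.221368e-02
820	1.236535e-02
822	1.251901e-02
824	1.267462e-02
826	1.283221e-02
828	1.299175e-02
830	1.315324e-02
832	1.331669e-02
834	1.348208e-02
836	1.364940e-02
838	1.381867e-02
840	1.398986e-02
842	1.416298e-02
844	1.433802e-02
846	1.451498e-02
848	1.469385e-02
850	1.487462e-02
852	1.505730e-02
854	1.524188e-02
856	1.542835e-02
858	1.561670e-02
860	1.580694e-02
862	1.599906e-02
864	1.619305e-02
866	1.638892e-02
868	1.658664e-02
870	1.678623e-02
872	1.698767e-02
874	1.719096e-02
876	1.739610e-02
878	1.760308e-02
880	1.781189e-02
882	1.802254e-02
884	1.823501e-02
886	1.844931e-02
888	1.866542e-02
890	1.888334e-02
892	1.910308e-02
894	1.932462e-02
896	1.954795e-02
898	1.977308e-02
900	2.000000e-02
902	2.022871e-02
904	2.045922e-02
906	2.069155e-02
908	2.092572e-02
910	2.116175e-02
912	2.139965e-02
914	2.163945e-02
916	2.188115e-02
918	2.212479e-02
920	2.237038e-02
922	2.261793e-02
924	2.286747e-02
926	2.311901e-02
928	2.337257e-02
930	2.362817e-02
932	2.388583e-02
934	2.414556e-02
936	2.440739e-02
938	2.467132e-02
940	2.493739e-02
942	2.520561e-02
944	2.547599e-02
946	2.574856e-02
948	2.602333e-02
950	2.630032e-02
952	2.657954e-02
954	2.686103e-02
956	2.714479e-02
958	2.743085e-02
960	2.771921e-02
962	2.800991e-02
964	2.830296e-02
966	2.859837e-02
968	2.889616e-02
970	2.919636e-02
972	2.949898e-02
974	2.980404e-02
976	3.011155e-02
978	3.042154e-02
980	3.073402e-02
982	3.104902e-02
984	3.136654e-02
986	3.168662e-02
988	3.200926e-02
990	3.233448e-02
992	3.266231e-02
994	3.299275e-02
996	3.332584e-02
998	3.366158e-02
1000	3.400000e-02
1002	3.434111e-02
1004	3.468495e-02
1006	3.503154e-02
1008	3.538092e-02
1010	3.573312e-02
1012	3.608817e-02
1014	3.644609e-02
1016	3.680693e-02
1018	3.717070e-02
1020	3.753745e-02
1022	3.790720e-02
1024	3.827998e-02
1026	3.865584e-02
1028	3.903478e-02
1030	3.941685e-02
1032	3.980208e-02
1034	4.019050e-02
1036	4.058214e-02
1038	4.097703e-02
1040	4.137521e-02
1042	4.177669e-02
1044	4.218152e-02
1046	4.258972e-02
1048	4.300133e-02
1050	4.341638e-02
1052	4.383489e-02
1054	4.425690e-02
1056	4.468245e-02
1058	4.511155e-02
1060	4.554424e-02
1062	4.598056e-02
1064	4.642053e-02
1066	4.686418e-02
1068	4.731155e-02
1070	4.776266e-02
1072	4.821755e-02
1074	4.867626e-02
1076	4.913879e-02
1078	4.960520e-02
1080	5.007552e-02
1082	5.054976e-02
1084	5.102796e-02
1086	5.151017e-02
1088	5.199639e-02
1090	5.248667e-02
1092	5.298104e-02
1094	5.347953e-02
1096	5.398216e-02
1098	5.448897e-02
1100	5.500000e-02
1102	5.551525e-02
1104	5.603470e-02
1106	5.655830e-02
1108	5.708601e-02
1110	5.761777e-02
1112	5.815354e-02
1114	5.869328e-02
1116	5.923694e-02
1118	5.978447e-02
1120	6.033582e-02
1122	6.089096e-02
1124	6.144984e-02
1126	6.201240e-02
1128	6.257861e-02
1130	6.314841e-02
1132	6.372177e-02
1134	6.429863e-02
1136	6.487895e-02
1138	6.546268e-02
1140	6.604978e-02
1142	6.664020e-02
1144	6.723390e-02
1146	6.783082e-02
1148	6.843093e-02
1150	6.903417e-02
1152	6.964050e-02
1154	7.024988e-02
1156	7.086226e-02
1158	7.147759e-02
1160	7.209582e-02
1162	7.271692e-02
1164	7.334083e-02
1166	7.396751e-02
1168	7.459691e-02
1170	7.522899e-02
1172	7.586370e-02
1174	7.650099e-02
1176	7.714082e-02
1178	7.778314e-02
1180	7.842791e-02
1182	7.907508e-02
1184	7.972460e-02
1186	8.037643e-02
1188	8.103053e-02
1190	8.168683e-02
1192	8.234531e-02
1194	8.300591e-02
1196	8.366859e-02
1198	8.433330e-02
1200	8.500000e-02
1202	8.566864e-02
1204	8.633918e-02
1206	8.701158e-02
1208	8.768580e-02
1210	8.836181e-02
1212	8.903956e-02
1214	8.971902e-02
1216	9.040015e-02
1218	9.108290e-02
1220	9.176725e-02
1222	9.245315e-02
1224	9.314056e-02
1226	9.382945e-02
1228	9.451977e-02
1230	9.521149e-02
1232	9.590457e-02
1234	9.659896e-02
1236	9.729464e-02
1238	9.799155e-02
1240	9.868967e-02
1242	9.938895e-02
1244	1.000894e-01
1246	1.007909e-01
1248	1.014934e-01
1250	1.021969e-01
1252	1.029015e-01
1254	1.036069e-01
1256	1.043133e-01
1258	1.050205e-01
1260	1.057285e-01
1262	1.064372e-01
1264	1.071468e-01
1266	1.078570e-01
1268	1.085679e-01
1270	1.092794e-01
1272	1.099915e-01
1274	1.107041e-01
1276	1.114172e-01
1278	1.121308e-01
1280	1.128448e-01
1282	1.135592e-01
1284	1.142740e-01
1286	1.149891e-01
1288	1.157044e-01
1290	1.164200e-01
1292	1.171358e-01
1294	1.178517e-01
1296	1.185677e-01
1298	1.192838e-01
1300	1.200000e-01
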