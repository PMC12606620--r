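wavelength_nm	k
600	2.864789e-02
602	2.831711e-02
604	2.798987e-02
606	2.766616e-02
608	2.734598e-02
610	2.702931e-02
612	2.671616e-02
614	2.640650e-02
616	2.610032e-02
618	2.579763e-02
620	2.549840e-02
622	2.520261e-02
624	2.491027e-02
626	2.462135e-02
628	2.433583e-02
630	2.405371e-02
632	2.377496e-02
634	2.349956e-02
636	2.322751e-02
638	2.295877e-02
640	2.269333e-02
642	2.243118e-02
644	2.217228e-02
646	2.191663e-02
648	2.166420e-02
650	2.141496e-02
652	2.116890e-02
654	2.092599e-02
656	2.068621e-02
658	2.044954e-02
660	2.021595e-02
662	1.998543e-02
664	1.975794e-02
666	1.953346e-02
668	1.931198e-02
670	1.909346e-02
672	1.887787e-02
674	1.866521e-02
676	1.845543e-02
678	1.824851e-02
680	1.804444e-02
682	1.784318e-02
684	1.764470e-02
686	1.744899e-02
688	1.725602e-02
690	1.706576e-02
692	1.687818e-02
694	1.669327e-02
696	1.651099e-02
698	1.633132e-02
700	1.615423e-02
702	1.597968e-02
704	1.580759e-02
706	1.563784e-02
708	1.547034e-02
710	1.530498e-02
712	1.514168e-02
714	1.498035e-02
716	1.482089e-02
718	1.466322e-02
720	1.450726e-02
722	1.435293e-02
724	1.420015e-02
726	1.404886e-02
728	1.389897e-02
730	1.375043e-02
732	1.360316e-02
734	1.345711e-02
736	1.331220e-02
738	1.316839e-02
740	1.302561e-02
742	1.288382e-02
744	1.274295e-02
746	1.260297e-02
748	1.246382e-02
750	1.232546e-02
752	1.218785e-02
754	1.205094e-02
756	1.191469e-02
758	1.177908e-02
760	1.164405e-02
762	1.150959e-02
764	1.137565e-02
766	1.124221e-02
768	1.110925e-02
770	1.097673e-02
772	1.084463e-02
774	1.071293e-02
776	1.058161e-02
778	1.045066e-02
780	1.032004e-02
782	1.018976e-02
784	1.005980e-02
786	9.930139e-03
788	9.800793e-03
790	9.671789e-03
792	9.543154e-03
794	9.414913e-03
796	9.287095e-03
798	9.159725e-03
800	9.032829e-03
802	8.906433e-03
804	8.780561e-03
806	8.655238e-03
808	8.530488e-03
810	8.406335e-03
812	8.282802e-03
814	8.159912e-03
816	8.037687e-03
818	7.916149e-03
820	7.795319e-03
822	7.675218e-03
824	7.555867e-03
826	7.437285e-03
828	7.319493e-03
830	7.202507e-03
832	7.086348e-03
834	6.971033e-03
836	6.856579e-03
838	6.743002e-03
840	6.630320e-03
842	6.518548e-03
844	6.407700e-03
846	6.297792e-03
848	6.188838e-03
850	6.080852e-03
852	5.973845e-03
854	5.867832e-03
856	5.762823e-03
858	5.658831e-03
860	5.555865e-03
862	5.453937e-03
864	5.353056e-03
866	5.253231e-03
868	5.154471e-03
870	5.056784e-03
872	4.960178e-03
874	4.864661e-03
876	4.770237e-03
878	4.676914e-03
880	4.584698e-03
882	4.493592e-03
884	4.403602e-03
886	4.314732e-03
888	4.226985e-03
890	4.140364e-03
892	4.054872e-03
894	3.970511e-03
896	3.887282e-03
898	3.805187e-03
900	3.724226e-03
902	3.644399e-03
904	3.565708e-03
906	3.488153e-03
908	3.411734e-03
910	3.336451e-03
912	3.262302e-03
914	3.189287e-03
916	3.117403e-03
918	3.046648e-03
920	2.977018e-03
922	2.908510e-03
924	2.841121e-03
926	2.774845e-03
928	2.709678e-03
930	2.645615e-03
932	2.582650e-03
934	2.520777e-03
936	2.459990e-03
938	2.400281e-03
940	2.341644e-03
942	2.284071e-03
944	2.227554e-03
946	2.172086e-03
948	2.117657e-03
950	2.064260e-03
952	2.011884e-03
954	1.960522e-03
956	1.910162e-03
958	1.860797e-03
960	1.812415e-03
962	1.765006e-03
964	1.718560e-03
966	1.673067e-03
968	1.628516e-03
970	1.584896e-03
972	1.542196e-03
974	1.500404e-03
976	1.459509e-03
978	1.419501e-03
980	1.380366e-03
982	1.342094e-03
984	1.304674e-03
986	1.268092e-03
988	1.232337e-03
990	1.197398e-03
992	1.163262e-03
994	1.129917e-03
996	1.097351e-03
998	1.065551e-03
1000	1.034507e-03
1002	1.004205e-03
1004	9.746287e-04
1006	9.457629e-04
1008	9.175920e-04
1010	8.901010e-04
1012	8.632753e-04
1014	8.371008e-04
1016	8.115639e-04
1018	7.866513e-04
1020	7.623502e-04
1022	7.386478e-04
1024	7.155321e-04
1026	6.929911e-04
1028	6.710132e-04
1030	6.495873e-04
1032	6.287022e-04
1034	6.083472e-04
1036	5.885120e-04
1038	5.691861e-04
1040	5.503597e-04
1042	5.320229e-04
1044	5.141661e-04
1046	4.967800e-04
1048	4.798553e-04
1050	4.633830e-04
1052	4.473544e-04
1054	4.317606e-04
1056	4.165932e-04
1058	4.018438e-04
1060	3.875041e-04
1062	3.735661e-04
1064	3.600217e-04
1066	3.468630e-04
1068	3.340824e-04
1070	3.216722e-04
1072	3.096248e-04
1074	2.979329e-04
1076	2.865891e-04
1078	2.755862e-04
1080	2.649170e-04
1082	2.545745e-04
1084	2.445517e-04
1086	2.348418e-04
1088	2.254379e-04
1090	2.163334e-04
1092	2.075215e-04
1094	1.989957e-04
1096	1.907495e-04
1098	1.827766e-04
1100	1.750704e-04
1102	1.676256e-04
1104	1.604390e-04
1106	1.535080e-04
1108	1.468290e-04
1110	1.403983e-04
1112	1.342115e-04
1114	1.282639e-04
1116	1.225504e-04
1118	1.170657e-04
1120	1.118043e-04
1122	1.067602e-04
1124	1.019276e-04
1126	9.730039e-05
1128	9.287236e-05
1130	8.863729e-05
1132	8.458892e-05
1134	8.072097e-05
1136	7.702720e-05
1138	7.350140e-05
1140	7.013742e-05
1142	6.692917e-05
1144	6.387069e-05
1146	6.095610e-05
1148	5.817964e-05
1150	5.553568e-05
1152	5.301872e-05
1154	5.062342e-05
1156	4.834456e-05
1158	4.617709e-05
1160	4.411612e-05
1162	4.215690e-05
1164	4.029486e-05
1166	3.852557e-05
1168	3.684477e-05
1170	3.524837e-05
1172	3.373241e-05
1174	3.229311e-05
1176	3.092683e-05
1178	2.963008e-05
1180	2.839953e-05
1182	2.723198e-05
1184	2.612438e-05
1186	2.507381e-05
1188	2.407749e-05
1190	2.313275e-05
1192	2.223709e-05
1194	2.138807e-05
1196	2.058342e-05
1198	1.982095e-05
1200	1.909859e-05
1202	1.841428e-05
1204	1.776566e-05
1206	1.715045e-05
1208	1.656654e-05
1210	1.601197e-05
1212	1.548490e-05
1214	1.498364e-05
1216	1.450661e-05
1218	1.405234e-05
1220	1.361946e-05
1222	1.320669e-05
1224	1.281284e-05
1226	1.243679e-05
1228	1.207751e-05
1230	1.173403e-05
1232	1.140543e-05
1234	1.109087e-05
1236	1.078955e-05
1238	1.050071e-05
1240	1.022367e-05
1242	9.957770e-06
1244	9.702385e-06
1246	9.456940e-06
1248	9.220890e-06
1250	8.993725e-06
1252	8.774963e-06
1254	8.564150e-06
1256	8.360861e-06
1258	8.164693e-06
1260	7.975267e-06
1262	7.792226e-06
1264	7.615233e-06
1266	7.443970e-06
1268	7.278135e-06
1270	7.117446e-06
1272	6.961634e-06
1274	6.810446e-06
1276	6.663642e-06
1278	6.520996e-06
1280	6.382293e-06
1282	6.247330e-06
1284	6.115917e-06
1286	5.987871e-06
1288	5.863021e-06
1290	5.741205e-06
1292	5.622269e-06
1294	5.506068e-06
1296	5.392464e-06
1298	5.281327e-06
1300	5.172536e-06
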