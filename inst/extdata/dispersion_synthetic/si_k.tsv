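wavelength_nm	k
600	1.991028e-02
602	1.965692e-02
604	1.940659e-02
606	1.915928e-02
608	1.891497e-02
610	1.867364e-02
612	1.843529e-02
614	1.819990e-02
616	1.796744e-02
618	1.773791e-02
620	1.751128e-02
622	1.728754e-02
624	1.706667e-02
626	1.684864e-02
628	1.663345e-02
630	1.642107e-02
632	1.621147e-02
634	1.600465e-02
636	1.580057e-02
638	1.559922e-02
640	1.540058e-02
642	1.520462e-02
644	1.501131e-02
646	1.482065e-02
648	1.463260e-02
650	1.444715e-02
652	1.426426e-02
654	1.408392e-02
656	1.390610e-02
658	1.373078e-02
660	1.355794e-02
662	1.338754e-02
664	1.321958e-02
666	1.305402e-02
668	1.289083e-02
670	1.273001e-02
672	1.257151e-02
674	1.241532e-02
676	1.226141e-02
678	1.210976e-02
680	1.196035e-02
682	1.181315e-02
684	1.166813e-02
686	1.152527e-02
688	1.138455e-02
690	1.124595e-02
692	1.110943e-02
694	1.097499e-02
696	1.084258e-02
698	1.071219e-02
700	1.058380e-02
702	1.045738e-02
704	1.033284e-02
706	1.021013e-02
708	1.008917e-02
710	9.969894e-03
712	9.852228e-03
714	9.736113e-03
716	9.621485e-03
718	9.508286e-03
720	9.396457e-03
722	9.285943e-03
724	9.176690e-03
726	9.068648e-03
728	8.961765e-03
730	8.855995e-03
732	8.751291e-03
734	8.647609e-03
736	8.544907e-03
738	8.443145e-03
740	8.342282e-03
742	8.242281e-03
744	8.143108e-03
746	8.044726e-03
748	7.947104e-03
750	7.850210e-03
752	7.754014e-03
754	7.658487e-03
756	7.563604e-03
758	7.469337e-03
760	7.375663e-03
762	7.282558e-03
764	7.190002e-03
766	7.097972e-03
768	7.006452e-03
770	6.915421e-03
772	6.824865e-03
774	6.734766e-03
776	6.645112e-03
778	6.555888e-03
780	6.467082e-03
782	6.378685e-03
784	6.290685e-03
786	6.203075e-03
788	6.115857e-03
790	6.029047e-03
792	5.942657e-03
794	5.856703e-03
796	5.771198e-03
798	5.686156e-03
800	5.601591e-03
802	5.517514e-03
804	5.433940e-03
806	5.350880e-03
808	5.268348e-03
810	5.186354e-03
812	5.104912e-03
814	5.024032e-03
816	4.943725e-03
818	4.864003e-03
820	4.784876e-03
822	4.706355e-03
824	4.628449e-03
826	4.551168e-03
828	4.474522e-03
830	4.398520e-03
832	4.323170e-03
834	4.248481e-03
836	4.174462e-03
838	4.101119e-03
840	4.028461e-03
842	3.956495e-03
844	3.885228e-03
846	3.814666e-03
848	3.744816e-03
850	3.675683e-03
852	3.607274e-03
854	3.539593e-03
856	3.472646e-03
858	3.406437e-03
860	3.340971e-03
862	3.276251e-03
864	3.212282e-03
866	3.149066e-03
868	3.086608e-03
870	3.024909e-03
872	2.963972e-03
874	2.903800e-03
876	2.844393e-03
878	2.785755e-03
880	2.727886e-03
882	2.670787e-03
884	2.614458e-03
886	2.558901e-03
888	2.504115e-03
890	2.450100e-03
892	2.396855e-03
894	2.344380e-03
896	2.292674e-03
898	2.241736e-03
900	2.191564e-03
902	2.142154e-03
904	2.093496e-03
906	2.045578e-03
908	1.998389e-03
910	1.951920e-03
912	1.906160e-03
914	1.861099e-03
916	1.816730e-03
918	1.773045e-03
920	1.730034e-03
922	1.687692e-03
924	1.646012e-03
926	1.604987e-03
928	1.564610e-03
930	1.524878e-03
932	1.485783e-03
934	1.447321e-03
936	1.409488e-03
938	1.372279e-03
940	1.335689e-03
942	1.299715e-03
944	1.264353e-03
946	1.229598e-03
948	1.195449e-03
950	1.161900e-03
952	1.128949e-03
954	1.096593e-03
956	1.064828e-03
958	1.033652e-03
960	1.003062e-03
962	9.730534e-04
964	9.436247e-04
966	9.147725e-04
968	8.864937e-04
970	8.587854e-04
972	8.316444e-04
974	8.050675e-04
976	7.790516e-04
978	7.535933e-04
980	7.286893e-04
982	7.043359e-04
984	6.805296e-04
986	6.572667e-04
988	6.345432e-04
990	6.123551e-04
992	5.906984e-04
994	5.695686e-04
996	5.489613e-04
998	5.288720e-04
1000	5.092958e-04
1002	4.902269e-04
1004	4.716555e-04
1006	4.535717e-04
1008	4.359660e-04
1010	4.188296e-04
1012	4.021544e-04
1014	3.859323e-04
1016	3.701562e-04
1018	3.548190e-04
1020	3.399139e-04
1022	3.254348e-04
1024	3.113753e-04
1026	2.977296e-04
1028	2.844921e-04
1030	2.716570e-04
1032	2.592188e-04
1034	2.471723e-04
1036	2.355120e-04
1038	2.242325e-04
1040	2.133285e-04
1042	2.027947e-04
1044	1.926256e-04
1046	1.828158e-04
1048	1.733596e-04
1050	1.642515e-04
1052	1.554856e-04
1054	1.470561e-04
1056	1.389569e-04
1058	1.311820e-04
1060	1.237251e-04
1062	1.165797e-04
1064	1.097393e-04
1066	1.031973e-04
1068	9.694682e-05
1070	9.098091e-05
1072	8.529253e-05
1074	7.987450e-05
1076	7.471954e-05
1078	6.982028e-05
1080	6.516925e-05
1082	6.075893e-05
1084	5.658173e-05
1086	5.263001e-05
1088	4.889610e-05
1090	4.537232e-05
1092	4.205099e-05
1094	3.892444e-05
1096	3.598504e-05
1098	3.322518e-05
1100	3.063733e-05
1102	2.821426e-05
1104	2.594960e-05
1106	2.383693e-05
1108	2.186962e-05
1110	2.004089e-05
1112	1.834386e-05
1114	1.677168e-05
1116	1.531748e-05
1118	1.397452e-05
1120	1.273617e-05
1122	1.159595e-05
1124	1.054759e-05
1126	9.585017e-06
1128	8.702395e-06
1130	7.894134e-06
1132	7.154898e-06
1134	6.479615e-06
1136	5.863478e-06
1138	5.301944e-06
1140	4.790737e-06
1142	4.325839e-06
1144	3.903486e-06
1146	3.520163e-06
1148	3.172592e-06
1150	2.857725e-06
1152	2.572735e-06
1154	2.315003e-06
1156	2.082109e-06
1158	1.871820e-06
1160	1.682082e-06
1162	1.511005e-06
1164	1.356858e-06
1166	1.218051e-06
1168	1.093133e-06
1170	9.807773e-07
1172	8.797741e-07
1174	7.890216e-07
1176	7.075172e-07
1178	6.343501e-07
1180	5.686937e-07
1182	5.097988e-07
1184	4.569867e-07
1186	4.096437e-07
1188	3.672149e-07
1190	3.291997e-07
1192	2.951460e-07
1194	2.646466e-07
1196	2.373347e-07
1198	2.128801e-07
1200	1.909859e-07
1202	1.713843e-07
1204	1.538312e-07
1206	1.381083e-07
1208	1.240208e-07
1210	1.113952e-07
1212	1.000769e-07
1214	8.992790e-08
1216	8.082505e-08
1218	7.265849e-08
1220	6.533011e-08
1222	5.875233e-08
1224	5.284685e-08
1226	4.754376e-08
1228	4.278051e-08
1230	3.850122e-08
1232	3.465588e-08
1234	3.119975e-08
1236	2.809278e-08
1238	2.529915e-08
1240	2.278675e-08
1242	2.052684e-08
1244	1.849366e-08
1246	1.666412e-08
1248	1.501754e-08
1250	1.353535e-08
1252	1.220093e-08
1254	1.099935e-08
1256	9.917193e-09
1258	8.942456e-09
1260	8.064338e-09
1262	7.273148e-09
1264	6.560180e-09
1266	5.917613e-09
1268	5.338420e-09
1270	4.816284e-09
1272	4.345528e-09
1274	3.921047e-09
1276	3.538247e-09
1278	3.193001e-09
1280	2.881591e-09
1282	2.600675e-09
1284	2.347243e-09
1286	2.118586e-09
1288	1.912266e-09
1290	1.726084e-09
1292	1.558065e-09
1294	1.406425e-09
1296	1.269559e-09
1298	1.146021e-09
1300	1.034507e-09
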