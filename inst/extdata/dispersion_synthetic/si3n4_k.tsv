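wavelength_nm	k
600	0.000000e+00
602	0.000000e+00
604	0.000000e+00
606	0.000000e+00
608	0.000000e+00
610	0.000000e+00
612	0.000000e+00
614	0.000000e+00
616	0.000000e+00
618	0.000000e+00
620	0.000000e+00
622	0.000000e+00
624	0.000000e+00
626	0.000000e+00
628	0.000000e+00
630	0.000000e+00
632	0.000000e+00
634	0.000000e+00
636	0.000000e+00
638	0.000000e+00
640	0.000000e+00
642	0.000000e+00
644	0.000000e+00
646	0.000000e+00
648	0.000000e+00
650	0.000000e+00
652	0.000000e+00
654	0.000000e+00
656	0.000000e+00
658	0.000000e+00
660	0.000000e+00
662	0.000000e+00
664	0.000000e+00
666	0.000000e+00
668	0.000000e+00
670	0.000000e+00
672	0.000000e+00
674	0.000000e+00
676	0.000000e+00
678	0.000000e+00
680	0.000000e+00
682	0.000000e+00
684	0.000000e+00
686	0.000000e+00
688	0.000000e+00
690	0.000000e+00
692	0.000000e+00
694	0.000000e+00
696	0.000000e+00
698	0.000000e+00
700	0.000000e+00
702	0.000000e+00
704	0.000000e+00
706	0.000000e+00
708	0.000000e+00
710	0.000000e+00
712	0.000000e+00
714	0.000000e+00
716	0.000000e+00
718	0.000000e+00
720	0.000000e+00
722	0.000000e+00
724	0.000000e+00
726	0.000000e+00
728	0.000000e+00
730	0.000000e+00
732	0.000000e+00
734	0.000000e+00
736	0.000000e+00
738	0.000000e+00
740	0.000000e+00
742	0.000000e+00
744	0.000000e+00
746	0.000000e+00
748	0.000000e+00
750	0.000000e+00
752	0.000000e+00
754	0.000000e+00
756	0.000000e+00
758	0.000000e+00
760	0.000000e+00
762	0.000000e+00
764	0.000000e+00
766	0.000000e+00
768	0.000000e+00
770	0.000000e+00
772	0.000000e+00
774	0.000000e+00
776	0.000000e+00
778	0.000000e+00
780	0.000000e+00
782	0.000000e+00
784	0.000000e+00
786	0.000000e+00
788	0.000000e+00
790	0.000000e+00
792	0.000000e+00
794	0.000000e+00
796	0.000000e+00
798	0.000000e+00
800	0.000000e+00
802	0.000000e+00
804	0.000000e+00
806	0.000000e+00
808	0.000000e+00
810	0.000000e+00
812	0.000000e+00
814	0.000000e+00
816	0.000000e+00
818	0.000000e+00
820	0.000000e+00
822	0.000000e+00
824	0.000000e+00
826	0.000000e+00
828	0.000000e+00
830	0.000000e+00
832	0.000000e+00
834	0.000000e+00
836	0.000000e+00
838	0.000000e+00
840	0.000000e+00
842	0.000000e+00
844	0.000000e+00
846	0.000000e+00
848	0.000000e+00
850	0.000000e+00
852	0.000000e+00
854	0.000000e+00
856	0.000000e+00
858	0.000000e+00
860	0.000000e+00
862	0.000000e+00
864	0.000000e+00
866	0.000000e+00
868	0.000000e+00
870	0.000000e+00
872	0.000000e+00
874	0.000000e+00
876	0.000000e+00
878	0.000000e+00
880	0.000000e+00
882	0.000000e+00
884	0.000000e+00
886	0.000000e+00
888	0.000000e+00
890	0.000000e+00
892	0.000000e+00
894	0.000000e+00
896	0.000000e+00
898	0.000000e+00
900	0.000000e+00
902	0.000000e+00
904	0.000000e+00
906	0.000000e+00
908	0.000000e+00
910	0.000000e+00
912	0.000000e+00
914	0.000000e+00
916	0.000000e+00
918	0.000000e+00
920	0.000000e+00
922	0.000000e+00
924	0.000000e+00
926	0.000000e+00
928	0.000000e+00
930	0.000000e+00
932	0.000000e+00
934	0.000000e+00
936	0.000000e+00
938	0.000000e+00
940	0.000000e+00
942	0.000000e+00
944	0.000000e+00
946	0.000000e+00
948	0.000000e+00
950	0.000000e+00
952	0.000000e+00
954	0.000000e+00
956	0.000000e+00
958	0.000000e+00
960	0.000000e+00
962	0.000000e+00
964	0.000000e+00
966	0.000000e+00
968	0.000000e+00
970	0.000000e+00
972	0.000000e+00
974	0.000000e+00
976	0.000000e+00
978	0.000000e+00
980	0.000000e+00
982	0.000000e+00
984	0.000000e+00
986	0.000000e+00
988	0.000000e+00
990	0.000000e+00
992	0.000000e+00
994	0.000000e+00
996	0.000000e+00
998	0.000000e+00
1000	0.000000e+00
1002	0.000000e+00
1004	0.000000e+00
1006	0.000000e+00
1008	0.000000e+00
1010	0.000000e+00
1012	0.000000e+00
1014	0.000000e+00
1016	0.000000e+00
1018	0.000000e+00
1020	0.000000e+00
1022	0.000000e+00
1024	0.000000e+00
1026	0.000000e+00
1028	0.000000e+00
1030	0.000000e+00
1032	0.000000e+00
1034	0.000000e+00
1036	0.000000e+00
1038	0.000000e+00
1040	0.000000e+00
1042	0.000000e+00
1044	0.000000e+00
1046	0.000000e+00
1048	0.000000e+00
1050	0.000000e+00
1052	0.000000e+00
1054	0.000000e+00
1056	0.000000e+00
1058	0.000000e+00
1060	0.000000e+00
1062	0.000000e+00
1064	0.000000e+00
1066	0.000000e+00
1068	0.000000e+00
1070	0.000000e+00
1072	0.000000e+00
1074	0.000000e+00
1076	0.000000e+00
1078	0.000000e+00
1080	0.000000e+00
1082	0.000000e+00
1084	0.000000e+00
1086	0.000000e+00
1088	0.000000e+00
1090	0.000000e+00
1092	0.000000e+00
1094	0.000000e+00
1096	0.000000e+00
1098	0.000000e+00
1100	0.000000e+00
1102	0.000000e+00
1104	0.000000e+00
1106	0.000000e+00
1108	0.000000e+00
1110	0.000000e+00
1112	0.000000e+00
1114	0.000000e+00
1116	0.000000e+00
1118	0.000000e+00
1120	0.000000e+00
1122	0.000000e+00
1124	0.000000e+00
1126	0.000000e+00
1128	0.000000e+00
1130	0.000000e+00
1132	0.000000e+00
1134	0.000000e+00
1136	0.000000e+00
1138	0.000000e+00
1140	0.000000e+00
1142	0.000000e+00
1144	0.000000e+00
1146	0.000000e+00
1148	0.000000e+00
1150	0.000000e+00
1152	0.000000e+00
1154	0.000000e+00
1156	0.000000e+00
1158	0.000000e+00
1160	0.000000e+00
1162	0.000000e+00
1164	0.000000e+00
1166	0.000000e+00
1168	0.000000e+00
1170	0.000000e+00
1172	0.000000e+00
1174	0.000000e+00
1176	0.000000e+00
1178	0.000000e+00
1180	0.000000e+00
1182	0.000000e+00
1184	0.000000e+00
1186	0.000000e+00
1188	0.000000e+00
1190	0.000000e+00
1192	0.000000e+00
1194	0.000000e+00
1196	0.000000e+00
1198	0.000000e+00
1200	0.000000e+00
1202	0.000000e+00
1204	0.000000e+00
1206	0.000000e+00
1208	0.000000e+00
1210	0.000000e+00
1212	0.000000e+00
1214	0.000000e+00
1216	0.000000e+00
1218	0.000000e+00
1220	0.000000e+00
1222	0.000000e+00
1224	0.000000e+00
1226	0.000000e+00
1228	0.000000e+00
1230	0.000000e+00
1232	0.000000e+00
1234	0.000000e+00
1236	0.000000e+00
1238	0.000000e+00
1240	0.000000e+00
1242	0.000000e+00
1244	0.000000e+00
1246	0.000000e+00
1248	0.000000e+00
1250	0.000000e+00
1252	0.000000e+00
1254	0.000000e+00
1256	0.000000e+00
1258	0.000000e+00
1260	0.000000e+00
1262	0.000000e+00
1264	0.000000e+00
1266	0.000000e+00
1268	0.000000e+00
1270	0.000000e+00
1272	0.000000e+00
1274	0.000000e+00
1276	0.000000e+00
1278	0.000000e+00
1280	0.000000e+00
1282	0.000000e+00
1284	0.000000e+00
1286	0.000000e+00
1288	0.000000e+00
1290	0.000000e+00
1292	0.000000e+00
1294	0.000000e+00
1296	0.000000e+00
1298	0.000000e+00
1300	0.000000e+00
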