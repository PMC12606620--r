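wavelength_nm	n
600	2.160000
602	2.159655
604	2.159310
606	2.158965
608	2.158620
610	2.158275
612	2.157930
614	2.157585
616	2.157241
618	2.156896
620	2.156552
622	2.156208
624	2.155864
626	2.155521
628	2.155178
630	2.154835
632	2.154492
634	2.154150
636	2.153809
638	2.153467
640	2.153126
642	2.152786
644	2.152446
646	2.152106
648	2.151767
650	2.151429
652	2.151091
654	2.150753
656	2.150416
658	2.150080
660	2.149745
662	2.149410
664	2.149076
666	2.148742
668	2.148410
670	2.148078
672	2.147747
674	2.147416
676	2.147087
678	2.146758
680	2.146430
682	2.146103
684	2.145777
686	2.145452
688	2.145128
690	2.144805
692	2.144482
694	2.144161
696	2.143841
698	2.143522
700	2.143204
702	2.142887
704	2.142571
706	2.142257
708	2.141943
710	2.141631
712	2.141320
714	2.141011
716	2.140702
718	2.140395
720	2.140089
722	2.139784
724	2.139481
726	2.139179
728	2.138879
730	2.138580
732	2.138282
734	2.137986
736	2.137692
738	2.137399
740	2.137107
742	2.136817
744	2.136529
746	2.136242
748	2.135957
750	2.135673
752	2.135391
754	2.135111
756	2.134833
758	2.134556
760	2.134281
762	2.134007
764	2.133736
766	2.133466
768	2.133199
770	2.132933
772	2.132669
774	2.132407
776	2.132146
778	2.131888
780	2.131632
782	2.131378
784	2.131125
786	2.130875
788	2.130627
790	2.130381
792	2.130137
794	2.129895
796	2.129655
798	2.129416
800	2.129180
802	2.128946
804	2.128714
806	2.128483
808	2.128255
810	2.128028
812	2.127804
814	2.127581
816	2.127360
818	2.127140
820	2.126923
822	2.126708
824	2.126494
826	2.126282
828	2.126071
830	2.125863
832	2.125656
834	2.125451
836	2.125248
838	2.125046
840	2.124846
842	2.124648
844	2.124451
846	2.124256
848	2.124063
850	2.123871
852	2.123681
854	2.123492
856	2.123305
858	2.123119
860	2.122935
862	2.122753
864	2.122572
866	2.122392
868	2.122214
870	2.122037
872	2.121862
874	2.121689
876	2.121516
878	2.121345
880	2.121176
882	2.121008
884	2.120841
886	2.120675
888	2.120511
890	2.120348
892	2.120187
894	2.120027
896	2.119868
898	2.119710
900	2.119554
902	2.119398
904	2.119244
906	2.119092
908	2.118940
910	2.118790
912	2.118640
914	2.118492
916	2.118345
918	2.118199
920	2.118054
922	2.117911
924	2.117768
926	2.117627
928	2.117486
930	2.117346
932	2.117208
934	2.117070
936	2.116934
938	2.116798
940	2.116664
942	2.116530
944	2.116397
946	2.116266
948	2.116135
950	2.116005
952	2.115876
954	2.115747
956	2.115620
958	2.115493
960	2.115367
962	2.115242
964	2.115118
966	2.114995
968	2.114872
970	2.114750
972	2.114629
974	2.114508
976	2.114388
978	2.114269
980	2.114151
982	2.114033
984	2.113916
986	2.113799
988	2.113683
990	2.113568
992	2.113453
994	2.113339
996	2.113226
998	2.113113
1000	2.113000
1002	2.112888
1004	2.112776
1006	2.112665
1008	2.112555
1010	2.112445
1012	2.112335
1014	2.112226
1016	2.112118
1018	2.112010
1020	2.111902
1022	2.111795
1024	2.111688
1026	2.111582
1028	2.111477
1030	2.111371
1032	2.111267
1034	2.111162
1036	2.111058
1038	2.110955
1040	2.110852
1042	2.110750
1044	2.110648
1046	2.110546
1048	2.110445
1050	2.110344
1052	2.110244
1054	2.110144
1056	2.110044
1058	2.109945
1060	2.109847
1062	2.109748
1064	2.109650
1066	2.109553
1068	2.109456
1070	2.109359
1072	2.109263
1074	2.109167
1076	2.109072
1078	2.108977
1080	2.108882
1082	2.108788
1084	2.108694
1086	2.108600
1088	2.108507
1090	2.108414
1092	2.108321
1094	2.108229
1096	2.108137
1098	2.108046
1100	2.107955
1102	2.107864
1104	2.107774
1106	2.107684
1108	2.107594
1110	2.107504
1112	2.107415
1114	2.107327
1116	2.107238
1118	2.107150
1120	2.107062
1122	2.106975
1124	2.106887
1126	2.106800
1128	2.106714
1130	2.106627
1132	2.106541
1134	2.106456
1136	2.106370
1138	2.106285
1140	2.106200
1142	2.106115
1144	2.106031
1146	2.105947
1148	2.105863
1150	2.105779
1152	2.105696
1154	2.105613
1156	2.105530
1158	2.105448
1160	2.105365
1162	2.105283
1164	2.105201
1166	2.105120
1168	2.105038
1170	2.104957
1172	2.104876
1174	2.104795
1176	2.104715
1178	2.104634
1180	2.104554
1182	2.104474
1184	2.104395
1186	2.104315
1188	2.104236
1190	2.104157
1192	2.104078
1194	2.103999
1196	2.103921
1198	2.103842
1200	2.103764
1202	2.103686
1204	2.103608
1206	2.103530
1208	2.103453
1210	2.103375
1212	2.103298
1214	2.103221
1216	2.103144
1218	2.103067
1220	2.102991
1222	2.102914
1224	2.102838
1226	2.102761
1228	2.102685
1230	2.102609
1232	2.102533
1234	2.102458
1236	2.102382
1238	2.102306
1240	2.102231
1242	2.102156
1244	2.102080
1246	2.102005
1248	2.101930
1250	2.101855
1252	2.101780
1254	2.101706
1256	2.101631
1258	2.101556
1260	2.101482
1262	2.101407
1264	2.101333
1266	2.101258
1268	2.101184
1270	2.101110
1272	2.101036
1274	2.100961
1276	2.100887
1278	2.100813
1280	2.100739
1282	2.100665
1284	2.100591
1286	2.100517
1288	2.100443
1290	2.100369
1292	2.100295
1294	2.100222
1296	2.100148
1298	2.100074
1300	2.100000
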