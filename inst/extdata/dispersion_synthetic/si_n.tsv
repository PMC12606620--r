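wavelength_nm	n
600	3.939000
602	3.935309
604	3.931620
606	3.927932
608	3.924247
610	3.920565
612	3.916889
614	3.913218
616	3.909553
618	3.905896
620	3.902248
622	3.898609
624	3.894980
626	3.891363
628	3.887757
630	3.884165
632	3.880587
634	3.877024
636	3.873477
638	3.869946
640	3.866434
642	3.862940
644	3.859466
646	3.856013
648	3.852581
650	3.849172
652	3.845786
654	3.842425
656	3.839088
658	3.835779
660	3.832496
662	3.829241
664	3.826016
666	3.822821
668	3.819656
670	3.816524
672	3.813424
674	3.810358
676	3.807327
678	3.804331
680	3.801372
682	3.798450
684	3.795567
686	3.792724
688	3.789920
690	3.787158
692	3.784439
694	3.781762
696	3.779129
698	3.776542
700	3.774000
702	3.771505
704	3.769056
706	3.766651
708	3.764291
710	3.761973
712	3.759697
714	3.757461
716	3.755265
718	3.753108
720	3.750988
722	3.748905
724	3.746857
726	3.744843
728	3.742863
730	3.740915
732	3.738999
734	3.737113
736	3.735255
738	3.733426
740	3.731625
742	3.729849
744	3.728098
746	3.726371
748	3.724667
750	3.722985
752	3.721324
754	3.719683
756	3.718060
758	3.716456
760	3.714868
762	3.713295
764	3.711737
766	3.710193
768	3.708661
770	3.707141
772	3.705631
774	3.704131
776	3.702639
778	3.701154
780	3.699676
782	3.698202
784	3.696733
786	3.695267
788	3.693804
790	3.692344
792	3.690886
794	3.689432
796	3.687981
798	3.686533
800	3.685089
802	3.683648
804	3.682211
806	3.680777
808	3.679348
810	3.677923
812	3.676501
814	3.675085
816	3.673672
818	3.672264
820	3.670861
822	3.669463
824	3.668069
826	3.666681
828	3.665298
830	3.663920
832	3.662547
834	3.661180
836	3.659819
838	3.658463
840	3.657114
842	3.655770
844	3.654433
846	3.653102
848	3.651778
850	3.650459
852	3.649148
854	3.647843
856	3.646546
858	3.645255
860	3.643972
862	3.642696
864	3.641427
866	3.640166
868	3.638912
870	3.637666
872	3.636429
874	3.635199
876	3.633977
878	3.632764
880	3.631559
882	3.630363
884	3.629175
886	3.627996
888	3.626826
890	3.625665
892	3.624513
894	3.623371
896	3.622238
898	3.621114
900	3.620000
902	3.618896
904	3.617801
906	3.616716
908	3.615641
910	3.614575
912	3.613519
914	3.612471
916	3.611433
918	3.610404
920	3.609384
922	3.608373
924	3.607371
926	3.606378
928	3.605393
930	3.604417
932	3.603449
934	3.602490
936	3.601539
938	3.600596
940	3.599662
942	3.598735
944	3.597817
946	3.596906
948	3.596004
950	3.595109
952	3.594221
954	3.593342
956	3.592469
958	3.591604
960	3.590747
962	3.589897
964	3.589053
966	3.588217
968	3.587388
970	3.586566
972	3.585750
974	3.584942
976	3.584139
978	3.583344
980	3.582555
982	3.581772
984	3.580995
986	3.580225
988	3.579461
990	3.578703
992	3.577951
994	3.577205
996	3.576464
998	3.575729
1000	3.575000
1002	3.574276
1004	3.573558
1006	3.572845
1008	3.572138
1010	3.571436
1012	3.570740
1014	3.570049
1016	3.569363
1018	3.568682
1020	3.568007
1022	3.567337
1024	3.566672
1026	3.566013
1028	3.565358
1030	3.564709
1032	3.564065
1034	3.563426
1036	3.562792
1038	3.562163
1040	3.561539
1042	3.560919
1044	3.560305
1046	3.559696
1048	3.559092
1050	3.558492
1052	3.557898
1054	3.557308
1056	3.556723
1058	3.556142
1060	3.555566
1062	3.554995
1064	3.554429
1066	3.553867
1068	3.553310
1070	3.552758
1072	3.552210
1074	3.551666
1076	3.551127
1078	3.550593
1080	3.550063
1082	3.549537
1084	3.549016
1086	3.548499
1088	3.547986
1090	3.547478
1092	3.546974
1094	3.546474
1096	3.545979
1098	3.545487
1100	3.545000
1102	3.544517
1104	3.544038
1106	3.543563
1108	3.543092
1110	3.542625
1112	3.542162
1114	3.541702
1116	3.541247
1118	3.540795
1120	3.540347
1122	3.539903
1124	3.539462
1126	3.539025
1128	3.538592
1130	3.538162
1132	3.537736
1134	3.537313
1136	3.536893
1138	3.536477
1140	3.536064
1142	3.535654
1144	3.535248
1146	3.534845
1148	3.534445
1150	3.534048
1152	3.533654
1154	3.533263
1156	3.532875
1158	3.532489
1160	3.532107
1162	3.531728
1164	3.531351
1166	3.530977
1168	3.530606
1170	3.530238
1172	3.529872
1174	3.529509
1176	3.529148
1178	3.528789
1180	3.528434
1182	3.528080
1184	3.527729
1186	3.527380
1188	3.527034
1190	3.526690
1192	3.526347
1194	3.526007
1196	3.525670
1198	3.525334
1200	3.525000
1202	3.524668
1204	3.524338
1206	3.524010
1208	3.523684
1210	3.523360
1212	3.523037
1214	3.522716
1216	3.522397
1218	3.522080
1220	3.521764
1222	3.521450
1224	3.521137
1226	3.520825
1228	3.520516
1230	3.520207
1232	3.519900
1234	3.519595
1236	3.519290
1238	3.518987
1240	3.518685
1242	3.518384
1244	3.518085
1246	3.517786
1248	3.517489
1250	3.517192
1252	3.516897
1254	3.516603
1256	3.516309
1258	3.516016
1260	3.515724
1262	3.515433
1264	3.515143
1266	3.514853
1268	3.514564
1270	3.514276
1272	3.513988
1274	3.513701
1276	3.513415
1278	3.513128
1280	3.512843
1282	3.512557
1284	3.512272
1286	3.511987
1288	3.511703
1290	3.511419
1292	3.511135
1294	3.510851
1296	3.510567
1298	3.510284
1300	3.510000
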