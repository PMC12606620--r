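wavelength_nm	n
600	1.930000
602	1.928604
604	1.927208
606	1.925812
608	1.924415
610	1.923019
612	1.921623
614	1.920227
616	1.918830
618	1.917434
620	1.916037
622	1.914640
624	1.913244
626	1.911847
628	1.910450
630	1.909053
632	1.907656
634	1.906258
636	1.904861
638	1.903463
640	1.902065
642	1.900667
644	1.899269
646	1.897870
648	1.896471
650	1.895072
652	1.893673
654	1.892274
656	1.890874
658	1.889474
660	1.888074
662	1.886674
664	1.885273
666	1.883872
668	1.882471
670	1.881069
672	1.879667
674	1.878265
676	1.876862
678	1.875459
680	1.874056
682	1.872652
684	1.871248
686	1.869843
688	1.868438
690	1.867033
692	1.865627
694	1.864221
696	1.862815
698	1.861407
700	1.860000
702	1.858592
704	1.857184
706	1.855775
708	1.854366
710	1.852956
712	1.851546
714	1.850136
716	1.848725
718	1.847314
720	1.845903
722	1.844491
724	1.843079
726	1.841667
728	1.840255
730	1.838843
732	1.837430
734	1.836017
736	1.834605
738	1.833192
740	1.831778
742	1.830365
744	1.828952
746	1.827539
748	1.826125
750	1.824712
752	1.823299
754	1.821886
756	1.820473
758	1.819059
760	1.817646
762	1.816234
764	1.814821
766	1.813408
768	1.811996
770	1.810584
772	1.809172
774	1.807760
776	1.806348
778	1.804937
780	1.803526
782	1.802115
784	1.800705
786	1.799295
788	1.797885
790	1.796476
792	1.795067
794	1.793659
796	1.792251
798	1.790843
800	1.789436
802	1.788030
804	1.786623
806	1.785218
808	1.783813
810	1.782408
812	1.781004
814	1.779601
816	1.778198
818	1.776795
820	1.775394
822	1.773993
824	1.772592
826	1.771192
828	1.769793
830	1.768395
832	1.766997
834	1.765600
836	1.764204
838	1.762808
840	1.761414
842	1.760020
844	1.758626
846	1.757234
848	1.755842
850	1.754452
852	1.753062
854	1.751673
856	1.750285
858	1.748897
860	1.747511
862	1.746126
864	1.744741
866	1.743358
868	1.741975
870	1.740594
872	1.739213
874	1.737834
876	1.736455
878	1.735078
880	1.733701
882	1.732326
884	1.730952
886	1.729579
888	1.728207
890	1.726836
892	1.725467
894	1.724098
896	1.722731
898	1.721365
900	1.720000
902	1.718636
904	1.717274
906	1.715912
908	1.714551
910	1.713191
912	1.711831
914	1.710471
916	1.709112
918	1.707752
920	1.706393
922	1.705033
924	1.703672
926	1.702311
928	1.700949
930	1.699585
932	1.698221
934	1.696855
936	1.695488
938	1.694119
940	1.692749
942	1.691376
944	1.690002
946	1.688625
948	1.687245
950	1.685863
952	1.684479
954	1.683091
956	1.681700
958	1.680306
960	1.678909
962	1.677508
964	1.676103
966	1.674695
968	1.673282
970	1.671865
972	1.670444
974	1.669018
976	1.667588
978	1.666153
980	1.664712
982	1.663267
984	1.661816
986	1.660360
988	1.658898
990	1.657431
992	1.655957
994	1.654477
996	1.652991
998	1.651499
1000	1.650000
1002	1.648494
1004	1.646982
1006	1.645463
1008	1.643938
1010	1.642407
1012	1.640870
1014	1.639328
1016	1.637779
1018	1.636226
1020	1.634667
1022	1.633103
1024	1.631534
1026	1.629961
1028	1.628383
1030	1.626800
1032	1.625214
1034	1.623623
1036	1.622029
1038	1.620431
1040	1.618829
1042	1.617224
1044	1.615616
1046	1.614005
1048	1.612391
1050	1.610774
1052	1.609155
1054	1.607534
1056	1.605911
1058	1.604285
1060	1.602658
1062	1.601029
1064	1.599399
1066	1.597767
1068	1.596134
1070	1.594501
1072	1.592866
1074	1.591231
1076	1.589596
1078	1.587960
1080	1.586324
1082	1.584689
1084	1.583053
1086	1.581418
1088	1.579784
1090	1.578150
1092	1.576518
1094	1.574886
1096	1.573256
1098	1.571627
1100	1.570000
1102	1.568375
1104	1.566751
1106	1.565129
1108	1.563509
1110	1.561890
1112	1.560273
1114	1.558658
1116	1.557044
1118	1.555431
1120	1.553820
1122	1.552210
1124	1.550601
1126	1.548994
1128	1.547388
1130	1.545783
1132	1.544179
1134	1.542577
1136	1.540975
1138	1.539374
1140	1.537775
1142	1.536176
1144	1.534578
1146	1.532981
1148	1.531384
1150	1.529789
1152	1.528194
1154	1.526599
1156	1.525006
1158	1.523412
1160	1.521820
1162	1.520227
1164	1.518636
1166	1.517044
1168	1.515453
1170	1.513862
1172	1.512271
1174	1.510681
1176	1.509090
1178	1.507500
1180	1.505910
1182	1.504320
1184	1.502729
1186	1.501139
1188	1.499548
1190	1.497958
1192	1.496367
1194	1.494776
1196	1.493184
1198	1.491592
1200	1.490000
1202	1.488407
1204	1.486814
1206	1.485221
1208	1.483627
1210	1.482032
1212	1.480437
1214	1.478842
1216	1.477246
1218	1.475650
1220	1.474054
1222	1.472457
1224	1.470860
1226	1.469263
1228	1.467665
1230	1.466067
1232	1.464469
1234	1.462870
1236	1.461271
1238	1.459672
1240	1.458072
1242	1.456472
1244	1.454872
1246	1.453272
1248	1.451671
1250	1.450070
1252	1.448469
1254	1.446868
1256	1.445267
1258	1.443665
1260	1.442063
1262	1.440461
1264	1.438859
1266	1.437256
1268	1.435654
1270	1.434051
1272	1.432448
1274	1.430846
1276	1.429242
1278	1.427639
1280	1.426036
1282	1.424433
1284	1.422829
1286	1.421226
1288	1.419622
1290	1.418019
1292	1.416415
1294	1.414811
1296	1.413207
1298	1.411604
1300	1.410000
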