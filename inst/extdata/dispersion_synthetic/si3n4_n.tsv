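wavelength_nm	n
600	2.027000
602	2.026760
604	2.026521
606	2.026281
608	2.026042
610	2.025803
612	2.025563
614	2.025324
616	2.025085
618	2.024846
620	2.024607
622	2.024369
624	2.024130
626	2.023892
628	2.023654
630	2.023416
632	2.023179
634	2.022941
636	2.022704
638	2.022467
640	2.022231
642	2.021995
644	2.021759
646	2.021524
648	2.021289
650	2.021054
652	2.020820
654	2.020586
656	2.020353
658	2.020120
660	2.019887
662	2.019655
664	2.019424
666	2.019193
668	2.018963
670	2.018733
672	2.018504
674	2.018275
676	2.018047
678	2.017820
680	2.017593
682	2.017367
684	2.017141
686	2.016916
688	2.016692
690	2.016469
692	2.016246
694	2.016025
696	2.015804
698	2.015583
700	2.015364
702	2.015145
704	2.014927
706	2.014710
708	2.014494
710	2.014279
712	2.014064
714	2.013851
716	2.013639
718	2.013427
720	2.013216
722	2.013007
724	2.012798
726	2.012591
728	2.012384
730	2.012178
732	2.011974
734	2.011771
736	2.011568
738	2.011367
740	2.011167
742	2.010968
744	2.010771
746	2.010574
748	2.010379
750	2.010184
752	2.009992
754	2.009800
756	2.009609
758	2.009420
760	2.009232
762	2.009046
764	2.008861
766	2.008677
768	2.008494
770	2.008313
772	2.008133
774	2.007955
776	2.007778
778	2.007603
780	2.007429
782	2.007256
784	2.007085
786	2.006915
788	2.006747
790	2.006581
792	2.006416
794	2.006252
796	2.006090
798	2.005929
800	2.005770
802	2.005612
804	2.005456
806	2.005301
808	2.005147
810	2.004995
812	2.004844
814	2.004694
816	2.004546
818	2.004399
820	2.004253
822	2.004109
824	2.003966
826	2.003824
828	2.003684
830	2.003545
832	2.003407
834	2.003270
836	2.003134
838	2.003000
840	2.002867
842	2.002735
844	2.002604
846	2.002474
848	2.002346
850	2.002219
852	2.002092
854	2.001967
856	2.001843
858	2.001720
860	2.001598
862	2.001477
864	2.001358
866	2.001239
868	2.001121
870	2.001004
872	2.000889
874	2.000774
876	2.000660
878	2.000547
880	2.000435
882	2.000325
884	2.000215
886	2.000105
888	1.999997
890	1.999890
892	1.999783
894	1.999678
896	1.999573
898	1.999469
900	1.999366
902	1.999264
904	1.999163
906	1.999062
908	1.998962
910	1.998863
912	1.998765
914	1.998667
916	1.998570
918	1.998474
920	1.998379
922	1.998284
924	1.998190
926	1.998096
928	1.998004
930	1.997912
932	1.997820
934	1.997729
936	1.997639
938	1.997549
940	1.997460
942	1.997372
944	1.997284
946	1.997196
948	1.997110
950	1.997023
952	1.996937
954	1.996852
956	1.996767
958	1.996683
960	1.996599
962	1.996516
964	1.996433
966	1.996350
968	1.996268
970	1.996186
972	1.996105
974	1.996024
976	1.995943
978	1.995863
980	1.995783
982	1.995704
984	1.995624
986	1.995545
988	1.995467
990	1.995388
992	1.995310
994	1.995232
996	1.995155
998	1.995077
1000	1.995000
1002	1.994923
1004	1.994846
1006	1.994770
1008	1.994693
1010	1.994617
1012	1.994541
1014	1.994466
1016	1.994390
1018	1.994315
1020	1.994239
1022	1.994165
1024	1.994090
1026	1.994015
1028	1.993941
1030	1.993867
1032	1.993793
1034	1.993719
1036	1.993645
1038	1.993572
1040	1.993498
1042	1.993425
1044	1.993352
1046	1.993280
1048	1.993207
1050	1.993135
1052	1.993062
1054	1.992990
1056	1.992919
1058	1.992847
1060	1.992775
1062	1.992704
1064	1.992633
1066	1.992562
1068	1.992491
1070	1.992420
1072	1.992350
1074	1.992279
1076	1.992209
1078	1.992139
1080	1.992069
1082	1.991999
1084	1.991930
1086	1.991860
1088	1.991791
1090	1.991722
1092	1.991652
1094	1.991584
1096	1.991515
1098	1.991446
1100	1.991378
1102	1.991309
1104	1.991241
1106	1.991173
1108	1.991105
1110	1.991037
1112	1.990970
1114	1.990902
1116	1.990835
1118	1.990768
1120	1.990700
1122	1.990633
1124	1.990567
1126	1.990500
1128	1.990433
1130	1.990367
1132	1.990300
1134	1.990234
1136	1.990168
1138	1.990102
1140	1.990036
1142	1.989970
1144	1.989904
1146	1.989838
1148	1.989773
1150	1.989707
1152	1.989642
1154	1.989577
1156	1.989512
1158	1.989447
1160	1.989382
1162	1.989317
1164	1.989252
1166	1.989188
1168	1.989123
1170	1.989059
1172	1.988994
1174	1.988930
1176	1.988866
1178	1.988802
1180	1.988738
1182	1.988674
1184	1.988610
1186	1.988546
1188	1.988483
1190	1.988419
1192	1.988356
1194	1.988292
1196	1.988229
1198	1.988165
1200	1.988102
1202	1.988039
1204	1.987976
1206	1.987913
1208	1.987850
1210	1.987787
1212	1.987724
1214	1.987661
1216	1.987599
1218	1.987536
1220	1.987473
1222	1.987411
1224	1.987348
1226	1.987286
1228	1.987224
1230	1.987161
1232	1.987099
1234	1.987037
1236	1.986974
1238	1.986912
1240	1.986850
1242	1.986788
1244	1.986726
1246	1.986664
1248	1.986602
1250	1.986540
1252	1.986478
1254	1.986417
1256	1.986355
1258	1.986293
1260	1.986231
1262	1.986169
1264	1.986108
1266	1.986046
1268	1.985984
1270	1.985923
1272	1.985861
1274	1.985800
1276	1.985738
1278	1.985676
1280	1.985615
1282	1.985553
1284	1.985492
1286	1.985430
1288	1.985369
1290	1.985307
1292	1.985246
1294	1.985184
1296	1.985123
1298	1.985061
1300	1.985000
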