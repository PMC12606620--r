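wavelength_nm	n
600	1.458000
602	1.457956
604	1.457912
606	1.457867
608	1.457823
610	1.457779
612	1.457735
614	1.457691
616	1.457647
618	1.457602
620	1.457558
622	1.457514
624	1.457470
626	1.457426
628	1.457382
630	1.457338
632	1.457294
634	1.457249
636	1.457205
638	1.457161
640	1.457117
642	1.457073
644	1.457029
646	1.456985
648	1.456941
650	1.456897
652	1.456853
654	1.456809
656	1.456765
658	1.456721
660	1.456677
662	1.456634
664	1.456590
666	1.456546
668	1.456502
670	1.456458
672	1.456415
674	1.456371
676	1.456327
678	1.456283
680	1.456240
682	1.456196
684	1.456152
686	1.456109
688	1.456065
690	1.456022
692	1.455978
694	1.455935
696	1.455891
698	1.455848
700	1.455805
702	1.455761
704	1.455718
706	1.455675
708	1.455631
710	1.455588
712	1.455545
714	1.455502
716	1.455459
718	1.455416
720	1.455373
722	1.455330
724	1.455287
726	1.455244
728	1.455201
730	1.455158
732	1.455116
734	1.455073
736	1.455030
738	1.454987
740	1.454945
742	1.454902
744	1.454860
746	1.454817
748	1.454775
750	1.454733
752	1.454690
754	1.454648
756	1.454606
758	1.454564
760	1.454522
762	1.454480
764	1.454438
766	1.454396
768	1.454354
770	1.454312
772	1.454270
774	1.454228
776	1.454187
778	1.454145
780	1.454104
782	1.454062
784	1.454021
786	1.453979
788	1.453938
790	1.453897
792	1.453856
794	1.453814
796	1.453773
798	1.453732
800	1.453692
802	1.453651
804	1.453610
806	1.453569
808	1.453528
810	1.453488
812	1.453447
814	1.453407
816	1.453366
818	1.453326
820	1.453286
822	1.453246
824	1.453206
826	1.453165
828	1.453125
830	1.453086
832	1.453046
834	1.453006
836	1.452966
838	1.452927
840	1.452887
842	1.452848
844	1.452808
846	1.452769
848	1.452730
850	1.452690
852	1.452651
854	1.452612
856	1.452573
858	1.452534
860	1.452496
862	1.452457
864	1.452418
866	1.452380
868	1.452341
870	1.452303
872	1.452265
874	1.452226
876	1.452188
878	1.452150
880	1.452112
882	1.452074
884	1.452036
886	1.451999
888	1.451961
890	1.451923
892	1.451886
894	1.451848
896	1.451811
898	1.451774
900	1.451737
902	1.451700
904	1.451663
906	1.451626
908	1.451589
910	1.451552
912	1.451516
914	1.451479
916	1.451443
918	1.451406
920	1.451370
922	1.451334
924	1.451298
926	1.451262
928	1.451226
930	1.451190
932	1.451155
934	1.451119
936	1.451083
938	1.451048
940	1.451013
942	1.450977
944	1.450942
946	1.450907
948	1.450872
950	1.450838
952	1.450803
954	1.450768
956	1.450734
958	1.450699
960	1.450665
962	1.450631
964	1.450596
966	1.450562
968	1.450529
970	1.450495
972	1.450461
974	1.450427
976	1.450394
978	1.450360
980	1.450327
982	1.450294
984	1.450261
986	1.450228
988	1.450195
990	1.450162
992	1.450130
994	1.450097
996	1.450065
998	1.450032
1000	1.450000
1002	1.449968
1004	1.449936
1006	1.449904
1008	1.449872
1010	1.449840
1012	1.449809
1014	1.449777
1016	1.449746
1018	1.449715
1020	1.449684
1022	1.449653
1024	1.449622
1026	1.449591
1028	1.449560
1030	1.449529
1032	1.449499
1034	1.449468
1036	1.449438
1038	1.449408
1040	1.449378
1042	1.449348
1044	1.449318
1046	1.449288
1048	1.449258
1050	1.449228
1052	1.449199
1054	1.449169
1056	1.449140
1058	1.449110
1060	1.449081
1062	1.449052
1064	1.449023
1066	1.448994
1068	1.448965
1070	1.448936
1072	1.448907
1074	1.448879
1076	1.448850
1078	1.448822
1080	1.448793
1082	1.448765
1084	1.448737
1086	1.448709
1088	1.448681
1090	1.448653
1092	1.448625
1094	1.448597
1096	1.448569
1098	1.448541
1100	1.448514
1102	1.448486
1104	1.448459
1106	1.448431
1108	1.448404
1110	1.448377
1112	1.448350
1114	1.448322
1116	1.448295
1118	1.448268
1120	1.448241
1122	1.448215
1124	1.448188
1126	1.448161
1128	1.448134
1130	1.448108
1132	1.448081
1134	1.448055
1136	1.448028
1138	1.448002
1140	1.447976
1142	1.447950
1144	1.447923
1146	1.447897
1148	1.447871
1150	1.447845
1152	1.447819
1154	1.447793
1156	1.447767
1158	1.447742
1160	1.447716
1162	1.447690
1164	1.447665
1166	1.447639
1168	1.447613
1170	1.447588
1172	1.447563
1174	1.447537
1176	1.447512
1178	1.447487
1180	1.447461
1182	1.447436
1184	1.447411
1186	1.447386
1188	1.447361
1190	1.447336
1192	1.447311
1194	1.447286
1196	1.447261
1198	1.447236
1200	1.447211
1202	1.447186
1204	1.447161
1206	1.447137
1208	1.447112
1210	1.447087
1212	1.447063
1214	1.447038
1216	1.447013
1218	1.446989
1220	1.446964
1222	1.446940
1224	1.446915
1226	1.446891
1228	1.446867
1230	1.446842
1232	1.446818
1234	1.446794
1236	1.446769
1238	1.446745
1240	1.446721
1242	1.446696
1244	1.446672
1246	1.446648
1248	1.446624
1250	1.446600
1252	1.446576
1254	1.446552
1256	1.446527
1258	1.446503
1260	1.446479
1262	1.446455
1264	1.446431
1266	1.446407
1268	1.446383
1270	1.446359
1272	1.446335
1274	1.446311
1276	1.446287
1278	1.446263
1280	1.446239
1282	1.446215
1284	1.446191
1286	1.446167
1288	1.446144
1290	1.446120
1292	1.446096
1294	1.446072
1296	1.446048
1298	1.446024
1300	1.446000
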