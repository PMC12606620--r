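wavelength_nm	n
600	3.950000
602	3.946239
604	3.942479
606	3.938721
608	3.934966
610	3.931215
612	3.927468
614	3.923728
616	3.919994
618	3.916267
620	3.912550
622	3.908842
624	3.905144
626	3.901459
628	3.897785
630	3.894125
632	3.890480
634	3.886850
636	3.883236
638	3.879640
640	3.876062
642	3.872503
644	3.868965
646	3.865447
648	3.861952
650	3.858480
652	3.855032
654	3.851609
656	3.848212
658	3.844842
660	3.841499
662	3.838186
664	3.834903
666	3.831650
668	3.828429
670	3.825241
672	3.822086
674	3.818967
676	3.815882
678	3.812835
680	3.809825
682	3.806853
684	3.803921
686	3.801029
688	3.798179
690	3.795371
692	3.792606
694	3.789886
696	3.787211
698	3.784582
700	3.782000
702	3.779466
704	3.776979
706	3.774538
708	3.772142
710	3.769790
712	3.767480
714	3.765213
716	3.762986
718	3.760798
720	3.758649
722	3.756537
724	3.754461
726	3.752421
728	3.750415
730	3.748442
732	3.746501
734	3.744591
736	3.742710
738	3.740859
740	3.739035
742	3.737238
744	3.735466
746	3.733719
748	3.731995
750	3.730294
752	3.728613
754	3.726953
756	3.725312
758	3.723690
760	3.722084
762	3.720493
764	3.718918
766	3.717357
768	3.715808
770	3.714270
772	3.712743
774	3.711226
776	3.709717
778	3.708215
780	3.706719
782	3.705229
784	3.703742
786	3.702259
788	3.700778
790	3.699299
792	3.697824
794	3.696351
796	3.694881
798	3.693415
800	3.691952
802	3.690492
804	3.689036
806	3.687583
808	3.686135
810	3.684690
812	3.683249
814	3.681813
816	3.680381
818	3.678954
820	3.677531
822	3.676114
824	3.674701
826	3.673293
828	3.671890
830	3.670493
832	3.669101
834	3.667715
836	3.666334
838	3.664959
840	3.663591
842	3.662228
844	3.660872
846	3.659522
848	3.658179
850	3.656843
852	3.655513
854	3.654190
856	3.652875
858	3.651566
860	3.650265
862	3.648972
864	3.647686
866	3.646408
868	3.645138
870	3.643875
872	3.642621
874	3.641376
876	3.640138
878	3.638910
880	3.637690
882	3.636479
884	3.635277
886	3.634084
888	3.632900
890	3.631726
892	3.630561
894	3.629406
896	3.628261
898	3.627125
900	3.626000
902	3.624885
904	3.623780
906	3.622685
908	3.621600
910	3.620525
912	3.619459
914	3.618404
916	3.617358
918	3.616321
920	3.615294
922	3.614277
924	3.613268
926	3.612269
928	3.611279
930	3.610298
932	3.609326
934	3.608363
936	3.607408
938	3.606463
940	3.605526
942	3.604597
944	3.603677
946	3.602765
948	3.601861
950	3.600966
952	3.600079
954	3.599200
956	3.598329
958	3.597465
960	3.596610
962	3.595762
964	3.594921
966	3.594088
968	3.593263
970	3.592445
972	3.591634
974	3.590831
976	3.590034
978	3.589245
980	3.588462
982	3.587687
984	3.586918
986	3.586156
988	3.585400
990	3.584651
992	3.583908
994	3.583172
996	3.582442
998	3.581718
1000	3.581000
1002	3.580288
1004	3.579582
1006	3.578882
1008	3.578189
1010	3.577500
1012	3.576818
1014	3.576142
1016	3.575471
1018	3.574806
1020	3.574146
1022	3.573493
1024	3.572844
1026	3.572202
1028	3.571565
1030	3.570933
1032	3.570307
1034	3.569686
1036	3.569071
1038	3.568461
1040	3.567857
1042	3.567257
1044	3.566663
1046	3.566074
1048	3.565490
1050	3.564912
1052	3.564338
1054	3.563769
1056	3.563206
1058	3.562647
1060	3.562094
1062	3.561545
1064	3.561001
1066	3.560462
1068	3.559928
1070	3.559398
1072	3.558873
1074	3.558353
1076	3.557838
1078	3.557327
1080	3.556820
1082	3.556319
1084	3.555821
1086	3.555328
1088	3.554840
1090	3.554356
1092	3.553876
1094	3.553401
1096	3.552930
1098	3.552463
1100	3.552000
1102	3.551541
1104	3.551087
1106	3.550637
1108	3.550190
1110	3.549748
1112	3.549309
1114	3.548874
1116	3.548443
1118	3.548016
1120	3.547592
1122	3.547172
1124	3.546756
1126	3.546343
1128	3.545933
1130	3.545527
1132	3.545124
1134	3.544724
1136	3.544328
1138	3.543934
1140	3.543544
1142	3.543157
1144	3.542773
1146	3.542392
1148	3.542013
1150	3.541638
1152	3.541265
1154	3.540895
1156	3.540527
1158	3.540163
1160	3.539800
1162	3.539440
1164	3.539083
1166	3.538728
1168	3.538375
1170	3.538025
1172	3.537676
1174	3.537330
1176	3.536986
1178	3.536644
1180	3.536304
1182	3.535966
1184	3.535630
1186	3.535295
1188	3.534963
1190	3.534632
1192	3.534302
1194	3.533974
1196	3.533648
1198	3.533323
1200	3.533000
1202	3.532678
1204	3.532357
1206	3.532038
1208	3.531720
1210	3.531403
1212	3.531087
1214	3.530773
1216	3.530460
1218	3.530148
1220	3.529837
1222	3.529527
1224	3.529218
1226	3.528910
1228	3.528603
1230	3.528298
1232	3.527993
1234	3.527689
1236	3.527386
1238	3.527084
1240	3.526782
1242	3.526482
1244	3.526182
1246	3.525883
1248	3.525585
1250	3.525287
1252	3.524991
1254	3.524694
1256	3.524399
1258	3.524104
1260	3.523810
1262	3.523516
1264	3.523222
1266	3.522930
1268	3.522637
1270	3.522345
1272	3.522054
1274	3.521763
1276	3.521472
1278	3.521181
1280	3.520891
1282	3.520601
1284	3.520312
1286	3.520022
1288	3.519733
1290	3.519444
1292	3.519155
1294	3.518866
1296	3.518577
1298	3.518289
1300	3.518000
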