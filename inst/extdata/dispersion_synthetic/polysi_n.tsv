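wavelength_nm	n
600	3.960000
602	3.956195
604	3.952391
606	3.948588
608	3.944789
610	3.940994
612	3.937203
614	3.933418
616	3.929640
618	3.925870
620	3.922109
622	3.918357
624	3.914616
626	3.910887
628	3.907170
630	3.903467
632	3.899779
634	3.896106
636	3.892450
638	3.888811
640	3.885191
642	3.881590
644	3.878009
646	3.874450
648	3.870914
650	3.867400
652	3.863911
654	3.860448
656	3.857010
658	3.853600
660	3.850218
662	3.846865
664	3.843542
666	3.840251
668	3.836991
670	3.833765
672	3.830573
674	3.827415
676	3.824294
678	3.821210
680	3.818163
682	3.815156
684	3.812188
686	3.809262
688	3.806377
690	3.803535
692	3.800736
694	3.797983
696	3.795275
698	3.792614
700	3.790000
702	3.787435
704	3.784917
706	3.782446
708	3.780020
710	3.777639
712	3.775300
714	3.773004
716	3.770749
718	3.768534
720	3.766358
722	3.764219
724	3.762117
726	3.760051
728	3.758019
730	3.756021
732	3.754055
734	3.752121
736	3.750217
738	3.748341
740	3.746494
742	3.744674
744	3.742880
746	3.741110
748	3.739364
750	3.737641
752	3.735939
754	3.734257
756	3.732595
758	3.730952
760	3.729325
762	3.727715
764	3.726119
766	3.724538
768	3.722969
770	3.721412
772	3.719866
774	3.718329
776	3.716801
778	3.715280
780	3.713766
782	3.712256
784	3.710751
786	3.709249
788	3.707750
790	3.706253
792	3.704760
794	3.703269
796	3.701781
798	3.700297
800	3.698816
802	3.697339
804	3.695865
806	3.694395
808	3.692929
810	3.691467
812	3.690009
814	3.688556
816	3.687107
818	3.685662
820	3.684222
822	3.682787
824	3.681357
826	3.679933
828	3.678513
830	3.677099
832	3.675690
834	3.674287
836	3.672889
838	3.671498
840	3.670112
842	3.668733
844	3.667360
846	3.665993
848	3.664633
850	3.663280
852	3.661933
854	3.660593
856	3.659261
858	3.657935
860	3.656617
862	3.655307
864	3.654004
866	3.652709
868	3.651421
870	3.650142
872	3.648871
874	3.647608
876	3.646353
878	3.645107
880	3.643869
882	3.642641
884	3.641421
886	3.640210
888	3.639009
890	3.637817
892	3.636634
894	3.635461
896	3.634297
898	3.633144
900	3.632000
902	3.630866
904	3.629743
906	3.628629
908	3.627525
910	3.626431
912	3.625347
914	3.624272
916	3.623207
918	3.622151
920	3.621105
922	3.620068
924	3.619040
926	3.618021
928	3.617012
930	3.616011
932	3.615019
934	3.614036
936	3.613062
938	3.612096
940	3.611139
942	3.610190
944	3.609250
946	3.608318
948	3.607394
950	3.606479
952	3.605571
954	3.604671
956	3.603780
958	3.602896
960	3.602020
962	3.601152
964	3.600291
966	3.599438
968	3.598592
970	3.597753
972	3.596922
974	3.596098
976	3.595281
978	3.594471
980	3.593668
982	3.592871
984	3.592082
986	3.591299
988	3.590523
990	3.589753
992	3.588990
994	3.588233
996	3.587483
998	3.586738
1000	3.586000
1002	3.585268
1004	3.584542
1006	3.583821
1008	3.583107
1010	3.582399
1012	3.581696
1014	3.580999
1016	3.580308
1018	3.579623
1020	3.578943
1022	3.578270
1024	3.577601
1026	3.576939
1028	3.576281
1030	3.575630
1032	3.574984
1034	3.574343
1036	3.573708
1038	3.573078
1040	3.572453
1042	3.571834
1044	3.571219
1046	3.570611
1048	3.570007
1050	3.569408
1052	3.568815
1054	3.568226
1056	3.567643
1058	3.567064
1060	3.566491
1062	3.565922
1064	3.565358
1066	3.564799
1068	3.564245
1070	3.563696
1072	3.563151
1074	3.562611
1076	3.562076
1078	3.561545
1080	3.561019
1082	3.560497
1084	3.559980
1086	3.559467
1088	3.558959
1090	3.558455
1092	3.557956
1094	3.557460
1096	3.556969
1098	3.556483
1100	3.556000
1102	3.555522
1104	3.555047
1106	3.554577
1108	3.554111
1110	3.553648
1112	3.553190
1114	3.552735
1116	3.552284
1118	3.551837
1120	3.551393
1122	3.550953
1124	3.550516
1126	3.550083
1128	3.549654
1130	3.549228
1132	3.548805
1134	3.548385
1136	3.547969
1138	3.547555
1140	3.547145
1142	3.546738
1144	3.546334
1146	3.545933
1148	3.545534
1150	3.545139
1152	3.544746
1154	3.544356
1156	3.543968
1158	3.543583
1160	3.543201
1162	3.542821
1164	3.542444
1166	3.542069
1168	3.541696
1170	3.541325
1172	3.540957
1174	3.540591
1176	3.540227
1178	3.539865
1180	3.539505
1182	3.539146
1184	3.538790
1186	3.538436
1188	3.538083
1190	3.537732
1192	3.537382
1194	3.537035
1196	3.536688
1198	3.536343
1200	3.536000
1202	3.535658
1204	3.535317
1206	3.534978
1208	3.534640
1210	3.534303
1212	3.533967
1214	3.533633
1216	3.533300
1218	3.532967
1220	3.532636
1222	3.532307
1224	3.531978
1226	3.531650
1228	3.531323
1230	3.530997
1232	3.530672
1234	3.530349
1236	3.530025
1238	3.529703
1240	3.529382
1242	3.529061
1244	3.528742
1246	3.528423
1248	3.528105
1250	3.527787
1252	3.527470
1254	3.527154
1256	3.526839
1258	3.526524
1260	3.526209
1262	3.525895
1264	3.525582
1266	3.525269
1268	3.524957
1270	3.524645
1272	3.524334
1274	3.524022
1276	3.523712
1278	3.523401
1280	3.523091
1282	3.522781
1284	3.522471
1286	3.522162
1288	3.521853
1290	3.521544
1292	3.521235
1294	3.520926
1296	3.520617
1298	3.520309
1300	3.520000
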