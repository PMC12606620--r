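wavelength_nm	n
600	2.437000
602	2.436128
604	2.435257
606	2.434386
608	2.433514
610	2.432643
612	2.431773
614	2.430902
616	2.430032
618	2.429163
620	2.428294
622	2.427426
624	2.426558
626	2.425691
628	2.424825
630	2.423959
632	2.423095
634	2.422231
636	2.421368
638	2.420506
640	2.419646
642	2.418786
644	2.417928
646	2.417071
648	2.416216
650	2.415362
652	2.414509
654	2.413657
656	2.412808
658	2.411960
660	2.411113
662	2.410269
664	2.409426
666	2.408585
668	2.407745
670	2.406908
672	2.406073
674	2.405240
676	2.404409
678	2.403580
680	2.402754
682	2.401930
684	2.401108
686	2.400288
688	2.399472
690	2.398657
692	2.397845
694	2.397036
696	2.396230
698	2.395426
700	2.394626
702	2.393828
704	2.393033
706	2.392241
708	2.391452
710	2.390666
712	2.389883
714	2.389104
716	2.388328
718	2.387555
720	2.386786
722	2.386020
724	2.385258
726	2.384499
728	2.383744
730	2.382993
732	2.382245
734	2.381501
736	2.380761
738	2.380025
740	2.379293
742	2.378565
744	2.377841
746	2.377121
748	2.376406
750	2.375694
752	2.374988
754	2.374285
756	2.373587
758	2.372893
760	2.372204
762	2.371520
764	2.370840
766	2.370165
768	2.369495
770	2.368830
772	2.368169
774	2.367514
776	2.366863
778	2.366218
780	2.365578
782	2.364943
784	2.364313
786	2.363688
788	2.363069
790	2.362455
792	2.361847
794	2.361243
796	2.360645
798	2.360052
800	2.359464
802	2.358881
804	2.358303
806	2.357731
808	2.357163
810	2.356600
812	2.356041
814	2.355488
816	2.354940
818	2.354396
820	2.353857
822	2.353322
824	2.352793
826	2.352268
828	2.351747
830	2.351231
832	2.350720
834	2.350213
836	2.349710
838	2.349212
840	2.348718
842	2.348229
844	2.347743
846	2.347262
848	2.346785
850	2.346313
852	2.345844
854	2.345380
856	2.344920
858	2.344463
860	2.344011
862	2.343562
864	2.343118
866	2.342677
868	2.342240
870	2.341807
872	2.341378
874	2.340952
876	2.340531
878	2.340112
880	2.339698
882	2.339287
884	2.338879
886	2.338475
888	2.338074
890	2.337677
892	2.337283
894	2.336893
896	2.336506
898	2.336122
900	2.335741
902	2.335364
904	2.334989
906	2.334618
908	2.334250
910	2.333885
912	2.333523
914	2.333164
916	2.332808
918	2.332454
920	2.332104
922	2.331756
924	2.331412
926	2.331069
928	2.330730
930	2.330393
932	2.330059
934	2.329728
936	2.329399
938	2.329073
940	2.328749
942	2.328427
944	2.328108
946	2.327791
948	2.327477
950	2.327165
952	2.326855
954	2.326548
956	2.326242
958	2.325939
960	2.325638
962	2.325339
964	2.325042
966	2.324747
968	2.324454
970	2.324162
972	2.323873
974	2.323586
976	2.323300
978	2.323016
980	2.322734
982	2.322454
984	2.322175
986	2.321898
988	2.321622
990	2.321348
992	2.321076
994	2.320805
996	2.320535
998	2.320267
1000	2.320000
1002	2.319734
1004	2.319470
1006	2.319207
1008	2.318946
1010	2.318686
1012	2.318427
1014	2.318169
1016	2.317912
1018	2.317657
1020	2.317403
1022	2.317150
1024	2.316899
1026	2.316648
1028	2.316399
1030	2.316151
1032	2.315905
1034	2.315659
1036	2.315415
1038	2.315172
1040	2.314930
1042	2.314689
1044	2.314449
1046	2.314210
1048	2.313973
1050	2.313736
1052	2.313501
1054	2.313267
1056	2.313034
1058	2.312802
1060	2.312571
1062	2.312341
1064	2.312112
1066	2.311884
1068	2.311658
1070	2.311432
1072	2.311207
1074	2.310983
1076	2.310761
1078	2.310539
1080	2.310318
1082	2.310098
1084	2.309879
1086	2.309661
1088	2.309445
1090	2.309228
1092	2.309013
1094	2.308799
1096	2.308586
1098	2.308374
1100	2.308162
1102	2.307952
1104	2.307742
1106	2.307533
1108	2.307325
1110	2.307118
1112	2.306912
1114	2.306706
1116	2.306501
1118	2.306298
1120	2.306095
1122	2.305892
1124	2.305691
1126	2.305490
1128	2.305290
1130	2.305091
1132	2.304893
1134	2.304695
1136	2.304498
1138	2.304302
1140	2.304106
1142	2.303911
1144	2.303717
1146	2.303524
1148	2.303331
1150	2.303139
1152	2.302948
1154	2.302757
1156	2.302567
1158	2.302377
1160	2.302189
1162	2.302000
1164	2.301813
1166	2.301626
1168	2.301439
1170	2.301253
1172	2.301068
1174	2.300884
1176	2.300699
1178	2.300516
1180	2.300333
1182	2.300150
1184	2.299968
1186	2.299787
1188	2.299606
1190	2.299425
1192	2.299245
1194	2.299066
1196	2.298887
1198	2.298708
1200	2.298530
1202	2.298352
1204	2.298175
1206	2.297998
1208	2.297821
1210	2.297645
1212	2.297470
1214	2.297294
1216	2.297120
1218	2.296945
1220	2.296771
1222	2.296597
1224	2.296424
1226	2.296250
1228	2.296078
1230	2.295905
1232	2.295733
1234	2.295561
1236	2.295390
1238	2.295218
1240	2.295047
1242	2.294876
1244	2.294706
1246	2.294536
1248	2.294366
1250	2.294196
1252	2.294026
1254	2.293857
1256	2.293688
1258	2.293519
1260	2.293350
1262	2.293182
1264	2.293013
1266	2.292845
1268	2.292677
1270	2.292509
1272	2.292341
1274	2.292173
1276	2.292006
1278	2.291838
1280	2.291671
1282	2.291503
1284	2.291336
1286	2.291169
1288	2.291002
1290	2.290835
1292	2.290668
1294	2.290501
1296	2.290334
1298	2.290167
1300	2.290000
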