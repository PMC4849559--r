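"sex","age","qx"
"male",18,0.000501203265398598
"male",19,0.000511407902217598
"male",20,0.000522640628228488
"male",21,0.000535005007239353
"male",22,0.000548615032654132
"male",23,0.000563596177207248
"male",24,0.000580086548226166
"male",25,0.000598238159004505
"male",26,0.000618218327923081
"male",27,0.000640211218115305
"male",28,0.000664419531745897
"male",29,0.000691066374374327
"male",30,0.000720397306404053
"male",31,0.000752682600308585
"male",32,0.00078821972417098
"male",33,0.000827336074103902
"male",34,0.000870391980338336
"male",35,0.000917784014208944
"male",36,0.000969948625930916
"male",37,0.00102736614598886
"male",38,0.00109056518615513
"male",39,0.00116012747965533
"male",40,0.00123669320382036
"male",41,0.00132096683274141
"male",42,0.00141372357199876
"male",43,0.00151581643250021
"male",44,0.00162818400587517
"male",45,0.00175185900974584
"male",46,0.00188797767758742
"male",47,0.00203779007481097
"male",48,0.00220267143019837
"male",49,0.00238413457992037
"male",50,0.00258384363009179
"male",51,0.00280362895320618
"male",52,0.00304550364385014
"male",53,0.0033116815698454
"male",54,0.00360459716639738
"male",55,0.0039269271329454
"male",56,0.00428161420516071
"male",57,0.00467189318789007
"male",58,0.00510131944869907
"male",59,0.00557380008591657
"male",60,0.00609362799955315
"male",61,0.00666551910793323
"male",62,0.00729465296705312
"male",63,0.00798671706316767
"male",64,0.00874795506142345
"male",65,0.00958521930387968
"male",66,0.0105060278581957
"male",67,0.0115186264226489
"male",68,0.0126320553927729
"male",69,0.0138562223882671
"male",70,0.0152019805241411
"male",71,0.0166812126850725
"male",72,0.018306922024025
"male",73,0.0200933288520585
"male",74,0.0220559740121139
"male",75,0.0242118287307638
"male",76,0.0265794108130699
"male",77,0.0291789068803385
"male",78,0.0320323001412689
"male",79,0.0351635029250368
"male",80,0.0385984928802768
"male",81,0.0423654513453495
"male",82,0.0464949019099239
"male",83,0.0510198466015886
"male",84,0.0559758964285028
"male",85,0.0614013921735882
"male",86,0.0673375103505558
"male",87,0.0738283480804968
"male",88,0.080920979314669
"male",89,0.0886654733022934
"male",90,0.0971148644748681
"male",91,0.106325060992361
"male",92,0.116354677085856
"male",93,0.127264772067919
"male",94,0.139118476522792
"male",95,0.151980483823215
"male",96,0.165916382881849
"male",97,0.180991806120335
"male",98,0.197271365283248
"male",99,0.214817347274464
"male",100,0.233688143082176
"male",101,0.253936385624059
"male",102,0.275606777636506
"male",103,0.298733599308776
"male",104,0.323337898069568
"male",105,0.349424380657738
"male",106,0.376978051204143
"male",107,0.405960669214301
"male",108,0.436307138432782
"male",109,0.467921981372912
"male",110,1
"female",18,0.000475883413856182
"female",19,0.000483537095120279
"female",20,0.000491961886382675
"female",21,0.000501235469622552
"female",22,0.000511443350946994
"female",23,0.000522679648300106
"female",24,0.000535047958405421
"female",25,0.000548662310895676
"female",26,0.000563648218379953
"female",27,0.000580143832073277
"female",28,0.000598301213573071
"female",29,0.000618287734423184
"female",30,0.000640287616267776
"female",31,0.000664503625667279
"female",32,0.000691158939051806
"female",33,0.000720499194820645
"female",34,0.000752794751282537
"female",35,0.000788343170981087
"female",36,0.000827471953978587
"female",37,0.000870541544895742
"female",38,0.000917948640940747
"female",39,0.000970129830834998
"female",40,0.00102756559746386
"female",41,0.00109078472028235
"female",42,0.00116036911700468
"female",43,0.00123695916793065
"female",44,0.00132125957044005
"female",45,0.00141404577574022
"female",46,0.00151617106492286
"female",47,0.00162857432679087
"female",48,0.00175228860579957
"female",49,0.00188845049484632
"female",50,0.00203831045456326
"female",51,0.00220324414827344
"female",52,0.00238476488986306
"female",53,0.00258453731055908
"female",54,0.00280439235998386
"female",55,0.0030463437669227
"female",56,0.00331260609598694
"female",57,0.00360561454779496
"female",58,0.00392804666240221
"female",59,0.00428284609847251
"female",60,0.00467324867403351
"female",61,0.00510281086851649
"female",62,0.00557544100002905
"female",63,0.00609543330628304
"female",64,0.0066675051720636
"female",65,0.00729683776029844
"female",66,0.00798912031727228
"female",67,0.00875059843484471
"female",68,0.00958812656304009
"female",69,0.0105092250743122
"female",70,0.011522142185155
"female",71,0.0126359210403354
"female",72,0.0138604722583691
"female",73,0.0152066522221356
"female",74,0.016686347373509
"female",75,0.0183125647329022
"female",76,0.0200995288104441
"female",77,0.0220627850012888
"female",78,0.0242193094586781
"female",79,0.0265876253094078
"female",80,0.0291879249108788
"female",81,0.03204219763945
"female",82,0.0351743624376694
"female",83,0.0386104040231555
"female",84,0.0423785112630615
"female",85,0.0465092157323805
"female",86,0.0510355278876841
"female",87,0.0559930675847625
"female",88,0.0614201848326658
"female",89,0.0673580656909037
"female",90,0.0738508170644336
"female",91,0.0809455228173287
"female",92,0.0886922620985587
"female",93,0.0971440790453357
"female",94,0.106356891102684
"female",95,0.116389321086549
"female",96,0.127302435854005
"female",97,0.139159372084805
"female",98,0.152024827313344
"female",99,0.165964392112003
"female",100,0.181043697403329
"female",101,0.197327349525078
"female",102,0.214877625226164
"female",103,0.233752899665422
"female",104,0.254005783257698
"female",105,0.275680948513692
"female",106,0.298812636609209
"female",107,0.32342184614123
"female",108,0.349513224270535
"female",109,0.377071704066616
"female",110,1
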