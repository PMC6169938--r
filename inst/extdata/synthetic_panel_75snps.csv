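rsid,risk_allele,or,freq
rs00001,A,0.938523318842134,0.86878038526047
rs00002,G,1.03904918895221,0.859807317564264
rs00003,C,0.891628377927245,0.197206070134416
rs00004,G,1.01009662670177,0.697987708961591
rs00005,A,1.13615457512297,0.278065853123553
rs00006,T,1.06320589589086,0.299869948043488
rs00007,A,1.03237625006288,0.714921745681204
rs00008,C,1.0565580241313,0.411389850638807
rs00009,C,0.901163477626478,0.385075204679742
rs00010,C,1.0255523964623,0.873869960056618
rs00011,C,0.978327314194637,0.599864154611714
rs00012,A,1.09360981351145,0.930895668105222
rs00013,A,0.903958996434492,0.24665767736733
rs00014,A,1.20098167068775,0.209506988083012
rs00015,T,1.09254521039551,0.758490841486491
rs00016,T,0.964660134166659,0.683841040404513
rs00017,C,0.996573508238149,0.506771052465774
rs00018,C,1.05001584020405,0.121997393085621
rs00019,A,0.950464547879978,0.654161635949276
rs00020,C,0.97003493780551,0.697536193439737
rs00021,C,0.897616092300927,0.321810266282409
rs00022,A,1.02064632760933,0.0956603854661807
rs00023,C,1.06243060322265,0.0950125659815967
rs00024,C,0.936579477962873,0.238152830954641
rs00025,G,0.878356419973482,0.623955959244631
rs00026,G,0.97000897360353,0.430636913562193
rs00027,C,1.03297786981064,0.673010158864781
rs00028,A,0.96321639726444,0.659500428824686
rs00029,G,0.963746844994643,0.730724106659181
rs00030,T,1.02324456361649,0.121440551616251
rs00031,A,0.930475225725957,0.942447617533617
rs00032,C,0.941830790976396,0.809067219658755
rs00033,T,0.992913298896081,0.72949900245294
rs00034,A,0.988941949462584,0.445535828382708
rs00035,T,0.985536318382754,0.367027455684729
rs00036,C,1.03804851198484,0.101769384928048
rs00037,A,0.946847124372012,0.120843530655839
rs00038,C,0.967425823490621,0.307236617919989
rs00039,T,0.960618535205626,0.576786471623927
rs00040,G,1.16381012067929,0.290734947635792
rs00041,C,1.10281566520636,0.127859976538457
rs00042,T,1.01371569079085,0.186088676284999
rs00043,A,1.06011716011338,0.42974746748805
rs00044,A,1.11918035984787,0.326138181937858
rs00045,A,1.00799415692494,0.476006326498464
rs00046,A,0.913531768325644,0.59784732600674
rs00047,T,0.987925492520406,0.341936105326749
rs00048,T,0.949183081810693,0.866869664844125
rs00049,C,1.00748212867944,0.444096723082475
rs00050,G,0.979393499492935,0.741364861698821
rs00051,C,0.892413699366787,0.649757130234502
rs00052,C,0.950698757870501,0.464031669939868
rs00053,A,1.02484092443224,0.839891526498832
rs00054,A,0.90859806837922,0.350342762772925
rs00055,C,0.995540966078027,0.243001269293018
rs00056,T,1.16030645893892,0.191934415046126
rs00057,A,0.960356713999746,0.163860728219151
rs00058,C,0.869822448645559,0.123338890704326
rs00059,G,1.10210192101885,0.363409380358644
rs00060,G,0.972424988823907,0.478491274337284
rs00061,G,1.00516937038014,0.168849155656062
rs00062,T,0.941462873421362,0.0529260176233947
rs00063,A,0.971632521531845,0.231017987127416
rs00064,A,1.03001820577419,0.613608449487947
rs00065,G,1.02308971202941,0.136980227730237
rs00066,T,1.02788777000698,0.357249454548582
rs00067,C,1.0886999150018,0.49777438887395
rs00068,C,1.07994098642777,0.352939545945264
rs00069,A,0.989303281874608,0.876063407515176
rs00070,A,1.05814942272569,0.687975609442219
rs00071,A,1.01335648338661,0.160940788313746
rs00072,G,0.963644706113811,0.671150108100846
rs00073,T,1.02287039339687,0.676691463286988
rs00074,G,0.985240648276327,0.305645993375219
rs00075,C,1.15828819980362,0.36095987665467
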