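"patient_id","arm","baseline","y_1","y_2","d_1","d_2"
"P0001",0,60.7659576564637,32.6170636170181,-2.61875390273304,0,0
"P0002",0,37.6681991832295,-24.6075162374375,-21.1090059832939,0,0
"P0003",0,69.01978264555,-57.9500018907342,-41.7340510715112,0,1
"P0004",0,46.5030236591346,18.5464349597928,-25.1481363954765,0,0
"P0005",0,38.7957435846762,-43.5386620372645,-19.9482184356164,0,0
"P0006",0,45.7278320521762,59.2408496896239,37.7104343326801,0,0
"P0007",0,37.497773809686,14.3183097333364,47.1465710152594,0,0
"P0008",0,45.4439075186124,14.149497589905,-15.0077411647661,0,0
"P0009",0,62.6031827292841,37.0229486975955,46.1503796930353,0,0
"P0010",0,54.7980370027996,28.1270290894929,17.8237249687843,0,0
"P0011",0,59.4179816398398,-12.5175888662259,3.60336668287482,0,0
"P0012",0,41.8750720363323,26.5443249304138,33.1803582039639,0,0
"P0013",0,65.1225828193861,79.5115851128901,80.8774067050743,0,0
"P0014",0,55.5584851170084,41.5017038187561,36.3758765766467,0,0
"P0015",0,60.2750328108978,53.9178520921561,21.3752384829907,0,0
"P0016",0,55.9974398733354,16.5358881785518,-13.3153130538753,1,1
"P0017",0,60.5304634974956,-8.91617533288334,-10.4921541152744,0,0
"P0018",0,59.875389478266,-20.8374692023276,-11.6973655488167,0,0
"P0019",0,62.2325844277831,43.5703352172029,20.5251728639129,0,0
"P0020",0,42.3343158352139,-16.3226524487229,-18.4270227689397,0,0
"P0021",0,52.2330481910598,-13.0798366963393,23.4565397460013,0,0
"P0022",0,50.8446059460167,37.0561649034363,65.2122332677128,0,0
"P0023",0,46.36054637477,35.2531320625998,39.9303915267273,0,0
"P0024",0,51.4055572809119,35.9601848597281,66.1227360264809,0,0
"P0025",0,52.0733054291955,-0.273992117480079,9.20030492099523,0,0
"P0026",0,50.482378432936,-19.4356835126913,-9.63113105403835,0,0
"P0027",0,48.0508808808911,-54.1854939663127,-35.2398438699723,0,0
"P0028",0,60.7286671814758,11.2475614782552,14.5999516373241,0,0
"P0029",0,49.1886257100444,36.1562291722451,30.9826667614623,0,0
"P0030",0,61.7530370902324,68.3505193621616,73.1171259350122,0,0
"P0031",0,47.7537778513184,-14.6322061617387,-27.3773477175533,0,0
"P0032",0,57.2205576232455,1.94091196650468,8.48283523416658,0,0
"P0033",0,43.2072086291042,40.1685750013421,15.6153524469388,0,0
"P0034",0,55.9067812470469,12.2773362754419,24.0898683502653,0,0
"P0035",0,59.3941199474344,28.11166093923,-18.6178625856626,0,0
"P0036",0,33.9701417099876,18.0547169539295,1.18124181518131,0,0
"P0037",0,39.8455801971192,25.4822350927596,-11.1040616862789,0,0
"P0038",0,57.3995366546271,33.4598191060863,-24.6787409056682,0,0
"P0039",0,44.2987841318746,-6.13476282484134,20.2434699195809,0,0
"P0040",0,70.1344096911511,40.1523976045647,52.1218529084946,0,0
"P0041",1,46.3594466251903,14.2361530894658,67.1783749306788,0,0
"P0042",1,53.0571434673826,19.0530774754665,-7.34842304746959,0,0
"P0043",1,38.3235692664261,12.5965114535925,12.8338993405895,0,0
"P0044",1,68.0549634223043,2.4706233510298,21.7506789823456,0,0
"P0045",1,49.9846430531535,-28.8382277032358,-6.18629934021628,0,0
"P0046",1,41.3057112452523,11.6568626390178,2.34401952617156,0,0
"P0047",1,22.9623745723109,59.2355685472264,87.1842030971075,0,0
"P0048",1,60.2153365302842,13.6618334770819,8.53227040860985,0,1
"P0049",1,46.3128707555876,12.0416200167814,0.797731792425285,1,1
"P0050",1,44.1906556752116,28.7014169884055,34.8031278268284,0,0
"P0051",1,44.2753614209964,-3.98669135888939,48.7590721333819,0,0
"P0052",1,25.1574388067527,-7.64995590526476,19.5616701401886,0,0
"P0053",1,58.9962856823074,37.0763071582892,37.9466574019351,0,0
"P0054",1,40.2164513492681,47.5202247973578,50.1882379140506,0,0
"P0055",1,41.153894498993,29.7700942116395,40.1057582893468,0,0
"P0056",1,41.1634416714496,-4.36181987580681,-36.1968013447594,0,0
"P0057",1,33.6060982143244,30.5498164138944,34.0402803956596,0,0
"P0058",1,53.2463587222067,43.2629757378185,58.8884559560677,0,0
"P0059",1,36.5051298762792,2.01797533415927,-12.9642600851252,0,0
"P0060",1,46.6802933341954,-77.2973072844214,-42.9442107193236,0,1
"P0061",1,41.3500005794696,25.3381951734155,19.0147988889917,0,0
"P0062",1,55.3201153260487,57.1005652631551,13.3511731115475,0,0
"P0063",1,53.8206801554208,15.9913095085539,25.9057604956927,0,0
"P0064",1,74.0960765644046,9.72501238291975,47.1214306794953,0,0
"P0065",1,65.7523299265625,-9.65728747977237,45.346362274607,0,0
"P0066",1,53.4526861129559,46.9980077303694,46.8084014184366,0,0
"P0067",1,38.3350164195149,47.8285706309096,56.5316639123391,0,1
"P0068",1,60.9443135096975,82.3247812730655,40.389985240618,0,0
"P0069",1,56.338510955536,68.7487892433108,97.6107335495115,0,0
"P0070",1,36.4280575874747,15.491474971648,28.5003791703444,0,0
"P0071",1,51.4905487707184,28.0991414888765,7.06541496472133,0,0
"P0072",1,29.2659576032494,17.6328266435615,21.8831526282496,0,0
"P0073",1,46.7994449261384,59.6150875095371,51.4679149888438,0,0
"P0074",1,62.4441034563117,30.0979582073903,51.806745903472,0,0
"P0075",1,54.0223281773133,17.6933921166455,40.3639693755662,0,0
"P0076",1,43.3465647814578,-57.2268829187057,-21.274938043648,0,0
"P0077",1,38.5946563379948,13.8270135723537,37.9532483466081,0,0
"P0078",1,30.2695336452462,69.5288057265074,43.5505871704735,0,0
"P0079",1,42.1651209405426,8.58138693504881,-3.05531332985545,0,0
"P0080",1,43.1408341767944,14.7982839890422,-13.3356565990841,0,0
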