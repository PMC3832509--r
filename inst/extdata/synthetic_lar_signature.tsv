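gene	weight
G00031	1.3730539470112
G00032	0.450256558531702
G00033	-0.146293855626384
G00034	0.128097239786609
G00035	-2.29472094700192
G00036	-1.36656892116054
G00037	-0.1974795527395
G00038	0.0680857821389511
G00039	0.0905034095405517
G00040	0.322759966641457
G00041	0.132978626116952
G00042	-1.67926431994023
G00043	-0.278479577423245
G00044	-1.55241099569706
G00045	-1.37969925458798
G00046	-1.35705659019825
G00047	-0.921137179625037
G00048	-0.866817735728827
G00049	1.65664438622586
G00050	-0.155079718047773
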