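sample_id,patient_id,ethnicity,stage,nodal,age,tissue_site
S001,PT001,EA,2,pos,53,primary
S002,PT002,AA,2,pos,35,primary
S003,PT003,EA,2,neg,49,primary
S004,PT004,EA,2,neg,36,primary
S005,PT005,EA,2,neg,38,primary
S006,PT006,AA,3,neg,38,primary
S007,PT007,AA,1,pos,43,primary
S008,PT008,EA,1,neg,43,primary
S009,PT009,EA,1,neg,69,primary
S010,PT010,EA,2,pos,50,primary
S011,PT011,EA,3,neg,36,primary
S012,PT012,EA,1,pos,58,primary
S013,PT013,EA,2,neg,55,primary
S014,PT014,AA,4,pos,48,primary
S015,PT015,EA,1,neg,41,primary
S016,PT016,EA,2,neg,51,primary
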