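term_id	name	parents	genes
GO:ROOT	biological process		
GO:PROLIF	cell proliferation	GO:ROOT	G00001|G00002|G00003|G00004|G00005|G00006|G00007|G00008|G00009|G00010
GO:MITOSIS	mitotic division	GO:PROLIF	G00001|G00002|G00003|G00004|G00005
GO:ADHESION	cell adhesion	GO:ROOT	G00051|G00052|G00053|G00054|G00055|G00056|G00057|G00058
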