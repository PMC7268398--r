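"label","step","cost_type","per_patient_cost","quantity","unit_price","note"
"saliva self-collection kit","sampling","other",27.5,,,""
"extraction consumables","dna_extraction","consumables",19.28,,,""
"extraction validation / quality control","dna_extraction","testing",32.91,,,""
"extraction labour","dna_extraction","labour",13.86,,,""
"outsourced library preparation and sequencing","sequencing","testing",750,,,"commercial service; library prep not separable"
"analysis labour","analysis","labour",17.29,,,""
"data storage (10 GB/sample, nearline)","data_storage","other",9.79,,,""
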