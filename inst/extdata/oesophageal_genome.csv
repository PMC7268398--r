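"label","step","cost_type","per_patient_cost","quantity","unit_price","note"
"blood sample collection","sampling","other",25.05,,,""
"extraction consumables (tumour and blood kits)","dna_extraction","consumables",84.19,,,"includes re-extraction for low tumour-content biopsies"
"extraction validation / quality control","dna_extraction","testing",180.7,,,""
"extraction labour","dna_extraction","labour",35.39,,,""
"outsourced library preparation and sequencing","sequencing","testing",4188.6,,,"commercial service; library prep not separable"
"analysis labour","analysis","labour",98.54,,,""
"data storage (150 GB tumour + 72 GB blood, nearline)","data_storage","other",217.28,,,""
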