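"label","step","cost_type","per_patient_cost","quantity","unit_price","note"
"blood sample collection","sampling","other",25.05,,,""
"extraction consumables","dna_extraction","consumables",72.69,,,""
"extraction validation / quality control","dna_extraction","testing",139.9,,,""
"extraction labour","dna_extraction","labour",31.05,,,""
"outsourced library preparation and sequencing","sequencing","testing",1631.26,,,"USD 600 per sample converted at 1.29038 AUD/USD"
"analysis labour","analysis","labour",777.96,,,""
"data storage (150 GB tumour + 72 GB blood, nearline)","data_storage","other",217.28,,,""
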