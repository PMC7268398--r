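"label","step","cost_type","per_patient_cost","quantity","unit_price","note"
"blood sample collection","sampling","other",25.05,,,""
"extraction consumables","dna_extraction","consumables",39.37,,,""
"extraction validation / quality control","dna_extraction","testing",5.34,,,""
"extraction labour","dna_extraction","labour",0.78,,,""
"library preparation consumables","library_preparation","consumables",149.67,,,""
"library preparation labour","library_preparation","labour",6.79,,,""
"sequencing (incl. MLPA)","sequencing","testing",79.67,,,"MLPA folded into the sequencing step"
"sequencing labour","sequencing","labour",3.88,,,""
"computing software","analysis","equipment",3.2,,,""
"analysis labour","analysis","labour",23.82,,,""
"data storage (2 GB/sample, nearline)","data_storage","other",1.96,,,""
"multidisciplinary team meeting","clinician_reporting","labour",7.56,,,"multidisciplinary team meeting, 10% of cases"
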