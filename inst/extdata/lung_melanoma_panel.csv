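"label","step","cost_type","per_patient_cost","quantity","unit_price","note"
"tumour sample (biopsied in routine care)","sampling","other",0,,,"no cost: biopsy stored in the normal course of diagnosis"
"extraction consumables","dna_extraction","consumables",22.13,,,""
"extraction validation / quality control","dna_extraction","testing",5.34,,,""
"extraction labour","dna_extraction","labour",0.78,,,""
"library preparation consumables","library_preparation","consumables",322.23,,,""
"pre-sequencing quality control","library_preparation","testing",0.78,,,""
"library preparation labour","library_preparation","labour",6.31,,,""
"computing software","analysis","equipment",1.74,,,""
"analysis labour","analysis","labour",59.74,,,""
"data storage (2 GB/sample, nearline)","data_storage","other",1.96,,,""
"multidisciplinary team meeting","clinician_reporting","labour",7.56,,,"multidisciplinary team meeting, 10% of cases"
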