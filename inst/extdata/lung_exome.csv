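"label","step","cost_type","per_patient_cost","quantity","unit_price","note"
"blood sample collection","sampling","other",25.05,,,""
"extraction consumables (blood and tumour)","dna_extraction","consumables",39.99,,,""
"extraction validation / quality control","dna_extraction","testing",81.5,,,""
"extraction labour","dna_extraction","labour",63.86,,,""
"library preparation consumables","library_preparation","consumables",1050.21,,,""
"pre-sequencing quality control","library_preparation","testing",11.54,,,""
"library preparation labour","library_preparation","labour",139.72,,,""
"sequencing","sequencing","testing",1111.75,,,""
"sequencing labour","sequencing","labour",69.86,,,""
"computing software","analysis","equipment",0.73,,,""
"analysis labour","analysis","labour",57.63,,,""
"data storage (20 GB/sample, nearline)","data_storage","other",39.15,,,""
"multidisciplinary team preparation","clinician_reporting","labour",96.54,,,""
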