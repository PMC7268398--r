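Package: seqcost
Title: Micro-Costing of Genomic Sequencing Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up (micro-costing) analysis of per-patient genomic
    sequencing costs in cancer care. Organises resource line items by the
    seven activity steps of a sequencing workflow (sampling through
    clinician reporting) and five cost types (labour, consumables, testing,
    equipment, other), annuitizes capital equipment into per-patient
    charges, models tiered cloud-storage prices and currency conversion,
    summarises cost shares across projects, and runs one-way deterministic
    sensitivity analyses with tornado-table output. Ships fixtures encoding
    six Australian cancer sequencing projects (targeted panel, exome and
    whole-genome designs) and a seeded synthetic project generator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
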