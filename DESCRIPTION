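Package: molstash
Title: Folder-Based Management, Querying and Scoring of Small-Molecule Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless compound-library manager for medicinal chemistry
    groups. Projects are plain folders holding an ordered table of molecules
    (SMILES, free-form property columns, highlight colours, per-molecule file
    attachments) plus a single-writer lock record so a folder synced through a
    file-sharing service can be used by several people at once. Supports
    import and export of CSV, XLSX and V2000 SDF compound tables with
    duplicate-ID reporting, structure resolution from CAS registry numbers
    through a PubChem-style interface (with an offline recorded-fixture
    client), physicochemical descriptor calculation (molecular weight, Hill
    formula, logP, TPSA and friends via OpenBabel), property queries with
    eight comparators, substructure, superstructure and Tanimoto-similarity
    structural queries over Morgan-style circular fingerprints, and 0-100
    consensus toxicity scores from seeded ensembles of fingerprint
    classifiers. Includes a deterministic synthetic-library generator with
    planted substructure and structure-toxicity signal, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    readxl,
    zip,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
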