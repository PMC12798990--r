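Package: afuScreen
Title: Affinity-Ultrafiltration LC-MS Screening of Enzyme Ligands
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens enzyme ligands from paired affinity-ultrafiltration
    LC-MS experiments (active enzyme vs denatured-enzyme control). Detects
    chromatographic features in centroided MS1 runs, aligns them across
    replicates into consensus compounds, computes the per-compound peak-area
    ratio (PAR) with a replicate t-test, selects ligands by the mean PAR > 1
    and p < 0.05 rule, assigns CHO molecular formulas from accurate mass,
    builds targeted-MS/MS precursor inclusion lists, and annotates hits
    against a packaged flavonoid knowledge base. Includes a ground-truthed
    synthetic-data generator emulating the paired experimental design so the
    whole pipeline is testable without raw vendor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    mzR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: MassSpectrometry, Metabolomics, Proteomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
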