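Package: venomeCorr
Title: Quantitative Transcriptome-Proteome Comparison for Venom Glands
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing venom-gland transcriptomes and proteomes on a
    common quantitative scale. Implements FPKM transcript quantification with a
    low-abundance retention filter, six-frame translation and multi-protease
    in-silico digestion (trypsin, chymotrypsin, Glu-C) to build peptide search
    spaces, a length-normalized protein abundance score based on fractionally
    attributed spectral counts, a bootstrap contaminant-derived abundance
    threshold, correlation of protein abundance against transcript abundance,
    and a reciprocal-best-hit homology check over local alignment scores. A
    synthetic venome generator with known ground truth makes every stage
    testable without external sequencing or mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    stringi
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, Transcriptomics, Sequencing, MassSpectrometry
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'contaminantFilter.R'
    'transcriptQuant.R'
    'proteolysis.R'
    'peptideAbundance.R'
    'correlation.R'
    'io.R'
    'pipeline.R'
    'rbh.R'
    'syntheticVenome.R'
    'venomeCorr-package.R'
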