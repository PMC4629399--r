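Package: sgSelect
Title: Potency Scoring and Exon-Restricted Specificity Filtering for
    CRISPR/Cas9 Guide RNA Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design of single guide RNAs (sgRNAs) for the Streptococcus
    pyogenes CRISPR/Cas9 system combining guide efficacy prediction and
    targeting specificity. Efficacy is modeled with a radial-basis-function
    support vector machine over heterogeneous guide features: nucleotide and
    k-mer composition, synthesis/transcription motif flags, position-specific
    base identity, guide self-folding free energy and full-sgRNA base
    accessibility computed with RNAfold, and RNA/DNA hybrid duplex stability
    from nearest-neighbor thermodynamics. Hard pre-filters eliminate
    unpromising candidates before scoring, and off-target screening is
    restricted to exon space via an exact 13-nt seed + NGG/NAG index and
    an ungapped 85 percent-similarity scan. Includes a synthetic guide
    activity screen generator, ten-fold and leave-one-gene-out
    cross-validation, ROC and precision-recall machinery, and a FASTA-in /
    ranked-TSV-out design pipeline.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
SystemRequirements: ViennaRNA RNAfold (>= 2.0) on the PATH
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
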