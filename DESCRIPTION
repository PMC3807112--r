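Package: metsubnet
Title: Phenotype-Correlated Metabolic Sub-Networks from Stoichiometric
    Null-Space Geometry
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies metabolic sub-networks whose activity correlates
    with a phenotype (cell growth rate or patient survival group) by
    combining a kernel-projection similarity measure between reactions of
    a genome-scale stoichiometric model with per-reaction significance
    scores derived from gene expression. Includes parsers for SBML Level 3
    and a simple tabular reaction format, null-space geometry and
    full-coupling classes, Spearman/Welch gene scoring with FDR control,
    sub-network seeding and coupling expansion, a degrees-of-freedom
    robustness calculus with essential-metabolite detection, hypergeometric
    metabolite-overlap statistics, a futile-cycle cofactor energetics
    auditor, protein-interaction sub-network reports, and a synthetic-data
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
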