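Package: tmcensus
Title: Census of Alpha-Helical Transmembrane Proteins in Prokaryotic Viruses and Their Hosts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for a comparative census of alpha-helical transmembrane (TM)
    proteins in double-stranded DNA viruses infecting bacteria and archaea
    versus their cellular hosts. Provides a hydropathy sliding-window TM
    topology predictor with positive-inside orientation and a signal-peptide
    guard, parsers for Phobius-style topology output, per-genome census
    statistics (TM counts, fractions, topology histograms, conservation
    cross-tabulations, protein-length stratification), redundancy reduction by
    shared-gene clustering, the Viral Quotient statistic for gene families with
    prophage correction, nonparametric and chi-squared group comparisons,
    orthogroup prediction-consistency analysis, and a fully seeded synthetic
    proteome generator so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
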