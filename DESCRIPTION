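Package: mixscan
Title: Mixed-Ploidy Selection Scans and De Novo versus Standing Variation Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Allele-frequency based scans for positive selection in mixed
    diploid/autotetraploid resequencing panels. Implements per-SNP Hudson FST
    against a synonymous-site neutral quantile, a modified FineMAV score using
    Grantham and rescaled SIFT deleteriousness, a McDonald-Kreitman alpha with
    allele-frequency-difference based divergence classes, haplotype-frequency
    reconstruction over linked candidate amino-acid substitutions, ploidy-aware
    genotypic Hamming distance and diameter tests that classify swept alleles
    as de novo or standing, relative sweep-age ranking, multinucleotide-
    mutation evidence tests, and conservation comparison via pairwise alignment
    identity. Ships a synthetic-data generator with planted sweeps and a
    machine-readable truth record for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
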