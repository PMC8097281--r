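#!/usr/bin/env Rscript
# Relative sweep ages (non-candidate tetraploid polymorphisms accumulated per
# bp of swept haplotype; higher = older) and multinucleotide-mutation
# evidence (candidate spacing Wilcoxon + transversion-excess z test).
sw <- read.delim("results/stages/sweep_age.tsv")
mnm <- read.delim("results/stages/mnm.tsv")

cat("Sweep-age ranking (rank 1 = oldest):\n")
print(sw, row.names = FALSE)
cat("\nMNM evidence per candidate gene:\n")
print(mnm[, c("gene", "n_candidates", "median_distance_bp",
              "genomewide_median_bp", "spacing_p", "n_transversions",
              "n_transitions", "tstv_p", "mnm_flag")], row.names = FALSE)
cat("\nGenes flagged as MNM-like:", paste(mnm$gene[mnm$mnm_flag], collapse = ", "), "\n")
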