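#!/usr/bin/env Rscript
# De novo versus standing variation: the per-AAS diploid presence screen, the
# reconstructed haplotype frequencies (HAFd/HAFa/HAFr), and the three-
# criterion Hamming verdict per candidate gene.
scr <- read.delim("results/stages/standing_screen.tsv")
verd <- read.delim("results/stages/verdicts.tsv")
haf <- read.delim("results/stages/haf.tsv")
rar <- read.delim("results/stages/rarefaction.tsv")

cat(sprintf("Candidate AASs absent from all sampled diploids: %d of %d (%.0f%%)\n",
            sum(!scr$present_in_diploids), nrow(scr),
            100 * mean(!scr$present_in_diploids)))
cat("Three-criterion de novo verdicts:\n")
print(verd[, c("gene", "n_candidates", "criterion_A_absent_aas",
               "criterion_B_absent_haplotype",
               "criterion_C_distance_exceeds_diameter", "verdict_de_novo")],
      row.names = FALSE)
tet <- grepl("^TET", haf$population)
cat(sprintf("Mean derived-haplotype frequency (HAFa) in tetraploid populations: %.2f\n",
            mean(haf$HAFa[tet])))
cat(sprintf("Mean ancestral-haplotype frequency (HAFd) in diploid populations: %.2f\n",
            mean(haf$HAFd[!tet])))
cat("Rarefaction of diploid variant discovery:\n")
print(rar, row.names = FALSE)
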