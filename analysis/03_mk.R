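#!/usr/bin/env Rscript
# Summarize the AFD-based McDonald-Kreitman scan: divergence classes are the
# upper-1% AFD outliers between ploidies, rare variants (overall derived
# frequency < 0.15) are excluded, and alpha = 1 - (Ds*Pn)/(Dn*Ps).
mk <- read.delim("results/stages/mk.tsv")

gw <- mk[mk$gene == "genomewide", ]
cat(sprintf("Genomewide: Dn=%d Ds=%d Pn=%d Ps=%d alpha=%.3f (Fisher p=%.2g)\n",
            gw$Dn, gw$Ds, gw$Pn, gw$Ps, gw$alpha, gw$p_value))
per <- mk[mk$gene != "genomewide" & !is.na(mk$alpha) & (mk$Dn + mk$Ds) > 0, ]
cat("Genes with defined alpha and at least one divergence:", nrow(per), "\n")
cat("  alpha > 0 (consistent with positive selection):", sum(per$alpha > 0), "\n")
top <- per[order(-per$alpha), ][1:min(8, nrow(per)), c("gene", "Dn", "Ds", "Pn", "Ps", "alpha")]
print(top, row.names = FALSE)
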