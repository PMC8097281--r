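#' Classify sites for the modified McDonald-Kreitman test
#'
#' With divergence between young lineages not yet reaching fixation, the
#' divergence classes (Dn, Ds) are defined as the upper-tail outliers of the
#' allele frequency difference between the two ploidy groups, and rare
#' polymorphisms (overall derived frequency below `af_min`) are excluded to
#' limit the impact of slightly deleterious segregating variants.
#'
#' @param f_overall Derived frequency in the combined panel, per site.
#' @param afd_values AFD between the two groups, per site.
#' @param effect Effect class per site ("synonymous"/"missense"/"other").
#' @param afd_quantile Quantile defining the divergence threshold (0.99); the
#'   threshold is recomputed from the sites at hand.
#' @param af_min Overall-frequency exclusion cutoff (0.15; strictly lower
#'   frequencies are excluded).
#' @param afd_threshold Optional fixed threshold overriding the quantile.
#' @return List with `class` (character per site: divergent / polymorphic /
#'   excluded) and `afd_threshold`.
#' @export
classify_mk_sites <- function(f_overall, afd_values, effect,
                              afd_quantile = 0.99, af_min = 0.15,
                              afd_threshold = NULL) {
  usable <- effect %in% c("synonymous", "missense")
  cls <- rep("excluded", length(f_overall))
  keep <- usable & !is.na(f_overall) & f_overall >= af_min & !is.na(afd_values)
  if (is.null(afd_threshold))
    afd_threshold <- neutral_quantile(afd_values[keep], afd_quantile)
  cls[keep] <- ifelse(afd_values[keep] > afd_threshold, "divergent", "polymorphic")
  list(class = cls, afd_threshold = afd_threshold)
}

#' McDonald-Kreitman alpha and Fisher significance
#'
#' `alpha = 1 - (Ds * Pn) / (Dn * Ps)`, the proportion of divergence driven by
#' positive selection; the p-value is a two-sided Fisher's exact test on the
#' 2x2 contingency table of divergence class by effect class.
#'
#' @param Dn,Ds Nonsynonymous and synonymous divergences.
#' @param Pn,Ps Nonsynonymous and synonymous polymorphisms.
#' @return List with `alpha` (NA when `Dn == 0` or `Ps == 0`) and `p_value`.
#' @export
mk_alpha <- function(Dn, Ds, Pn, Ps) {
  stopifnot(Dn >= 0, Ds >= 0, Pn >= 0, Ps >= 0)
  alpha <- if (Dn == 0 || Ps == 0) NA_real_ else 1 - (Ds * Pn) / (Dn * Ps)
  p <- stats::fisher.test(matrix(c(Dn, Ds, Pn, Ps), 2, byrow = TRUE))$p.value
  list(alpha = alpha, p_value = p)
}

#' Per-gene and genomewide McDonald-Kreitman scan
#'
#' Counts divergent and polymorphic synonymous/missense sites per gene (as
#' classified by [classify_mk_sites()]) and computes alpha per gene plus a
#' pooled genomewide row.
#'
#' @param site_gene Gene id per site.
#' @param site_effect Effect class per site.
#' @param site_class Classification per site (from [classify_mk_sites()]).
#' @param genes Optional gene universe (defaults to genes observed).
#' @return data.frame of MK results, last row `genomewide`.
#' @export
mk_scan <- function(site_gene, site_effect, site_class, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(site_gene[!is.na(site_gene)]))
  count4 <- function(sel) {
    c(Dn = sum(sel & site_class == "divergent" & site_effect == "missense"),
      Ds = sum(sel & site_class == "divergent" & site_effect == "synonymous"),
      Pn = sum(sel & site_class == "polymorphic" & site_effect == "missense"),
      Ps = sum(sel & site_class == "polymorphic" & site_effect == "synonymous"))
  }
  rows <- lapply(c(genes, "genomewide"), function(g) {
    sel <- if (g == "genomewide") !is.na(site_gene) else !is.na(site_gene) & site_gene == g
    k <- count4(sel)
    mk <- mk_alpha(k["Dn"], k["Ds"], k["Pn"], k["Ps"])
    data.frame(gene = g, Dn = k["Dn"], Ds = k["Ds"], Pn = k["Pn"], Ps = k["Ps"],
               alpha = mk$alpha, p_value = mk$p_value, row.names = NULL)
  })
  do.call(rbind, rows)
}
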