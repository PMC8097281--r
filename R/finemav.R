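#' Rescale a raw SIFT score to a deleteriousness score
#'
#' Raw SIFT is 0 for the most deleterious and 1 for the most tolerated change;
#' the rescaled score `1 - raw` makes higher mean more damaging, matching the
#' orientation of the Grantham score.
#'
#' @param raw Raw SIFT score(s) in [0, 1]; NA passes through.
#' @return `1 - raw`.
#' @export
rescale_sift <- function(raw) {
  if (any(!is.na(raw) & (raw < 0 | raw > 1))) stop("raw SIFT outside [0,1]")
  1 - raw
}

#' Derived allele purity
#'
#' `max(f) / sum(f)` over the per-group derived frequencies: 1 when the
#' derived allele is private to one group, 1/k when evenly shared among k.
#'
#' @param f_vector Derived frequencies per group (NAs dropped).
#' @return DAP, or NA when all frequencies are zero.
#' @export
dap <- function(f_vector) {
  f <- f_vector[!is.na(f_vector)]
  if (!length(f) || sum(f) == 0) return(NA_real_)
  if (any(f < 0 | f > 1)) stop("frequencies outside [0,1]")
  max(f) / sum(f)
}

#' FineMAV score for one site
#'
#' `f_max * DAP^exponent * functional_score`, attributed to the group with
#' the maximal derived frequency (ties broken toward the lowest group index).
#' The functional score is either the Grantham distance of the amino-acid
#' pair or the rescaled SIFT score.
#'
#' @param f_vector Derived frequencies per group.
#' @param functional_score Non-negative deleteriousness score.
#' @param exponent DAP exponent (default 3.5).
#' @return List with `score` (NA when DAP undefined or score missing) and
#'   `top_group` (index of the arg-max group, NA likewise).
#' @export
finemav_score <- function(f_vector, functional_score, exponent = 3.5) {
  d <- dap(f_vector)
  if (is.na(d) || is.na(functional_score))
    return(list(score = NA_real_, top_group = NA_integer_))
  if (functional_score < 0) stop("functional score must be >= 0")
  top <- which.max(f_vector)  # lowest index on ties
  list(score = max(f_vector, na.rm = TRUE) * d^exponent * functional_score,
       top_group = top)
}

finemav_table <- function(f_groups, grantham_scores, sift_raw, exponent = 3.5) {
  # vectorized FineMAV over a matrix of per-group derived frequencies
  fs <- f_groups
  fs[is.na(fs)] <- 0
  fmax <- do.call(pmax, as.data.frame(fs))
  fsum <- rowSums(fs)
  d <- ifelse(fsum > 0, fmax / fsum, NA_real_)
  top <- max.col(fs, ties.method = "first")
  top[fsum == 0] <- NA_integer_
  base <- fmax * d^exponent
  data.frame(dap = d, top_group = colnames(f_groups)[top],
             finemav_grantham = base * grantham_scores,
             finemav_sift = base * rescale_sift(sift_raw))
}

#' Call candidate amino-acid substitutions for one contrast
#'
#' A site is a candidate when its per-SNP FST exceeds the synonymous-site
#' neutral threshold and its FineMAV score exceeds the genomewide missense
#' quantile for the Grantham variant and for the SIFT variant (sites with no
#' SIFT annotation are judged on Grantham alone).
#'
#' @param fst Per-site FST for the contrast (missense sites).
#' @param finemav_grantham,finemav_sift FineMAV scores for the same sites
#'   (NA = unavailable).
#' @param fst_threshold Neutral FST threshold (synonymous 99% quantile).
#' @param finemav_quantile Quantile for the FineMAV outlier flags (0.99).
#' @return data.frame of logical flags `fst_outlier`,
#'   `finemav_grantham_outlier`, `finemav_sift_outlier` (NA when no SIFT) and
#'   `is_candidate`.
#' @export
call_candidates <- function(fst, finemav_grantham, finemav_sift,
                            fst_threshold, finemav_quantile = 0.99) {
  if (!length(fst)) stop("empty candidate table")
  qg <- neutral_quantile(finemav_grantham, finemav_quantile)
  has_sift <- !is.na(finemav_sift)
  qs <- if (any(has_sift)) neutral_quantile(finemav_sift, finemav_quantile) else NA_real_
  fst_out <- !is.na(fst) & fst > fst_threshold
  g_out <- !is.na(finemav_grantham) & finemav_grantham > qg
  s_out <- ifelse(has_sift, finemav_sift > qs, NA)
  data.frame(fst_outlier = fst_out,
             finemav_grantham_outlier = g_out,
             finemav_sift_outlier = s_out,
             is_candidate = fst_out & g_out & (is.na(s_out) | s_out))
}

#' Gene-set enrichment of candidate genes
#'
#' Two-sided Fisher's exact test of the 2x2 table of focus-set membership
#' against candidate status over a gene universe.
#'
#' @param candidate_genes Genes containing at least one candidate site.
#' @param focus_set The focal gene set (e.g. meiosis genes).
#' @param universe All genes considered.
#' @return List with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
gene_set_enrichment <- function(candidate_genes, focus_set, universe) {
  if (!length(universe)) stop("empty gene universe")
  if (!length(intersect(focus_set, universe)))
    stop("focus set disjoint from universe")
  cand <- universe %in% candidate_genes
  foc <- universe %in% focus_set
  tab <- matrix(c(sum(foc & cand), sum(foc & !cand),
                  sum(!foc & cand), sum(!foc & !cand)), 2, byrow = TRUE,
                dimnames = list(c("focus", "nonfocus"),
                                c("candidate", "noncandidate")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
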