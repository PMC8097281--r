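#' Relative sweep-age statistic for one gene
#'
#' A hard sweep clears variation on the swept haplotype; polymorphisms then
#' re-accumulate with time. The ratio of segregating tetraploid SNPs strictly
#' between the first and last candidate site (candidates excluded) to the
#' span in bp is therefore a proxy for sweep age: higher = older.
#'
#' @param candidate_positions Positions of the gene's candidate sites (>= 2).
#' @param segregating_positions Positions segregating in the tetraploid panel.
#' @return List: `span_bp`, `n_accumulated`, `ratio`; all NA with a `reason`
#'   when fewer than 2 candidates.
#' @export
sweep_age <- function(candidate_positions, segregating_positions) {
  if (length(candidate_positions) < 2)
    return(list(span_bp = NA_integer_, n_accumulated = NA_integer_,
                ratio = NA_real_, reason = "fewer than 2 candidate sites"))
  lo <- min(candidate_positions); hi <- max(candidate_positions)
  inside <- segregating_positions > lo & segregating_positions < hi &
    !segregating_positions %in% candidate_positions
  list(span_bp = hi - lo, n_accumulated = sum(inside),
       ratio = sum(inside) / (hi - lo), reason = NA_character_)
}

#' Rank sweeps from oldest to youngest
#'
#' Descending by accumulated-mutation ratio; rank 1 is the oldest sweep.
#' Ties share the minimum rank.
#'
#' @param ratios Named numeric vector of sweep-age ratios (NA dropped).
#' @return data.frame: gene, ratio, rank.
#' @export
rank_sweeps <- function(ratios) {
  r <- ratios[!is.na(ratios)]
  rk <- rank(-r, ties.method = "min")
  out <- data.frame(gene = names(r), ratio = unname(r), rank = as.integer(rk))
  out[order(out$rank), , drop = FALSE]
}

consecutive_distances <- function(positions) {
  p <- sort(unique(positions))
  if (length(p) < 2) return(integer(0))
  diff(p)
}

#' Spacing test for multinucleotide-mutation signal
#'
#' Compares consecutive distances between a gene's candidate sites with the
#' genomewide distribution of consecutive distances between missense SNPs
#' (within genes only), by two-sided Wilcoxon rank-sum. Closely spaced
#' candidates (the working MNM definition being < 20 bp apart) give small
#' p-values.
#'
#' @param candidate_distances Consecutive bp distances within the candidate
#'   set (use [consecutive_distances()]).
#' @param genomewide_distances Pooled consecutive missense distances.
#' @return List: medians, `p_value` (NA with fewer than 2 distances).
#' @export
spacing_test <- function(candidate_distances, genomewide_distances) {
  med_c <- stats::median(candidate_distances)
  med_g <- stats::median(genomewide_distances)
  p <- if (length(candidate_distances) < 2 || !length(genomewide_distances)) {
    NA_real_
  } else {
    suppressWarnings(stats::wilcox.test(
      candidate_distances, genomewide_distances,
      exact = length(candidate_distances) + length(genomewide_distances) < 20,
      correct = TRUE)$p.value)
  }
  list(median_candidate_bp = med_c, median_genomewide_bp = med_g, p_value = p)
}

#' Transversion test for a single substitution
#'
#' @param ref,alt Single nucleotides.
#' @return TRUE for a transversion (purine-pyrimidine change), FALSE for a
#'   transition (A<->G or C<->T). Vectorized.
#' @export
is_transversion <- function(ref, alt) {
  pur <- c("A", "G")
  if (any(!c(ref, alt) %in% c("A", "C", "G", "T"))) stop("non-ACGT allele")
  if (any(ref == alt)) stop("ref and alt must differ")
  (ref %in% pur) != (alt %in% pur)
}

#' Two-proportion z test for transversion excess
#'
#' Tests whether the transversion fraction among candidate substitutions
#' exceeds the genomewide fraction, using the pooled-variance two-proportion
#' z statistic.
#'
#' @param k_tv Transversions among the candidates.
#' @param n Candidate substitutions.
#' @param k_tv_gw,n_gw Genomewide counts.
#' @return List: `z`, `p_one_sided` (excess direction), `p_two_sided`;
#'   z is NA when the pooled proportion is degenerate (0 or 1).
#' @export
tstv_excess_test <- function(k_tv, n, k_tv_gw, n_gw) {
  if (n < 1 || n_gw < 1) stop("need at least one substitution per group")
  p_pool <- (k_tv + k_tv_gw) / (n + n_gw)
  if (p_pool <= 0 || p_pool >= 1)
    return(list(z = NA_real_, p_one_sided = NA_real_, p_two_sided = NA_real_))
  z <- (k_tv / n - k_tv_gw / n_gw) /
    sqrt(p_pool * (1 - p_pool) * (1 / n + 1 / n_gw))
  list(z = z, p_one_sided = stats::pnorm(z, lower.tail = FALSE),
       p_two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Per-gene MNM evidence report
#'
#' Combines the spacing Wilcoxon test and the transversion-excess z test for
#' one gene's candidate substitutions against genomewide baselines; the gene
#' is flagged as MNM-like when both reject at `alpha`.
#'
#' @param cand_positions Candidate site positions in the gene.
#' @param cand_ref,cand_alt Alleles of the candidate substitutions.
#' @param gw_distances Genomewide consecutive missense distances.
#' @param gw_tv,gw_n Genomewide transversion and total counts.
#' @param alpha Flagging level (0.01).
#' @return One-row data.frame with distances, medians, p-values, counts and
#'   `mnm_flag`.
#' @export
mnm_report <- function(cand_positions, cand_ref, cand_alt,
                       gw_distances, gw_tv, gw_n, alpha = 0.01) {
  d <- consecutive_distances(cand_positions)
  sp <- spacing_test(d, gw_distances)
  tv <- is_transversion(cand_ref, cand_alt)
  zt <- tstv_excess_test(sum(tv), length(tv), gw_tv, gw_n)
  flag <- !is.na(sp$p_value) && !is.na(zt$p_one_sided) &&
    sp$p_value < alpha && zt$p_one_sided < alpha &&
    sp$median_candidate_bp < sp$median_genomewide_bp
  data.frame(n_candidates = length(cand_positions),
             median_distance_bp = sp$median_candidate_bp,
             genomewide_median_bp = sp$median_genomewide_bp,
             spacing_p = sp$p_value,
             n_transversions = sum(tv), n_transitions = sum(!tv),
             genomewide_tv_fraction = gw_tv / gw_n,
             tstv_z = zt$z, tstv_p = zt$p_one_sided,
             mnm_flag = flag)
}
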