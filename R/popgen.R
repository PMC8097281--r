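#' Apply the genotype depth and missingness filters
#'
#' Genotypes with read depth <= `min_depth` are set missing (only depths
#' strictly greater than the cutoff are kept); variants whose missing-genotype
#' fraction reaches `max_missing` in any group are removed.
#'
#' @param gm A `genotype_matrix`.
#' @param min_depth Depth cutoff; genotypes at or below it are masked.
#' @param max_missing Per-group missing fraction at or above which a variant
#'   is dropped.
#' @param grouping Character vector (one per individual) assigning groups;
#'   defaults to the popmap lineage.
#' @return Filtered `genotype_matrix`.
#' @export
apply_genotype_filters <- function(gm, min_depth = 8, max_missing = 0.5,
                                   grouping = gm$individuals$lineage) {
  stopifnot(length(grouping) == nrow(gm$individuals))
  if (any(table(grouping) == 0)) stop("empty group in grouping")
  dosage <- gm$dosage
  dosage[gm$depth <= min_depth] <- NA_integer_
  groups <- unique(grouping)
  keep <- rep(TRUE, nrow(dosage))
  for (g in groups) {
    cols <- grouping == g
    frac <- rowMeans(is.na(dosage[, cols, drop = FALSE]))
    keep <- keep & frac < max_missing
  }
  new_genotype_matrix(gm$variants[keep, , drop = FALSE], gm$individuals,
                      dosage[keep, , drop = FALSE],
                      gm$depth[keep, , drop = FALSE])
}

#' Subsample a group to a fixed chromosome count
#'
#' Selects individuals of one group until their summed ploidy reaches
#' `target_chromosomes` (e.g. 32 chromosomes = 16 diploids, 160 = 40
#' tetraploids), either by highest mean depth or at random. Individuals
#' outside the group are dropped.
#'
#' @param gm A `genotype_matrix`.
#' @param group Group label (matched against `grouping`).
#' @param target_chromosomes Desired summed ploidy.
#' @param rule `"highest_depth"` or `"random"`.
#' @param grouping Character vector per individual; defaults to lineage.
#' @param seed Seed used when `rule = "random"`.
#' @return `genotype_matrix` restricted to the selected individuals.
#' @export
subsample_chromosomes <- function(gm, group, target_chromosomes,
                                  rule = c("highest_depth", "random"),
                                  grouping = gm$individuals$lineage, seed = 1L) {
  rule <- match.arg(rule)
  idx <- which(grouping == group)
  if (!length(idx)) stop("unknown or empty group: ", group)
  pl <- gm$individuals$ploidy[idx]
  if (length(unique(pl)) != 1L) stop("mixed ploidy within group ", group)
  if (target_chromosomes %% pl[1] != 0)
    stop("target of ", target_chromosomes,
         " chromosomes not representable with ploidy ", pl[1])
  n_need <- target_chromosomes %/% pl[1]
  if (n_need > length(idx))
    stop("group ", group, " has only ", sum(pl), " chromosomes, need ",
         target_chromosomes)
  ord <- if (rule == "highest_depth") {
    order(colMeans(gm$depth[, idx, drop = FALSE]), decreasing = TRUE)
  } else {
    set.seed(seed)
    sample(length(idx))
  }
  sel <- sort(idx[ord[seq_len(n_need)]])
  ind <- gm$individuals[sel, , drop = FALSE]
  rownames(ind) <- NULL
  new_genotype_matrix(gm$variants, ind,
                      gm$dosage[, sel, drop = FALSE],
                      gm$depth[, sel, drop = FALSE])
}

#' Polarize variants into ancestral/derived states
#'
#' The derived allele is the one not matching the outgroup consensus state;
#' where the outgroup is uninformative the overall minor-frequency allele is
#' taken as derived, with an exact 0.5 tie broken toward ALT (logged).
#'
#' @param gm A `genotype_matrix`.
#' @param outgroup_states Character vector of ancestral bases per variant
#'   (`NA` = uninformative); defaults to the `AA` states read from the VCF.
#' @return `genotype_matrix` with `variants$derived` set to "ref"/"alt".
#' @export
polarize <- function(gm, outgroup_states = gm$variants$aa) {
  v <- gm$variants
  n <- nrow(v)
  if (is.null(outgroup_states)) outgroup_states <- rep(NA_character_, n)
  stopifnot(length(outgroup_states) == n)
  derived <- rep(NA_character_, n)
  derived[outgroup_states == v$ref] <- "alt"
  derived[outgroup_states == v$alt] <- "ref"
  open <- is.na(derived)
  if (any(open)) {
    sub <- gm$dosage[open, , drop = FALSE]
    an <- as.vector((!is.na(sub)) %*% gm$individuals$ploidy)
    ac <- rowSums(sub, na.rm = TRUE)
    f_alt <- ifelse(an > 0, ac / an, NA_real_)
    d <- ifelse(is.na(f_alt) | f_alt <= 0.5, "alt", "ref")
    ties <- sum(!is.na(f_alt) & f_alt == 0.5)
    if (ties) message(ties, " site(s) with overall frequency exactly 0.5; derived = alt")
    derived[open] <- d
  }
  gm$variants$derived <- derived
  gm
}

derived_dosage <- function(gm) {
  # dosage of the derived allele (flip where derived == ref)
  d <- gm$dosage
  flip <- which(gm$variants$derived == "ref")
  if (length(flip)) {
    pl <- rep(gm$individuals$ploidy, each = length(flip))
    d[flip, ] <- matrix(pl, length(flip)) - d[flip, , drop = FALSE]
  }
  d
}

#' Derived-allele counts and frequencies per group
#'
#' AC sums derived dosage over non-missing genotypes, AN sums ploidy over the
#' same genotypes; `f = AC/AN`, NA when no chromosomes were called.
#'
#' @param gm A polarized `genotype_matrix`.
#' @param grouping Character vector per individual (default: lineage).
#' @return List with integer matrices `AC`, `AN` and numeric `f`
#'   (variants x groups, group names as columns).
#' @export
group_frequencies <- function(gm, grouping = gm$individuals$lineage) {
  if (all(is.na(gm$variants$derived))) stop("polarize() the matrix first")
  dd <- derived_dosage(gm)
  groups <- unique(grouping)
  nv <- nrow(dd)
  AC <- AN <- matrix(0L, nv, length(groups), dimnames = list(NULL, groups))
  for (j in seq_along(groups)) {
    cols <- which(grouping == groups[j])
    sub <- dd[, cols, drop = FALSE]
    called <- !is.na(sub)
    AC[, j] <- as.integer(rowSums(sub, na.rm = TRUE))
    AN[, j] <- as.integer(called %*% gm$individuals$ploidy[cols])
  }
  f <- ifelse(AN > 0, AC / AN, NA_real_)
  list(AC = AC, AN = AN, f = f)
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity `2j(n-j) / (n(n-1))` for an allele count
#' `j` of `AC` among `n = AN` called chromosomes.
#'
#' @param AC Derived (or either) allele count.
#' @param AN Called chromosomes.
#' @return Numeric; NA where `AN < 2`. Vectorized.
#' @export
site_pi <- function(AC, AN) {
  n <- max(length(AC), length(AN))
  AC <- rep_len(AC, n); AN <- rep_len(AN, n)
  out <- 2 * AC * (AN - AC) / (AN * (AN - 1))
  out[AN < 2] <- NA_real_
  out
}

#' Tajima's D from a window summary
#'
#' Standard Tajima (1989) statistic computed from the number of segregating
#' sites `S`, the summed per-site heterozygosity (theta-pi) and a constant
#' chromosome count `n`.
#'
#' @param S Number of segregating sites (>= 1 for a defined D).
#' @param pi_sum Sum of [site_pi()] over the window's sites.
#' @param AN Chromosome count, constant across sites.
#' @return Tajima's D, or NA when `S == 0`.
#' @export
tajimas_d <- function(S, pi_sum, AN) {
  if (AN < 2) stop("need at least 2 chromosomes")
  if (S == 0) return(NA_real_)
  n <- AN
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Hudson's per-SNP FST estimator
#'
#' Ratio-of-estimates form suitable for single-variant computation:
#' numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`. Negative values are retained, not clamped.
#'
#' @param p1,p2 Allele frequencies in the two groups.
#' @param n1,n2 Chromosome counts (post-filter AN), both > 1.
#' @return FST, or NA where the denominator is zero. Vectorized.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(stats::na.omit(c(n1, n2)) <= 1)) stop("chromosome counts must exceed 1")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(!is.na(den) & den > 0, num / den, NA_real_)
}

#' Absolute allele frequency difference
#' @param p1,p2 Frequencies.
#' @return `|p1 - p2|`, vectorized.
#' @export
afd <- function(p1, p2) abs(p1 - p2)

#' Empirical neutral quantile threshold
#'
#' Threshold for outlier calling taken from the empirical distribution of a
#' statistic over putatively neutral (synonymous) sites, with type-7 linear
#' interpolation between order statistics.
#'
#' @param values Numeric vector (NAs removed).
#' @param q Quantile, default 0.99.
#' @return The quantile value.
#' @export
neutral_quantile <- function(values, q = 0.99) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to take a quantile of")
  if (length(values) < 100)
    warning("neutral quantile computed from fewer than 100 values")
  unname(stats::quantile(values, q, type = 7))
}

#' Diversity summary per group on fourfold-degenerate sites
#'
#' Computes per-group nucleotide diversity (mean per-site pi over the group's
#' fourfold sites) and Tajima's D at constant chromosome count; sites with
#' residual missingness in the group are dropped for D, as the Tajima
#' constants require a fixed n.
#'
#' @param gm Polarized, filtered, subsampled `genotype_matrix`.
#' @param annotations Annotation table (for the fourfold flag).
#' @param grouping Character vector per individual.
#' @return data.frame: group, n_sites, S, pi (mean per site), tajima_d.
#' @export
diversity_scan <- function(gm, annotations, grouping = gm$individuals$lineage) {
  ff <- annotations$fourfold %in% TRUE
  key <- site_key(gm$variants$chrom, gm$variants$pos)
  use <- key %in% site_key(annotations$chrom[ff], annotations$pos[ff])
  fr <- group_frequencies(gm, grouping)
  groups <- colnames(fr$f)
  out <- lapply(groups, function(g) {
    full <- use & fr$AN[, g] == max(fr$AN[use, g])
    AC <- fr$AC[full, g]; AN <- fr$AN[full, g]
    pis <- site_pi(AC, AN)
    S <- sum(AC > 0 & AC < AN)
    data.frame(group = g, n_sites = sum(full), S = S,
               pi = mean(pis),
               tajima_d = if (S > 0) tajimas_d(S, sum(pis[AC > 0 & AC < AN]),
                                               AN[1]) else NA_real_)
  })
  do.call(rbind, out)
}
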