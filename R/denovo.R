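#' Screen for standing variation of tetraploid-derived alleles in diploids
#'
#' For each candidate site, asks whether any diploid individual in the full
#' (unsubsampled) diploid panel carries at least one copy of the
#' tetraploid-derived allele.
#'
#' @param gm Polarized `genotype_matrix` of the full panel.
#' @param site_index Row indices of the candidate sites.
#' @param diploid_cols Column indices of the diploid individuals (default:
#'   all ploidy-2 individuals).
#' @return data.frame: site row, `present` (any diploid carrier), and
#'   `carrier_count`.
#' @export
standing_screen <- function(gm, site_index,
                            diploid_cols = which(gm$individuals$ploidy == 2L)) {
  if (any(site_index < 1 | site_index > nrow(gm$variants)))
    stop("candidate site absent from matrix")
  dd <- derived_dosage(gm)[site_index, diploid_cols, drop = FALSE]
  carriers <- rowSums(dd >= 1, na.rm = TRUE)
  data.frame(site = site_index, present = carriers > 0, carrier_count = carriers)
}

#' Reconstruct haplotype class frequencies over linked candidate sites
#'
#' With `M_i` the per-site frequency (in the focal group) of the allele that
#' is major in the combined sample, the ancestral-haplotype frequency is
#' `HAFd = min(M)`, the fully derived haplotype `HAFa = 1 - max(M)`, and the
#' recombinant remainder `HAFr = 1 - HAFd - HAFa`. The triple always sums to
#' one and each component lies in [0, 1].
#'
#' @param M_vector `M_i` per candidate site of one gene.
#' @return Named numeric vector `c(HAFd, HAFa, HAFr)`.
#' @export
reconstruct_haf <- function(M_vector) {
  if (!length(M_vector)) stop("empty M vector")
  if (any(is.na(M_vector) | M_vector < 0 | M_vector > 1))
    stop("M values must lie in [0,1]")
  hafd <- min(M_vector)
  hafa <- 1 - max(M_vector)
  c(HAFd = hafd, HAFa = hafa, HAFr = 1 - hafd - hafa)
}

# genotypic-distance lookup tables, transcribed from the printed pair lists.
# Rows/cols indexed by dosage of one fixed allele + 1.
.gd22 <- matrix(0L, 3, 3); .gd22[1, 3] <- .gd22[3, 1] <- 1L  # AA~aa only
.gd44 <- matrix(0L, 5, 5)
for (.p in list(c(4,0), c(3,0), c(4,1), c(1,4), c(0,3), c(0,4)))
  .gd44[.p[1] + 1L, .p[2] + 1L] <- 1L
.gd24 <- matrix(0L, 3, 5)
for (.p in list(c(2,0), c(2,1), c(0,4), c(0,3)))
  .gd24[.p[1] + 1L, .p[2] + 1L] <- 1L
rm(.p)

#' Genotypic distance between two individuals at one site
#'
#' Binary distance from explicit lookup tables: a diploid pair differs (1)
#' only for opposite homozygotes; a tetraploid pair only when dosages differ
#' by at least 3; a diploid-tetraploid pair only when the diploid is
#' homozygous and the tetraploid carries at most one copy of the diploid's
#' allele. Missing dosages contribute 0.
#'
#' @param d1,d2 Allele dosages (same fixed allele for both).
#' @param ploidy1,ploidy2 Ploidies (2 or 4).
#' @return 0 or 1. Vectorized over sites.
#' @export
genotypic_distance <- function(d1, ploidy1, d2, ploidy2) {
  stopifnot(ploidy1 %in% c(2L, 4L), ploidy2 %in% c(2L, 4L))
  ok1 <- is.na(d1) | (d1 >= 0 & d1 <= ploidy1)
  ok2 <- is.na(d2) | (d2 >= 0 & d2 <= ploidy2)
  if (!all(ok1, ok2)) stop("invalid dosage for ploidy")
  out <- integer(length(d1))
  known <- !is.na(d1) & !is.na(d2)
  tab <- if (ploidy1 == 2L && ploidy2 == 2L) .gd22
         else if (ploidy1 == 4L && ploidy2 == 4L) .gd44
         else if (ploidy1 == 2L) .gd24
         else t(.gd24)
  out[known] <- tab[cbind(d1[known] + 1L, d2[known] + 1L)]
  out
}

#' Hamming distance between two individuals over a site set
#'
#' Sum of per-site genotypic distances over the candidate sites of a gene.
#'
#' @param d1,d2 Dosage vectors over the sites.
#' @param ploidy1,ploidy2 Ploidies.
#' @return Integer distance.
#' @export
hamming_distance <- function(d1, ploidy1, d2, ploidy2) {
  sum(genotypic_distance(d1, ploidy1, d2, ploidy2))
}

#' Hamming diameter of a group
#'
#' Maximum pairwise Hamming distance among a group of individuals over the
#' candidate sites; 0 for groups of size one. Individuals missing more than
#' half the sites are excluded.
#'
#' @param dosages Sites x individuals dosage matrix (one fixed allele).
#' @param ploidy Common ploidy of the group.
#' @return Integer diameter.
#' @export
hamming_diameter <- function(dosages, ploidy) {
  keep <- colMeans(is.na(dosages)) <= 0.5
  dosages <- dosages[, keep, drop = FALSE]
  n <- ncol(dosages)
  if (n < 2) return(0L)
  dmax <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    h <- hamming_distance(dosages[, i], ploidy, dosages[, j], ploidy)
    if (h > dmax) dmax <- h
  }
  dmax
}

#' Inter-ploidy Hamming distance and Hamming report for one gene
#'
#' Computes the within-diploid and within-tetraploid Hamming diameters and
#' the diploid-tetraploid distance (summary over all cross-ploidy pairs;
#' `"median"` by default, `"min"` for the most conservative reading) over the
#' gene's candidate sites.
#'
#' @param dip_dosages,tet_dosages Sites x individuals derived-dosage matrices.
#' @param between Cross-pair summary: `"median"` or `"min"`.
#' @return List: `diameter_diploid`, `diameter_tetraploid`,
#'   `distance_between`, `de_novo_supported` (distance exceeds diploid
#'   diameter).
#' @export
hamming_report <- function(dip_dosages, tet_dosages,
                           between = c("median", "min")) {
  between <- match.arg(between)
  keep_d <- colMeans(is.na(dip_dosages)) <= 0.5
  keep_t <- colMeans(is.na(tet_dosages)) <= 0.5
  dip <- dip_dosages[, keep_d, drop = FALSE]
  tet <- tet_dosages[, keep_t, drop = FALSE]
  cross <- numeric(0)
  for (i in seq_len(ncol(dip))) for (j in seq_len(ncol(tet)))
    cross <- c(cross, hamming_distance(dip[, i], 2L, tet[, j], 4L))
  dist_bt <- if (!length(cross)) 0 else if (between == "min") min(cross) else stats::median(cross)
  dd <- hamming_diameter(dip, 2L)
  dt <- hamming_diameter(tet, 4L)
  list(diameter_diploid = dd, diameter_tetraploid = dt,
       distance_between = dist_bt, de_novo_supported = dist_bt > dd)
}

#' Three-criterion de novo verdict for one gene
#'
#' The gene's derived tetraploid haplotype is called de novo only when all
#' three criteria point that way: (A) at least one candidate site's derived
#' allele is absent from every diploid individual, (B) no diploid individual
#' carries the derived allele simultaneously at every candidate site (the
#' complete haplotype is absent; genotype co-occurrence stands in for phased
#' haplotypes), and (C) the diploid-tetraploid Hamming distance exceeds the
#' diploid Hamming diameter.
#'
#' @param gm Polarized full-panel `genotype_matrix`.
#' @param site_index Candidate site rows of the gene (>= 1).
#' @param between Cross-ploidy distance summary (see [hamming_report()]).
#' @return List with the three criterion flags, the `hamming` sublist, and
#'   `verdict`.
#' @export
de_novo_verdict <- function(gm, site_index, between = c("median", "min")) {
  if (!length(site_index)) stop("gene with zero candidate sites")
  dip_cols <- which(gm$individuals$ploidy == 2L)
  tet_cols <- which(gm$individuals$ploidy == 4L)
  dd <- derived_dosage(gm)[site_index, , drop = FALSE]
  scr <- standing_screen(gm, site_index, dip_cols)
  crit_A <- any(!scr$present)
  carries_all <- colSums(dd[, dip_cols, drop = FALSE] >= 1, na.rm = TRUE) ==
    length(site_index)
  crit_B <- !any(carries_all)
  ham <- hamming_report(dd[, dip_cols, drop = FALSE],
                        dd[, tet_cols, drop = FALSE], between = between)
  crit_C <- ham$de_novo_supported
  list(criterion_A_absent_aas = crit_A,
       criterion_B_absent_haplotype = crit_B,
       criterion_C_distance_exceeds_diameter = crit_C,
       hamming = ham,
       verdict = crit_A && crit_B && crit_C)
}

#' Rarefaction of diploid variant discovery
#'
#' For each subsample size, the mean (over random subsets of individuals)
#' fraction of the full panel's segregating variants recovered. Used to judge
#' whether a diploid sampling saturates the standing variation.
#'
#' @param gm Polarized `genotype_matrix` (diploid panel or any panel).
#' @param site_index Polymorphic site rows to track (default: all sites
#'   segregating in the panel).
#' @param sample_sizes Individual counts to rarefy to.
#' @param n_reps Random subsets per size.
#' @param seed RNG seed.
#' @return data.frame: size, mean_fraction.
#' @export
rarefaction_curve <- function(gm, site_index = NULL,
                              sample_sizes = c(5, 10, 20, 40, 80),
                              n_reps = 20, seed = 1L) {
  dd <- derived_dosage(gm)
  seg_full <- rowSums(dd >= 1, na.rm = TRUE) > 0
  if (is.null(site_index)) site_index <- which(seg_full)
  site_index <- site_index[seg_full[site_index]]
  n_ind <- ncol(dd)
  if (any(sample_sizes > n_ind)) stop("sample size exceeds panel size")
  set.seed(seed)
  sub <- dd[site_index, , drop = FALSE]
  out <- vapply(sample_sizes, function(s) {
    mean(vapply(seq_len(n_reps), function(r) {
      cols <- sample(n_ind, s)
      mean(rowSums(sub[, cols, drop = FALSE] >= 1, na.rm = TRUE) > 0)
    }, numeric(1)))
  }, numeric(1))
  data.frame(size = sample_sizes, mean_fraction = out)
}
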