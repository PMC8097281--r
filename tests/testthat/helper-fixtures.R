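# Shared fixtures and independent oracles. Bundles are memoised so multiple
# test files can reuse the same simulated panels.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_cfg <- function(seed = 11) sim_config(n_genes = 60, n_sites_per_gene = 60,
                                            seed = seed)

small_bundle <- function(seed = 11)
  memo(paste0("small", seed), simulate_dataset(small_cfg(seed)))

default_run <- function(seed = 1) {
  memo(paste0("run", seed), {
    b <- simulate_dataset(sim_config(seed = seed))
    list(bundle = b, res = analyze_bundle(b))
  })
}

# toy genotype matrix from a dosage matrix
toy_gm <- function(dosage, ploidy, depth = 30L, lineage = NULL, pop = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(lineage)) lineage <- rep("L1", m)
  if (is.null(pop)) pop <- lineage
  ind <- data.frame(id = sprintf("i%02d", seq_len(m)), population = pop,
                    lineage = lineage, ploidy = as.integer(ploidy))
  v <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                  ref = "A", alt = "T", aa = "A", derived = "alt")
  mixscan:::new_genotype_matrix(v, ind, dosage,
                                matrix(as.integer(depth), n, m))
}

# ---- independent oracles -------------------------------------------------

# Tajima's D recomputed with explicit loops over the constants
tajima_oracle <- function(S, pi_sum, n) {
  a1 <- 0; a2 <- 0
  for (i in seq_len(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (pi_sum - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# per-site pi by explicit pair enumeration over a 0/1 chromosome vector
site_pi_oracle <- function(AC, AN) {
  x <- c(rep(1, AC), rep(0, AN - AC))
  diffs <- 0; pairs <- 0
  for (i in seq_len(AN - 1)) for (j in seq(i + 1, AN)) {
    pairs <- pairs + 1
    if (x[i] != x[j]) diffs <- diffs + 1
  }
  diffs / pairs  # mean pairwise difference == 2j(n-j)/(n(n-1))
}

# PAI by explicit pair enumeration
pai_oracle <- function(column) {
  k <- length(column)
  ident <- 0; pairs <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    pairs <- pairs + 1
    if (column[i] != "-" && column[j] != "-" && column[i] == column[j])
      ident <- ident + 1
  }
  ident / pairs
}

planted_keys <- function(bundle) {
  unlist(lapply(bundle$truth$genes,
                function(t) paste0("chr1:", t$candidate_pos)), use.names = FALSE)
}

called_keys <- function(res) {
  tet <- res$candidates_ploidy
  dip <- res$candidates_diploid_union
  union(paste0(tet$chrom, ":", tet$pos),
        if (is.null(dip)) character(0) else paste0(dip$chrom, ":", dip$pos))
}
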