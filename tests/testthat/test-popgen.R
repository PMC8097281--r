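test_that("depth and missingness filters follow the strict cutoffs", {
  dos <- matrix(1L, 4, 8)
  dep <- matrix(30L, 4, 8)
  dep[1, 1] <- 8L    # at the cutoff: masked (only depth > 8 kept)
  dep[2, 1] <- 9L    # just above: kept
  dos[3, 1:4] <- NA  # 4 of 8 missing = 0.5 fraction: dropped
  gm <- toy_gm(dos, rep(2L, 8))
  gm$depth <- dep
  out <- apply_genotype_filters(gm, grouping = rep("L1", 8))
  expect_equal(nrow(out$variants), 3)         # variant 3 dropped
  expect_true(is.na(out$dosage[1, 1]))        # depth == 8 masked
  expect_equal(out$dosage[2, 1], 1L)          # depth == 9 kept

  clean <- apply_genotype_filters(toy_gm(matrix(1L, 2, 4), rep(2L, 4)),
                                  grouping = rep("L1", 4))
  expect_equal(dim(clean$dosage), c(2L, 4L))
  expect_true(all(clean$dosage == 1L))
})

test_that("chromosome subsampling selects by summed ploidy", {
  dep <- matrix(rep(c(40L, 10L), times = c(16, 4)), 3, 20, byrow = TRUE)
  gm <- toy_gm(matrix(1L, 3, 20), rep(2L, 20))
  gm$depth <- dep
  out <- subsample_chromosomes(gm, "L1", 32)
  expect_equal(nrow(out$individuals), 16)
  expect_equal(sum(out$individuals$ploidy), 32)
  expect_true(all(colMeans(out$depth) == 40))  # the highest-depth 16 kept

  gm4 <- toy_gm(matrix(1L, 2, 40), rep(4L, 40))
  out4 <- subsample_chromosomes(gm4, "L1", 160)
  expect_equal(nrow(out4$individuals), 40)
  expect_error(subsample_chromosomes(gm, "L1", 33), "not representable")
  expect_error(subsample_chromosomes(gm, "L1", 64), "only")
})

test_that("polarization uses the outgroup, then the minor-allele rule with alt tie-break", {
  gm <- toy_gm(matrix(c(1L, 1L, 1L,
                        2L, 2L, 1L,
                        1L, 1L, 0L,
                        1L, 1L, 2L), 4, 3, byrow = TRUE), rep(2L, 3))
  out <- polarize(gm, outgroup_states = c("A", "T", NA, NA))
  expect_equal(out$variants$derived[1], "alt")  # outgroup fixed for ref
  expect_equal(out$variants$derived[2], "ref")  # outgroup carries alt
  expect_equal(out$variants$derived[3], "alt")  # overall alt freq 2/6 minor
  # overall alt frequency 4/6 > 0.5: alt is major, derived = ref
  expect_equal(out$variants$derived[4], "ref")
  gm2 <- toy_gm(matrix(c(1L, 2L, 0L), 1, 3), rep(2L, 3))
  expect_message(out2 <- polarize(gm2, outgroup_states = NA_character_),
                 "0.5")
  expect_equal(out2$variants$derived, "alt")    # documented tie-break
})

test_that("group frequencies use AC/AN over non-missing chromosomes", {
  gm <- toy_gm(matrix(1L, 1, 4), rep(2L, 4))
  fr <- group_frequencies(gm, rep("g", 4))
  expect_equal(unname(fr$AC[1, "g"]), 4L)
  expect_equal(unname(fr$AN[1, "g"]), 8L)
  expect_equal(unname(fr$f[1, "g"]), 0.5)

  gm2 <- toy_gm(matrix(c(4L, 4L, NA), 1, 3), rep(4L, 3))
  fr2 <- group_frequencies(gm2, rep("g", 3))
  expect_equal(unname(fr2$AC[1, "g"]), 8L)
  expect_equal(unname(fr2$AN[1, "g"]), 8L)
  expect_equal(unname(fr2$f[1, "g"]), 1)

  gm3 <- toy_gm(matrix(NA_integer_, 1, 2), rep(2L, 2))
  fr3 <- group_frequencies(gm3, rep("g", 2))
  expect_true(is.na(fr3$f[1, "g"]))
})

test_that("per-site pi matches hand values and the pair-enumeration oracle", {
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(1, 2), 1)
  expect_equal(site_pi(2, 4), 2 * 2 * 2 / (4 * 3))
  expect_true(is.na(site_pi(1, 1)))
  set.seed(1)
  for (r in 1:50) {
    AN <- sample(2:30, 1); AC <- sample(0:AN, 1)
    expect_equal(site_pi(AC, AN), site_pi_oracle(AC, AN), tolerance = 1e-12)
  }
  # maximum at intermediate frequency, invariant to which allele is counted
  expect_true(site_pi(10, 20) >= max(site_pi(0:20, 20) - 1e-12))
  expect_equal(site_pi(3, 20), site_pi(17, 20))
})

test_that("Tajima's D matches an independently coded oracle and neutral behavior", {
  expect_equal(tajimas_d(16, 16 / sum(1 / 1:9), 10), 0)  # theta_pi == theta_W
  expect_true(is.na(tajimas_d(0, 0, 10)))
  d <- tajimas_d(16, 3.888889, 10)
  expect_equal(d, tajima_oracle(16, 3.888889, 10), tolerance = 1e-9)
  set.seed(2)
  for (r in 1:100) {
    n <- sample(4:200, 1); S <- sample(1:500, 1)
    pi_sum <- stats::runif(1, 0, S)
    expect_equal(tajimas_d(S, pi_sum, n), tajima_oracle(S, pi_sum, n),
                 tolerance = 1e-9)
  }
  # a 1/i site-frequency spectrum (neutral equilibrium) gives D near zero
  n <- 40
  xi <- round(2000 / seq_len(n - 1))
  S <- sum(xi)
  pi_sum <- sum(xi * site_pi(seq_len(n - 1), n))
  expect_lt(abs(tajimas_d(S, pi_sum, n)), 0.2)
})

test_that("Hudson FST matches hand evaluations and its invariants", {
  expect_equal(hudson_fst(1, 20, 0, 20), 1)       # fixed difference
  expect_true(is.na(hudson_fst(0, 20, 0, 20)))    # undefined denominator
  expect_equal(hudson_fst(0.5, 20, 0.9, 20), 0.1421053 / 0.5, tolerance = 1e-6)
  expect_error(hudson_fst(0.5, 1, 0.5, 20), "exceed")
  set.seed(3)
  for (r in 1:100) {
    p1 <- stats::runif(1); p2 <- stats::runif(1)
    n1 <- sample(2:300, 1); n2 <- sample(2:300, 1)
    f <- hudson_fst(p1, n1, p2, n2)
    if (is.na(f)) next
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    expect_equal(f, num / den, tolerance = 1e-9)
    expect_lte(f, 1)
    expect_equal(f, hudson_fst(p2, n2, p1, n1))           # group swap
    expect_equal(f, hudson_fst(1 - p1, n1, 1 - p2, n2))   # allele relabel
  }
})

test_that("AFD and the neutral quantile behave as documented", {
  expect_equal(afd(0.9, 0.2), 0.7)
  expect_equal(afd(0.31, 0.31), 0)
  expect_equal(afd(0, 1), 1)
  v <- seq(0.01, 1, by = 0.01)
  expect_equal(neutral_quantile(v, 0.99), unname(stats::quantile(v, 0.99)))
  expect_equal(neutral_quantile(v, 0.99), 0.9901)
  expect_equal(suppressWarnings(neutral_quantile(rep(0.3, 50))), 0.3)
  expect_warning(neutral_quantile(rep(0.3, 50)), "fewer than 100")
  expect_error(neutral_quantile(numeric(0)), "no values")
})

test_that("lineage diversity on fourfold sites tracks the generator's heterozygosity", {
  b <- small_bundle()
  gm <- polarize(apply_genotype_filters(b$gm))
  gm <- subsample_panel(gm)
  ann <- mixscan:::match_annotations(gm, b$annotations)
  div <- diversity_scan(gm, ann)
  expect_true(all(div$pi > 0 & div$pi < 0.5))
  expect_true(all(is.finite(div$tajima_d)))
  # diploid and tetraploid lineages are generated by the same frequency
  # process, so their diversities should be close
  pi_dip <- mean(div$pi[div$group %in% c("DL1", "DL2", "DL3", "DL4", "DL5")])
  pi_tet <- div$pi[div$group == "TET"]
  expect_lt(abs(pi_tet - pi_dip) / pi_dip, 0.15)
})
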