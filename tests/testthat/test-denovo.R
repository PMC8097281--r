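test_that("standing screen reports diploid carriers of the derived allele", {
  dos <- matrix(c(0L, 0L, 0L, 3L,
                  1L, 0L, 0L, 4L), 2, 4, byrow = TRUE)
  gm <- toy_gm(dos, c(2L, 2L, 2L, 4L))
  scr <- standing_screen(gm, 1:2, diploid_cols = 1:3)
  expect_equal(scr$present, c(FALSE, TRUE))
  expect_equal(scr$carrier_count, c(0, 1))
  expect_error(standing_screen(gm, 5), "absent")
})

test_that("HAF reconstruction follows the min/max formulas and sums to one", {
  expect_equal(reconstruct_haf(c(0.9, 0.8)),
               c(HAFd = 0.8, HAFa = 0.1, HAFr = 0.1))
  expect_equal(reconstruct_haf(c(1, 1, 1)), c(HAFd = 1, HAFa = 0, HAFr = 0))
  expect_equal(reconstruct_haf(0.7), c(HAFd = 0.7, HAFa = 0.3, HAFr = 0))
  expect_error(reconstruct_haf(numeric(0)), "empty")
  set.seed(9)
  for (r in 1:1000) {
    M <- stats::runif(sample(1:12, 1))
    h <- reconstruct_haf(M)
    expect_equal(unname(sum(h)), 1, tolerance = 1e-12)
    expect_true(all(h >= -1e-12 & h <= 1 + 1e-12))
  }
})

test_that("genotypic distance transcribes the printed pair lists exactly", {
  # diploid pairs: distance 1 exactly for opposite homozygotes
  for (d1 in 0:2) for (d2 in 0:2)
    expect_equal(genotypic_distance(d1, 2L, d2, 2L),
                 as.integer(abs(d1 - d2) == 2))
  # tetraploid pairs: the six printed pairs are exactly |diff| >= 3
  for (d1 in 0:4) for (d2 in 0:4)
    expect_equal(genotypic_distance(d1, 4L, d2, 4L),
                 as.integer(abs(d1 - d2) >= 3))
  # cross-ploidy: diploid homozygote vs <= 1 shared copy
  for (d1 in 0:2) for (d2 in 0:4) {
    expected <- as.integer((d1 == 2 && d2 <= 1) || (d1 == 0 && d2 >= 3))
    expect_equal(genotypic_distance(d1, 2L, d2, 4L), expected)
    expect_equal(genotypic_distance(d2, 4L, d1, 2L), expected)  # symmetry
  }
  # the spec's spot examples
  expect_equal(genotypic_distance(2, 2L, 0, 2L), 1L)
  expect_equal(genotypic_distance(2, 2L, 1, 2L), 0L)
  expect_equal(genotypic_distance(3, 4L, 0, 4L), 1L)
  expect_equal(genotypic_distance(3, 4L, 1, 4L), 0L)
  expect_equal(genotypic_distance(2, 2L, 1, 4L), 1L)
  expect_equal(genotypic_distance(1, 2L, 0, 4L), 0L)
  expect_equal(genotypic_distance(NA_integer_, 2L, 2, 2L), 0L)  # missing -> 0
  expect_error(genotypic_distance(3, 2L, 0, 2L), "invalid")
})

test_that("Hamming distance and diameter sum per-site distances", {
  expect_equal(hamming_distance(c(2L, 1L, 0L), 2L, c(2L, 1L, 0L), 2L), 0L)
  expect_equal(hamming_distance(c(2L, 2L, 2L), 2L, c(0L, 0L, 0L), 2L), 3L)
  expect_equal(hamming_distance(c(2L, 1L, 0L), 2L, c(0L, 1L, 2L), 2L), 2L)
  expect_equal(hamming_diameter(matrix(1L, 3, 4), 2L), 0L)  # monomorphic
  expect_equal(hamming_diameter(cbind(c(0L, 0L), c(2L, 2L), c(1L, 1L)), 2L), 2L)
  expect_equal(hamming_diameter(matrix(0L, 2, 1), 2L), 0L)  # single individual
})

test_that("the three-criterion verdict is a strict conjunction", {
  # diploids carry nothing; tetraploids carry the full haplotype at dosage 4
  dos <- rbind(c(0L, 0L, 0L, 4L, 4L, 3L),
               c(0L, 0L, 0L, 4L, 4L, 4L))
  gm <- toy_gm(dos, c(2L, 2L, 2L, 4L, 4L, 4L))
  vd <- de_novo_verdict(gm, 1:2)
  expect_true(vd$criterion_A_absent_aas)
  expect_true(vd$criterion_B_absent_haplotype)
  expect_true(vd$criterion_C_distance_exceeds_diameter)
  expect_true(vd$verdict)

  # a diploid carrying the full haplotype defeats A and B
  dos2 <- rbind(c(1L, 0L, 0L, 4L, 4L, 3L),
                c(1L, 0L, 0L, 4L, 4L, 4L))
  gm2 <- toy_gm(dos2, c(2L, 2L, 2L, 4L, 4L, 4L))
  vd2 <- de_novo_verdict(gm2, 1:2)
  expect_false(vd2$criterion_A_absent_aas)
  expect_false(vd2$criterion_B_absent_haplotype)
  expect_false(vd2$verdict)

  # A true but C false (tetraploid haplotype not beyond diploid variation)
  dos3 <- rbind(c(0L, 0L, 0L, 2L, 2L, 2L),
                c(0L, 0L, 0L, 2L, 2L, 2L))
  gm3 <- toy_gm(dos3, c(2L, 2L, 2L, 4L, 4L, 4L))
  vd3 <- de_novo_verdict(gm3, 1:2)
  expect_true(vd3$criterion_A_absent_aas)
  expect_false(vd3$criterion_C_distance_exceeds_diameter)
  expect_false(vd3$verdict)
  expect_error(de_novo_verdict(gm, integer(0)), "zero candidate")
})

test_that("verdicts recover the planted sweep modes on the default bundle", {
  r <- default_run(1)
  v <- r$res$verdicts
  for (t in r$bundle$truth$genes) {
    row <- v[v$gene == t$gene, ]
    if (!nrow(row)) next
    if (t$mode == "de_novo") expect_true(row$verdict_de_novo, label = t$gene)
    if (t$mode %in% c("standing", "parallel"))
      expect_false(row$verdict_de_novo, label = t$gene)
  }
  scr <- r$res$standing_screen
  for (t in r$bundle$truth$genes) {
    s <- scr[scr$gene == t$gene, ]
    if (t$mode == "standing") expect_true(all(s$present_in_diploids))
    if (t$mode == "de_novo" && !isTRUE(t$mnm_cluster))
      expect_false(any(s$present_in_diploids))
  }
})

test_that("rarefaction saturates at the full panel and increases with sampling", {
  set.seed(10)
  dos <- matrix(rbinom(200 * 30, 2, 0.08), 200, 30)
  gm <- toy_gm(dos, rep(2L, 30))
  rc <- rarefaction_curve(gm, sample_sizes = c(2, 5, 10, 20, 30), n_reps = 30)
  expect_equal(rc$mean_fraction[rc$size == 30], 1)
  expect_true(all(diff(rc$mean_fraction) >= -0.02))  # monotone in expectation
  expect_error(rarefaction_curve(gm, sample_sizes = 31), "exceeds")
  # all-singleton data: one individual carries each variant, so a single
  # sampled individual recovers 1/N of them in expectation
  sing <- matrix(0L, 30, 30); diag(sing) <- 1L
  gms <- toy_gm(sing, rep(2L, 30))
  rc1 <- rarefaction_curve(gms, sample_sizes = 1, n_reps = 400, seed = 2)
  expect_equal(rc1$mean_fraction, 1 / 30, tolerance = 0.25)
})
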