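test_that("the generator is fully deterministic under a fixed seed", {
  b1 <- simulate_dataset(small_cfg(seed = 42))
  b2 <- simulate_dataset(small_cfg(seed = 42))
  expect_identical(b1$gm$dosage, b2$gm$dosage)
  expect_identical(b1$gm$depth, b2$gm$depth)
  expect_identical(b1$annotations, b2$annotations)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$msas, b2$msas)
})

test_that("lineage frequencies concentrate on the ancestral value as F -> 0", {
  cfg <- sim_config(n_genes = 10, n_sites_per_gene = 100, F_lineage = 1e-4,
                    seed = 3)
  fr <- simulate_frequencies(cfg)
  expect_lt(max(abs(fr$f - fr$p_anc)), 0.05)
})

test_that("lineage frequencies are unbiased around the ancestral spectrum", {
  cfg <- sim_config(n_genes = 100, n_sites_per_gene = 100, seed = 5)
  fr <- simulate_frequencies(cfg)
  # law of total expectation: E[f_lineage] = E[p]; Monte-Carlo tolerance at
  # 10^4 sites (sd of the mean difference ~ sd(f - p)/100)
  for (j in seq_len(ncol(fr$f)))
    expect_lt(abs(mean(fr$f[, j]) - mean(fr$p_anc)), 0.005)
  expect_error(simulate_frequencies(within(cfg, lineages$F <- 1.5)), "F must")
})

test_that("planted sweep modes set the promised lineage frequencies", {
  cfg <- small_cfg(seed = 7)
  sites <- mixscan:::sim_sites(cfg)
  fr <- simulate_frequencies(cfg)
  dip <- cfg$lineages$lineage[cfg$lineages$ploidy == 2]

  set.seed(99)
  ps <- mixscan:::plant_sweep(fr, sites, "g011", "de_novo", 3, 0.95, cfg)
  expect_true(all(ps$f[ps$truth$candidate_rows, dip] == 0))
  expect_true(all(ps$f[ps$truth$candidate_rows, "TET"] == 0.95))

  ps2 <- mixscan:::plant_sweep(fr, sites, "g012", "standing", 3, 0.95, cfg)
  expect_true(all(ps2$f[ps2$truth$candidate_rows, dip] > 0))
  expect_true(all(ps2$f[ps2$truth$candidate_rows, dip] <= 0.15))

  ps3 <- mixscan:::plant_sweep(fr, sites, "g013", "parallel", 3, 0.95, cfg)
  expect_true(all(ps3$f[ps3$truth$candidate_rows, cfg$parallel_lineage] == 0.95))
  expect_true(all(ps3$f[ps3$truth$candidate_rows, setdiff(dip, cfg$parallel_lineage)] == 0))

  ps0 <- mixscan:::plant_sweep(fr, sites, "g014", "none", 3, 0.95, cfg)
  expect_identical(ps0$f, fr$f)
})

test_that("MNM clusters have bounded spacing and the requested tv composition", {
  cfg <- small_cfg(seed = 8)
  sites <- mixscan:::sim_sites(cfg)
  set.seed(1)
  pm <- mixscan:::plant_mnm(sites, "g020", 6, 19, 1, cfg)
  pos <- sort(pm$sites$pos[pm$cluster_rows])
  expect_true(all(diff(pos) <= 19))
  expect_true(all(is_transversion(pm$sites$ref[pm$cluster_rows],
                                  pm$sites$alt[pm$cluster_rows])))
  set.seed(1)
  pm0 <- mixscan:::plant_mnm(sites, "g021", 6, 19, 0, cfg)
  expect_false(any(is_transversion(pm0$sites$ref[pm0$cluster_rows],
                                   pm0$sites$alt[pm0$cluster_rows])))
  expect_false(anyDuplicated(pm$sites$pos[pm$sites$gene == "g020"]) > 0)
  expect_error(mixscan:::plant_mnm(sites, "g022", 1000, 19, 1, cfg), "too short")
})

test_that("binomial dosage sampling matches its moments and edge cases", {
  cfg <- small_cfg(seed = 9)
  ind <- data.frame(id = sprintf("i%d", 1:4), population = "p",
                    lineage = c("A", "A", "B", "C"), ploidy = c(4L, 4L, 2L, 4L))
  f <- cbind(A = rep(0.5, 10000), B = rep(1, 10000), C = rep(0, 10000))
  g <- mixscan:::sample_genotypes(f, ind, cfg, seed = 4)
  m <- mean(g$dosage[, 1], na.rm = TRUE)
  se <- sqrt(4 * 0.5 * 0.5) / sqrt(sum(!is.na(g$dosage[, 1])))
  expect_lt(abs(m - 2), 3 * se)
  expect_true(all(g$dosage[, 3] == 2, na.rm = TRUE))  # f = 1
  expect_true(all(g$dosage[, 4] == 0, na.rm = TRUE))  # f = 0
  expect_true(all(is.na(g$dosage[g$depth <= 8])))     # depth filter exercised
})

test_that("simulated alignments honor constraint classes", {
  cfg_msa <- list(n_species = 17L, conserved_rate = 0, neutral_rate = 0.45,
                  background_rate = 0.2, gap_prob = 0)
  L <- 600
  constraint <- rep(c("conserved", "neutral"), each = L / 2)
  msa <- simulate_msa(L, constraint, cfg_msa, seed = 2)
  expect_equal(length(msa$seqs), 17)
  mat <- do.call(rbind, strsplit(msa$seqs, ""))
  pai <- apply(mat, 2, pai_column)
  expect_true(all(pai[constraint == "conserved"] == 1))
  # closed-form mean pair identity under rate-s substitution to 19 other
  # residues: pairs with ref give 1-s, non-ref pairs (1-s)^2 + s^2/19
  s <- 0.45; m <- 16
  exp_pai <- (m * (1 - s) + choose(m, 2) * ((1 - s)^2 + s^2 / 19)) / choose(17, 2)
  expect_lt(abs(mean(pai[constraint == "neutral"]) - exp_pai), 0.02)
})

test_that("de novo planted sites are guaranteed absent from diploid samples", {
  b <- small_bundle()
  dd <- mixscan:::derived_dosage(polarize(b$gm))
  dip <- which(b$gm$individuals$ploidy == 2)
  for (t in b$truth$genes) {
    if (t$mode != "de_novo") next
    rows <- match(t$candidate_pos, b$gm$variants$pos)
    expect_true(all(dd[rows, dip] == 0, na.rm = TRUE))
  }
})

test_that("an emitted bundle is complete and round-trips through the readers", {
  dir <- withr::local_tempdir()
  paths <- emit_dataset(small_bundle(), dir)
  for (p in paths[c("vcf", "annotations", "popmap", "sift", "grantham", "truth", "genes")])
    expect_true(file.exists(p))
  b2 <- read_bundle(dir)
  b <- small_bundle()
  expect_identical(unname(b2$gm$dosage), unname(b$gm$dosage))
  expect_equal(b2$annotations$pos, b$annotations$pos)
  expect_equal(sort(names(b2$msas)), sort(names(b$msas)))
  expect_equal(length(b2$truth$genes), length(b$truth$genes))
  n_planted <- sum(vapply(b2$truth$genes, function(t) length(t$candidate_pos), 1))
  expect_equal(n_planted,
               sum(vapply(b$truth$genes, function(t) length(t$candidate_pos), 1)))
})

test_that("the neutral synonymous FST quantile is stable across seeds", {
  q <- vapply(c(101, 102, 103), function(s) {
    cfg <- sim_config(n_genes = 120, n_sites_per_gene = 60, seed = s)
    cfg$sweep_plan <- cfg$sweep_plan[0, ]
    cfg$mnm_plan <- cfg$mnm_plan[0, ]
    b <- simulate_dataset(cfg)
    gm <- polarize(apply_genotype_filters(b$gm))
    gm <- subsample_panel(gm)
    ann <- mixscan:::match_annotations(gm, b$annotations)
    fr <- group_frequencies(gm, ifelse(gm$individuals$ploidy == 2, "d", "t"))
    fst <- hudson_fst(fr$f[, "d"], fr$AN[, "d"], fr$f[, "t"], fr$AN[, "t"])
    neutral_quantile(fst[ann$effect == "synonymous"], 0.99)
  }, numeric(1))
  expect_lt(max(q) - min(q), 0.05)
})
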