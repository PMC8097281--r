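test_that("popmap reader validates ploidy and uniqueness", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tpopulation\tlineage\tploidy",
               "a\tp1\tL1\t2", "b\tp1\tL1\t4", "c\tp2\tL2\t2"), tf)
  pm <- read_popmap(tf)
  expect_equal(nrow(pm), 3)
  expect_equal(pm$ploidy, c(2L, 4L, 2L))

  writeLines(c("id\tpopulation\tlineage\tploidy", "a\tp1\tL1\t3"), tf)
  expect_error(read_popmap(tf), "ploidy")

  writeLines(c("id\tpopulation\tlineage\tploidy",
               "a\tp1\tL1\t2", "a\tp2\tL1\t2"), tf)
  expect_error(read_popmap(tf), "duplicated")
})

test_that("VCF parsing counts ALT alleles per ploidy, handles missing and multiallelics", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  pm <- data.frame(id = c("d1", "t1"), population = "p", lineage = c("L1", "T"),
                   ploidy = c(2L, 4L))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\td1\tt1",
    "chr1\t10\t.\tA\tG\t.\tPASS\tAA=A\tGT:DP\t0/1:20\t0/1/1/1:30",
    "chr1\t20\t.\tC\tT\t.\tPASS\t.\tGT:DP\t./.:5\t1/1/1/1:22",
    "chr1\t30\t.\tG\tA,T\t.\tPASS\t.\tGT:DP\t0/1:9\t0/0/0/1:9",
    "chr1\t40\t.\tT\tTA\t.\tPASS\t.\tGT:DP\t0/0:9\t0/0/0/0:9"), tf)
  expect_message(gm <- read_vcf(tf, pm), "2 non-biallelic-SNP")
  expect_equal(nrow(gm$variants), 2)
  expect_equal(unname(gm$dosage[1, ]), c(1L, 3L))
  expect_true(is.na(gm$dosage[2, 1]))
  expect_equal(gm$dosage[2, 2], 4L)
  expect_equal(gm$variants$aa, c("A", NA))
  expect_equal(attr(gm, "skipped"), 2)
})

test_that("GT arity mismatching the popmap ploidy is an error naming the sample", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  pm <- data.frame(id = "t1", population = "p", lineage = "T", ploidy = 4L)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tt1",
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:20"), tf)
  expect_error(read_vcf(tf, pm), "t1")
  pm2 <- data.frame(id = "x9", population = "p", lineage = "T", ploidy = 4L)
  expect_error(read_vcf(tf, pm2), "not in popmap")
})

test_that("a simulated panel round-trips exactly through VCF", {
  b <- small_bundle()
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(b$gm, tf)
  gm2 <- read_vcf(tf, b$gm$individuals)
  expect_identical(unname(gm2$dosage), unname(b$gm$dosage))
  expect_identical(unname(gm2$depth), unname(b$gm$depth))
  expect_equal(gm2$variants$pos, b$gm$variants$pos)
  expect_equal(gm2$variants$aa, b$gm$variants$aa)
})

test_that("annotation reader enforces the missense and fourfold contracts", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "chrom\tpos\tref\talt\tgene\teffect\taa_pos\taa_ref\taa_alt\tfourfold"
  writeLines(c(hdr,
               "chr1\t10\tA\tG\tg1\tmissense\t3\tL\tR\tFALSE",
               "chr1\t20\tC\tT\tg1\tsynonymous\tNA\tNA\tNA\tTRUE",
               "chr1\t30\tG\tA\tg1\tsplice_region\tNA\tNA\tNA\tFALSE"), tf)
  an <- read_annotations(tf)
  expect_equal(an$effect, c("missense", "synonymous", "other"))
  expect_true(an$fourfold[2])

  writeLines(c(hdr, "chr1\t10\tA\tG\tg1\tmissense\t3\t\tR\tFALSE"), tf)
  expect_error(read_annotations(tf), "missense")
  writeLines(c(hdr, "chr1\t10\tA\tG\tg1\tmissense\t3\tL\tR\tTRUE"), tf)
  expect_error(read_annotations(tf), "fourfold")
})

test_that("bundled Grantham matrix has the published structure", {
  g <- read_grantham()
  expect_equal(dim(g), c(20, 20))
  expect_true(isSymmetric(unname(g)))
  expect_true(all(diag(g) == 0))
  expect_equal(g["C", "W"], 215)   # the most radical exchange in the table
  expect_equal(g["L", "I"], 5)
  expect_equal(g["S", "S"], 0)
})

test_that("malformed Grantham and SIFT inputs are rejected", {
  g <- read_grantham()
  tf <- withr::local_tempfile(fileext = ".tsv")
  g2 <- g; g2["A", "C"] <- 1
  utils::write.table(data.frame(aa = rownames(g2), g2, check.names = FALSE),
                     tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_grantham(tf), "symmetric")

  writeLines(c("chrom\tpos\tsift", "chr1\t10\t1.4"), tf)
  expect_error(read_sift(tf), "SIFT")
})

test_that("MSA reader enforces equal lengths and reference presence", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref", "MKL-A", ">sp01", "MKLRA"), tf)
  msa <- read_msa(tf)
  expect_equal(length(msa$seqs), 2)
  writeLines(c(">ref", "MKL", ">sp01", "MKLRA"), tf)
  expect_error(read_msa(tf), "ragged")
  writeLines(c(">a", "MKL", ">b", "MKL"), tf)
  expect_error(read_msa(tf), "reference")
})
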