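#' @keywords internal
"_PACKAGE"

AA1 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

MISSING_DOSAGE <- NA_integer_

#' Read a population map
#'
#' A population map assigns every sequenced individual to a population, a
#' lineage and a ploidy level. Downstream grouping (lineage frequencies,
#' ploidy contrasts) is driven entirely by this table.
#'
#' @param path Path to a tab-separated file with columns `id`, `population`,
#'   `lineage`, `ploidy`.
#' @return A data.frame of individuals with integer `ploidy` (2 or 4).
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "population", "lineage", "ploidy")
  if (!all(need %in% names(pm)))
    stop("popmap must have columns: ", paste(need, collapse = ", "))
  pm <- pm[, need]
  pm$ploidy <- suppressWarnings(as.integer(pm$ploidy))
  validate_individuals(pm)
  pm
}

validate_individuals <- function(pm) {
  if (anyNA(pm$ploidy) || !all(pm$ploidy %in% c(2L, 4L)))
    stop("ploidy must be 2 or 4 for every individual")
  if (anyDuplicated(pm$id))
    stop("duplicated individual id in popmap: ",
         paste(unique(pm$id[duplicated(pm$id)]), collapse = ", "))
  invisible(pm)
}

new_genotype_matrix <- function(variants, individuals, dosage, depth) {
  stopifnot(nrow(dosage) == nrow(variants), ncol(dosage) == nrow(individuals),
            all(dim(dosage) == dim(depth)))
  pl <- matrix(rep(individuals$ploidy, each = nrow(variants)), nrow(variants))
  bad <- !is.na(dosage) & (dosage < 0L | dosage > pl)
  if (any(bad)) stop("dosage outside 0..ploidy at ", sum(bad), " genotypes")
  structure(list(variants = variants, individuals = individuals,
                 dosage = dosage, depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNPs x %d individuals (%d diploid, %d tetraploid)\n",
              nrow(x$variants), nrow(x$individuals),
              sum(x$individuals$ploidy == 2), sum(x$individuals$ploidy == 4)))
  invisible(x)
}

#' Read a mixed-ploidy VCF into a genotype matrix
#'
#' Parses GT (arity 2 or 4, matching each sample's ploidy in the popmap) and
#' DP per genotype. Only biallelic SNP records are retained; multiallelic or
#' indel records are skipped and counted. A GT containing `.` anywhere is
#' treated as missing. The optional `AA` INFO key (ancestral allele) is
#' carried along for polarization.
#'
#' @param path VCF file (plain text or gzipped).
#' @param popmap Data.frame from [read_popmap()]; every VCF sample must be
#'   present in it.
#' @return A `genotype_matrix` with `variants` (chrom, pos, ref, alt, aa,
#'   derived), `individuals`, integer `dosage` (count of ALT alleles, NA =
#'   missing) and integer `depth`, plus a `skipped` attribute with the count
#'   of non-biallelic-SNP records dropped.
#' @export
read_vcf <- function(path, popmap) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, popmap$id)
  if (length(unknown))
    stop("VCF sample(s) not in popmap: ", paste(unknown, collapse = ", "))
  ind <- popmap[match(samples, popmap$id), , drop = FALSE]
  rownames(ind) <- NULL

  snp <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  skipped <- sum(!snp)
  if (skipped) message(skipped, " non-biallelic-SNP record(s) skipped")

  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[snp, , drop = FALSE]
  dp[is.na(dp)] <- 0
  mode(dp) <- "integer"

  miss <- is.na(gt) | grepl(".", gt, fixed = TRUE)
  # arity check on called genotypes: number of allele fields must equal ploidy
  arity <- nchar(gt) - nchar(gsub("[/|]", "", gt)) + 1L
  pl <- matrix(rep(ind$ploidy, each = nrow(gt)), nrow(gt))
  bad <- !miss & arity != pl
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("GT arity does not match ploidy for sample %s at record %s:%s",
                 samples[w[2]], fix$CHROM[snp][w[1]], fix$POS[snp][w[1]]))
  }
  dosage <- nchar(gt) - nchar(gsub("1", "", gt, fixed = TRUE))
  mode(dosage) <- "integer"
  dosage[miss] <- NA_integer_

  info <- fix$INFO[snp]
  aa <- rep(NA_character_, length(info))
  has <- grepl("AA=", info, fixed = TRUE)
  aa[has] <- sub(".*AA=([ACGT]).*", "\\1", info[has])
  aa[has & !aa %in% c("A", "C", "G", "T")] <- NA_character_

  variants <- data.frame(chrom = fix$CHROM[snp], pos = as.integer(fix$POS[snp]),
                         ref = fix$REF[snp], alt = fix$ALT[snp],
                         aa = aa, derived = NA_character_,
                         stringsAsFactors = FALSE)
  gm <- new_genotype_matrix(variants, ind, dosage, dp)
  attr(gm, "skipped") <- skipped
  gm
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Emits GT/DP per sample with GT arity equal to each individual's ploidy and
#' the ancestral allele (when known) as `AA=` in INFO. Round-trips exactly
#' through [read_vcf()].
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  n <- nrow(v)
  header <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals$id), collapse = "\t"))
  info <- ifelse(is.na(v$aa), ".", paste0("AA=", v$aa))
  # genotype strings per ploidy/dosage, precomputed lookup
  gt2 <- c("0/0", "0/1", "1/1")
  gt4 <- c("0/0/0/0", "0/0/0/1", "0/0/1/1", "0/1/1/1", "1/1/1/1")
  cols <- lapply(seq_len(nrow(gm$individuals)), function(i) {
    d <- gm$dosage[, i]
    g <- if (gm$individuals$ploidy[i] == 2L) gt2[d + 1L] else gt4[d + 1L]
    g[is.na(d)] <- if (gm$individuals$ploidy[i] == 2L) "./." else "./././."
    paste0(g, ":", gm$depth[, i])
  })
  body <- do.call(paste, c(list(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                                info, "GT:DP"), cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant annotation table
#'
#' One row per biallelic SNP with its gene assignment, effect class and, for
#' missense variants, the amino-acid change. Effect values other than
#' `synonymous`/`missense` are mapped to `other`.
#'
#' @param path TSV with columns chrom, pos, ref, alt, gene, effect, aa_pos,
#'   aa_ref, aa_alt, fourfold.
#' @return A typed data.frame; `fourfold` is logical and implies synonymous.
#' @export
read_annotations <- function(path) {
  an <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "effect", "aa_pos",
            "aa_ref", "aa_alt", "fourfold")
  if (!all(need %in% names(an)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  an <- an[, need]
  an$pos <- as.integer(an$pos)
  an$effect[!an$effect %in% c("synonymous", "missense")] <- "other"
  an$fourfold <- as.logical(an$fourfold)
  an$aa_pos <- as.integer(an$aa_pos)
  mis <- an$effect == "missense"
  bad <- mis & (is.na(an$aa_ref) | is.na(an$aa_alt) | is.na(an$aa_pos) |
                  an$aa_ref == an$aa_alt)
  if (any(bad))
    stop("missense annotation lacking (or with identical) amino-acid fields at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(an$fourfold & an$effect != "synonymous"))
    stop("fourfold sites must be synonymous")
  an
}

#' Read a gene model table
#'
#' @param path TSV with columns gene, chrom, start, end, in_focus (1-based
#'   inclusive intervals; `in_focus` marks membership in the focal gene set,
#'   e.g. a curated meiosis-gene list).
#' @return data.frame of gene models.
#' @export
read_genes <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  g$start <- as.integer(g$start); g$end <- as.integer(g$end)
  g$in_focus <- as.logical(g$in_focus)
  if (any(g$start > g$end)) stop("gene with start > end")
  if (anyDuplicated(g$gene)) stop("duplicated gene id")
  g
}

#' Read the Grantham amino-acid distance matrix
#'
#' @param path Whitespace-delimited 20x20 table with single-letter amino-acid
#'   header row and column. Defaults to the bundled 1974 matrix.
#' @return A symmetric 20x20 numeric matrix with zero diagonal, max entry 215.
#' @export
read_grantham <- function(path = system.file("extdata", "grantham1974.tsv",
                                             package = "mixscan")) {
  g <- utils::read.table(path, header = TRUE, row.names = 1, check.names = FALSE)
  g <- as.matrix(g)
  if (!all(sort(rownames(g)) == sort(AA1)) || !all(sort(colnames(g)) == sort(AA1)))
    stop("Grantham matrix must be indexed by the 20 amino acids")
  g <- g[AA1, AA1]
  if (!isSymmetric(unname(g))) stop("Grantham matrix is not symmetric")
  if (any(diag(g) != 0)) stop("Grantham matrix diagonal must be zero")
  if (any(g < 0) || max(g) != 215) stop("Grantham matrix entries out of range")
  g
}

#' Read a per-variant SIFT score table
#'
#' Raw SIFT scores lie in [0, 1] with 0 the most deleterious. Variants absent
#' from the table (e.g. proteins with no SIFT database entry) are simply not
#' listed; downstream scoring treats them as score-unavailable.
#'
#' @param path TSV with columns chrom, pos, sift.
#' @return data.frame with chrom, pos, sift.
#' @export
read_sift <- function(path) {
  s <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  s$pos <- as.integer(s$pos)
  s$sift <- as.numeric(s$sift)
  if (any(!is.na(s$sift) & (s$sift < 0 | s$sift > 1)))
    stop("SIFT scores must lie in [0,1]")
  s
}

#' Read a protein multiple sequence alignment
#'
#' @param path FASTA file of aligned amino-acid sequences (gap `-`).
#' @param reference_name Name of the reference row (must be present).
#' @return List with `seqs` (named character vector of equal-length aligned
#'   sequences) and `reference_name`.
#' @export
read_msa <- function(path, reference_name = "ref") {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences differ in length")
  if (!reference_name %in% names(seqs))
    stop("reference sequence '", reference_name, "' absent from alignment")
  list(seqs = seqs, reference_name = reference_name)
}

# site key shared by annotation/SIFT/variant joins
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
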