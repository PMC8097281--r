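#' Pairwise alignment identity of one alignment column
#'
#' Mean pairwise identity over all unordered sequence pairs in the column;
#' any pair involving a gap counts as non-identical (gaps are sites with zero
#' identity), so a fully conserved gap-free column scores 1.
#'
#' @param column Character vector of residues (single letters, `-` for gap)
#'   of length >= 2.
#' @return PAI in [0, 1].
#' @export
pai_column <- function(column) {
  k <- length(column)
  if (k < 2) stop("column needs at least 2 sequences")
  res <- column[column != "-"]
  ident <- sum(choose(table(res), 2))
  ident / choose(k, 2)
}

#' Map a reference protein position to an alignment column
#'
#' @param msa Alignment from [read_msa()].
#' @param ref_protein_pos 1-based residue position in the ungapped reference.
#' @return 1-based alignment column index of that residue.
#' @export
map_reference_position <- function(msa, ref_protein_pos) {
  ref <- strsplit(msa$seqs[[msa$reference_name]], "")[[1]]
  non_gap <- which(ref != "-")
  if (ref_protein_pos < 1 || ref_protein_pos > length(non_gap))
    stop("position ", ref_protein_pos, " beyond reference length ",
         length(non_gap))
  non_gap[ref_protein_pos]
}

#' Conservation table for a gene's candidate residues
#'
#' @param msa Alignment from [read_msa()].
#' @param ref_positions Reference protein positions of the candidate sites.
#' @return data.frame: ref_pos, column, pai, n_sequences, n_gaps.
#' @export
conservation_table <- function(msa, ref_positions) {
  mat <- do.call(rbind, strsplit(msa$seqs, ""))
  rows <- lapply(ref_positions, function(p) {
    col <- map_reference_position(msa, p)
    cc <- mat[, col]
    data.frame(ref_pos = p, column = col, pai = pai_column(cc),
               n_sequences = length(cc), n_gaps = sum(cc == "-"))
  })
  do.call(rbind, rows)
}

#' Compare conservation of two candidate sets
#'
#' Two-sided Wilcoxon rank-sum test of the PAI values at tetraploid-contrast
#' candidate sites against diploid-contrast candidate sites.
#'
#' @param pai_tetraploid,pai_diploid PAI samples (both non-empty).
#' @return List: medians, `W`, `p_value`.
#' @export
conservation_compare <- function(pai_tetraploid, pai_diploid) {
  if (!length(pai_tetraploid) || !length(pai_diploid))
    stop("both PAI samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(pai_tetraploid, pai_diploid))
  list(median_tetraploid = stats::median(pai_tetraploid),
       median_diploid = stats::median(pai_diploid),
       W = unname(wt$statistic), p_value = wt$p.value)
}
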