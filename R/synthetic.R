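#' Default simulation configuration
#'
#' Describes a mixed-ploidy resequencing panel in the style of a range-wide
#' diploid/autotetraploid sampling: five diploid lineages (14 populations)
#' and one tetraploid lineage (11 populations), 8 individuals per population,
#' with hierarchical Balding-Nichols lineage frequencies over a 1/p ancestral
#' spectrum, planted selective sweeps (de novo / standing / parallel),
#' multinucleotide-mutation clusters, per-site annotations, SIFT scores and
#' ortholog alignments.
#'
#' @param n_genes Number of genes.
#' @param n_sites_per_gene SNPs per gene.
#' @param F_lineage Balding-Nichols drift parameter per lineage, in (0,1).
#' @param depth_mean Mean Poisson read depth.
#' @param missing_rate Extra missing-genotype probability.
#' @param target_freq Swept-haplotype frequency in the selected lineage(s).
#' @param seed RNG seed; the whole bundle is deterministic given it.
#' @return A `sim_config` list; see fields in the source.
#' @export
sim_config <- function(n_genes = 400, n_sites_per_gene = 100,
                       F_lineage = 0.05, depth_mean = 25,
                       missing_rate = 0.02, target_freq = 0.95,
                       seed = 1L) {
  stopifnot(F_lineage > 0, F_lineage < 1, missing_rate >= 0, missing_rate < 1,
            target_freq > 0.5, target_freq <= 1)
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  lineages <- data.frame(
    lineage = c("DL1", "DL2", "DL3", "DL4", "DL5", "TET"),
    ploidy = c(2L, 2L, 2L, 2L, 2L, 4L),
    n_pops = c(3L, 3L, 3L, 3L, 2L, 11L),
    F = F_lineage)
  sweep_plan <- data.frame(
    gene = gene_ids[1:8],
    mode = c(rep("de_novo", 4), rep("standing", 2), rep("parallel", 2)),
    n_aas = 3L,
    target_freq = target_freq,
    # staggered sweep ages: post-sweep mutations re-accumulated in the span
    n_post_sweep_snps = c(8L, 4L, 2L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  mnm_plan <- data.frame(
    gene = gene_ids[9:10], cluster_size = 10L, max_spacing_bp = 19L,
    transversion_prob = 0.95, stringsAsFactors = FALSE)
  list(
    n_genes = n_genes, n_sites_per_gene = n_sites_per_gene,
    gene_ids = gene_ids, lineages = lineages,
    inds_per_pop = 8L,
    gene_span = 3000L, gene_stride = 10000L, chrom = "chr1",
    N_grid = 100L,
    effect_props = c(missense = 0.50, synonymous = 0.45, other = 0.05),
    fourfold_frac = 0.5,
    tv_prob_neutral = 0.4,
    sweep_plan = sweep_plan, mnm_plan = mnm_plan,
    parallel_lineage = "DL1",
    standing_freq_range = c(0.02, 0.15),
    post_sweep_freq_range = c(0.05, 0.25),
    candidate_block_bp = 600L,
    planted_grantham_min = 180L,
    planted_sift_max = 0.05,
    neutral_sift_range = c(0.2, 1),
    sift_missing_genes = c(gene_ids[4],
                           gene_ids[seq_len(n_genes)[seq_len(n_genes) %% 20 == 0]]),
    aa_missing_frac = 0.1, ref_derived_frac = 0.1,
    n_focus_neutral = 10L,
    msa = list(n_species = 17L, conserved_rate = 0.02, neutral_rate = 0.45,
               background_rate = 0.2, gap_prob = 0.02),
    depth_mean = depth_mean, missing_rate = missing_rate,
    seed = as.integer(seed))
}

sim_individuals <- function(cfg) {
  rows <- list()
  p <- 0L
  for (i in seq_len(nrow(cfg$lineages))) {
    ln <- cfg$lineages[i, ]
    for (k in seq_len(ln$n_pops)) {
      p <- p + 1L
      pop <- sprintf("%s_p%02d", ln$lineage, k)
      rows[[p]] <- data.frame(
        id = sprintf("%s_i%d", pop, seq_len(cfg$inds_per_pop)),
        population = pop, lineage = ln$lineage, ploidy = ln$ploidy,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Hierarchical lineage allele frequencies
#'
#' Ancestral derived-allele frequency per site drawn from a neutral-like 1/p
#' spectrum truncated to `[1/(2N), 1 - 1/(2N)]`; each lineage's frequency is
#' a Balding-Nichols draw `Beta(p(1-F)/F, (1-p)(1-F)/F)` around it.
#'
#' @param cfg A `sim_config`.
#' @return List: `p_anc` (ancestral frequencies) and `f` (sites x lineages).
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes * cfg$n_sites_per_gene
  pmin <- 1 / (2 * cfg$N_grid); pmax <- 1 - pmin
  p <- pmin * (pmax / pmin)^stats::runif(n)  # density proportional to 1/p
  nl <- nrow(cfg$lineages)
  f <- matrix(NA_real_, n, nl, dimnames = list(NULL, cfg$lineages$lineage))
  for (j in seq_len(nl)) {
    F <- cfg$lineages$F[j]
    if (F <= 0 || F >= 1) stop("F must lie in (0,1)")
    f[, j] <- stats::rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  list(p_anc = p, f = f)
}

# lay out per-site gene assignment, positions, effects, alleles
sim_sites <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n_g <- cfg$n_genes; n_s <- cfg$n_sites_per_gene
  gene <- rep(cfg$gene_ids, each = n_s)
  start <- rep((seq_len(n_g) - 1L) * cfg$gene_stride + 1L, each = n_s)
  pos <- integer(n_g * n_s)
  for (i in seq_len(n_g)) {
    idx <- ((i - 1L) * n_s + 1L):(i * n_s)
    pos[idx] <- sort(sample(seq.int(start[idx][1], start[idx][1] + cfg$gene_span - 1L), n_s))
  }
  effect <- sample(names(cfg$effect_props), n_g * n_s, replace = TRUE,
                   prob = cfg$effect_props)
  fourfold <- effect == "synonymous" & stats::runif(n_g * n_s) < cfg$fourfold_frac
  # nucleotide alleles with the neutral transversion probability
  alleles <- draw_alleles(n_g * n_s, cfg$tv_prob_neutral)
  # amino-acid bookkeeping for missense sites: position = rank among the
  # gene's missense sites; random distinct amino-acid pair
  aa_pos <- integer(n_g * n_s) * NA_integer_
  aa_ref <- aa_alt <- rep(NA_character_, n_g * n_s)
  mis <- which(effect == "missense")
  aa_pos[mis] <- stats::ave(seq_along(mis), gene[mis], FUN = seq_along)
  acc <- snp_accessible_aa_pairs()
  pick <- sample.int(nrow(acc), length(mis), replace = TRUE, prob = acc$weight)
  aa_ref[mis] <- acc$aa_ref[pick]
  aa_alt[mis] <- acc$aa_alt[pick]
  data.frame(chrom = cfg$chrom, pos = pos, gene = gene,
             ref = alleles$ref, alt = alleles$alt,
             effect = effect, fourfold = fourfold,
             aa_pos = aa_pos, aa_ref = aa_ref, aa_alt = aa_alt,
             stringsAsFactors = FALSE)
}

# amino-acid pairs reachable by a single nucleotide change somewhere in the
# standard genetic code, weighted by the number of codon paths; a random SNP
# can only ever produce these, which keeps radical exchanges appropriately rare
snp_accessible_aa_pairs <- function() {
  cached <- get0("aa_pairs", envir = .mixscan_cache)
  if (!is.null(cached)) return(cached)
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  from <- character(0); to <- character(0)
  for (cd in names(gc_tab)) {
    a1 <- gc_tab[[cd]]
    if (a1 == "*") next
    for (i in 1:3) for (b in setdiff(bases, substr(cd, i, i))) {
      cd2 <- cd
      substr(cd2, i, i) <- b
      a2 <- gc_tab[[cd2]]
      if (a2 == "*" || a2 == a1) next
      from <- c(from, a1); to <- c(to, a2)
    }
  }
  ag <- stats::aggregate(list(weight = rep(1L, length(from))),
                         list(aa_ref = from, aa_alt = to), sum)
  assign("aa_pairs", ag, envir = .mixscan_cache)
  ag
}

.mixscan_cache <- new.env(parent = emptyenv())

draw_alleles <- function(n, tv_prob) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  ref <- sample(bases, n, replace = TRUE)
  is_tv <- stats::runif(n) < tv_prob
  alt <- ifelse(is_tv,
                vapply(ref, function(b) sample(tv_partners[[b]], 1), ""),
                unname(transition[ref]))
  list(ref = ref, alt = alt)
}

#' Plant a selective sweep into the lineage frequency matrix
#'
#' Selects candidate missense sites inside a contiguous block of the gene and
#' sets lineage frequencies by mode: `de_novo` zeroes every diploid lineage
#' and puts the tetraploid at `target_freq`; `standing` additionally leaves a
#' low diploid frequency (drawn from `standing_freq_range`); `parallel` puts
#' both the tetraploid and one designated diploid lineage at `target_freq`.
#' The swept lineage's non-candidate sites inside the candidate span are
#' cleared (hard-sweep hitchhiking), then `n_post_sweep_snps` of them regain
#' low-frequency variation, emulating post-sweep mutation accumulation.
#'
#' @param freqs From [simulate_frequencies()].
#' @param sites From the site layout (internal).
#' @param gene Gene id.
#' @param mode One of de_novo / standing / parallel / none.
#' @param n_aas Number of candidate amino-acid substitutions.
#' @param target_freq Swept frequency.
#' @param cfg The `sim_config`.
#' @param candidate_rows Optional explicit candidate rows (used for MNM
#'   clusters).
#' @param n_post_sweep_snps Post-sweep re-accumulated SNPs inside the span.
#' @return List: modified `freqs$f`, `truth` entry.
#' @keywords internal
plant_sweep <- function(freqs, sites, gene, mode, n_aas, target_freq, cfg,
                        candidate_rows = NULL, n_post_sweep_snps = 0L) {
  f <- freqs$f
  rows_gene <- which(sites$gene == gene)
  if (mode == "none")
    return(list(f = f, truth = list(gene = gene, mode = "none")))
  if (is.null(candidate_rows)) {
    mis <- rows_gene[sites$effect[rows_gene] == "missense"]
    if (length(mis) < n_aas) stop("gene ", gene, " has too few missense sites")
    mis_ok <- mis[sites$pos[mis] <= max(sites$pos[mis]) - cfg$candidate_block_bp]
    if (!length(mis_ok)) mis_ok <- mis[1]
    anchor <- mis_ok[sample.int(length(mis_ok), 1)]
    block <- mis[sites$pos[mis] >= sites$pos[anchor] &
                   sites$pos[mis] <= sites$pos[anchor] + cfg$candidate_block_bp]
    if (length(block) < n_aas) block <- mis[order(abs(sites$pos[mis] - sites$pos[anchor]))][seq_len(n_aas)]
    candidate_rows <- sort(block[sample.int(length(block), n_aas)])
  }
  dip <- cfg$lineages$lineage[cfg$lineages$ploidy == 2L]
  tet <- cfg$lineages$lineage[cfg$lineages$ploidy == 4L]
  f_dip <- switch(mode,
                  de_novo = 0,
                  standing = stats::runif(1, cfg$standing_freq_range[1],
                                          cfg$standing_freq_range[2]),
                  parallel = 0)
  f[candidate_rows, dip] <- f_dip
  f[candidate_rows, tet] <- target_freq
  swept <- tet
  if (mode == "parallel") {
    f[candidate_rows, cfg$parallel_lineage] <- target_freq
    swept <- c(tet, cfg$parallel_lineage)
  }
  # hard-sweep clearing within the candidate span, swept lineages only
  span <- range(sites$pos[candidate_rows])
  inside <- rows_gene[sites$pos[rows_gene] > span[1] &
                        sites$pos[rows_gene] < span[2] &
                        !rows_gene %in% candidate_rows]
  f[inside, swept] <- 0
  post <- integer(0)
  if (n_post_sweep_snps > 0 && length(inside)) {
    post <- sort(sample(inside, min(n_post_sweep_snps, length(inside))))
    f[post, tet] <- stats::runif(length(post), cfg$post_sweep_freq_range[1],
                                 cfg$post_sweep_freq_range[2])
  }
  list(f = f,
       truth = list(gene = gene, mode = mode,
                    candidate_rows = candidate_rows,
                    candidate_pos = sites$pos[candidate_rows],
                    f_diploid = f_dip, f_tetraploid = target_freq,
                    post_sweep_rows = post,
                    parallel_lineage = if (mode == "parallel") cfg$parallel_lineage else NA))
}

#' Plant a multinucleotide-mutation cluster
#'
#' Rewrites the positions of `cluster_size` missense sites of the gene into a
#' tight run with consecutive spacings at most `max_spacing_bp` (the working
#' MNM definition being substitutions < 20 bp apart) and redraws their
#' ref/alt alleles with the cluster's transversion probability.
#'
#' @return List: modified `sites`, cluster rows.
#' @keywords internal
plant_mnm <- function(sites, gene, cluster_size, max_spacing_bp,
                      transversion_prob, cfg) {
  rows_gene <- which(sites$gene == gene)
  mis <- rows_gene[sites$effect[rows_gene] == "missense"]
  if (length(mis) < cluster_size) stop("gene ", gene, " too short for MNM cluster")
  gaps <- sample(seq(3L, max_spacing_bp), cluster_size - 1L, replace = TRUE)
  gene_start <- min(sites$pos[rows_gene])
  anchor <- gene_start + sample.int(cfg$gene_span - sum(gaps) - 10L, 1)
  new_pos <- anchor + c(0L, cumsum(gaps))
  # avoid collisions with other sites of the gene
  clash <- rows_gene[sites$pos[rows_gene] %in% new_pos]
  cluster_rows <- sort(mis[seq_len(cluster_size)])
  sites$pos[cluster_rows] <- new_pos
  drop_clash <- setdiff(clash, cluster_rows)
  if (length(drop_clash)) {  # move colliding background sites to free positions
    occupied <- sites$pos[setdiff(rows_gene, drop_clash)]
    free <- setdiff(seq.int(gene_start, gene_start + cfg$gene_span - 1L), occupied)
    sites$pos[drop_clash] <- sort(free)[seq_along(drop_clash)]
  }
  al <- draw_alleles(cluster_size, transversion_prob)
  sites$ref[cluster_rows] <- al$ref
  sites$alt[cluster_rows] <- al$alt
  # keep the gene's rows position-sorted
  ord <- rows_gene[order(sites$pos[rows_gene])]
  sites[rows_gene, ] <- sites[ord, ]
  cluster_rows <- rows_gene[sites$pos[rows_gene] %in% new_pos]
  list(sites = sites, cluster_rows = cluster_rows)
}

#' Sample genotypes from lineage frequencies
#'
#' Dosages are Binomial(ploidy, f) per individual (tetrasomic inheritance for
#' tetraploids); at planted candidate blocks the draw is made once per
#' individual and shared across the block's sites, emulating the linkage of a
#' swept haplotype. Depth is Poisson; a genotype is missing with probability
#' `missing_rate` and always when its depth is at most 8.
#'
#' @param f Sites x lineages frequency matrix.
#' @param individuals Individual table (id, population, lineage, ploidy).
#' @param cfg The `sim_config`.
#' @param linked_blocks List of integer row vectors to treat as single
#'   haplotype blocks.
#' @param seed RNG seed.
#' @return A `genotype_matrix` without variant metadata (dosage in derived
#'   allele units).
#' @keywords internal
sample_genotypes <- function(f, individuals, cfg, linked_blocks = list(),
                             seed = cfg$seed + 2L) {
  set.seed(seed)
  n <- nrow(f); m <- nrow(individuals)
  lin_col <- match(individuals$lineage, colnames(f))
  dosage <- matrix(NA_integer_, n, m)
  for (i in seq_len(m)) {
    dosage[, i] <- stats::rbinom(n, individuals$ploidy[i], f[, lin_col[i]])
  }
  for (bl in linked_blocks) {
    for (i in seq_len(m)) {
      d1 <- stats::rbinom(1, individuals$ploidy[i], f[bl[1], lin_col[i]])
      dosage[bl, i] <- d1
    }
  }
  depth <- matrix(stats::rpois(n * m, cfg$depth_mean), n, m)
  miss <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m) | depth <= 8L
  dosage[miss] <- NA_integer_
  list(dosage = dosage, depth = depth)
}

#' Simulate an ortholog protein alignment for one gene
#'
#' The reference row is a random protein; each other species substitutes each
#' residue with a per-column rate set by the column's constraint class
#' (conserved / background / neutral) and carries occasional gaps.
#'
#' @param L Protein length.
#' @param constraint Character vector per column: "conserved", "background"
#'   or "neutral".
#' @param cfg_msa The `msa` sublist of a `sim_config`.
#' @param seed RNG seed.
#' @return `list(seqs, reference_name)` compatible with [read_msa()].
#' @export
simulate_msa <- function(L, constraint, cfg_msa, seed = 1L) {
  stopifnot(length(constraint) == L)
  set.seed(seed)
  rate <- c(conserved = cfg_msa$conserved_rate,
            background = cfg_msa$background_rate,
            neutral = cfg_msa$neutral_rate)[constraint]
  ref <- sample(AA1, L, replace = TRUE)
  seqs <- character(cfg_msa$n_species)
  names(seqs) <- c("ref", sprintf("sp%02d", seq_len(cfg_msa$n_species - 1L)))
  seqs["ref"] <- paste(ref, collapse = "")
  for (s in names(seqs)[-1]) {
    res <- ref
    sub <- stats::runif(L) < rate
    res[sub] <- vapply(ref[sub], function(a) sample(setdiff(AA1, a), 1), "")
    gap <- stats::runif(L) < cfg_msa$gap_prob
    res[gap] <- "-"
    seqs[s] <- paste(res, collapse = "")
  }
  list(seqs = seqs, reference_name = "ref")
}

#' Simulate a complete mixed-ploidy dataset with planted truth
#'
#' Produces, fully in memory, everything the analysis consumes: a polarizable
#' genotype matrix, the annotation table, gene models with a focal gene set,
#' SIFT scores, ortholog alignments for the planted genes and a truth record
#' listing every planted sweep, cluster and constraint class.
#'
#' @param cfg A [sim_config()].
#' @return List: `gm`, `annotations`, `genes`, `sift`, `msas`, `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  sites <- sim_sites(cfg)
  set.seed(cfg$seed + 3L)
  # MNM clusters first (they rewrite positions)
  mnm_truth <- list()
  for (i in seq_len(nrow(cfg$mnm_plan))) {
    mp <- cfg$mnm_plan[i, ]
    pm <- plant_mnm(sites, mp$gene, mp$cluster_size, mp$max_spacing_bp,
                    mp$transversion_prob, cfg)
    sites <- pm$sites
    mnm_truth[[mp$gene]] <- pm$cluster_rows
  }
  freqs <- simulate_frequencies(cfg)
  set.seed(cfg$seed + 4L)
  truth <- list()
  for (i in seq_len(nrow(cfg$sweep_plan))) {
    sp <- cfg$sweep_plan[i, ]
    ps <- plant_sweep(freqs, sites, sp$gene, sp$mode, sp$n_aas,
                      sp$target_freq, cfg,
                      n_post_sweep_snps = sp$n_post_sweep_snps)
    freqs$f <- ps$f
    truth[[sp$gene]] <- ps$truth
  }
  for (g in names(mnm_truth)) {  # MNM genes carry a de novo sweep over the cluster
    ps <- plant_sweep(freqs, sites, g, "de_novo", length(mnm_truth[[g]]),
                      cfg$sweep_plan$target_freq[1], cfg,
                      candidate_rows = mnm_truth[[g]])
    freqs$f <- ps$f
    ps$truth$mnm_cluster <- TRUE
    truth[[g]] <- ps$truth
  }
  individuals <- sim_individuals(cfg)
  blocks <- lapply(truth[!vapply(truth, function(t) t$mode, "") %in% "none"],
                   function(t) t$candidate_rows)
  geno <- sample_genotypes(freqs$f, individuals, cfg, linked_blocks = blocks)

  # polarization bookkeeping: most sites carry the derived allele as ALT and
  # an AA= ancestral state; a fraction are flipped and a fraction lack AA
  set.seed(cfg$seed + 5L)
  n <- nrow(sites)
  planted_rows <- sort(unique(unlist(lapply(truth, function(t) t$candidate_rows))))
  ref_derived <- stats::runif(n) < cfg$ref_derived_frac & !seq_len(n) %in% planted_rows
  aa_missing <- stats::runif(n) < cfg$aa_missing_frac & !seq_len(n) %in% planted_rows
  alt_dosage <- geno$dosage
  pl <- individuals$ploidy
  if (any(ref_derived)) {
    flip <- which(ref_derived)
    alt_dosage[flip, ] <- rep(pl, each = length(flip)) - alt_dosage[flip, , drop = FALSE]
  }
  aa_state <- ifelse(ref_derived, sites$alt, sites$ref)
  aa_state[aa_missing] <- NA_character_

  # drop sites monomorphic in the sample (a variant caller emits variants)
  an_tot <- (!is.na(alt_dosage)) %*% pl
  ac_tot <- rowSums(alt_dosage, na.rm = TRUE)
  seg <- ac_tot > 0 & ac_tot < an_tot
  seg[planted_rows] <- TRUE  # planted sites always emitted
  keep <- which(seg)
  remap <- match(seq_len(n), keep)

  variants <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                         ref = sites$ref[keep], alt = sites$alt[keep],
                         aa = aa_state[keep], derived = NA_character_,
                         stringsAsFactors = FALSE)
  gm <- new_genotype_matrix(variants, individuals,
                            alt_dosage[keep, , drop = FALSE],
                            geno$depth[keep, , drop = FALSE])

  annotations <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                            ref = sites$ref[keep], alt = sites$alt[keep],
                            gene = sites$gene[keep], effect = sites$effect[keep],
                            aa_pos = sites$aa_pos[keep],
                            aa_ref = sites$aa_ref[keep], aa_alt = sites$aa_alt[keep],
                            fourfold = sites$fourfold[keep],
                            stringsAsFactors = FALSE)

  # planted candidates get radical amino-acid pairs (high Grantham)
  gr <- read_grantham()
  hi_pairs <- which(gr >= cfg$planted_grantham_min, arr.ind = TRUE)
  hi_pairs <- hi_pairs[hi_pairs[, 1] != hi_pairs[, 2], , drop = FALSE]
  for (t in truth) {
    if (is.null(t$candidate_rows)) next
    kr <- remap[t$candidate_rows]
    pick <- hi_pairs[sample(nrow(hi_pairs), length(kr), replace = TRUE), , drop = FALSE]
    annotations$aa_ref[kr] <- rownames(gr)[pick[, 1]]
    annotations$aa_alt[kr] <- colnames(gr)[pick[, 2]]
  }

  # SIFT: low raw (deleterious) at planted/conserved sites, anti-correlated
  # with constraint; whole genes without any SIFT entry emulate database gaps
  set.seed(cfg$seed + 6L)
  mis_rows <- which(annotations$effect == "missense")
  sift <- data.frame(chrom = annotations$chrom[mis_rows],
                     pos = annotations$pos[mis_rows],
                     sift = stats::runif(length(mis_rows),
                                         cfg$neutral_sift_range[1],
                                         cfg$neutral_sift_range[2]))
  planted_keep <- stats::na.omit(remap[planted_rows])
  pk <- match(planted_keep, mis_rows)
  sift$sift[stats::na.omit(pk)] <- stats::runif(sum(!is.na(pk)), 0, cfg$planted_sift_max)
  sift <- sift[!annotations$gene[mis_rows] %in% cfg$sift_missing_genes, ]

  genes <- data.frame(gene = cfg$gene_ids, chrom = cfg$chrom,
                      start = (seq_len(cfg$n_genes) - 1L) * cfg$gene_stride + 1L,
                      end = (seq_len(cfg$n_genes) - 1L) * cfg$gene_stride + cfg$gene_span,
                      stringsAsFactors = FALSE)
  planted_genes <- names(truth)
  set.seed(cfg$seed + 7L)
  neutral_pool <- setdiff(cfg$gene_ids, planted_genes)
  focus_extra <- neutral_pool[sample.int(length(neutral_pool),
                                         min(cfg$n_focus_neutral, length(neutral_pool)))]
  genes$in_focus <- genes$gene %in% c(planted_genes, focus_extra)

  # ortholog alignments for the planted genes: tetraploid-sweep candidate
  # residues on conserved columns, parallel (diploid) candidates on neutral
  # columns, the rest background
  msas <- list()
  constraint_truth <- list()
  for (g in planted_genes) {
    t <- truth[[g]]
    kr <- remap[t$candidate_rows]
    apos <- annotations$aa_pos[kr]
    gene_mis <- annotations$aa_pos[annotations$gene == g &
                                     annotations$effect == "missense"]
    L <- max(gene_mis, apos, na.rm = TRUE) + 5L
    constraint <- rep("background", L)
    constraint[apos] <- if (t$mode == "parallel") "neutral" else "conserved"
    msas[[g]] <- simulate_msa(L, constraint, cfg$msa,
                              seed = cfg$seed + 100L + match(g, planted_genes))
    constraint_truth[[g]] <- constraint
  }

  truth_out <- list(
    config = list(seed = cfg$seed, n_genes = cfg$n_genes,
                  n_sites_per_gene = cfg$n_sites_per_gene,
                  target_freq = cfg$sweep_plan$target_freq[1]),
    genes = lapply(truth, function(t) {
      kr <- remap[t$candidate_rows]
      list(gene = t$gene, mode = t$mode,
           mnm_cluster = isTRUE(t$mnm_cluster),
           candidate_pos = annotations$pos[kr],
           candidate_aa_pos = annotations$aa_pos[kr],
           f_diploid = t$f_diploid, f_tetraploid = t$f_tetraploid,
           post_sweep_pos = annotations$pos[stats::na.omit(remap[t$post_sweep_rows])],
           parallel_lineage = t$parallel_lineage)
    }),
    constraint = constraint_truth)

  list(gm = gm, annotations = annotations, genes = genes, sift = sift,
       msas = msas, truth = truth_out, cfg = cfg)
}

#' Write a simulated dataset bundle to disk
#'
#' Emits the seven analysis inputs — VCF, annotation TSV, popmap TSV, SIFT
#' TSV, Grantham matrix, per-gene MSA FASTAs, truth JSON — plus the gene
#' table, all as plain text re-readable by the package's readers.
#'
#' @param cfg A [sim_config()], or an already-built [simulate_dataset()]
#'   bundle.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly; the in-memory bundle as
#'   attribute `bundle`.
#' @export
emit_dataset <- function(cfg, outdir) {
  bundle <- if (!is.null(cfg$gm)) cfg else simulate_dataset(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("cannot write to ", outdir)
  paths <- list(
    vcf = file.path(outdir, "panel.vcf"),
    annotations = file.path(outdir, "annotations.tsv"),
    popmap = file.path(outdir, "popmap.tsv"),
    sift = file.path(outdir, "sift.tsv"),
    grantham = file.path(outdir, "grantham.tsv"),
    msa_dir = file.path(outdir, "msa"),
    truth = file.path(outdir, "truth.json"),
    genes = file.path(outdir, "genes.tsv"))
  write_vcf(bundle$gm, paths$vcf)
  utils::write.table(bundle$annotations, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$gm$individuals, paths$popmap, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$sift, paths$sift, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  file.copy(system.file("extdata", "grantham1974.tsv", package = "mixscan"),
            paths$grantham, overwrite = TRUE)
  dir.create(paths$msa_dir, showWarnings = FALSE)
  for (g in names(bundle$msas)) {
    s <- bundle$msas[[g]]$seqs
    writeLines(paste0(">", names(s), "\n", s), file.path(paths$msa_dir, paste0(g, ".fasta")))
  }
  utils::write.table(bundle$genes, paths$genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(paths, "bundle") <- bundle
  invisible(paths)
}
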