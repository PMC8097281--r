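#' Default analysis parameters
#'
#' Every threshold of the scan in one place: depth and missingness genotype
#' filters, subsampling targets (32 chromosomes per diploid lineage, 160
#' tetraploid chromosomes), the synonymous-FST and FineMAV outlier quantiles
#' (both 0.99), the DAP exponent (3.5), the MK rare-frequency cutoff (0.15)
#' and AFD divergence quantile (0.99), and the cross-ploidy Hamming summary.
#'
#' @param ... Overrides for any default.
#' @return Named list of parameters (validated).
#' @export
scan_params <- function(...) {
  p <- list(min_depth = 8, max_missing = 0.5,
            dip_target_chrom = 32L, tet_target_chrom = 160L,
            fst_quantile = 0.99, finemav_quantile = 0.99,
            dap_exponent = 3.5,
            af_min = 0.15, afd_quantile = 0.99, afd_threshold = NULL,
            hamming_between = "median",
            rarefaction_sizes = c(5, 10, 20, 40, 80),
            rarefaction_reps = 20L,
            mnm_alpha = 0.01,
            seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  for (q in c("fst_quantile", "finemav_quantile", "afd_quantile"))
    if (p[[q]] <= 0 || p[[q]] >= 1) stop(q, " must lie in (0,1)")
  if (p$dap_exponent <= 0) stop("dap_exponent must be positive")
  p
}

#' Subsample a mixed-ploidy panel for the selection scans
#'
#' Each diploid lineage is reduced to `dip_target_chrom` chromosomes and the
#' tetraploid group to `tet_target_chrom`, keeping the highest-depth
#' individuals, so that allele-frequency estimates are comparable across
#' lineages and ploidies.
#'
#' @param gm Filtered `genotype_matrix`.
#' @param params From [scan_params()].
#' @return Subsampled `genotype_matrix`.
#' @export
subsample_panel <- function(gm, params = scan_params()) {
  lin <- unique(gm$individuals$lineage)
  keep_ids <- character(0)
  for (g in lin) {
    pl <- unique(gm$individuals$ploidy[gm$individuals$lineage == g])
    target <- if (pl == 2L) params$dip_target_chrom else params$tet_target_chrom
    sub <- subsample_chromosomes(gm, g, target, rule = "highest_depth")
    keep_ids <- c(keep_ids, sub$individuals$id)
  }
  sel <- which(gm$individuals$id %in% keep_ids)
  ind <- gm$individuals[sel, , drop = FALSE]
  rownames(ind) <- NULL
  new_genotype_matrix(gm$variants, ind, gm$dosage[, sel, drop = FALSE],
                      gm$depth[, sel, drop = FALSE])
}

# align annotation rows to the variant table by chrom:pos key
match_annotations <- function(gm, annotations) {
  idx <- match(site_key(gm$variants$chrom, gm$variants$pos),
               site_key(annotations$chrom, annotations$pos))
  if (anyNA(idx)) message(sum(is.na(idx)), " variant(s) without annotation skipped from classified analyses")
  annotations[idx, , drop = FALSE]
}

grantham_lookup <- function(gr, aa_ref, aa_alt) {
  out <- rep(NA_real_, length(aa_ref))
  ok <- !is.na(aa_ref) & !is.na(aa_alt)
  out[ok] <- gr[cbind(aa_ref[ok], aa_alt[ok])]
  out
}

contrast_fst <- function(fr, g1, g2) {
  hudson_fst(fr$f[, g1], fr$AN[, g1], fr$f[, g2], fr$AN[, g2])
}

#' Run the full selection-scan analysis on a dataset bundle
#'
#' Executes filtering, polarization, subsampling, diversity, the per-SNP
#' Hudson-FST and FineMAV scans with candidate calling in the ploidy contrast
#' and all pairwise diploid-lineage contrasts, gene-set enrichment, the
#' AFD-based McDonald-Kreitman scan, the standing-variation screen, HAF
#' reconstruction, Hamming distance/diameter de novo verdicts, rarefaction,
#' sweep-age ranking, MNM evidence and the conservation comparison.
#'
#' @param bundle A [simulate_dataset()] bundle or the equivalent list of
#'   objects read from disk (`gm`, `annotations`, `genes`, `sift`, `msas`).
#' @param params From [scan_params()].
#' @return A list of per-stage result objects (see the pipeline vignette).
#' @export
analyze_bundle <- function(bundle, params = scan_params()) {
  gr <- read_grantham()
  gm_full <- apply_genotype_filters(bundle$gm, params$min_depth,
                                    params$max_missing)
  gm_full <- polarize(gm_full)
  ann_full <- match_annotations(gm_full, bundle$annotations)
  gm_sub <- subsample_panel(gm_full, params)
  ann <- match_annotations(gm_sub, bundle$annotations)

  ploidy_group <- ifelse(gm_sub$individuals$ploidy == 2L, "diploid", "tetraploid")
  fr_lin <- group_frequencies(gm_sub)
  fr_plo <- group_frequencies(gm_sub, ploidy_group)

  diversity <- rbind(diversity_scan(gm_sub, ann),
                     diversity_scan(gm_sub, ann, ploidy_group))

  syn <- ann$effect %in% "synonymous"
  mis <- ann$effect %in% "missense"

  # FineMAV over the six lineages, shared by every contrast
  sift_idx <- match(site_key(gm_sub$variants$chrom, gm_sub$variants$pos),
                    site_key(bundle$sift$chrom, bundle$sift$pos))
  sift_raw <- bundle$sift$sift[sift_idx]
  g_score <- grantham_lookup(gr, ann$aa_ref, ann$aa_alt)
  fm <- finemav_table(fr_lin$f, g_score, sift_raw, params$dap_exponent)
  fm$finemav_grantham[!mis] <- NA_real_
  fm$finemav_sift[!mis] <- NA_real_

  dip_lineages <- sort(unique(gm_sub$individuals$lineage[gm_sub$individuals$ploidy == 2L]))
  contrasts <- c(list(c("diploid", "tetraploid")),
                 utils::combn(dip_lineages, 2, simplify = FALSE))
  names(contrasts) <- vapply(contrasts, paste, "", collapse = "_vs_")

  candidate_tables <- list()
  fst_tables <- list()
  for (cn in names(contrasts)) {
    gp <- contrasts[[cn]]
    fr <- if (cn == "diploid_vs_tetraploid") fr_plo else fr_lin
    fst <- contrast_fst(fr, gp[1], gp[2])
    thr <- neutral_quantile(fst[syn], params$fst_quantile)
    flags <- call_candidates(fst[mis], fm$finemav_grantham[mis],
                             fm$finemav_sift[mis], thr, params$finemav_quantile)
    tab <- data.frame(chrom = gm_sub$variants$chrom[mis],
                      pos = gm_sub$variants$pos[mis],
                      gene = ann$gene[mis],
                      aa_pos = ann$aa_pos[mis], aa_ref = ann$aa_ref[mis],
                      aa_alt = ann$aa_alt[mis],
                      contrast = cn, fst = fst[mis],
                      p1 = fr$f[mis, gp[1]], p2 = fr$f[mis, gp[2]],
                      afd = afd(fr$f[mis, gp[1]], fr$f[mis, gp[2]]),
                      dap = fm$dap[mis], top_group = fm$top_group[mis],
                      finemav_grantham = fm$finemav_grantham[mis],
                      finemav_sift = fm$finemav_sift[mis],
                      flags, row.names = NULL)
    candidate_tables[[cn]] <- tab
    fst_tables[[cn]] <- data.frame(chrom = gm_sub$variants$chrom,
                                   pos = gm_sub$variants$pos, gene = ann$gene,
                                   effect = ann$effect, fst = fst,
                                   threshold = thr, row.names = NULL)
  }
  cand_ploidy <- candidate_tables$diploid_vs_tetraploid
  dip_tabs <- candidate_tables[names(candidate_tables) != "diploid_vs_tetraploid"]
  dip_union <- do.call(rbind, lapply(dip_tabs, function(t) t[t$is_candidate, ]))
  if (!is.null(dip_union) && nrow(dip_union)) {
    # attribute each site once, to the contrast whose top frequency is higher
    dip_union <- dip_union[order(dip_union$pos, -pmax(dip_union$p1, dip_union$p2)), ]
    dip_union <- dip_union[!duplicated(dip_union$pos), ]
    rownames(dip_union) <- NULL
  }

  focus <- bundle$genes$gene[bundle$genes$in_focus]
  tet_cand <- cand_ploidy[cand_ploidy$is_candidate, ]
  enrichment <- list(
    ploidy = gene_set_enrichment(unique(tet_cand$gene), focus, bundle$genes$gene),
    diploid = if (!is.null(dip_union) && nrow(dip_union))
      gene_set_enrichment(unique(dip_union$gene), focus, bundle$genes$gene)
    else NULL)

  # --- McDonald-Kreitman with AFD-outlier divergence ---
  f_overall <- rowSums(fr_plo$AC) / pmax(rowSums(fr_plo$AN), 1L)
  afd_all <- afd(fr_plo$f[, "diploid"], fr_plo$f[, "tetraploid"])
  mk_cls <- classify_mk_sites(f_overall, afd_all, ann$effect,
                              params$afd_quantile, params$af_min,
                              params$afd_threshold)
  mk <- mk_scan(ann$gene, ann$effect, mk_cls$class)

  # --- de novo versus standing variation ---
  # haplotype panel: the full diploid sampling plus the subsampled tetraploid
  # panel, so combined-sample chromosome counts are dominated by diploids and
  # the major allele at a swept site is the ancestral one
  hap_cols <- which(gm_full$individuals$ploidy == 2L |
                      gm_full$individuals$id %in%
                        gm_sub$individuals$id[gm_sub$individuals$ploidy == 4L])
  gm_hap <- local({
    ind <- gm_full$individuals[hap_cols, , drop = FALSE]; rownames(ind) <- NULL
    new_genotype_matrix(gm_full$variants, ind,
                        gm_full$dosage[, hap_cols, drop = FALSE],
                        gm_full$depth[, hap_cols, drop = FALSE])
  })
  cand_genes <- sort(unique(tet_cand$gene))
  full_key <- site_key(gm_hap$variants$chrom, gm_hap$variants$pos)
  dip_cols <- which(gm_hap$individuals$ploidy == 2L)
  dd_full <- derived_dosage(gm_hap)
  fr_pop_full <- group_frequencies(gm_hap, gm_hap$individuals$population)
  fr_all_full <- group_frequencies(gm_hap, rep("all", nrow(gm_hap$individuals)))

  screen_rows <- list(); haf_rows <- list(); verdict_rows <- list()
  lineage_presence <- list()
  for (g in cand_genes) {
    sites_g <- tet_cand[tet_cand$gene == g, ]
    rows <- match(site_key(sites_g$chrom, sites_g$pos), full_key)
    if (anyNA(rows)) stop("candidate site of ", g, " absent from full matrix")
    scr <- standing_screen(gm_hap, rows, dip_cols)
    screen_rows[[g]] <- data.frame(gene = g, pos = sites_g$pos,
                                   present_in_diploids = scr$present,
                                   diploid_carriers = scr$carrier_count)
    # per-diploid-lineage carrier counts (reported separately; parallel
    # sharing with a single diploid lineage shows up here)
    for (ln in dip_lineages) {
      cols <- which(gm_hap$individuals$lineage == ln)
      lineage_presence[[paste(g, ln)]] <- data.frame(
        gene = g, lineage = ln,
        n_sites_present = sum(rowSums(dd_full[rows, cols, drop = FALSE] >= 1,
                                      na.rm = TRUE) > 0))
    }
    # HAF per population over the combined-sample major allele
    f_all <- fr_all_full$f[rows, 1]
    major_is_derived <- f_all > 0.5
    for (pop in colnames(fr_pop_full$f)) {
      fp <- fr_pop_full$f[rows, pop]
      M <- ifelse(major_is_derived, fp, 1 - fp)
      M[is.na(M)] <- ifelse(major_is_derived[is.na(M)], 0, 1)
      haf <- reconstruct_haf(M)
      haf_rows[[paste(g, pop)]] <- data.frame(
        gene = g, population = pop, HAFd = haf["HAFd"], HAFa = haf["HAFa"],
        HAFr = haf["HAFr"], n_sites = length(rows), row.names = NULL)
    }
    vd <- de_novo_verdict(gm_hap, rows, between = params$hamming_between)
    verdict_rows[[g]] <- data.frame(
      gene = g, n_candidates = length(rows),
      criterion_A_absent_aas = vd$criterion_A_absent_aas,
      criterion_B_absent_haplotype = vd$criterion_B_absent_haplotype,
      criterion_C_distance_exceeds_diameter = vd$criterion_C_distance_exceeds_diameter,
      diameter_diploid = vd$hamming$diameter_diploid,
      diameter_tetraploid = vd$hamming$diameter_tetraploid,
      distance_between = vd$hamming$distance_between,
      verdict_de_novo = vd$verdict)
  }
  gm_dip_full <- local({
    sel <- dip_cols
    ind <- gm_hap$individuals[sel, , drop = FALSE]; rownames(ind) <- NULL
    new_genotype_matrix(gm_hap$variants, ind, gm_hap$dosage[, sel, drop = FALSE],
                        gm_hap$depth[, sel, drop = FALSE])
  })
  sizes <- params$rarefaction_sizes[params$rarefaction_sizes <= length(dip_cols)]
  rarefaction <- rarefaction_curve(gm_dip_full, sample_sizes = c(sizes, length(dip_cols)),
                                   n_reps = params$rarefaction_reps,
                                   seed = params$seed)

  # --- sweep age on genes with >= 2 ploidy-contrast candidates ---
  tet_cols_sub <- which(gm_sub$individuals$ploidy == 4L)
  fr_tet <- fr_plo$f[, "tetraploid"]
  seg_tet_pos <- gm_sub$variants$pos[!is.na(fr_tet) & fr_tet > 0 & fr_tet < 1]
  sweep_rows <- list()
  for (g in cand_genes) {
    cp <- tet_cand$pos[tet_cand$gene == g]
    sa <- sweep_age(cp, seg_tet_pos)
    sweep_rows[[g]] <- data.frame(gene = g, span_bp = sa$span_bp,
                                  n_accumulated = sa$n_accumulated,
                                  ratio = sa$ratio)
  }
  sweep_tab <- do.call(rbind, sweep_rows)
  sweep_rank <- if (!is.null(sweep_tab) && any(!is.na(sweep_tab$ratio))) {
    r <- stats::setNames(sweep_tab$ratio, sweep_tab$gene)
    rank_sweeps(r)
  } else NULL

  # --- MNM evidence ---
  gw_dist <- unlist(lapply(split(ann$pos[mis], ann$gene[mis]),
                           consecutive_distances), use.names = FALSE)
  gw_tv <- sum(is_transversion(gm_sub$variants$ref[mis], gm_sub$variants$alt[mis]))
  gw_n <- sum(mis)
  mnm_rows <- list()
  for (g in cand_genes) {
    sel <- tet_cand$gene == g
    if (sum(sel) < 2) next
    rows <- match(site_key(tet_cand$chrom[sel], tet_cand$pos[sel]),
                  site_key(gm_sub$variants$chrom, gm_sub$variants$pos))
    mnm_rows[[g]] <- cbind(gene = g,
                           mnm_report(tet_cand$pos[sel],
                                      gm_sub$variants$ref[rows],
                                      gm_sub$variants$alt[rows],
                                      gw_dist, gw_tv, gw_n,
                                      alpha = params$mnm_alpha))
  }
  mnm_tab <- do.call(rbind, mnm_rows)

  # --- conservation at candidate residues ---
  dip_sites <- if (!is.null(dip_union)) site_key(dip_union$chrom, dip_union$pos) else character(0)
  pai_tet <- numeric(0); pai_dip <- numeric(0); cons_rows <- list()
  for (g in names(bundle$msas)) {
    msa <- bundle$msas[[g]]
    ct_tet <- tet_cand[tet_cand$gene == g &
                         !site_key(tet_cand$chrom, tet_cand$pos) %in% dip_sites, ]
    ct_dip <- if (!is.null(dip_union)) dip_union[dip_union$gene == g, ] else NULL
    if (nrow(ct_tet)) {
      tab <- conservation_table(msa, ct_tet$aa_pos)
      pai_tet <- c(pai_tet, tab$pai)
      cons_rows[[paste(g, "tet")]] <- cbind(gene = g, group = "tetraploid", tab)
    }
    if (!is.null(ct_dip) && nrow(ct_dip)) {
      tab <- conservation_table(msa, ct_dip$aa_pos)
      pai_dip <- c(pai_dip, tab$pai)
      cons_rows[[paste(g, "dip")]] <- cbind(gene = g, group = "diploid", tab)
    }
  }
  conservation <- if (length(pai_tet) && length(pai_dip))
    conservation_compare(pai_tet, pai_dip) else NULL

  list(params = params,
       gm_filtered = gm_full, gm_subsampled = gm_sub,
       annotations_sub = ann,
       diversity = diversity,
       fst_tables = fst_tables,
       finemav = fm,
       candidate_tables = candidate_tables,
       candidates_ploidy = tet_cand,
       candidates_diploid_union = dip_union,
       enrichment = enrichment,
       mk = mk, mk_afd_threshold = mk_cls$afd_threshold,
       standing_screen = do.call(rbind, screen_rows),
       lineage_presence = do.call(rbind, lineage_presence),
       haf = do.call(rbind, haf_rows),
       verdicts = do.call(rbind, verdict_rows),
       rarefaction = rarefaction,
       sweep_age = sweep_tab, sweep_rank = sweep_rank,
       mnm = mnm_tab,
       conservation = conservation,
       conservation_table = do.call(rbind, cons_rows))
}

#' Read a dataset bundle from disk
#'
#' @param dir Directory written by [emit_dataset()].
#' @return Bundle list consumable by [analyze_bundle()].
#' @export
read_bundle <- function(dir) {
  popmap <- read_popmap(file.path(dir, "popmap.tsv"))
  msa_files <- list.files(file.path(dir, "msa"), pattern = "\\.fasta$",
                          full.names = TRUE)
  msas <- lapply(msa_files, read_msa)
  names(msas) <- sub("\\.fasta$", "", basename(msa_files))
  list(gm = read_vcf(file.path(dir, "panel.vcf"), popmap),
       annotations = read_annotations(file.path(dir, "annotations.tsv")),
       genes = read_genes(file.path(dir, "genes.tsv")),
       sift = read_sift(file.path(dir, "sift.tsv")),
       msas = msas,
       truth = if (file.exists(file.path(dir, "truth.json")))
         jsonlite::read_json(file.path(dir, "truth.json")) else NULL)
}

write_stage_tsv <- function(x, path) {
  if (is.null(x) || !nrow(x)) {
    writeLines("# empty", path)
  } else {
    x <- x[do.call(order, unname(x[, intersect(c("gene", "contrast", "group",
                                                 "population", "lineage",
                                                 "chrom", "pos", "size"),
                                               names(x)), drop = FALSE])), ,
           drop = FALSE]
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  path
}

#' Run the whole pipeline on a bundle directory
#'
#' Reads the bundle, runs [analyze_bundle()] and writes every stage table
#' under `outdir` with deterministic row ordering, plus a JSON run manifest
#' of per-stage row counts.
#'
#' @param bundle_dir Directory written by [emit_dataset()].
#' @param outdir Output directory.
#' @param params From [scan_params()].
#' @return The [analyze_bundle()] result, invisibly.
#' @export
run_all <- function(bundle_dir, outdir, params = scan_params()) {
  bundle <- read_bundle(bundle_dir)
  res <- analyze_bundle(bundle, params)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(
    diversity = res$diversity,
    fst_ploidy = res$fst_tables$diploid_vs_tetraploid,
    candidates_ploidy = res$candidates_ploidy,
    candidates_diploid_union = res$candidates_diploid_union,
    mk = res$mk,
    standing_screen = res$standing_screen,
    lineage_presence = res$lineage_presence,
    haf = res$haf,
    verdicts = res$verdicts,
    rarefaction = res$rarefaction,
    sweep_age = if (!is.null(res$sweep_rank)) res$sweep_rank else res$sweep_age,
    mnm = res$mnm,
    conservation = res$conservation_table)
  for (s in names(stages))
    write_stage_tsv(stages[[s]], file.path(outdir, paste0(s, ".tsv")))
  summary <- list(
    n_candidates_ploidy = nrow(res$candidates_ploidy),
    n_candidates_diploid = if (is.null(res$candidates_diploid_union)) 0L
    else nrow(res$candidates_diploid_union),
    enrichment_ploidy_p = res$enrichment$ploidy$p_value,
    enrichment_diploid_p = if (is.null(res$enrichment$diploid)) NA
    else res$enrichment$diploid$p_value,
    mk_alpha_genomewide = res$mk$alpha[res$mk$gene == "genomewide"],
    mk_afd_threshold = res$mk_afd_threshold,
    conservation_p = if (is.null(res$conservation)) NA else res$conservation$p_value,
    stage_rows = lapply(stages, function(x) if (is.null(x)) 0L else nrow(x)))
  jsonlite::write_json(summary, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
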