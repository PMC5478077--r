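#' Run the full comparative mitogenome analysis
#'
#' Orchestrates the whole analysis on a set of annotated mitogenomes:
#' optional read QC, rotation and pairwise alignment of every genome against
#' the reference, variant classification and regional breakdown, per-gene
#' selection table, base composition and divergence reports, center-star
#' multiple alignment, composite TN93 distances, NJ tree with bootstrap
#' support, ML tree, outgroup rooting, relative-rate dating and calibration.
#' Every output is written as TSV/Newick under `outdir`, together with a log
#' of all seeds and parameters, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param genomes Named list of `genome_record` objects (reference first or
#'   named by `reference`).
#' @param reference Id of the reference genome (defaults to the first).
#' @param outgroups Character vector of outgroup ids (may be empty: then no
#'   rooting/dating is done).
#' @param calibration A [calibration_point()], or `NULL` to skip dating.
#' @param outdir Output directory (created if needed).
#' @param reads Optional list of `quality_read` objects to QC.
#' @param qc_base_threshold,qc_max_low_fraction Read-filter settings.
#' @param nj_bootstrap NJ bootstrap replicates (0 = skip supports).
#' @param ml Also infer the ML tree (slower)?
#' @param seed Integer seed driving all resampling.
#' @return Invisibly, a list with all intermediate objects (`variants`,
#'   `selection`, `composition`, `divergence`, `msa`, `dist`, `nj`,
#'   `ml`, `timetree_nj`, `timetree_ml`, `files`).
#' @export
run_pipeline <- function(genomes, reference = NULL, outgroups = character(0),
                         calibration = NULL, outdir = "mitochron_out",
                         reads = NULL, qc_base_threshold = 7L,
                         qc_max_low_fraction = 0.10,
                         nj_bootstrap = 1000L, ml = TRUE, seed = 1L) {
  if (length(genomes) < 3L) stop("need at least 3 genomes")
  ids <- vapply(genomes, `[[`, "", "id")
  names(genomes) <- ids
  if (is.null(reference)) reference <- ids[1L]
  if (!reference %in% ids) stop("reference '", reference, "' not among genomes")
  g_ref <- genomes[[reference]]
  if (!nrow(g_ref$features))
    stop("reference genome '", reference, "' carries no annotation")
  miss_og <- setdiff(outgroups, ids)
  if (length(miss_og)) stop("outgroup(s) not among genomes: ",
                            paste(miss_og, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  log_lines <- c(sprintf("mitochron run %s", format(Sys.time(), "%Y-%m-%d")),
                 sprintf("seed\t%d", seed),
                 sprintf("reference\t%s", reference),
                 sprintf("genomes\t%s", paste(ids, collapse = ",")),
                 sprintf("outgroups\t%s", paste(outgroups, collapse = ",")),
                 sprintf("qc\tQ<=%d, >%g%% discards", qc_base_threshold,
                         100 * qc_max_low_fraction),
                 sprintf("nj_bootstrap\t%d", nj_bootstrap))

  out <- list(files = NULL)

  ## -- read QC -------------------------------------------------------------
  if (!is.null(reads)) {
    qc <- filter_reads(reads, qc_base_threshold, qc_max_low_fraction)
    emit(data.frame(metric = names(qc$stats),
                    value = unlist(qc$stats)), "qc_stats.tsv")
    out$qc <- qc$stats
    log_lines <- c(log_lines, sprintf("reads\t%d kept of %d",
                                      qc$stats$kept, qc$stats$total))
  }

  ## -- pairwise comparisons against the reference --------------------------
  others <- setdiff(ids, reference)
  rotated <- lapply(others, function(id) {
    g <- genomes[[id]]
    if (g$circular && g_ref$circular) rotate_to_reference(g_ref, g) else g
  })
  names(rotated) <- others
  alns <- lapply(rotated, function(g) align_pair(g_ref, g))
  vts <- lapply(alns, classify_variants, ref_features = g_ref$features,
                ref_length = genome_length(g_ref))
  out$variants <- vts
  vrows <- do.call(rbind, lapply(others, function(id) {
    v <- vts[[id]]$variants
    if (nrow(v)) cbind(query = id, v) else NULL
  }))
  if (!is.null(vrows))
    emit(vrows, "variants.tsv")
  emit(do.call(rbind, lapply(others, function(id) {
    b <- region_breakdown(vts[[id]])
    cbind(query = id, b, percent = round(b$percent, 2))[, c(1:3, 5)]
  })), "region_breakdown.tsv")

  sel <- lapply(alns, gene_selection_table, g_ref = g_ref)
  out$selection <- sel
  emit(do.call(rbind, lapply(others, function(id) {
    s <- sel[[id]]
    data.frame(query = id, gene = s$gene, synonymous = s$n_synonymous,
               nonsynonymous = s$n_nonsynonymous,
               replacements = s$aa_changes,
               dnds = ifelse(is.na(s$dnds), "-", sprintf("%.6g", s$dnds)),
               category = s$category)
  })), "selection.tsv")

  comp <- lapply(genomes, base_composition)
  out$composition <- comp
  emit(do.call(rbind, lapply(ids, function(id) {
    cc <- comp[[id]]
    data.frame(genome = id, T = round(cc$pct_T, 1), C = round(cc$pct_C, 1),
               A = round(cc$pct_A, 1), G = round(cc$pct_G, 1),
               total = cc$total)
  })), "composition.tsv")

  divg <- lapply(alns, divergence_summary)
  out$divergence <- divg
  emit(do.call(rbind, lapply(others, function(id) {
    d <- divg[[id]]
    data.frame(pair = paste(d$pair, collapse = "-"),
               divergent_bases = d$n_divergent,
               percent = round(d$pct_divergent, 2), gaps = d$n_gaps)
  })), "divergence.tsv")

  ## -- multiple alignment, distances, trees --------------------------------
  msa <- msa_center_star(c(list(g_ref), rotated), center = reference)
  out$msa <- msa
  write_msa_fasta(msa, file.path(outdir, "msa.fasta"))
  files <- c(files, file.path(outdir, "msa.fasta"))
  dm <- build_distance_matrix(msa, model = "TN93-MCL", policy = "complete")
  out$dist <- dm
  write_distance_tsv(dm, file.path(outdir, "distances.tsv"))
  files <- c(files, file.path(outdir, "distances.tsv"))
  log_lines <- c(log_lines, sprintf("msa_columns_complete\t%d", dm$n_sites))

  nj <- if (nj_bootstrap > 0L)
    bootstrap_support(msa, model = "TN93-MCL", policy = "complete",
                      n_replicates = nj_bootstrap, seed = seed)
  else nj_tree(dm)
  out$nj <- nj
  write_newick(nj, decorations = if (nj_bootstrap > 0L) "support" else "none",
               file = file.path(outdir, "tree_nj.nwk"))
  files <- c(files, file.path(outdir, "tree_nj.nwk"))
  log_lines <- c(log_lines, sprintf("nj_branch_length_sum\t%.8f",
                                    sum(nj$edge.length)))

  if (ml) {
    mlfit <- optimize_ml_tree(msa, model = "TN93", policy = "complete")
    out$ml <- mlfit
    write_newick(mlfit$tree, file = file.path(outdir, "tree_ml.nwk"))
    files <- c(files, file.path(outdir, "tree_ml.nwk"))
    log_lines <- c(log_lines, sprintf("ml_log_likelihood\t%.4f", mlfit$lnl))
  }

  ## -- dating ---------------------------------------------------------------
  if (length(outgroups) && !is.null(calibration)) {
    date_one <- function(tree, tag) {
      rooted <- root_with_outgroup(tree, outgroups)
      tt <- calibrate_timetree(reltime_relative(rooted, outgroups),
                               calibration)
      na <- node_ages(tt)
      emit(na, sprintf("node_ages_%s.tsv", tag))
      write_newick(tt, decorations = "age",
                   file = file.path(outdir, sprintf("timetree_%s.nwk", tag)))
      files <<- c(files, file.path(outdir, sprintf("timetree_%s.nwk", tag)))
      tt
    }
    out$timetree_nj <- date_one(nj, "nj")
    if (ml) out$timetree_ml <- date_one(out$ml$tree, "ml")
  }

  writeLines(log_lines, file.path(outdir, "run_log.tsv"))
  files <- c(files, file.path(outdir, "run_log.tsv"))
  out$files <- files
  invisible(out)
}
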