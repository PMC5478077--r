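#' Vertebrate mitochondrial genetic code
#'
#' NCBI translation table 2: relative to the standard code, ATA encodes Met,
#' TGA encodes Trp, and AGA/AGG are stop codons.
#'
#' @param transl_table NCBI genetic-code id (default 2).
#' @return Named character vector mapping codons to amino-acid letters
#'   (`*` = stop).
#' @export
genetic_code <- function(transl_table = 2L) {
  Biostrings::getGeneticCode(as.character(transl_table))
}

translate_codons <- function(codons, code) {
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"   # codons containing N or other ambiguity
  aa
}

#' Translate a protein-coding gene
#'
#' Extracts the CDS (strand-aware, honoring `codon_start`) and translates it
#' under the vertebrate mitochondrial code (or the table the feature names).
#' A trailing incomplete codon -- completed by polyadenylation in vivo, as is
#' common for mitochondrial genes -- is dropped.
#'
#' @param g A `genome_record`.
#' @param f One feature row (or a gene name).
#' @return Amino-acid string; a terminal stop is reported as `*`.
#' @export
translate_cds <- function(g, f) {
  if (is.character(f)) {
    i <- match(f, g$features$name)
    if (is.na(i)) stop("no feature named '", f, "'")
    f <- g$features[i, ]
  }
  if (f$ftype != "CDS") stop("feature '", f$name, "' is not a CDS")
  s <- feature_sequence(g, f)
  if (f$codon_start > 0L) s <- substring(s, f$codon_start + 1L)
  n_codon <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- translate_codons(codons, genetic_code(f$transl_table))
  internal_stop <- which(aa == "*")
  internal_stop <- internal_stop[internal_stop < n_codon]
  if (length(internal_stop))
    stop("internal stop codon in '", f$name, "' at codon ", internal_stop[1L])
  paste(aa, collapse = "")
}

#' Codon-level effect of substitutions
#'
#' Compares a reference codon with its aligned query codon and calls the pair
#' synonymous (identical translation) or nonsynonymous, recording the
#' amino-acid replacement. Codons differing at more than one position are
#' evaluated once on the whole codon. Codons containing an ambiguous base or
#' an alignment gap are unclassified.
#'
#' @param ref_codon,qry_codon Three-base strings.
#' @param transl_table NCBI genetic-code id.
#' @return List with `effect` (`"synonymous"`, `"nonsynonymous"` or
#'   `"unclassified"`), `aa_change` (e.g. `"T-A"`, `NA` unless
#'   nonsynonymous) and `n_diff` (differing positions).
#' @export
classify_codon_pair <- function(ref_codon, qry_codon, transl_table = 2L) {
  rc <- strsplit(ref_codon, "")[[1L]]
  qc <- strsplit(qry_codon, "")[[1L]]
  stopifnot(length(rc) == 3L, length(qc) == 3L)
  n_diff <- sum(rc != qc)
  base <- c("A", "C", "G", "T")
  if (!all(c(rc, qc) %in% base))
    return(list(effect = "unclassified", aa_change = NA_character_,
                n_diff = n_diff))
  code <- genetic_code(transl_table)
  aa_r <- translate_codons(ref_codon, code)
  aa_q <- translate_codons(qry_codon, code)
  if (aa_r == aa_q)
    list(effect = "synonymous", aa_change = NA_character_, n_diff = n_diff)
  else
    list(effect = "nonsynonymous", aa_change = paste0(aa_r, "-", aa_q),
         n_diff = n_diff)
}

#' Per-gene selection table (count-ratio dN/dS)
#'
#' For each protein-coding gene, counts synonymous and nonsynonymous
#' substitutions between a reference genome and an aligned query, lists the
#' amino-acid replacements, and reports dN/dS as the raw ratio of
#' nonsynonymous to synonymous substitution *counts* -- not a site-normalized
#' estimator (see [dnds_site_normalized()] for that variant). The ratio is
#' defined only when both counts are positive, matching the em-dash
#' convention of comparative mitogenome reports; the category is `purifying`
#' (<1), `neutral` (=1, exact integer equality), `positive` (>1) or
#' `undefined`.
#'
#' Codons hit by more than one substitution are evaluated once on the whole
#' codon and the event is attributed to each differing position, so per-gene
#' counts sum to the CDS substitution total of the regional breakdown.
#'
#' @param aln A `pairwise_alignment` of the two genomes (reference first).
#' @param g_ref Reference `genome_record` carrying the CDS annotation.
#' @param genes Optional subset of gene names (default: all CDS features).
#' @return Data frame with one row per gene: `gene`, `n_synonymous`,
#'   `n_nonsynonymous`, `aa_changes`, `dnds`, `category`.
#' @export
gene_selection_table <- function(aln, g_ref, genes = NULL) {
  cds <- g_ref$features[g_ref$features$ftype == "CDS", , drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, cds$name)
    if (length(missing))
      stop("gene(s) absent from annotation: ", paste(missing, collapse = ", "))
    cds <- cds[match(genes, cds$name), , drop = FALSE]
  }
  if (!nrow(cds)) stop("no CDS features annotated")

  n <- genome_length(g_ref)
  ## reference position -> query base (NA at gaps / beyond)
  qmap <- rep(NA_character_, n)
  qc <- strsplit(aln$qry_aln, "")[[1L]]
  ok <- !is.na(aln$column_to_ref) & qc != "-"
  qmap[aln$column_to_ref[ok] + 1L] <- qc[ok]
  rch <- strsplit(g_ref$sequence, "")[[1L]]

  rows <- lapply(seq_len(nrow(cds)), function(i) {
    f <- cds[i, ]
    pos <- seq.int(f$start, f$end - 1L) %% n          # genome coords, 5'->3' on +
    if (f$strand == "-") pos <- rev(pos)
    if (f$codon_start > 0L) pos <- pos[-seq_len(f$codon_start)]
    n_codon <- length(pos) %/% 3L
    pos <- pos[seq_len(3L * n_codon)]
    rb <- rch[pos + 1L]
    qb <- qmap[pos + 1L]
    if (f$strand == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      rb <- unname(comp[rb])
      qb <- ifelse(is.na(qb), NA, unname(comp[qb]))
    }
    n_syn <- 0L; n_nonsyn <- 0L; changes <- character(0)
    diff_idx <- which(!is.na(qb) & rb != qb)
    for (cd in unique((diff_idx - 1L) %/% 3L)) {
      j <- 3L * cd + 1:3
      if (any(is.na(qb[j]))) next                      # gapped codon: skip
      res <- classify_codon_pair(paste(rb[j], collapse = ""),
                                 paste(qb[j], collapse = ""),
                                 f$transl_table)
      n_at <- sum(rb[j] != qb[j])
      if (res$effect == "synonymous") n_syn <- n_syn + n_at
      else if (res$effect == "nonsynonymous") {
        n_nonsyn <- n_nonsyn + n_at
        changes <- c(changes, res$aa_change)
      }
    }
    call <- dnds_call(n_syn, n_nonsyn)
    dnds <- call$dnds
    category <- call$category
    data.frame(gene = f$name, n_synonymous = n_syn, n_nonsynonymous = n_nonsyn,
               aa_changes = if (length(changes)) paste(changes, collapse = "/")
                            else "-",
               dnds = dnds, category = category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Selection call from raw substitution counts
#'
#' The count-ratio convention of comparative mitogenome tables: dN/dS is
#' `n_nonsynonymous / n_synonymous`, defined only when both counts are
#' positive (rendered as an em dash otherwise); the category is decided on
#' exact integer comparison of the counts -- `purifying` when fewer
#' nonsynonymous than synonymous, `neutral` on equality, `positive`
#' otherwise, `undefined` when the ratio is undefined.
#'
#' @param n_synonymous,n_nonsynonymous Non-negative integer counts.
#' @return List with `dnds` (`NA` when undefined) and `category`.
#' @export
dnds_call <- function(n_synonymous, n_nonsynonymous) {
  stopifnot(n_synonymous >= 0, n_nonsynonymous >= 0)
  dnds <- if (n_synonymous > 0L && n_nonsynonymous > 0L)
    n_nonsynonymous / n_synonymous else NA_real_
  category <- if (is.na(dnds)) "undefined"
    else if (n_nonsynonymous == n_synonymous) "neutral"
    else if (n_nonsynonymous < n_synonymous) "purifying" else "positive"
  list(dnds = dnds, category = category)
}

#' Site-normalized dN/dS (Nei-Gojobori style)
#'
#' Optional variant of the selection ratio normalizing substitution counts by
#' the numbers of nonsynonymous and synonymous *sites* (each codon position
#' contributes the fraction of its possible single-base changes that are
#' nonsynonymous). Offered for comparison; the default pipeline reports the
#' raw count ratio.
#'
#' @inheritParams gene_selection_table
#' @return The selection table with extra columns `n_sites_syn`,
#'   `n_sites_nonsyn`, `dnds_site` (pN/pS ratio of per-site proportions).
#' @export
dnds_site_normalized <- function(aln, g_ref, genes = NULL) {
  tab <- gene_selection_table(aln, g_ref, genes)
  code <- genetic_code(2L)
  base <- c("A", "C", "G", "T")
  site_counts <- function(codon) {
    rc <- strsplit(codon, "")[[1L]]
    if (!all(rc %in% base)) return(c(syn = 0, nonsyn = 0))
    aa0 <- translate_codons(codon, code)
    syn <- 0
    for (p in 1:3) for (b in setdiff(base, rc[p])) {
      mut <- rc; mut[p] <- b
      if (translate_codons(paste(mut, collapse = ""), code) == aa0)
        syn <- syn + 1 / 3
    }
    c(syn = syn, nonsyn = 3 - syn)
  }
  cds <- g_ref$features[g_ref$features$ftype == "CDS", , drop = FALSE]
  cds <- cds[match(tab$gene, cds$name), , drop = FALSE]
  ns <- t(vapply(seq_len(nrow(cds)), function(i) {
    s <- feature_sequence(g_ref, cds[i, ])
    if (cds$codon_start[i] > 0L) s <- substring(s, cds$codon_start[i] + 1L)
    k <- nchar(s) %/% 3L
    codons <- substring(s, 3L * seq_len(k) - 2L, 3L * seq_len(k))
    rowSums(vapply(codons, site_counts, c(syn = 0, nonsyn = 0)))
  }, c(syn = 0, nonsyn = 0)))
  tab$n_sites_syn <- ns[, "syn"]
  tab$n_sites_nonsyn <- ns[, "nonsyn"]
  pn <- tab$n_nonsynonymous / tab$n_sites_nonsyn
  ps <- tab$n_synonymous / tab$n_sites_syn
  tab$dnds_site <- ifelse(ps > 0 & pn > 0, pn / ps, NA_real_)
  tab
}
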