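#' Global pairwise alignment of two mitogenomes
#'
#' Deterministic global (Needleman-Wunsch) alignment with affine gap costs,
#' the reproducible replacement for interactive similarity searches when
#' comparing near-identical whole mitogenomes. Circular queries should be
#' rotated onto the reference frame first ([rotate_to_reference()]).
#'
#' Scoring: `match` and `mismatch` per aligned base pair; a gap of length L
#' costs `gap_open + L * gap_extend`.
#'
#' @param ref,qry `genome_record` objects.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A `pairwise_alignment`: equal-length gapped strings `ref_aln`,
#'   `qry_aln`, per-column source coordinates `column_to_ref`,
#'   `column_to_qry` (0-based, `NA` at gaps), and the alignment `score`.
#' @export
align_pair <- function(ref, qry, match = 1, mismatch = -2,
                       gap_open = 5, gap_extend = 2) {
  if (!nzchar(ref$sequence) || !nzchar(qry$sequence))
    stop("cannot align an empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref$sequence), Biostrings::DNAString(qry$sequence),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  ra <- as.character(Biostrings::alignedPattern(aln))
  qa <- as.character(Biostrings::alignedSubject(aln))
  pairwise_alignment(ref$id, qry$id, ra, qa, score = Biostrings::score(aln))
}

#' @rdname align_pair
#' @param ref_id,qry_id Sequence identifiers.
#' @param ref_aln,qry_aln Equal-length gapped strings.
#' @param score Optional alignment score.
#' @export
pairwise_alignment <- function(ref_id, qry_id, ref_aln, qry_aln, score = NA_real_) {
  if (nchar(ref_aln) != nchar(qry_aln))
    stop("aligned rows differ in length")
  rc <- strsplit(ref_aln, "")[[1L]]
  qc <- strsplit(qry_aln, "")[[1L]]
  if (any(rc == "-" & qc == "-")) stop("column gapped on both sides")
  structure(list(
    ref_id = ref_id, qry_id = qry_id,
    ref_aln = ref_aln, qry_aln = qry_aln,
    column_to_ref = ifelse(rc == "-", NA_integer_, cumsum(rc != "-") - 1L),
    column_to_qry = ifelse(qc == "-", NA_integer_, cumsum(qc != "-") - 1L),
    score = score
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: %d columns, score %s\n",
              x$ref_id, x$qry_id, nchar(x$ref_aln), format(x$score)))
  invisible(x)
}

#' Rotate a circular genome onto a reference frame
#'
#' Finds the query position best matching the start of the reference (by
#' seeding the first `seed_length` reference bases against the doubled query,
#' tolerating up to `max_mismatch_frac` mismatches) and rotates the query so
#' that position becomes its origin. Annotation coordinates are rotated
#' consistently; features pushed across the new origin are unrolled.
#'
#' @param ref,qry Circular `genome_record` objects.
#' @param seed_length Length of the reference-start seed.
#' @param max_mismatch_frac Mismatch tolerance within the seed.
#' @return The rotated query `genome_record`, with attribute `"offset"`
#'   (the recovered rotation, in query coordinates).
#' @export
rotate_to_reference <- function(ref, qry, seed_length = 200L,
                                max_mismatch_frac = 0.2) {
  if (!ref$circular || !qry$circular)
    stop("rotation requires circular genomes")
  n_ref <- genome_length(ref)
  n_qry <- genome_length(qry)
  seed_length <- min(seed_length, n_ref, n_qry)
  doubled <- Biostrings::DNAString(
    paste0(qry$sequence, substr(qry$sequence, 1L, seed_length)))
  mm <- as.integer(floor(max_mismatch_frac * seed_length))
  count_mm <- function(s, seed) {
    sum(strsplit(as.character(doubled[s:(s + seed_length - 1L)]), "")[[1L]] !=
          strsplit(seed, "")[[1L]])
  }
  ## anchor seeds at several reference positions: a single anchor can sit in
  ## a hyper-diverged region (e.g. the control region)
  anchors <- as.integer(floor(n_ref * (0:7) / 8))
  anchors <- anchors[anchors + seed_length <= n_ref]
  for (p in anchors) {
    seed <- substr(ref$sequence, p + 1L, p + seed_length)
    hits <- Biostrings::matchPattern(seed, doubled, max.mismatch = mm,
                                     with.indels = FALSE)
    st <- BiocGenerics::start(hits)
    st <- st[st <= n_qry]
    if (!length(st)) next
    if (length(st) > 1L) {
      nmm <- vapply(st, count_mm, 0L, seed = seed)
      st <- st[order(nmm, st)][1L]
    }
    return(rotate_genome(qry, (st - 1L - p) %% n_qry))
  }
  stop("no seed match for rotation; genomes may be too diverged -- ",
       "consider aligning in linear mode")
}

#' @rdname rotate_to_reference
#' @param g A circular `genome_record`.
#' @param offset 0-based position that becomes the new origin.
#' @export
rotate_genome <- function(g, offset) {
  n <- genome_length(g)
  offset <- as.integer(offset %% n)
  if (offset == 0L) {
    attr(g, "offset") <- 0L
    return(g)
  }
  seq2 <- paste0(substr(g$sequence, offset + 1L, n), substr(g$sequence, 1L, offset))
  f <- g$features
  if (nrow(f)) {
    len <- f$end - f$start
    f$start <- (f$start - offset) %% n
    f$end <- f$start + len
    f <- f[order(f$start), , drop = FALSE]
  }
  out <- genome_record(g$id, seq2, circular = g$circular, features = f,
                       label = g$label)
  attr(out, "offset") <- offset
  out
}

#' Center-star multiple alignment
#'
#' Merges global pairwise alignments of every genome against a designated
#' center sequence under the "once a gap, always a gap" rule. Suited to sets
#' of near-identical mitogenomes, where the center-star approximation is
#' essentially exact.
#'
#' @param genomes List of `genome_record` objects (>= 3).
#' @param center Id of the center genome (default: the first).
#' @param max_divergence Warn when any pairwise divergence from the center
#'   exceeds this proportion.
#' @param ... Scoring parameters passed to [align_pair()].
#' @return An object of class `msa`: `rows` (named gapped strings, genome
#'   order preserved), `center`, and `column_to_center` (0-based center
#'   coordinate per column, `NA` at center-gap columns).
#' @export
msa_center_star <- function(genomes, center = NULL, max_divergence = 0.30, ...) {
  if (length(genomes) < 3L) stop("need at least 3 genomes")
  ids <- vapply(genomes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  if (is.null(center)) center <- ids[1L]
  ci <- match(center, ids)
  if (is.na(ci)) stop("center '", center, "' not among genomes")
  cg <- genomes[[ci]]
  n <- genome_length(cg)
  others <- setdiff(seq_along(genomes), ci)

  alns <- lapply(others, function(i) align_pair(cg, genomes[[i]], ...))
  ## next aligned center coordinate at or after each column (NA past the end)
  next_aligned <- function(r) {
    idx <- which(!is.na(r))
    p <- findInterval(seq_along(r) - 1L, idx) + 1L  # first aligned column >= j
    out <- rep(NA_integer_, length(r))
    ok <- p <= length(idx)
    out[ok] <- r[idx[p[ok]]]
    out
  }
  ## per-pair: number of query-insertion columns immediately before each
  ## center position i (slot n+1 = after the last position)
  ins_of <- function(a) {
    cols <- is.na(a$column_to_ref)            # insertion relative to center
    slot <- ifelse(is.na(next_aligned(a$column_to_ref)), n,
                   next_aligned(a$column_to_ref))
    tabulate(slot[cols] + 1L, nbins = n + 1L)
  }
  ins <- lapply(alns, ins_of)
  master <- Reduce(pmax, ins, rep(0L, n + 1L))

  ## master column layout: [slot_1 gaps][c_1][slot_2 gaps][c_2]...[slot_{n+1} gaps]
  total <- n + sum(master)
  pos_col <- seq_len(n) + cumsum(master)[seq_len(n)]  # column of center base i
  cc <- strsplit(cg$sequence, "")[[1L]]
  center_row <- rep("-", total)
  center_row[pos_col] <- cc

  expand_row <- function(a) {
    qc <- strsplit(a$qry_aln, "")[[1L]]
    out <- rep("-", total)
    aligned <- !is.na(a$column_to_ref)
    out[pos_col[a$column_to_ref[aligned] + 1L]] <- qc[aligned]
    cols <- which(!aligned)
    if (length(cols)) {
      nxt <- next_aligned(a$column_to_ref)
      slot <- ifelse(is.na(nxt[cols]), n, nxt[cols]) + 1L  # master slot index
      block_start <- c(pos_col - master[seq_len(n)], total - master[n + 1L] + 1L)
      rank <- stats::ave(seq_along(cols), slot, FUN = seq_along)
      k_of <- tabulate(slot, nbins = n + 1L)
      ## right-align this pair's insertions within the master slot
      out[block_start[slot] + (master[slot] - k_of[slot]) + rank - 1L] <- qc[cols]
    }
    out
  }
  rows <- vector("list", length(genomes))
  rows[[ci]] <- center_row
  for (k in seq_along(others)) rows[[others[k]]] <- expand_row(alns[[k]])
  div <- vapply(alns, function(a) {
    rc <- strsplit(a$ref_aln, "")[[1L]]; qc <- strsplit(a$qry_aln, "")[[1L]]
    both <- rc != "-" & qc != "-"
    mean(rc[both] != qc[both])
  }, 0)
  if (any(div > max_divergence))
    warning("divergence from center exceeds ", max_divergence, " for: ",
            paste(ids[others][div > max_divergence], collapse = ", "))
  ccoord <- cumsum(rows[[ci]] != "-") - 1L
  ccoord[rows[[ci]] == "-"] <- NA_integer_
  structure(list(rows = stats::setNames(vapply(rows, paste, "", collapse = ""), ids),
                 center = center, column_to_center = ccoord),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns (center: %s)\n",
              length(x$rows), nchar(x$rows[[1L]]), x$center))
  invisible(x)
}

#' Build an MSA object from pre-aligned rows
#'
#' @param rows Named character vector of equal-length gapped strings.
#' @param center Optional center id.
#' @export
msa_from_rows <- function(rows, center = names(rows)[1L]) {
  stopifnot(!is.null(names(rows)), length(unique(nchar(rows))) == 1L)
  cc <- strsplit(rows[[center]], "")[[1L]]
  ccoord <- cumsum(cc != "-") - 1L
  ccoord[cc == "-"] <- NA_integer_
  structure(list(rows = rows, center = center, column_to_center = ccoord),
            class = "msa")
}

#' Complete-deletion column filter
#'
#' Drops every column containing a gap or an ambiguous base (anything outside
#' ACGT) in any row -- the site set entering distance and likelihood
#' computations when positions with gaps and missing data are eliminated.
#'
#' @param msa An `msa` object.
#' @return An `msa` with the retained columns only; attribute
#'   `"n_retained"` gives the column count.
#' @export
msa_complete_deletion <- function(msa) {
  m <- msa_matrix(msa)
  keep <- colSums(m == "A" | m == "C" | m == "G" | m == "T") == nrow(m)
  m2 <- m[, keep, drop = FALSE]
  rows <- apply(m2, 1L, paste, collapse = "")
  out <- msa_from_rows(stats::setNames(rows, rownames(m)), center = msa$center)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' @rdname msa_complete_deletion
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$rows), ""))
  rownames(m) <- names(msa$rows)
  m
}

#' Write an MSA as gapped multi-FASTA
#' @param msa An `msa` object.
#' @param file Optional output path.
#' @param width FASTA line width.
#' @export
write_msa_fasta <- function(msa, file = NULL, width = 70L) {
  txt <- paste(vapply(names(msa$rows), function(id) {
    s <- msa$rows[[id]]
    starts <- seq.int(1L, nchar(s), by = width)
    paste0(">", id, "\n",
           paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 collapse = "\n"))
  }, ""), collapse = "\n")
  if (is.null(file)) return(paste0(txt, "\n"))
  writeLines(txt, file)
  invisible(NULL)
}

#' Read a gapped multi-FASTA into an MSA
#' @param path FASTA path.
#' @param center Optional center id (defaults to first record).
#' @export
read_msa_fasta <- function(path, center = NULL) {
  recs <- parse_fasta(paste(readLines(path), collapse = "\n"))
  rows <- stats::setNames(unlist(recs), names(recs))
  msa_from_rows(rows, center = if (is.null(center)) names(rows)[1L] else center)
}
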