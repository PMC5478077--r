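PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Substitution class of a base pair
#' @param ref,alt Single bases (ACGT).
#' @return `"transition"` or `"transversion"`.
#' @export
substitution_class <- function(ref, alt) {
  ifelse((ref %in% PURINES) == (alt %in% PURINES), "transition", "transversion")
}

#' Classify every difference in a pairwise mitogenome alignment
#'
#' Each mismatching base column becomes one directed substitution (reference
#' to query orientation, so C-to-T is distinct from T-to-C), labelled
#' transition or transversion. Each maximal run of gap columns on one side
#' becomes a single indel event, regardless of its length. Columns with an
#' ambiguous base (N etc.) on either side are excluded from substitution
#' counts and reported in `n_excluded`. Every variant is assigned the
#' reference feature containing it (`other_noncoding` when none does).
#'
#' @param aln A `pairwise_alignment` (see [align_pair()]).
#' @param ref_features Feature data frame of the reference genome
#'   (0-based half-open internal coordinates), or `NULL`.
#' @param ref_length Reference length, required to resolve circular
#'   (unrolled) features; defaults to the number of reference positions in
#'   the alignment.
#' @return A `variant_table`: data frame `variants` plus the summary counts
#'   `n_substitutions`, `n_transitions`, `n_transversions`, `n_indel_events`,
#'   `n_excluded`, and the directed substitution spectrum `per_direction`.
#' @export
classify_variants <- function(aln, ref_features = NULL, ref_length = NULL) {
  rc <- strsplit(aln$ref_aln, "")[[1L]]
  qc <- strsplit(aln$qry_aln, "")[[1L]]
  if (is.null(ref_length)) ref_length <- sum(rc != "-")
  base <- c("A", "C", "G", "T")
  both_base <- rc %in% base & qc %in% base
  gapped <- rc == "-" | qc == "-"
  excluded <- !both_base & !gapped

  sub_cols <- which(both_base & rc != qc)
  subs <- if (length(sub_cols)) {
    data.frame(
      ref_pos = aln$column_to_ref[sub_cols],
      ref_base = rc[sub_cols], alt_base = qc[sub_cols],
      vclass = substitution_class(rc[sub_cols], qc[sub_cols]),
      stringsAsFactors = FALSE)
  } else {
    data.frame(ref_pos = integer(), ref_base = character(),
               alt_base = character(), vclass = character(),
               stringsAsFactors = FALSE)
  }

  ## indel events: maximal gap runs, one side at a time
  r <- rle(ifelse(rc == "-", "ins", ifelse(qc == "-", "del", "base")))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- which(r$values != "base")
  indels <- if (length(ev)) {
    anchor <- vapply(starts[ev], function(s) {
      prior <- aln$column_to_ref[seq_len(s - 1L)]
      prior <- prior[!is.na(prior)]
      if (length(prior)) prior[length(prior)] else 0L
    }, 0L)
    data.frame(
      ref_pos = anchor,
      ref_base = ifelse(r$values[ev] == "ins", "-",
                        substring(aln$ref_aln, starts[ev], ends[ev])),
      alt_base = ifelse(r$values[ev] == "del", "-",
                        substring(aln$qry_aln, starts[ev], ends[ev])),
      vclass = ifelse(r$values[ev] == "ins", "insertion", "deletion"),
      stringsAsFactors = FALSE)
  } else subs[0L, ]

  variants <- rbind(subs, indels)
  variants <- variants[order(variants$ref_pos), , drop = FALSE]
  rownames(variants) <- NULL
  reg <- assign_region(variants$ref_pos, ref_features, ref_length)
  variants$region <- reg$name
  variants$ftype <- reg$ftype

  dirs <- table(paste0(subs$ref_base, ">", subs$alt_base))
  structure(list(
    variants = variants,
    n_substitutions = nrow(subs),
    n_transitions = sum(subs$vclass == "transition"),
    n_transversions = sum(subs$vclass == "transversion"),
    n_indel_events = length(ev),
    n_excluded = sum(excluded),
    per_direction = dirs
  ), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(paste0("<variant_table> %d variable positions: %d transitions, ",
                     "%d transversions, %d indel events\n"),
              x$n_substitutions + x$n_indel_events,
              x$n_transitions, x$n_transversions, x$n_indel_events))
  invisible(x)
}

## feature containing each 0-based reference position (circular-aware)
assign_region <- function(pos, features, ref_length) {
  if (is.null(features) || !nrow(features) || !length(pos))
    return(list(name = rep("other_noncoding", length(pos)),
                ftype = rep("other_noncoding", length(pos))))
  name <- rep("other_noncoding", length(pos))
  ftype <- rep("other_noncoding", length(pos))
  for (i in seq_len(nrow(features))) {
    s <- features$start[i]; e <- features$end[i]
    hit <- if (e <= ref_length) pos >= s & pos < e
           else pos >= s | pos < (e %% ref_length)   # unrolled across origin
    fresh <- hit & name == "other_noncoding"
    name[fresh] <- features$name[i]
    ftype[fresh] <- features$ftype[i]
  }
  list(name = name, ftype = ftype)
}

#' Regional breakdown of substitutions
#'
#' Partitions the substitutions of a [classify_variants()] table among the
#' control region, protein-coding genes, tRNAs, rRNAs and unannotated
#' spans. Percentages use the substitution count as denominator; indel
#' events are excluded.
#'
#' @param vt A `variant_table`.
#' @return Data frame with columns `region_class`, `count`, `percent`.
#' @export
region_breakdown <- function(vt) {
  subs <- vt$variants[vt$variants$vclass %in% c("transition", "transversion"), ]
  classes <- c("control_region", "CDS", "tRNA", "rRNA", "other_noncoding")
  cnt <- vapply(classes, function(k) sum(subs$ftype == k), 0L)
  data.frame(region_class = classes, count = as.integer(cnt),
             percent = if (nrow(subs)) 100 * cnt / nrow(subs) else rep(0, 5L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Base composition of a genome
#'
#' Percentages of T, C, A, G over unambiguous positions, printed at one
#' decimal in reports.
#'
#' @param g A `genome_record`.
#' @return List with `pct_T`, `pct_C`, `pct_A`, `pct_G` and `total`
#'   (the sequence length).
#' @export
base_composition <- function(g) {
  ch <- strsplit(g$sequence, "")[[1L]]
  n_acgt <- sum(ch %in% c("A", "C", "G", "T"))
  pct <- function(b) 100 * sum(ch == b) / n_acgt
  list(pct_T = pct("T"), pct_C = pct("C"), pct_A = pct("A"), pct_G = pct("G"),
       total = length(ch))
}

#' Pairwise divergence summary
#'
#' Counts mismatched base columns (the divergence base number) and gap
#' events between two aligned genomes; the percentage is over aligned,
#' unambiguous base columns.
#'
#' @param aln A `pairwise_alignment`.
#' @return List with `pair`, `n_divergent`, `pct_divergent`, `n_gaps`,
#'   `n_compared`.
#' @export
divergence_summary <- function(aln) {
  rc <- strsplit(aln$ref_aln, "")[[1L]]
  qc <- strsplit(aln$qry_aln, "")[[1L]]
  base <- c("A", "C", "G", "T")
  both <- rc %in% base & qc %in% base
  ndiv <- sum(both & rc != qc)
  r <- rle(ifelse(rc == "-", "ins", ifelse(qc == "-", "del", "base")))
  ngap <- sum(r$values != "base")
  list(pair = c(aln$ref_id, aln$qry_id),
       n_divergent = ndiv,
       pct_divergent = 100 * ndiv / sum(both),
       n_gaps = ngap,
       n_compared = sum(both))
}
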