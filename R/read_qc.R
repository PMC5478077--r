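#' Low-quality base test
#'
#' A base is called low-quality when its Phred score is less than or equal to
#' the threshold (default Q7), the rule applied before assembling
#' mitochondrial short-read data.
#'
#' @param q Integer Phred score(s), >= 0.
#' @param threshold Inclusive quality threshold.
#' @return Logical vector.
#' @export
is_low_quality_base <- function(q, threshold = 7L) {
  stopifnot(all(q >= 0))
  q <= threshold
}

#' Filter low-quality reads
#'
#' Discards a read when more than `max_low_fraction` of its bases are
#' low-quality per [is_low_quality_base()]. The boundary is strict: a 100-bp
#' read with exactly 10 bases at or below Q7 is kept under the defaults.
#' Zero-length reads are discarded and counted separately. N bases are not
#' treated specially; only the quality score decides.
#'
#' @param reads List of `quality_read` objects (see [parse_fastq()]).
#' @param base_threshold Phred threshold defining a low-quality base.
#' @param max_low_fraction Maximum tolerated fraction of low-quality bases.
#' @return A list with `kept` (reads, input order preserved) and `stats`
#'   (total, kept, discarded, empty, bases_kept, bases_total).
#' @export
filter_reads <- function(reads, base_threshold = 7L, max_low_fraction = 0.10) {
  stopifnot(base_threshold >= 0, max_low_fraction >= 0, max_low_fraction <= 1)
  len <- vapply(reads, function(r) length(r$quals), 0L)
  nlow <- vapply(reads, function(r) sum(is_low_quality_base(r$quals, base_threshold)), 0L)
  empty <- len == 0L
  keep <- !empty & (nlow / pmax(len, 1L)) <= max_low_fraction
  list(
    kept = reads[keep],
    stats = list(
      total = length(reads),
      kept = sum(keep),
      discarded = sum(!keep),
      empty = sum(empty),
      bases_kept = sum(len[keep]),
      bases_total = sum(len)
    )
  )
}
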