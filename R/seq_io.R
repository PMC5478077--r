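#' Annotated mitochondrial genome records
#'
#' A `genome_record` bundles one (usually circular) mitochondrial genome
#' sequence with its feature annotation: the 13 protein-coding genes, 22
#' tRNAs, 2 rRNAs and the noncoding control region typical of a vertebrate
#' mitogenome.
#'
#' Internally all feature coordinates are 0-based half-open; every external
#' representation (feature-table files, printed reports) is 1-based inclusive,
#' the GenBank convention. Features of circular genomes that span the origin
#' are stored "unrolled" (end may exceed the sequence length) and normalized
#' on access.
#'
#' @param id Accession-like identifier.
#' @param sequence Uppercase IUPAC DNA string. By default only `ACGTN` are
#'   accepted; set `allow_ambiguity = TRUE` to admit the full IUPAC set.
#' @param circular Is the molecule circular?
#' @param features A data frame as returned by [parse_feature_table()], or
#'   `NULL` for an unannotated genome.
#' @param label Display name (e.g. `"SNJ R. roxellana"`); defaults to `id`.
#' @param allow_ambiguity Accept IUPAC ambiguity codes other than N.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, circular = TRUE, features = NULL,
                          label = id, allow_ambiguity = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("genome sequence must be non-empty")
  alphabet <- if (allow_ambiguity) "ACGTNRYSWKMBDHV" else "ACGTN"
  bad <- gsub(sprintf("[%s]", alphabet), "", sequence)
  if (nzchar(bad)) {
    stop("sequence of '", id, "' contains characters outside [", alphabet,
         "]: ", paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  }
  features <- validate_features(features, nchar(sequence), circular)
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 features = features, label = label),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s)\n", x$id, x$label))
  cat(sprintf("  %d bp, %s, %d features\n", genome_length(x),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

#' @rdname genome_record
#' @param g A `genome_record`.
#' @export
genome_length <- function(g) nchar(g$sequence)

empty_features <- function() {
  data.frame(name = character(), ftype = character(),
             start = integer(), end = integer(), strand = character(),
             codon_start = integer(), transl_table = integer(),
             stringsAsFactors = FALSE)
}

FEATURE_TYPES <- c("CDS", "tRNA", "rRNA", "control_region", "other_noncoding")

validate_features <- function(features, seqlen, circular) {
  if (is.null(features) || nrow(features) == 0L) return(empty_features())
  needed <- names(empty_features())
  miss <- setdiff(needed, names(features))
  if (length(miss)) stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  features <- features[needed]
  if (anyDuplicated(features$name))
    stop("duplicate gene names in annotation: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  if (!all(features$ftype %in% FEATURE_TYPES))
    stop("unknown feature type(s): ",
         paste(setdiff(features$ftype, FEATURE_TYPES), collapse = ", "))
  if (any(features$start >= features$end))
    stop("features must satisfy start < end after unrolling")
  if (any(features$start < 0L))
    stop("negative feature start")
  over <- features$end > seqlen
  if (any(over) && !circular)
    stop("feature(s) exceed sequence length on a linear genome: ",
         paste(features$name[over], collapse = ", "))
  if (any(features$end > 2L * seqlen))
    stop("unrolled feature end beyond one full wrap")
  is_cds <- features$ftype == "CDS"
  if (any(is_cds & (features$end - features$start - features$codon_start) < 3L))
    stop("CDS shorter than one codon after codon_start offset")
  features[order(features$start), , drop = FALSE]
}

#' Parse a genome plus its feature table
#'
#' Reads a single-record FASTA and a simplified tab-separated feature table
#' (columns: type, name, span, strand, and optionally codon_start and
#' transl_table; span is 1-based inclusive like `"3307..4262"`) into a
#' [genome_record()].
#'
#' @param fasta_text FASTA text containing exactly one record.
#' @param feature_table_text Feature-table text; `""` means no annotation.
#' @param circular Treat the genome as circular.
#' @param allow_ambiguity Passed to [genome_record()].
#' @return A `genome_record`.
#' @export
parse_genome <- function(fasta_text, feature_table_text = "",
                         circular = TRUE, allow_ambiguity = FALSE) {
  recs <- parse_fasta(fasta_text)
  if (length(recs) != 1L)
    stop("expected exactly one FASTA record, found ", length(recs))
  features <- parse_feature_table(feature_table_text)
  genome_record(id = names(recs)[1L], sequence = recs[[1L]],
                circular = circular, features = features,
                allow_ambiguity = allow_ambiguity)
}

## Minimal FASTA reader on in-memory text (files go through read_genome()).
parse_fasta <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA header found")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(gsub("\\s", "", x), collapse = "")),
                 "")
  stats::setNames(as.list(seqs), ids)
}

#' @rdname parse_genome
#' @param g A `genome_record`.
#' @param width Line width for the sequence body.
#' @return `write_genome_fasta()` returns the FASTA text, invisibly if `file`
#'   is given.
#' @param file Optional path; when given, text is written there.
#' @export
write_genome_fasta <- function(g, file = NULL, width = 70L) {
  seq <- g$sequence
  starts <- seq.int(1L, nchar(seq), by = width)
  body <- substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
  txt <- paste0(">", g$id, "\n", paste(body, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(sub("\n$", "", txt), file)
  invisible(txt)
}

#' Read and write the simplified feature table
#'
#' The feature-table dialect is tab-separated with columns
#' `ftype  name  span  strand  [codon_start]  [transl_table]`, spans 1-based
#' inclusive (`"start..end"`); lines starting with `#` are comments. A span
#' whose end exceeds the genome length denotes an origin-spanning feature on
#' a circular genome, stored unrolled.
#'
#' @param text Feature-table text (or a length-1 path handled by the caller).
#' @return A data frame with 0-based half-open `start`/`end` columns.
#' @export
parse_feature_table <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_features())
  parts <- strsplit(lines, "\t|\\s+")
  rows <- lapply(parts, function(p) {
    if (length(p) < 4L) stop("malformed feature line: ", paste(p, collapse = " "))
    span <- strsplit(p[3L], "..", fixed = TRUE)[[1L]]
    if (length(span) != 2L) stop("malformed span: ", p[3L])
    s1 <- as.integer(span[1L]); e1 <- as.integer(span[2L])
    if (is.na(s1) || is.na(e1) || s1 < 1L) stop("bad span: ", p[3L])
    data.frame(name = p[2L], ftype = p[1L],
               start = s1 - 1L, end = e1,   # 1-based inclusive -> 0-based half-open
               strand = p[4L],
               codon_start = if (length(p) >= 5L) as.integer(p[5L]) else 0L,
               transl_table = if (length(p) >= 6L) as.integer(p[6L]) else 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!all(out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  out
}

#' @rdname parse_feature_table
#' @param features A feature data frame (internal coordinates).
#' @param file Optional output path.
#' @export
write_feature_table <- function(features, file = NULL) {
  lines <- sprintf("%s\t%s\t%d..%d\t%s\t%d\t%d",
                   features$ftype, features$name,
                   features$start + 1L, features$end,  # back to 1-based inclusive
                   features$strand, features$codon_start, features$transl_table)
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(lines, file)
  invisible(txt)
}

#' Read a genome (FASTA + optional feature table) from files
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param feature_path Optional path to a feature table.
#' @inheritParams parse_genome
#' @export
read_genome <- function(fasta_path, feature_path = NULL, circular = TRUE,
                        allow_ambiguity = FALSE) {
  ft <- if (is.null(feature_path)) "" else
    paste(readLines(feature_path), collapse = "\n")
  parse_genome(paste(readLines(fasta_path), collapse = "\n"), ft,
               circular = circular, allow_ambiguity = allow_ambiguity)
}

#' Extract a feature's nucleotide sequence
#'
#' Honors circular wrapping (unrolled coordinates) and strand: minus-strand
#' features are returned reverse-complemented, ready for translation.
#'
#' @param g A `genome_record`.
#' @param feature One row of `g$features` (or a name matched against it).
#' @return A DNA string.
#' @export
feature_sequence <- function(g, feature) {
  if (is.character(feature)) {
    i <- match(feature, g$features$name)
    if (is.na(i)) stop("no feature named '", feature, "'")
    feature <- g$features[i, ]
  }
  n <- genome_length(g)
  pos <- seq.int(feature$start, feature$end - 1L) %% n
  s <- paste(strsplit(g$sequence, "")[[1L]][pos + 1L], collapse = "")
  if (feature$strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a DNA string
#' @param s DNA string (ACGTN).
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## ---- FASTQ -----------------------------------------------------------------

#' Quality-scored sequencing reads
#'
#' `parse_fastq()` reads Phred+33 FASTQ text into a list of `quality_read`
#' objects (`id`, `bases`, `quals`); `write_fastq()` is its inverse. The
#' 4-line-per-record layout is enforced and a base/quality length mismatch is
#' reported with the offending record id.
#'
#' @param text FASTQ text.
#' @return A list of `quality_read` objects.
#' @export
parse_fastq <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) return(list())
  if (length(lines) %% 4L != 0L)
    stop("FASTQ line count not a multiple of 4")
  n <- length(lines) %/% 4L
  out <- vector("list", n)
  for (k in seq_len(n)) {
    i <- (k - 1L) * 4L
    if (!startsWith(lines[i + 1L], "@"))
      stop("record ", k, ": header does not start with '@'")
    if (!startsWith(lines[i + 3L], "+"))
      stop("record ", k, ": separator line does not start with '+'")
    id <- sub("^@", "", strsplit(lines[i + 1L], "\\s+")[[1L]][1L])
    bases <- toupper(lines[i + 2L])
    quals <- as.integer(utf8ToInt(lines[i + 4L])) - 33L
    if (nchar(bases) != length(quals))
      stop("record '", id, "': base and quality lengths differ")
    if (any(quals < 0L | quals > 93L))
      stop("record '", id, "': Phred score outside [0, 93]")
    out[[k]] <- structure(list(id = id, bases = bases, quals = quals),
                          class = "quality_read")
  }
  out
}

#' @rdname parse_fastq
#' @param reads List of `quality_read` objects.
#' @param file Optional output path.
#' @export
write_fastq <- function(reads, file = NULL) {
  lines <- unlist(lapply(reads, function(r) {
    c(paste0("@", r$id), r$bases, "+", intToUtf8(r$quals + 33L))
  }), use.names = FALSE)
  if (is.null(file)) return(paste0(paste(lines, collapse = "\n"), "\n"))
  writeLines(lines, file)
  invisible(NULL)
}

#' @rdname parse_fastq
#' @param path Path to a FASTQ file.
#' @export
read_fastq <- function(path) parse_fastq(paste(readLines(path), collapse = "\n"))
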