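#!/usr/bin/env Rscript

# Downloads the 11 published mitogenome accessions used by the comparative
# analysis and converts each GenBank record into the package's plain-text
# formats: <acc>.fasta and <acc>.ft.tsv (simplified feature table) under
# inst/extdata/accessions/. Requires network access to NCBI E-utilities;
# run once from the repository root, then reinstall the package so the
# panel-dependent acceptance checks can run.

accessions <- c("KM504390.1", "DQ355300.1", "JQ821835.1", "JQ821836.1",
                "HM125579.1", "JQ821838.1", "HM125578.1", "JF293094.1",
                "JQ821840.1", "HQ149047.1", "DQ355299.1")

outdir <- file.path("inst", "extdata", "accessions")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
base_url <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"

fetch <- function(acc, rettype) {
  url <- sprintf("%s?db=nuccore&id=%s&rettype=%s&retmode=text",
                 base_url, acc, rettype)
  readLines(url, warn = FALSE)
}

# minimal extraction of CDS / tRNA / rRNA / D-loop spans from a GenBank
# feature table; enough for the package's simplified annotation format
gb_features <- function(gb) {
  ft <- grep("^     (CDS|tRNA|rRNA|D-loop)", gb)
  rows <- list()
  for (i in ft) {
    head <- sub("^\\s+", "", gb[i])
    parts <- strsplit(head, "\\s+")[[1L]]
    ftype <- parts[1L]
    loc <- parts[2L]
    strand <- if (grepl("complement", loc)) "-" else "+"
    span <- regmatches(loc, regexpr("[0-9]+\\.\\.[0-9]+", loc))
    if (!length(span)) next
    ## gene/product name from the qualifier block
    name <- NA_character_
    codon_start <- 0L
    for (j in (i + 1L):min(i + 12L, length(gb))) {
      if (grepl("^     [A-Za-z]", gb[j])) break
      q <- sub("^\\s+/", "", gb[j])
      if (startsWith(q, "gene=")) name <- gsub("\"", "", sub("gene=", "", q))
      if (is.na(name) && startsWith(q, "product="))
        name <- gsub("\"", "", sub("product=", "", q))
      if (startsWith(q, "codon_start="))
        codon_start <- as.integer(gsub("\"", "", sub("codon_start=", "", q))) - 1L
    }
    if (is.na(name)) name <- sprintf("%s_%s", ftype, span)
    ftype2 <- switch(ftype, `D-loop` = "control_region", CDS = "CDS",
                     tRNA = "tRNA", rRNA = "rRNA")
    rows[[length(rows) + 1L]] <-
      sprintf("%s\t%s\t%s\t%s\t%d\t2", ftype2, gsub("\\s+", "_", name),
              span, strand, codon_start)
  }
  ## disambiguate duplicated names (e.g. the two Leu/Ser tRNAs)
  lines <- unlist(rows)
  nm <- vapply(strsplit(lines, "\t"), `[`, "", 2L)
  dup <- ave(seq_along(nm), nm, FUN = seq_along)
  nm2 <- ifelse(dup > 1L, paste0(nm, "_", dup), nm)
  vapply(seq_along(lines), function(k) {
    p <- strsplit(lines[k], "\t")[[1L]]
    p[2L] <- nm2[k]
    paste(p, collapse = "\t")
  }, "")
}

for (acc in accessions) {
  message("fetching ", acc)
  fa <- fetch(acc, "fasta")
  writeLines(fa, file.path(outdir, paste0(acc, ".fasta")))
  gb <- fetch(acc, "gb")
  writeLines(gb_features(gb), file.path(outdir, paste0(acc, ".ft.tsv")))
  Sys.sleep(0.5)   # E-utilities rate courtesy
}
message("done; reinstall the package to expose the panel via system.file()")
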