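# The reference panel of 11 published snub-nosed-monkey / colobine
# mitogenomes. The sequences are not redistributed with the package; they can
# be fetched once with scripts/fetch_accessions.R, which writes
# <acc>.fasta and <acc>.ft.tsv files into inst/extdata/accessions (source
# tree) so they are installed with the package.

ACCESSION_PANEL <- c(
  "KM504390.1" = "SNJ R. roxellana",
  "DQ355300.1" = "SG R. roxellana",
  "JQ821835.1" = "QL R. roxellana",
  "JQ821836.1" = "R. brelichi",
  "HM125579.1" = "R. bieti",
  "JQ821838.1" = "R. strykeri",
  "HM125578.1" = "R. avunculus",
  "JF293094.1" = "N. larvatus",
  "JQ821840.1" = "P. nigripes",
  "HQ149047.1" = "T. germaini",
  "DQ355299.1" = "P. melalophos")

PANEL_OUTGROUPS <- c("N. larvatus", "P. nigripes", "T. germaini",
                     "P. melalophos")

accession_dir <- function() {
  d <- system.file("extdata", "accessions", package = "mitochron")
  if (nzchar(d) && file.exists(file.path(d, "KM504390.1.fasta"))) return(d)
  d2 <- file.path("inst", "extdata", "accessions")
  if (file.exists(file.path(d2, "KM504390.1.fasta"))) return(d2)
  ""
}

have_accessions <- function() nzchar(accession_dir())

load_accession <- function(acc, with_features = TRUE) {
  d <- accession_dir()
  ft <- file.path(d, paste0(acc, ".ft.tsv"))
  read_genome(file.path(d, paste0(acc, ".fasta")),
              if (with_features && file.exists(ft)) ft else NULL,
              circular = TRUE)
}

load_panel <- function() {
  gs <- lapply(names(ACCESSION_PANEL), load_accession)
  for (i in seq_along(gs)) gs[[i]]$label <- ACCESSION_PANEL[[i]]
  names(gs) <- names(ACCESSION_PANEL)
  gs
}

MISSING_PANEL_MSG <- paste(
  "the 11 GenBank mitogenome accessions are not present under",
  "inst/extdata/accessions; run scripts/fetch_accessions.R on a networked",
  "machine to enable this check")
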