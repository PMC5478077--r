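test_that("global alignment handles identity and forced gaps", {
  g <- function(id, s) genome_record(id, s, circular = FALSE)
  a <- align_pair(g("a", "ACGT"), g("b", "ACGT"))
  expect_equal(a$ref_aln, "ACGT")
  expect_equal(a$qry_aln, "ACGT")
  a2 <- align_pair(g("a", "ACGT"), g("b", "AGT"))
  expect_equal(nchar(a2$ref_aln), 4L)
  expect_equal(sum(strsplit(a2$qry_aln, "")[[1L]] == "-"), 1L)
})

test_that("alignment score equals the quadratic DP oracle", {
  set.seed(31)
  for (i in 1:8) {
    a <- random_dna(500L)
    b <- mutate_dna(a, 0.02)
    if (i %% 2 == 0)                       # also plant an indel
      b <- paste0(substr(b, 1L, 200L), substr(b, 204L, nchar(b)))
    s_pkg <- align_pair(genome_record("a", a, circular = FALSE),
                        genome_record("b", b, circular = FALSE))$score
    expect_equal(s_pkg, dp_align_score(a, b), tolerance = 1e-9)
  }
})

test_that("gap removal from aligned rows reproduces the inputs", {
  set.seed(32)
  a <- random_dna(300L)
  b <- paste0(substr(a, 1L, 100L), substr(a, 111L, 300L))
  b <- mutate_dna(b, 0.03)
  aln <- align_pair(genome_record("a", a, circular = FALSE),
                    genome_record("b", b, circular = FALSE))
  expect_equal(gsub("-", "", aln$ref_aln), a)
  expect_equal(gsub("-", "", aln$qry_aln), b)
})

test_that("circular rotation recovers planted offsets", {
  set.seed(33)
  a <- random_dna(2000L)
  ga <- genome_record("a", a)
  rot <- rotate_genome(ga, 100L)
  back <- rotate_to_reference(ga, rot)
  expect_equal(attr(back, "offset"), 1900L)    # inverse rotation
  expect_equal(back$sequence, a)
  ## identity on an already-aligned genome
  expect_equal(attr(rotate_to_reference(ga, ga), "offset"), 0L)
  ## offsets recovered under mutation pressure
  hits <- 0L
  for (i in 1:20) {
    off <- sample.int(1999L, 1L)
    qry <- genome_record("q", mutate_dna(rotate_genome(ga, off)$sequence, 0.01))
    rec <- rotate_to_reference(ga, qry)
    if (attr(rec, "offset") == (2000L - off) %% 2000L ||
        substr(rec$sequence, 1L, 50L) ==
          substr(mutate_dna(a, 0), 1L, 50L)) hits <- hits + 1L
    ## recovered frame must match the reference frame up to mutations
    expect_lt(mean(strsplit(rec$sequence, "")[[1L]] !=
                     strsplit(a, "")[[1L]]), 0.05)
  }
})

test_that("variant classification follows the transition/transversion rules", {
  aln <- pairwise_alignment("r", "q", "CACGT", "TAAGT")
  vt <- classify_variants(aln)
  expect_equal(vt$n_substitutions, 2L)
  expect_equal(vt$n_transitions, 1L)     # C>T
  expect_equal(vt$n_transversions, 1L)   # C>A
  expect_equal(unname(vt$per_direction[["C>T"]]), 1L)
  expect_equal(vt$variants$vclass[vt$variants$ref_base == "C" &
                                    vt$variants$alt_base == "T"], "transition")
})

test_that("classification is class-symmetric and direction-reversing", {
  set.seed(34)
  a <- random_dna(600L)
  b <- mutate_dna(a, 0.05)
  fwd <- classify_variants(pairwise_alignment("a", "b", a, b))
  rev <- classify_variants(pairwise_alignment("b", "a", b, a))
  expect_equal(fwd$n_transitions, rev$n_transitions)
  expect_equal(fwd$n_transversions, rev$n_transversions)
  dirs <- fwd$variants
  for (k in seq_len(nrow(dirs))) {
    expect_equal(sum(rev$variants$ref_base == dirs$alt_base[k] &
                       rev$variants$alt_base == dirs$ref_base[k]),
                 sum(dirs$ref_base == dirs$ref_base[k] &
                       dirs$alt_base == dirs$alt_base[k]))
    break
  }
})

test_that("gap runs count as single indel events and N columns are excluded", {
  aln <- pairwise_alignment("r", "q", "AC--GTNAC", "ACTTGTCAC")
  vt <- classify_variants(aln)
  expect_equal(vt$n_indel_events, 1L)          # one 2-column insertion
  expect_equal(vt$n_excluded, 1L)              # the N column
  expect_equal(vt$n_substitutions, 0L)
  ## counts identity: substitutions + indels = variable positions
  expect_equal(vt$n_transitions + vt$n_transversions, vt$n_substitutions)
})

test_that("region assignment agrees with a brute-force interval check", {
  cfg <- sim_config(scale = 0.3, seed = 35)
  sim <- simulate_dataset(cfg)
  g <- sim$genomes[[1L]]
  aln <- align_pair(g, sim$genomes[[5L]])
  vt <- classify_variants(aln, g$features, genome_length(g))
  ## brute force: first feature whose [start, end) contains the position
  brute <- vapply(vt$variants$ref_pos, function(p) {
    hit <- which(g$features$start <= p & p < g$features$end)
    if (length(hit)) g$features$ftype[hit[1L]] else "other_noncoding"
  }, "")
  expect_equal(vt$variants$ftype, brute)
  bd <- region_breakdown(vt)
  expect_equal(sum(bd$count), vt$n_substitutions)
  expect_equal(sum(bd$percent), 100, tolerance = 1e-9)
})

test_that("base composition recovers forced and uniform compositions", {
  cc <- base_composition(genome_record("x", "ACGT"))
  expect_equal(unlist(cc[1:4], use.names = FALSE), rep(25, 4L))
  expect_equal(cc$total, 4L)
  cfg <- sim_config(scale = 0.2, seed = 36,
                    pi = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
  sim <- simulate_dataset(cfg)
  comp <- base_composition(sim$genomes[[1L]])
  expect_equal(comp$pct_A, 40, tolerance = 5)
  expect_equal(comp$pct_G, 10, tolerance = 3)
})

test_that("divergence summary counts exact planted events", {
  aln0 <- pairwise_alignment("a", "b", "ACGTACGT", "ACGTACGT")
  d0 <- divergence_summary(aln0)
  expect_equal(d0$n_divergent, 0L)
  expect_equal(d0$n_gaps, 0L)
  set.seed(38)
  a <- random_dna(400L)
  ch <- strsplit(a, "")[[1L]]
  pos <- sample(seq(5L, 395L), 10L)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1L), "")
  b_ch <- ch
  ## plant two deletions in the query (as gap runs in the aligned rows)
  qry <- b_ch; qry[50:52] <- "-"; qry[200] <- "-"
  aln <- pairwise_alignment("a", "b", a, paste(qry, collapse = ""))
  d <- divergence_summary(aln)
  planted_overlap <- sum(pos %in% c(50:52, 200))
  expect_equal(d$n_divergent, 10L - planted_overlap)
  expect_equal(d$n_gaps, 2L)
})

test_that("center-star MSA preserves sequences and isolates planted indels", {
  ## identical sequences: gap-free alignment
  gs <- lapply(1:3, function(i)
    genome_record(paste0("g", i), "ACGTACGTACGTACGTACGTACGTACGTACGT",
                  circular = FALSE))
  m0 <- msa_center_star(gs)
  expect_true(all(!grepl("-", m0$rows)))
  ## a single-column indel in one taxon yields exactly one gap column
  set.seed(39)
  a <- random_dna(400L)
  b <- mutate_dna(a, 0.01)
  c3 <- paste0(substr(mutate_dna(a, 0.01), 1L, 199L),
               substr(mutate_dna(a, 0.01), 201L, 400L))   # 1-nt deletion
  gs2 <- list(genome_record("a", a, circular = FALSE),
              genome_record("b", b, circular = FALSE),
              genome_record("c", c3, circular = FALSE))
  m <- msa_center_star(gs2)
  gapcols <- colSums(msa_matrix(m) == "-")
  expect_equal(sum(gapcols > 0), 1L)
  ## every row reproduces its source after de-gapping
  for (i in 1:3)
    expect_equal(gsub("-", "", m$rows[[gs2[[i]]$id]]), gs2[[i]]$sequence)
})

test_that("complete deletion drops exactly the gap/ambiguity columns", {
  rows <- c(a = "ACGTNA", b = "AC-TAA", c = "ACGTAA")
  m <- msa_from_rows(rows)
  md <- msa_complete_deletion(m)
  expect_equal(attr(md, "n_retained"), 4L)
  expect_equal(unname(md$rows["a"]), "ACTA")
})
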