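test_that("simulated timetrees are ultrametric, labelled and deterministic", {
  cfg <- sim_config(scale = 0.05, seed = 91)
  t1 <- simulate_timetree(cfg)
  t2 <- simulate_timetree(cfg)
  expect_identical(ape::write.tree(t1$time_phylo), ape::write.tree(t2$time_phylo))
  expect_true(ape::is.ultrametric(t1$time_phylo, tol = 1e-8))
  expect_equal(length(t1$time_phylo$tip.label), cfg$n_taxa)
  expect_setequal(c(t1$ingroup, t1$outgroups), t1$time_phylo$tip.label)
  ## strict clock: substitution tree is ultrametric too
  expect_true(ape::is.ultrametric(t1$subs_phylo, tol = 1e-8))
  ## all tips at the configured total depth
  d <- ape::node.depth.edgelength(t1$time_phylo)
  expect_equal(max(d[1:cfg$n_taxa]) , cfg$outgroup_depth, tolerance = 1e-8)
})

test_that("identical configurations reproduce identical datasets", {
  cfg <- sim_config(scale = 0.05, seed = 92)
  s1 <- simulate_dataset(cfg, reads = TRUE)
  s2 <- simulate_dataset(cfg, reads = TRUE)
  expect_identical(s1$msa$rows, s2$msa$rows)
  expect_identical(write_fastq(s1$reads), write_fastq(s2$reads))
})

test_that("zero branch lengths leave all genomes identical", {
  cfg <- sim_config(scale = 0.05, seed = 93)
  tt <- simulate_timetree(cfg)
  tt$subs_phylo$edge.length[] <- 0
  ev <- evolve_genome(tt$subs_phylo, cfg)
  seqs <- vapply(ev$genomes, `[[`, "", "sequence")
  expect_equal(length(unique(seqs)), 1L)
})

test_that("the feature layout tiles the genome without overlap", {
  cfg <- sim_config(scale = 1)
  f <- cfg$features
  expect_equal(f$start[1L], 0L)
  expect_equal(f$start[-1L], f$end[-nrow(f)])       # contiguous blocks
  expect_equal(max(f$end), cfg$genome_length)
  expect_equal(sum(f$ftype == "CDS"), 13L)
  expect_equal(sum(f$ftype == "tRNA"), 22L)
  expect_equal(sum(f$ftype == "rRNA"), 2L)
  expect_true(all((f$end - f$start)[f$ftype == "CDS"] %% 3L == 0L))
  expect_equal(cfg$genome_length, 16542L)           # ~16.5 kb
})

test_that("realized transition bias matches the TN93 expectation", {
  ## per the configured rate structure, the expected transition:transversion
  ## substitution count ratio is (pi_A pi_G k1 + pi_C pi_T k2) / (pi_R pi_Y)
  cfg <- sim_config(scale = 1, seed = 94, k1 = 8, k2 = 8,
                    n_taxa = 4L, n_outgroups = 1L, mean_rate = 0.02)
  sim <- simulate_dataset(cfg)
  pi <- cfg$pi
  expected <- (pi[["A"]] * pi[["G"]] * 8 + pi[["C"]] * pi[["T"]] * 8) /
    ((pi[["A"]] + pi[["G"]]) * (pi[["C"]] + pi[["T"]]))
  vt <- classify_variants(pairwise_alignment("a", "b",
                                             sim$msa$rows[[1L]],
                                             sim$msa$rows[[4L]]))
  realized <- vt$n_transitions / vt$n_transversions
  expect_equal(realized, expected, tolerance = 0.25)
  expect_gt(vt$n_transitions, vt$n_transversions)   # transition bias
})

test_that("per-region divergence ordering is control > CDS/rRNA > tRNA", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(scale = 0.5, seed = 400 + s, n_taxa = 4L,
                      n_outgroups = 1L, mean_rate = 0.03)
    sim <- simulate_dataset(cfg)
    g <- sim$genomes[[1L]]
    vt <- classify_variants(align_pair(g, sim$genomes[[3L]]),
                            g$features, genome_length(g))
    bd <- region_breakdown(vt)
    span <- vapply(split(as.numeric(g$features$end - g$features$start),
                         g$features$ftype), sum, 0)
    dens <- setNames(bd$count / span[bd$region_class], bd$region_class)
    if (dens[["control_region"]] > dens[["rRNA"]] &&
        dens[["control_region"]] > dens[["CDS"]] &&
        dens[["rRNA"]] > dens[["tRNA"]] && dens[["CDS"]] > dens[["tRNA"]])
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("codon-aware evolution drives dN/dS toward its target", {
  cfg <- sim_config(scale = 1, seed = 95, n_taxa = 4L, n_outgroups = 1L,
                    mean_rate = 0.04, dnds_target = 0.3)
  sim <- simulate_dataset(cfg)
  g <- sim$genomes[[1L]]
  tab <- gene_selection_table(align_pair(g, sim$genomes[[4L]]), g)
  ratio <- sum(tab$n_nonsynonymous) / sum(tab$n_synonymous)
  expect_equal(ratio, 0.3, tolerance = 0.5)       # pooled across genes
  expect_lt(ratio, 1)                             # clearly purifying
})

test_that("simulated CDS regions stay free of internal stops", {
  cfg <- sim_config(scale = 0.3, seed = 96, mean_rate = 0.04)
  sim <- simulate_dataset(cfg)
  for (g in sim$genomes[c(1L, 5L, 11L)]) {
    for (gene in g$features$name[g$features$ftype == "CDS"]) {
      expect_no_error(translate_cds(g, gene))
    }
  }
})

test_that("read simulation honors the configured geometry and qualities", {
  cfg <- sim_config(scale = 1, seed = 97, coverage = 10, read_length = 100L)
  g <- genome_record("g", random_dna(16500L))
  reads <- simulate_reads(g, cfg)
  expect_equal(length(reads), 1650L)              # coverage * L / read length
  expect_true(all(vapply(reads, function(r) nchar(r$bases), 0L) == 100L))
  ## reads re-map to the (doubled, circular) genome
  doubled <- paste0(g$sequence, g$sequence)
  expect_true(all(vapply(reads[1:20], function(r)
    grepl(r$bases, doubled, fixed = TRUE), TRUE)))
  ## with no low-quality bases, the filter keeps everything
  cfg0 <- sim_config(scale = 1, seed = 98, p_low_quality = 0)
  reads0 <- simulate_reads(g, cfg0)
  expect_equal(filter_reads(reads0)$stats$kept, length(reads0))
})

test_that("deletions are planted only in noncoding regions and tracked", {
  cfg <- sim_config(scale = 0.3, seed = 99, n_indels = 3L)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$deletions), 3L)
  m <- msa_matrix(sim$msa)
  gap_cols <- which(colSums(m == "-") > 0L)
  ## every gap column lies in a noncoding block of the root annotation
  f <- sim$features
  noncod <- unlist(lapply(which(f$ftype %in% c("control_region",
                                               "other_noncoding")),
                          function(i) seq.int(f$start[i] + 1L, f$end[i])))
  expect_true(all(gap_cols %in% noncod))
  ## de-gapped rows equal the genome sequences
  for (tx in names(sim$genomes))
    expect_equal(gsub("-", "", sim$msa$rows[[tx]]),
                 sim$genomes[[tx]]$sequence)
})

test_that("true pairwise differences equal the aligner's classification", {
  cfg <- sim_config(scale = 0.3, seed = 100)
  sim <- simulate_dataset(cfg)
  ## truth from the simulator's exact alignment (no indels planted)
  a <- sim$msa$rows[[2L]]; b <- sim$msa$rows[[9L]]
  truth <- classify_variants(pairwise_alignment("a", "b", a, b))
  ## package route: re-align the raw genomes from scratch
  est <- classify_variants(align_pair(sim$genomes[[2L]], sim$genomes[[9L]]))
  expect_equal(est$n_substitutions, truth$n_substitutions)
  expect_equal(est$n_transitions, truth$n_transitions)
  expect_equal(est$n_transversions, truth$n_transversions)
  expect_equal(est$n_indel_events, 0L)
})
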