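test_that("NJ recovers additive 4-taxon matrices exactly", {
  ## tree ((A,B),(C,D)) with pendant lengths 1,2,3,4 and internal branch 1
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:4):0.5);")
  d <- tree_distances(tr, c("A", "B", "C", "D"))
  est <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), est), structure(0),
               ignore_attr = TRUE)
  dhat <- tree_distances(est, c("A", "B", "C", "D"))
  expect_equal(dhat, d, tolerance = 1e-9)
})

test_that("3 taxa resolve as the unique star with closed-form lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2L])], tr$tip.label)
  expect_equal(unname(len[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("NJ equals the exhaustive least-squares oracle on additive matrices", {
  set.seed(61)
  for (n in c(5L, 6L)) {
    for (rep in 1:5) {
      true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
      taxa <- true$tip.label
      d <- tree_distances(true, taxa)
      est <- nj_tree(d)
      ## oracle: the only topology with zero least-squares residual
      rss <- vapply(all_topologies(taxa), ls_fit_rss, 0, d = d)
      best <- which(rss < 1e-12)
      expect_equal(length(best), 1L)
      est_rss <- ls_fit_rss(est, d)
      expect_lt(est_rss, 1e-12)
    }
  }
})

test_that("two-taxon single-site likelihood matches the closed form", {
  ## JC: P(i->j, t) = 1/4 + 3/4 e^{-4t/3} (i = j), 1/4 - 1/4 e^{-4t/3} (else)
  model <- subst_model("JC")
  for (t in c(0.05, 0.3, 1)) {
    for (pair in list(c("A", "A"), c("A", "G"))) {
      m <- msa_from_rows(c(x = pair[1L], y = pair[2L]))
      tr <- ape::read.tree(text = sprintf("(x:%g,y:%g);", t / 2, t / 2))
      pij <- if (pair[1L] == pair[2L]) 0.25 + 0.75 * exp(-4 * t / 3)
             else 0.25 - 0.25 * exp(-4 * t / 3)
      expect_equal(tree_log_likelihood(tr, m, model), log(0.25 * pij),
                   tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant to rerooting and pattern compression", {
  cfg <- sim_config(scale = 0.1, seed = 62, n_taxa = 5L, n_outgroups = 1L)
  sim <- simulate_dataset(cfg)
  msa <- msa_complete_deletion(sim$msa)
  model <- mitochron:::estimate_model(msa, "TN93")
  tr <- nj_tree(build_distance_matrix(msa, "TN93", "pairwise"))
  l0 <- tree_log_likelihood(tr, msa, model)
  for (og in tr$tip.label[1:3]) {
    l1 <- tree_log_likelihood(ape::root(tr, outgroup = og,
                                        resolve.root = TRUE), msa, model)
    expect_lt(abs(l1 - l0), 1e-8)
  }
  ## compressed patterns equal an uncompressed site-by-site evaluation
  cols <- strsplit(unname(msa$rows), "")
  persite <- sum(vapply(seq_len(nchar(msa$rows[[1L]])), function(j) {
    one <- msa_from_rows(setNames(vapply(cols, `[`, "", j), names(msa$rows)))
    tree_log_likelihood(tr, one, model)
  }, 0))
  expect_equal(l0, persite, tolerance = 1e-6)
})

test_that("likelihood agrees with an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  cfg <- sim_config(scale = 0.1, seed = 63)
  sim <- simulate_dataset(cfg)
  msa <- msa_complete_deletion(sim$msa)
  model <- mitochron:::estimate_model(msa, "TN93")
  tr <- nj_tree(build_distance_matrix(msa, "TN93-MCL", "pairwise"))
  mine <- tree_log_likelihood(tr, msa, model)
  m <- msa_matrix(msa)
  dat <- phangorn::phyDat(m)
  fit <- phangorn::pml(tr, dat, model = "TrN", bf = model$pi,
                       Q = c(1, model$k1, 1, 1, model$k2, 1))
  expect_equal(mine, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("ML search recovers simulated topologies and is locally optimal", {
  recovered <- 0L
  lnls <- c()
  for (s in 1:5) {
    cfg <- sim_config(scale = 0.12, seed = 100 + s, n_taxa = 6L,
                      n_outgroups = 1L)
    sim <- simulate_dataset(cfg)
    fit <- optimize_ml_tree(sim$msa, model = "TN93")
    rf <- ape::dist.topo(ape::unroot(fit$tree),
                         ape::unroot(sim$tree$subs_phylo))
    if (rf == 0) recovered <- recovered + 1L
    ## re-optimizing from the returned tree does not change the topology
    pat <- mitochron:::compress_patterns(msa_complete_deletion(sim$msa))
    again <- mitochron:::optimize_branch_lengths(fit$tree, pat, fit$model)
    expect_gte(again$lnl, fit$lnl - 1e-6)
    lnls <- c(lnls, fit$lnl)
  }
  expect_gte(recovered, 4L)
})

test_that("bootstrap supports behave at the degenerate and strong-signal ends", {
  ## no variable sites: every replicate returns the same tree, support 100
  rows <- setNames(rep(strrep("ACGT", 25L), 4L), c("a", "b", "c", "d"))
  m0 <- msa_from_rows(rows)
  b0 <- bootstrap_support(m0, model = "p", n_replicates = 50L, seed = 1L)
  expect_true(all(attr(b0, "supports") == 100))
  ## 50 diagnostic columns for a 4-taxon split: support > 95
  set.seed(64)
  core <- random_dna(450L)
  diag_ab <- strrep("A", 50L); diag_cd <- strrep("G", 50L)
  m1 <- msa_from_rows(c(a = paste0(core, diag_ab), b = paste0(core, diag_ab),
                        c = paste0(core, diag_cd), d = paste0(core, diag_cd)))
  b1 <- bootstrap_support(m1, model = "p", n_replicates = 1000L, seed = 2L)
  expect_gt(attr(b1, "supports")[[1L]], 95)
  expect_true(all(attr(b1, "supports") >= 0 & attr(b1, "supports") <= 100))
})

test_that("bootstrap replicates are reproducible under a fixed seed", {
  cfg <- sim_config(scale = 0.1, seed = 65)
  sim <- simulate_dataset(cfg)
  b1 <- bootstrap_support(sim$msa, n_replicates = 100L, seed = 9L)
  b2 <- bootstrap_support(sim$msa, n_replicates = 100L, seed = 9L)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))
})

test_that("BIC selects sensible models and is taxon-order invariant", {
  ## data simulated under JC: JC within 2 BIC units of the winner
  cfg_jc <- sim_config(scale = 0.12, seed = 66, n_taxa = 5L, n_outgroups = 1L,
                       pi = c(A = .25, C = .25, G = .25, T = .25),
                       k1 = 1, k2 = 1)
  sim_jc <- simulate_dataset(cfg_jc)
  sel_jc <- select_model_bic(sim_jc$msa)
  bics <- vapply(sel_jc$fits, `[[`, 0, "bic")
  expect_lte(bics[["JC"]] - min(bics), 2)
  ## strong transition bias: K2P or TN93 beat JC by > 10
  cfg_ts <- sim_config(scale = 0.12, seed = 67, n_taxa = 5L, n_outgroups = 1L,
                       k1 = 8, k2 = 8)
  sim_ts <- simulate_dataset(cfg_ts)
  sel_ts <- select_model_bic(sim_ts$msa)
  bics_ts <- vapply(sel_ts$fits, `[[`, 0, "bic")
  expect_gt(bics_ts[["JC"]] - min(bics_ts[c("K2P", "TN93")]), 10)
  ## ordering invariant to taxon order
  perm <- sample(names(sim_ts$msa$rows))
  sel_perm <- select_model_bic(msa_from_rows(sim_ts$msa$rows[perm]))
  expect_equal(sel_perm$best, sel_ts$best)
  expect_equal(vapply(sel_perm$fits, `[[`, 0, "bic"), bics_ts,
               tolerance = 1e-3)
})
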