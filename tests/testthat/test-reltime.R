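test_that("outgroup rooting places the root on the separating branch", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1,O:3);")
  rooted <- root_with_outgroup(tr, "O")
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("A", "B", "C")))
  ## rerooting then unrooting preserves the unrooted topology
  expect_equal(ape::dist.topo(ape::unroot(rooted), ape::unroot(tr)),
               structure(0), ignore_attr = TRUE)
  ## non-separable outgroups are refused
  tr2 <- ape::read.tree(text = "((A:1,O1:1):1,(B:1,O2:1):1,C:1);")
  expect_error(root_with_outgroup(tr2, c("O1", "O2")), "not separable")
  expect_error(root_with_outgroup(tr, "Z"), "not in tree")
})

test_that("clock-like trees get unit rates and heights equal to node depths", {
  cfg <- sim_config(scale = 0.1, seed = 71)
  sim_t <- simulate_timetree(cfg)
  tt <- reltime_relative(sim_t$time_phylo, sim_t$outgroups)
  expect_true(all(abs(tt$rate - 1) < 1e-9))
  d <- ape::node.depth.edgelength(sim_t$time_phylo)
  expect_equal(tt$rel_height, max(d) - d, tolerance = 1e-9)
})

test_that("a two-lineage rate contrast is partitioned geometrically", {
  ## sisters with tip depths 2 and 1 below their common node: rates 2:1
  ## normalized to geometric mean 1, shared node height sqrt(2 * 1)
  tr <- ape::read.tree(text = "((A:2,B:1):1,O:5);")
  tt <- reltime_relative(tr, "O")
  node_ab <- ape::getMRCA(tr, c("A", "B"))
  eA <- which(tt$tree$edge[, 2L] == match("A", tt$tree$tip.label))
  eB <- which(tt$tree$edge[, 2L] == match("B", tt$tree$tip.label))
  expect_equal(tt$rate[eA] / tt$rate[eB], 2)
  ## local factors multiply to one: the sister product equals the squared
  ## parent-lineage rate
  e_ab <- which(tt$tree$edge[, 2L] == node_ab)
  expect_equal(tt$rate[eA] * tt$rate[eB], tt$rate[e_ab]^2, tolerance = 1e-12)
  ## both children agree on the shared node height after rate division
  expect_equal(2 / tt$rate[eA], 1 / tt$rate[eB])
  expect_equal(tt$rel_height[node_ab], 2 / tt$rate[eA], tolerance = 1e-12)
  ## the outgroup contrast scales ingroup rates only uniformly: calibrated
  ## ages are invariant to the outgroup branch length
  tr2 <- ape::read.tree(text = "((A:2,B:1):1,O:50);")
  cal <- calibration_point("A", "B", 1)
  a1 <- calibrate_timetree(reltime_relative(tr, "O"), cal)
  a2 <- calibrate_timetree(reltime_relative(tr2, "O"), cal)
  expect_equal(a1$age[node_ab], a2$age[node_ab], tolerance = 1e-12)
})

test_that("calibration scales ages linearly and respects its interval", {
  cfg <- sim_config(scale = 0.1, seed = 72)
  sim_t <- simulate_timetree(cfg)
  tt <- reltime_relative(sim_t$time_phylo, sim_t$outgroups)
  cal1 <- calibration_point("IG01", "IG02", 6.57, c(6.45, 6.69))
  cal2 <- calibration_point("IG01", "IG02", 13.14, c(12.9, 13.38))
  a1 <- calibrate_timetree(tt, cal1)
  a2 <- calibrate_timetree(tt, cal2)
  ok <- !is.na(a1$age)
  expect_equal(a2$age[ok], 2 * a1$age[ok], tolerance = 1e-12)
  ## CI endpoints bracket the point estimates
  expect_true(all(a1$ci[ok, 1L] <= a1$age[ok] + 1e-12))
  expect_true(all(a1$ci[ok, 2L] >= a1$age[ok] - 1e-12))
  expect_error(calibration_point("A", "B", 5, c(6, 7)), "interval")
})

test_that("ages are parent-monotone under lineage-rate variation", {
  for (s in 1:5) {
    cfg <- sim_config(scale = 0.1, seed = 80 + s, rate_model = "lognormal",
                      rate_sigma = 0.4)
    sim_t <- simulate_timetree(cfg)
    tt <- reltime_relative(sim_t$subs_phylo, sim_t$outgroups)
    e <- tt$tree$edge
    expect_true(all(tt$rel_height[e[, 1L]] > tt$rel_height[e[, 2L]] - 1e-12))
  }
})

test_that("relative node ages track the truth under lognormal rates", {
  ## pooled Spearman correlation between true and inferred relative ingroup
  ## node ages across replicate trees
  pooled_t <- c(); pooled_e <- c()
  for (s in 1:40) {
    cfg <- sim_config(scale = 0.1, seed = 200 + s, rate_model = "lognormal",
                      rate_sigma = 0.4)
    sim_t <- simulate_timetree(cfg)
    tt <- reltime_relative(sim_t$subs_phylo, sim_t$outgroups)
    d <- ape::node.depth.edgelength(sim_t$time_phylo)
    h <- max(d) - d
    ntip <- length(sim_t$time_phylo$tip.label)
    ig <- match(sim_t$ingroup, sim_t$time_phylo$tip.label)
    igroot <- ape::getMRCA(sim_t$time_phylo, sim_t$ingroup)
    sets <- mitochron:::tree_bipartitions_all(sim_t$time_phylo)
    nodes <- seq.int(ntip + 2L, ntip + sim_t$time_phylo$Nnode)
    keep <- nodes[vapply(nodes, function(nd) all(sets[[nd - 1L]] %in% ig),
                         TRUE)]
    pooled_t <- c(pooled_t, h[keep] / h[igroot])
    pooled_e <- c(pooled_e, tt$rel_height[keep] / tt$rel_height[igroot])
  }
  expect_gte(cor(pooled_t, pooled_e, method = "spearman"), 0.95)
})

test_that("bootstrap age intervals contain the point estimate and shrink", {
  cal <- calibration_point("IG01", "IG02", 6.57, c(6.45, 6.69))
  widths <- c()
  for (scale in c(0.05, 0.2)) {
    cfg <- sim_config(scale = scale, seed = 73, n_taxa = 5L, n_outgroups = 1L)
    sim <- simulate_dataset(cfg)
    msa <- msa_complete_deletion(sim$msa)
    model <- mitochron:::estimate_model(msa, "TN93")
    tr <- root_with_outgroup(
      nj_tree(build_distance_matrix(msa, "TN93", "pairwise")), "OG01")
    tt <- timetree_ci(msa, tr, cal, model, outgroups = "OG01",
                      n_boot = 100L, seed = 5L)
    ok <- !is.na(tt$age) & tt$age > 0
    expect_true(all(tt$ci[ok, 1L] <= tt$age[ok] + 1e-9))
    expect_true(all(tt$ci[ok, 2L] >= tt$age[ok] - 1e-9))
    ig_root <- ape::getMRCA(tt$tree, paste0("IG0", 1:4))
    widths <- c(widths, tt$ci[ig_root, 2L] - tt$ci[ig_root, 1L])
  }
  ## quadrupling the sequence length narrows the interval
  expect_lt(widths[2L], widths[1L])
})

test_that("true node ages fall inside their bootstrap intervals", {
  cal_tips <- c("IG01", "IG02")
  inside <- 0L
  for (s in 1:6) {
    cfg <- sim_config(scale = 0.1, seed = 300 + s, n_taxa = 5L,
                      n_outgroups = 1L)
    sim <- simulate_dataset(cfg)
    msa <- msa_complete_deletion(sim$msa)
    model <- mitochron:::estimate_model(msa, "TN93")
    tr <- root_with_outgroup(
      nj_tree(build_distance_matrix(msa, "TN93", "pairwise")), "OG01")
    d <- ape::node.depth.edgelength(sim$tree$time_phylo)
    h <- max(d) - d
    cal_node_true <- ape::getMRCA(sim$tree$time_phylo, cal_tips)
    cal <- calibration_point(cal_tips[1L], cal_tips[2L],
                             h[cal_node_true] * 10)   # truth in Ma-like units
    tt <- tryCatch(timetree_ci(msa, tr, cal, model, outgroups = "OG01",
                               n_boot = 100L, seed = s), error = function(e) NULL)
    if (is.null(tt)) next
    ig_root_est <- ape::getMRCA(tt$tree, paste0("IG0", 1:4))
    ig_root_true <- ape::getMRCA(sim$tree$time_phylo, paste0("IG0", 1:4))
    truth <- h[ig_root_true] * 10
    if (tt$ci[ig_root_est, 1L] <= truth && truth <= tt$ci[ig_root_est, 2L])
      inside <- inside + 1L
  }
  expect_gte(inside, 4L)
})

test_that("node-age reports cover ingroup nodes and honor rounding", {
  cfg <- sim_config(scale = 0.1, seed = 74)
  sim_t <- simulate_timetree(cfg)
  tt <- calibrate_timetree(reltime_relative(sim_t$time_phylo, sim_t$outgroups),
                           calibration_point("IG01", "OG01", 6.57,
                                             c(6.45, 6.69)))
  na <- node_ages(tt)
  expect_true(all(na$age == round(na$age, 2L)))
  expect_true(all(na$n_tips >= 2L))
  expect_equal(mrca_age(tt, c("IG01", "OG01")), 6.57, tolerance = 1e-9)
})
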