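#' Root a tree with an outgroup
#'
#' Places the root on the branch separating the outgroup taxa from the
#' ingroup, which must be separable on the unrooted tree (a single leaf
#' always is).
#'
#' @param tree An unrooted `phylo`.
#' @param outgroups Character vector of outgroup tip labels.
#' @return A rooted `phylo` with the ingroup monophyletic.
#' @export
root_with_outgroup <- function(tree, outgroups) {
  miss <- setdiff(outgroups, tree$tip.label)
  if (length(miss)) stop("outgroup tip(s) not in tree: ",
                         paste(miss, collapse = ", "))
  if (length(outgroups) < length(tree$tip.label) &&
      !ape::is.monophyletic(tree, outgroups))
    stop("outgroups are not separable from the ingroup on this tree: ",
         paste(outgroups, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroups, resolve.root = TRUE)
  rooted
}

#' Relative-rate (RelTime-style) node heights
#'
#' Assigns every lineage a relative substitution rate and every internal node
#' a relative height from the branch lengths of a rooted tree, without
#' assuming a global clock. In a postorder pass, each node's mean tip depth
#' is computed; the two child lineages of a node receive relative rates
#' proportional to their mean tip depths, normalized by their geometric mean
#' so sister rates multiply to one, and the factors propagate root-ward along
#' each path. Relative node heights are then branch durations
#' (length / lineage rate) accumulated tip-ward; where the two children's
#' height estimates disagree their mean is taken (their maximum when needed
#' to keep every parent strictly older than its children). A perfectly
#' clock-like tree gets all rates equal to 1 and heights equal to node
#' depths.
#'
#' Outgroup lineages are excluded from rate estimation: rates and heights are
#' computed on the ingroup-plus-calibration structure, and pure-outgroup
#' internal nodes inherit rate 1 (no ages are reported for them downstream).
#' Lineages subtending a single tip, and zero-length sister pairs, default to
#' rate 1.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param outgroups Character vector of outgroup tips (possibly empty).
#' @return A `time_tree`: the tree plus `rel_height` (per node, tips = 0),
#'   `rate` (per edge), `age` (absolute ages, `NA` until
#'   [calibrate_timetree()]), and bookkeeping fields.
#' @export
reltime_relative <- function(tree, outgroups = character(0)) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  children <- split(seq_len(nrow(po$edge)), po$edge[, 1L])

  ## postorder: mean tip depth (branch-length units) and tip count below;
  ## child means are final before their own parent edge is processed
  sum_depth <- numeric(nn)
  mean_depth <- numeric(nn)
  n_tips_below <- integer(nn)
  n_tips_below[seq_len(ntip)] <- 1L
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; chi <- po$edge[k, 2L]
    w <- n_tips_below[chi]
    if (chi > ntip) mean_depth[chi] <- sum_depth[chi] / w
    sum_depth[par] <- sum_depth[par] +
      w * (mean_depth[chi] + po$edge.length[k])
    n_tips_below[par] <- n_tips_below[par] + w
  }
  root_id <- ntip + 1L
  mean_depth[root_id] <- sum_depth[root_id] / n_tips_below[root_id]

  ## preorder: local geometric-mean factors propagated into lineage rates
  edge_of <- integer(nn)                   # edge leading to each node
  edge_of[po$edge[, 2L]] <- seq_len(nrow(po$edge))
  rate <- rep(1, nrow(po$edge))
  root <- ntip + 1L
  pre <- rev(seq_len(nrow(po$edge)))       # reverse postorder = preorder
  for (k in pre) {
    par <- po$edge[k, 1L]
    kids <- children[[as.character(par)]]
    if (is.null(kids)) next
    D <- po$edge.length[kids] + mean_depth[po$edge[, 2L][kids]]
    parent_rate <- if (par == root) 1 else rate[edge_of[par]]
    if (all(D > 0) && length(kids) >= 2L) {
      g <- exp(mean(log(D)))
      rate[kids] <- parent_rate * D / g
    } else {
      rate[kids] <- parent_rate           # zero-length pair: rates equal
    }
  }

  ## tip-ward accumulation of relative heights
  rel <- numeric(nn)
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; chi <- po$edge[k, 2L]
    est <- rel[chi] + po$edge.length[k] / rate[k]
    if (rel[par] == 0) rel[par] <- est
    else {
      prev <- rel[par]
      rel[par] <- mean(c(prev, est))
      kidh <- max(rel[po$edge[po$edge[, 1L] == par, 2L]])
      if (rel[par] <= kidh) rel[par] <- max(prev, est)
    }
  }
  rel[seq_len(ntip)] <- 0

  structure(list(tree = po, rel_height = rel, rate = rate,
                 age = rep(NA_real_, nn), ci = NULL,
                 outgroups = outgroups, calibration = NULL),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat(sprintf("<time_tree> %d tips, %d internal nodes%s\n", ntip,
              x$tree$Nnode,
              if (all(is.na(x$age))) " (relative heights only)"
              else " (calibrated, Ma)"))
  invisible(x)
}

#' Calibration point
#'
#' A node (the MRCA of two named taxa) of known age, with an uncertainty
#' interval, used to convert relative heights to absolute ages.
#'
#' @param taxon_a,taxon_b Tip labels whose MRCA is calibrated.
#' @param age Point age (Ma).
#' @param interval Length-2 `(min, max)` interval (Ma).
#' @export
calibration_point <- function(taxon_a, taxon_b, age,
                              interval = c(age, age)) {
  interval <- sort(as.numeric(interval))
  if (!(interval[1L] <= age && age <= interval[2L]))
    stop("calibration age outside its interval")
  structure(list(taxon_a = taxon_a, taxon_b = taxon_b, age = age,
                 interval = interval), class = "calibration_point")
}

#' Convert relative heights to absolute ages
#'
#' Scales every relative node height by `cal$age / rel_height(MRCA)`. When
#' the time tree carries bootstrap sampling intervals, the calibration
#' interval is compounded with them; otherwise CI endpoints reflect the
#' calibration interval alone.
#'
#' @param tt A `time_tree` from [reltime_relative()].
#' @param cal A [calibration_point()].
#' @return The `time_tree` with `age` (and `ci`, a 2-column matrix) filled.
#' @export
calibrate_timetree <- function(tt, cal) {
  node <- ape::getMRCA(tt$tree, c(cal$taxon_a, cal$taxon_b))
  h <- tt$rel_height[node]
  if (!isTRUE(h > 0)) stop("calibration node has no positive relative height")
  factor <- cal$age / h
  tt$age <- tt$rel_height * factor
  lo_f <- cal$interval[1L] / cal$age
  hi_f <- cal$interval[2L] / cal$age
  if (is.null(tt$ci)) {
    tt$ci <- cbind(lower = tt$age * lo_f, upper = tt$age * hi_f)
  } else {
    tt$ci <- cbind(lower = tt$ci[, 1L] * factor * lo_f,
                   upper = tt$ci[, 2L] * factor * hi_f)
  }
  tt$calibration <- cal
  tt$calibration_node <- node
  tt
}

#' Node ages of a calibrated time tree
#'
#' @param tt A calibrated `time_tree`.
#' @param digits Rounding applied to the report (ages print at 2 decimals by
#'   convention); use `NULL` for full precision.
#' @return Data frame of internal nodes: `node`, `age`, `ci_lower`,
#'   `ci_upper`, and the two earliest-diverging descendant tips as a
#'   readable `clade` hint. Pure-outgroup nodes are omitted.
#' @export
node_ages <- function(tt, digits = 2L) {
  if (all(is.na(tt$age))) stop("time tree is not calibrated")
  ntip <- length(tt$tree$tip.label)
  bp <- tree_bipartitions(tt$tree, tt$tree$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + tt$tree$Nnode)
  og <- match(tt$outgroups, tt$tree$tip.label)
  keep <- vapply(nodes, function(nd) {
    tips <- bp$below[[nd]]
    !all(tips %in% og)                 # drop pure-outgroup clades
  }, TRUE)
  nodes <- nodes[keep]
  rnd <- function(x) if (is.null(digits)) x else round(x, digits)
  data.frame(
    node = nodes,
    clade = vapply(nodes, function(nd)
      paste(utils::head(tt$tree$tip.label[sort(bp$below[[nd]])], 2L),
            collapse = " + "), ""),
    n_tips = vapply(nodes, function(nd) length(bp$below[[nd]]), 0L),
    age = rnd(tt$age[nodes]),
    ci_lower = rnd(tt$ci[nodes, 1L]),
    ci_upper = rnd(tt$ci[nodes, 2L]),
    stringsAsFactors = FALSE)
}

#' Age of the MRCA of a set of taxa
#' @param tt A calibrated `time_tree`.
#' @param taxa Tip labels.
#' @export
mrca_age <- function(tt, taxa) {
  node <- if (length(taxa) == 1L) match(taxa, tt$tree$tip.label)
          else ape::getMRCA(tt$tree, taxa)
  tt$age[node]
}

#' Bootstrap confidence intervals for node ages
#'
#' Site-resamples the alignment, re-optimizes branch lengths on the fixed
#' topology per replicate, reruns the relative-rate dating and calibration,
#' and reports percentile 2.5/97.5 intervals per node (compounded with the
#' calibration interval by [calibrate_timetree()]).
#'
#' @param msa The alignment the tree was estimated from.
#' @param tree The rooted reference `phylo`.
#' @param cal A [calibration_point()].
#' @param model A [subst_model()] for branch re-optimization.
#' @param outgroups Outgroup tips passed to [reltime_relative()].
#' @param n_boot Number of replicates (>= 100).
#' @param seed Integer seed.
#' @param max_failures Maximal tolerated fraction of failed replicates.
#' @return A calibrated `time_tree` whose `ci` comes from the bootstrap.
#' @export
timetree_ci <- function(msa, tree, cal, model, outgroups = character(0),
                        n_boot = 200L, seed = 1L, max_failures = 0.05) {
  stopifnot(n_boot >= 100L)
  work <- msa_complete_deletion(msa)
  pat <- compress_patterns(work)
  ntip <- length(tree$tip.label)
  ages <- matrix(NA_real_, n_boot, ntip + tree$Nnode)
  for (b in seq_len(n_boot)) {
    set.seed(seed + b)
    w <- as.numeric(stats::rmultinom(1L, pat$n_sites,
                                     pat$weights / pat$n_sites))
    pat_b <- pat; pat_b$weights <- w
    res <- tryCatch({
      fit <- optimize_branch_lengths(tree, pat_b, model, max_sweeps = 3L,
                                     tol = 1e-6)
      tt <- reltime_relative(fit$tree, outgroups)
      tt <- calibrate_timetree(tt, cal)
      ## node numbering of fit$tree follows `tree` (same topology/labels)
      tt$age
    }, error = function(e) NULL)
    if (!is.null(res)) ages[b, ] <- res
  }
  fail <- mean(is.na(ages[, ntip + 1L]))
  if (fail > max_failures)
    stop("bootstrap replicate failure rate ", round(100 * fail, 1), "%")
  tt0 <- calibrate_timetree(reltime_relative(tree, outgroups), cal)
  lo <- apply(ages, 2L, stats::quantile, 0.025, na.rm = TRUE)
  hi <- apply(ages, 2L, stats::quantile, 0.975, na.rm = TRUE)
  ## compound the percentile interval with the calibration interval, and keep
  ## the point estimate inside its own CI
  tt0$ci <- cbind(lower = pmin(lo * cal$interval[1L] / cal$age, tt0$age),
                  upper = pmax(hi * cal$interval[2L] / cal$age, tt0$age))
  tt0
}
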