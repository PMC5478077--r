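## canonical bipartition key: the side not containing taxon 1, as sorted
## original taxon indices
canonical_split <- function(idx_set, n_taxa) {
  s <- sort(idx_set)
  if (1L %in% s) s <- setdiff(seq_len(n_taxa), s)
  paste(s, collapse = ",")
}

## all non-trivial bipartitions of an unrooted phylo, keyed canonically,
## with the internal node each corresponds to
tree_bipartitions <- function(tree, taxa = tree$tip.label) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- match(tree$tip.label[i], taxa)
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; chi <- po$edge[k, 2L]
    below[[par]] <- c(below[[par]], below[[chi]])
  }
  nodes <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), ntip + 1L)
  keys <- vapply(nodes, function(nd) {
    s <- below[[nd]]
    if (length(s) <= 1L || length(s) >= length(taxa) - 1L) return(NA_character_)
    canonical_split(s, length(taxa))
  }, "")
  ok <- !is.na(keys)
  list(keys = keys[ok], nodes = nodes[ok], below = below)
}

## NJ joins expressed as bipartitions, without building a phylo (fast path
## for bootstrap replicates)
nj_splits <- function(d) {
  m0 <- nrow(d)
  sets <- as.list(seq_len(m0))
  keys <- character(0)
  while (nrow(d) > 3L) {
    mm <- nrow(d)
    r <- rowSums(d)
    qm <- (mm - 2) * d - outer(r, r, `+`)
    diag(qm) <- Inf
    best <- which(qm == min(qm), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[[1L]]; j <- best[[2L]]
    u <- c(sets[[i]], sets[[j]])
    if (length(u) <= m0 - 2L) keys <- c(keys, canonical_split(u, m0))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(mm), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sets <- c(sets[keep], list(u))
  }
  keys
}

#' Bootstrap clade support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' neighbor-joining tree per replicate, and reports for each internal edge of
#' the original tree the percentage of replicates containing the same
#' bipartition. Replicate resampling is driven deterministically by `seed`.
#'
#' For speed the replicate distances use the closed-form estimator of the
#' requested family (`"TN93-MCL"` replicates use the TN93 closed form with
#' alignment-wide pooled frequencies -- topologically equivalent at the
#' divergences involved); the reference tree itself is built with the full
#' model.
#'
#' @param msa An `msa` object.
#' @param model Distance model (see [build_distance_matrix()]).
#' @param policy Deletion policy.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param tree Optional reference tree; defaults to the NJ tree of the full
#'   data under `model`.
#' @return The reference `phylo` with `node.label` set to support
#'   percentages (`""` at the root), plus attribute `"supports"` (named
#'   vector keyed by bipartition).
#' @export
bootstrap_support <- function(msa, model = "TN93-MCL",
                              policy = c("complete", "pairwise"),
                              n_replicates = 1000L, seed = 1L, tree = NULL) {
  policy <- match.arg(policy)
  stopifnot(n_replicates >= 1L)
  work <- if (policy == "complete") msa_complete_deletion(msa) else msa
  taxa <- names(work$rows)
  m <- length(taxa)
  if (is.null(tree))
    tree <- nj_tree(build_distance_matrix(work, model = model,
                                          policy = "pairwise"))

  ## site patterns and per-pair category codes (1 same / 2 purine ts /
  ## 3 pyrimidine ts / 4 tv / 0 not comparable)
  mat <- msa_matrix(work)
  key <- apply(mat, 2L, paste, collapse = "\r")
  uk <- unique(key)
  w0 <- as.numeric(table(factor(key, uk)))
  cols <- mat[, match(uk, key), drop = FALSE]
  base <- c("A", "C", "G", "T")
  code <- matrix(match(cols, base), nrow = m)   # NA for gap/ambiguous
  pur <- function(x) x == 1L | x == 3L          # A, G
  npair <- m * (m - 1L) / 2L
  npat <- length(uk)
  cat_idx <- matrix(0L, npair, npat)
  pair_i <- integer(npair); pair_j <- integer(npair)
  idx <- 0L
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    idx <- idx + 1L
    pair_i[idx] <- i; pair_j[idx] <- j
    a <- code[i, ]; b <- code[j, ]
    ok <- !is.na(a) & !is.na(b)
    cat <- integer(npat)
    cat[ok] <- 1L
    dif <- ok & a != b
    cat[dif & pur(a) & pur(b)] <- 2L
    cat[dif & !pur(a) & !pur(b)] <- 3L
    cat[dif & (pur(a) != pur(b))] <- 4L
    cat_idx[idx, ] <- cat
  }
  M <- lapply(1:4, function(k) (cat_idx == k) * 1)  # npair x npat indicators

  pooled_pi <- NULL
  if (model %in% c("TN93", "TN93-MCL")) {
    tb <- table(factor(mat, base))
    pooled_pi <- stats::setNames(as.numeric(tb / sum(tb)), base)
  }
  dist_from_counts <- function(nsame, np1, np2, nq) {
    n <- nsame + np1 + np2 + nq
    P <- (np1 + np2) / n; Q <- nq / n
    if (model == "p") return(P + Q)
    if (model == "K2P") {
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      return(ifelse(w1 > 0 & w2 > 0, -0.5 * log(w1 * sqrt(w2)), Inf))
    }
    pi <- pooled_pi
    pR <- pi[["A"]] + pi[["G"]]; pY <- pi[["C"]] + pi[["T"]]
    k1 <- 2 * pi[["A"]] * pi[["G"]] / pR
    k2 <- 2 * pi[["T"]] * pi[["C"]] / pY
    k3 <- 2 * (pR * pY - pi[["A"]] * pi[["G"]] * pY / pR -
                 pi[["T"]] * pi[["C"]] * pR / pY)
    w1 <- 1 - (np1 / n) / k1 - Q / (2 * pR)
    w2 <- 1 - (np2 / n) / k2 - Q / (2 * pY)
    w3 <- 1 - Q / (2 * pR * pY)
    ifelse(w1 > 0 & w2 > 0 & w3 > 0,
           -k1 * log(w1) - k2 * log(w2) - k3 * log(w3), Inf)
  }

  ref <- tree_bipartitions(tree, taxa)
  hits <- stats::setNames(numeric(length(ref$keys)), ref$keys)
  n_cols <- sum(w0)
  for (rep_i in seq_len(n_replicates)) {
    set.seed(seed + rep_i)                 # replicate seeds derived from root
    w <- as.numeric(stats::rmultinom(1L, n_cols, w0 / n_cols))
    cnt <- vapply(M, function(Mk) as.numeric(Mk %*% w), numeric(npair))
    dvec <- dist_from_counts(cnt[, 1L], cnt[, 2L], cnt[, 3L], cnt[, 4L])
    if (any(!is.finite(dvec))) next        # saturated replicate: no votes
    d <- matrix(0, m, m)
    d[cbind(pair_i, pair_j)] <- dvec
    d <- d + t(d)
    ks <- nj_splits(d)
    found <- ref$keys %in% ks
    hits[found] <- hits[found] + 1
  }
  supports <- 100 * hits / n_replicates
  ntip <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  lab[ref$nodes - ntip] <- sprintf("%g", round(supports, 1))
  tree$node.label <- lab
  attr(tree, "supports") <- supports
  tree
}
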