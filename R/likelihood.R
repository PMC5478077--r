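#' Substitution model specification
#'
#' Nested family used throughout likelihood computations: Jukes-Cantor
#' (`"JC"`, equal frequencies, one rate), Kimura 2-parameter (`"K2P"`, equal
#' frequencies, transition/transversion ratio `kappa`), and Tamura-Nei
#' (`"TN93"`, empirical frequencies, separate purine and pyrimidine
#' transition ratios `k1`, `k2`). The rate matrix is scaled to one expected
#' substitution per site so branch lengths are substitutions/site.
#'
#' @param name Model name.
#' @param pi Stationary base frequencies (named A/C/G/T).
#' @param k1,k2 Transition/transversion rate ratios (purine, pyrimidine).
#' @return A `subst_model` object.
#' @export
subst_model <- function(name = c("TN93", "K2P", "JC"),
                        pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        k1 = 1, k2 = 1) {
  name <- match.arg(name)
  if (name == "JC") { pi <- c(A = .25, C = .25, G = .25, T = .25); k1 <- k2 <- 1 }
  if (name == "K2P") { pi <- c(A = .25, C = .25, G = .25, T = .25); k2 <- k1 }
  pi <- pi[c("A", "C", "G", "T")] / sum(pi)
  if (any(pi <= 0) || k1 <= 0 || k2 <= 0) stop("invalid model parameters")
  structure(list(name = name, pi = pi, k1 = k1, k2 = k2,
                 eigen = rate_matrix_eigen(tn93_rate_matrix(pi, k1, k2))),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s: pi=(%s), k1=%.4g, k2=%.4g\n", x$name,
              paste(sprintf("%.3f", x$pi), collapse = ", "), x$k1, x$k2))
  invisible(x)
}

#' Free parameter count of a substitution model (frequencies + rate ratios)
#' @param model A `subst_model`.
#' @export
n_model_params <- function(model) {
  switch(model$name, JC = 0L, K2P = 1L, TN93 = 5L)
}

## compress an alignment into site patterns; non-ACGT characters become
## missing data (likelihood 1 over all states)
compress_patterns <- function(msa) {
  m <- msa_matrix(msa)
  key <- apply(m, 2L, paste, collapse = "\r")
  uk <- unique(key)
  w <- as.numeric(table(factor(key, uk)))
  cols <- m[, match(uk, key), drop = FALSE]
  base <- c("A", "C", "G", "T")
  tipL <- lapply(seq_len(nrow(cols)), function(i) {
    L <- matrix(1, 4L, length(uk))
    known <- cols[i, ] %in% base
    L[, known] <- 0
    L[cbind(match(cols[i, known], base), which(known))] <- 1
    L
  })
  names(tipL) <- rownames(m)
  list(tipL = tipL, weights = w, n_sites = ncol(m), n_patterns = length(uk))
}

#' Log-likelihood of a tree (Felsenstein pruning)
#'
#' Computes `sum_sites log P(site | tree, model)` by postorder pruning with
#' site-pattern compression and per-node numerical rescaling. The model is
#' time-reversible, so the value does not depend on where the (un)rooted tree
#' is rooted.
#'
#' @param tree A `phylo` with branch lengths (substitutions/site).
#' @param msa An `msa` whose row names match the tip labels, or a
#'   pre-compressed pattern object from the internal compressor.
#' @param model A [subst_model()].
#' @return The log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(tree, msa, model) {
  pat <- if (inherits(msa, "msa")) compress_patterns(msa) else msa
  if (!all(tree$tip.label %in% names(pat$tipL)))
    stop("tip labels missing from alignment: ",
         paste(setdiff(tree$tip.label, names(pat$tipL)), collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  npat <- pat$n_patterns
  L <- vector("list", ntip + nnode)
  SC <- vector("list", ntip + nnode)      # accumulated log scalers per pattern
  for (i in seq_len(ntip)) {
    L[[i]] <- pat$tipL[[tree$tip.label[i]]]
    SC[[i]] <- numeric(npat)
  }
  eg <- model$eigen
  edges <- po$edge
  elen <- po$edge.length
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; chi <- edges[k, 2L]
    P <- transition_probs(eg, elen[k])
    msg <- P %*% L[[chi]]
    if (is.null(L[[par]])) {
      L[[par]] <- msg
      SC[[par]] <- SC[[chi]]
    } else {
      L[[par]] <- L[[par]] * msg
      SC[[par]] <- SC[[par]] + SC[[chi]]
    }
    if (max(L[[par]]) < 1e-80) {          # rescale lazily
      s <- apply(L[[par]], 2L, max)
      s[s == 0] <- 1
      L[[par]] <- sweep(L[[par]], 2L, s, "/")
      SC[[par]] <- SC[[par]] + log(s)
    }
  }
  root <- ntip + 1L
  site_l <- as.numeric(model$pi %*% L[[root]])
  sum(pat$weights * (log(site_l) + SC[[root]]))
}

## Brent optimization of every branch length, sweeping until convergence
optimize_branch_lengths <- function(tree, pat, model, max_sweeps = 20L,
                                    tol = 1e-8, max_len = 10) {
  lnl <- tree_log_likelihood(tree, pat, model)
  for (s in seq_len(max_sweeps)) {
    prev <- lnl
    for (k in seq_along(tree$edge.length)) {
      f <- function(x) {
        tree$edge.length[k] <- x
        tree_log_likelihood(tree, pat, model)
      }
      opt <- stats::optimize(f, c(0, max_len), maximum = TRUE, tol = tol)
      if (opt$objective > lnl) {
        tree$edge.length[k] <- opt$maximum
        lnl <- opt$objective
      }
    }
    if (lnl - prev < 1e-6) break
  }
  list(tree = tree, lnl = lnl, sweeps = s)
}

## the two NNI exchanges around an internal edge; tree assumed binary
## (root may be trifurcating -- its edges are not eligible)
nni_neighbors <- function(tree, edge_idx) {
  ntip <- length(tree$tip.label)
  par <- tree$edge[edge_idx, 1L]; chi <- tree$edge[edge_idx, 2L]
  if (chi <= ntip) return(list())
  kids_chi <- which(tree$edge[, 1L] == chi)
  sibs <- setdiff(which(tree$edge[, 1L] == par), edge_idx)
  if (length(kids_chi) != 2L || !length(sibs)) return(list())
  sib <- sibs[1L]
  lapply(kids_chi, function(kc) {
    t2 <- tree
    t2$edge[kc, 2L] <- tree$edge[sib, 2L]   # swap subtrees across the edge
    t2$edge[sib, 2L] <- tree$edge[kc, 2L]
    t2
  })
}

#' Maximum-likelihood tree search
#'
#' Hill-climbing ML inference in the spirit of distance-started heuristic
#' searches: starting trees come from neighbor-joining and BioNJ on composite
#' TN93 distances, branch lengths are optimized per-branch (Brent, full-tree
#' sweeps), nearest-neighbor interchanges are accepted when they improve the
#' log-likelihood by more than `1e-6`, and the better of the two starts is
#' returned. Model parameters (frequencies, rate ratios) are estimated from
#' the data unless a fitted [subst_model()] is supplied.
#'
#' @param msa An `msa` object.
#' @param model A `subst_model`, or a model name to be estimated
#'   (`"TN93"`, `"K2P"`, `"JC"`).
#' @param policy Deletion policy for the underlying distance matrices and
#'   likelihood columns.
#' @param start Starting trees to try.
#' @param max_rounds Maximum NNI improvement rounds.
#' @return List with `tree` (ML `phylo`), `lnl`, `model`, and `fit`
#'   (a model-fit record with the BIC).
#' @export
optimize_ml_tree <- function(msa, model = "TN93",
                             policy = c("complete", "pairwise"),
                             start = c("NJ", "BioNJ"), max_rounds = 10L) {
  policy <- match.arg(policy)
  if (length(msa$rows) < 4L) stop("need at least 4 taxa")
  work <- if (policy == "complete") msa_complete_deletion(msa) else msa
  if (is.character(model)) model <- estimate_model(work, model)
  pat <- compress_patterns(work)
  dm <- build_distance_matrix(work, model = "TN93-MCL", policy = "pairwise")
  starts <- list()
  if ("NJ" %in% start) starts$NJ <- nj_tree(dm)
  if ("BioNJ" %in% start) {
    bt <- ape::bionj(stats::as.dist(dm$d))
    bt$edge.length[bt$edge.length < 0] <- 0
    starts$BioNJ <- bt
  }
  best <- NULL
  for (tr in starts) {
    cur <- optimize_branch_lengths(tr, pat, model)
    repeat_rounds <- 0L
    repeat {
      improved <- FALSE
      internal <- which(cur$tree$edge[, 2L] > length(cur$tree$tip.label))
      for (e in internal) {
        for (cand in nni_neighbors(cur$tree, e)) {
          fit <- optimize_branch_lengths(cand, pat, model, max_sweeps = 3L)
          if (fit$lnl > cur$lnl + 1e-6) {
            cur <- optimize_branch_lengths(fit$tree, pat, model)
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      repeat_rounds <- repeat_rounds + 1L
      if (!improved || repeat_rounds >= max_rounds) break
    }
    if (is.null(best) || cur$lnl > best$lnl) best <- cur
  }
  fit <- model_fit(model, best$lnl,
                   k = length(best$tree$edge.length) + n_model_params(model),
                   n_sites = pat$n_sites)
  list(tree = best$tree, lnl = best$lnl, model = model, fit = fit)
}

## empirical model estimate: frequencies from the alignment, rate ratios from
## the pooled pair counts (the same composite pooling the distances use)
estimate_model <- function(msa, name = "TN93") {
  if (name == "JC") return(subst_model("JC"))
  m <- length(msa$rows)
  counts <- list(); idx <- 0L
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    idx <- idx + 1L
    counts[[idx]] <- count_site_pairs(msa$rows[[i]], msa$rows[[j]])
  }
  pooled <- pool_pair_counts(counts, msa)
  if (name == "K2P")
    subst_model("K2P", k1 = sqrt(pooled$k1 * pooled$k2))
  else
    subst_model("TN93", pi = pooled$pi, k1 = pooled$k1, k2 = pooled$k2)
}

model_fit <- function(model, lnl, k, n_sites) {
  structure(list(model = model$name, lnl = lnl, k = k, n_sites = n_sites,
                 bic = -2 * lnl + k * log(n_sites)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: lnL = %.4f, k = %d, n = %d, BIC = %.2f\n",
              x$model, x$lnl, x$k, x$n_sites, x$bic))
  invisible(x)
}

#' Substitution-model selection by BIC
#'
#' Fits each candidate model on a fixed neighbor-joining topology (branch
#' lengths re-optimized per model; `kappa`-type parameters optimized
#' numerically) and ranks them by the Bayesian information criterion
#' `BIC = -2 lnL + k log(n_sites)` where `k` counts free branch lengths plus
#' model parameters.
#'
#' @param msa An `msa` object.
#' @param candidates Model names to compare.
#' @param policy Deletion policy.
#' @return List with `fits` (one `model_fit` per candidate, input order) and
#'   `best` (name of the lowest-BIC model).
#' @export
select_model_bic <- function(msa, candidates = c("JC", "K2P", "TN93"),
                             policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  work <- if (policy == "complete") msa_complete_deletion(msa) else msa
  pat <- compress_patterns(work)
  base_tree <- nj_tree(build_distance_matrix(work, model = "p",
                                             policy = "pairwise"))
  fits <- lapply(candidates, function(nm) {
    model <- estimate_model(work, nm)
    ## refine rate ratios jointly with branch lengths (one refit pass)
    if (nm != "JC") {
      obj <- function(par) {
        mod <- if (nm == "K2P") subst_model("K2P", k1 = exp(par[1L]))
               else subst_model("TN93", pi = model$pi,
                                k1 = exp(par[1L]), k2 = exp(par[2L]))
        -optimize_branch_lengths(base_tree, pat, mod, max_sweeps = 2L,
                                 tol = 1e-4)$lnl
      }
      p0 <- if (nm == "K2P") log(model$k1) else log(c(model$k1, model$k2))
      fit <- stats::optim(p0, obj, method = if (nm == "K2P") "Brent" else "Nelder-Mead",
                          lower = if (nm == "K2P") log(1e-3) else -Inf,
                          upper = if (nm == "K2P") log(1e3) else Inf,
                          control = list(maxit = 60, reltol = 1e-8))
      model <- if (nm == "K2P") subst_model("K2P", k1 = exp(fit$par[1L]))
               else subst_model("TN93", pi = model$pi,
                                k1 = exp(fit$par[1L]), k2 = exp(fit$par[2L]))
    }
    bl <- optimize_branch_lengths(base_tree, pat, model)
    model_fit(model, bl$lnl,
              k = length(base_tree$edge.length) + n_model_params(model),
              n_sites = pat$n_sites)
  })
  names(fits) <- candidates
  list(fits = fits, best = candidates[which.min(vapply(fits, `[[`, 0, "bic"))])
}
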