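#' Site-pair counts between two aligned rows
#'
#' Tallies, over comparable sites, the proportions of transition- and
#' transversion-differing site pairs, split into purine (A/G) and pyrimidine
#' (C/T) transitions as the Tamura-Nei model requires, together with the
#' base frequencies of the compared sites (both rows pooled). Sites with a
#' gap or ambiguous base in either row are excluded (pairwise deletion);
#' complete deletion is applied by the caller via [msa_complete_deletion()].
#'
#' @param row_i,row_j Equal-length (gapped) sequence strings.
#' @return List with `P` (all transitions), `Q` (transversions), `P1`
#'   (purine transitions), `P2` (pyrimidine transitions), `base_freqs`
#'   (named A/C/G/T), `n_sites`.
#' @export
count_site_pairs <- function(row_i, row_j) {
  a <- strsplit(row_i, "")[[1L]]
  b <- strsplit(row_j, "")[[1L]]
  if (length(a) != length(b)) stop("rows differ in length")
  base <- c("A", "C", "G", "T")
  ok <- a %in% base & b %in% base
  if (!any(ok)) stop("zero comparable sites")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  diff <- a != b
  pur <- function(x) x == "A" | x == "G"
  ts <- diff & (pur(a) == pur(b))
  p1 <- sum(ts & pur(a)) / n
  p2 <- sum(ts & !pur(a)) / n
  q <- sum(diff & (pur(a) != pur(b))) / n
  freqs <- (table(factor(a, base)) + table(factor(b, base))) / (2 * n)
  list(P = p1 + p2, Q = q, P1 = p1, P2 = p2,
       base_freqs = stats::setNames(as.numeric(freqs), base), n_sites = n)
}

#' p-distance
#' @param c Site-pair counts from [count_site_pairs()].
#' @export
p_distance <- function(c) c$P + c$Q

#' Kimura 2-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with P the transition and Q
#' the transversion proportion. Saturated pairs (non-positive logarithm
#' argument) yield `Inf` with a warning.
#'
#' @param c Site-pair counts from [count_site_pairs()].
#' @export
k2p_distance <- function(c) {
  w1 <- 1 - 2 * c$P - c$Q
  w2 <- 1 - 2 * c$Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P distance saturated (P=", signif(c$P, 4), ", Q=",
            signif(c$Q, 4), ")")
    return(Inf)
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Tamura-Nei (TN93) distance
#'
#' Closed-form distance with unequal base frequencies and separate purine /
#' pyrimidine transition rates:
#' \deqn{d = -\frac{2\pi_A\pi_G}{\pi_R}\ln w_1
#'       - \frac{2\pi_T\pi_C}{\pi_Y}\ln w_2
#'       - 2\left(\pi_R\pi_Y - \frac{\pi_A\pi_G\pi_Y}{\pi_R}
#'                 - \frac{\pi_T\pi_C\pi_R}{\pi_Y}\right)\ln w_3}
#' with \eqn{w_1 = 1 - \pi_R P_1/(2\pi_A\pi_G) - Q/(2\pi_R)},
#' \eqn{w_2 = 1 - \pi_Y P_2/(2\pi_T\pi_C) - Q/(2\pi_Y)} and
#' \eqn{w_3 = 1 - Q/(2\pi_R\pi_Y)}.
#'
#' @param c Site-pair counts from [count_site_pairs()].
#' @param freqs Optional externally pooled base frequencies (named A/C/G/T);
#'   defaults to the pair's own.
#' @export
tn93_distance <- function(c, freqs = NULL) {
  pi <- if (is.null(freqs)) c$base_freqs else freqs[c("A", "C", "G", "T")]
  pR <- pi[["A"]] + pi[["G"]]; pY <- pi[["C"]] + pi[["T"]]
  k1 <- 2 * pi[["A"]] * pi[["G"]] / pR
  k2 <- 2 * pi[["T"]] * pi[["C"]] / pY
  k3 <- 2 * (pR * pY - pi[["A"]] * pi[["G"]] * pY / pR -
               pi[["T"]] * pi[["C"]] * pR / pY)
  w1 <- 1 - c$P1 / k1 - c$Q / (2 * pR)
  w2 <- 1 - c$P2 / k2 - c$Q / (2 * pY)
  w3 <- 1 - c$Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    warning("TN93 distance saturated")
    return(Inf)
  }
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

## TN93 rate matrix with stationary frequencies pi and transition/transversion
## rate ratios k1 (A<->G), k2 (C<->T), scaled to one substitution per site.
tn93_rate_matrix <- function(pi, k1, k2) {
  base <- c("A", "C", "G", "T")
  pi <- pi[base]
  R <- matrix(0, 4, 4, dimnames = list(base, base))
  for (i in base) for (j in base) {
    if (i == j) next
    rate <- if ((i %in% c("A", "G")) && (j %in% c("A", "G"))) k1
            else if ((i %in% c("C", "T")) && (j %in% c("C", "T"))) k2
            else 1
    R[i, j] <- rate * pi[[j]]
  }
  diag(R) <- -rowSums(R)
  mu <- -sum(pi * diag(R))
  R / mu
}

## eigen-decomposed transition probabilities P(t) = V exp(D t) V^-1
rate_matrix_eigen <- function(R) {
  e <- eigen(R)
  list(V = e$vectors, Vi = solve(e$vectors), d = Re(e$values))
}

transition_probs <- function(eg, t) {
  P <- Re(eg$V %*% (exp(eg$d * t) * eg$Vi))
  P[P < 0] <- 0
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

## expected site-pair category probabilities (same / purine ts / pyrimidine
## ts / tv) at distance t under a TN93 structure
tn93_pair_probs <- function(pi, eg, t) {
  P <- transition_probs(eg, t)
  J <- pi * P                   # joint P(i at one end, j at the other)
  base <- c("A", "C", "G", "T")
  dimnames(J) <- list(base, base)
  c(same = sum(diag(J)),
    p1 = J["A", "G"] + J["G", "A"],
    p2 = J["C", "T"] + J["T", "C"],
    q = sum(J) - sum(diag(J)) - J["A", "G"] - J["G", "A"] -
        J["C", "T"] - J["T", "C"])
}

## one-dimensional ML distance for a pair given a fixed TN93 rate structure
ml_pair_distance <- function(counts, pi, eg, upper = 5) {
  x <- c(same = counts$n_sites * (1 - counts$P - counts$Q),
         p1 = counts$n_sites * counts$P1,
         p2 = counts$n_sites * counts$P2,
         q = counts$n_sites * counts$Q)
  if (x[["p1"]] + x[["p2"]] + x[["q"]] == 0) return(0)
  nll <- function(t) {
    pr <- pmax(tn93_pair_probs(pi, eg, t), 1e-300)
    -sum(x * log(pr))
  }
  stats::optimize(nll, c(1e-9, upper))$minimum
}

#' Pairwise evolutionary distance matrix
#'
#' Computes all pairwise distances of an alignment under a chosen model.
#' `"TN93-MCL"` is the composite variant: base frequencies are pooled over
#' the whole alignment and one global transition/transversion rate structure
#' (`k1`, `k2`) is estimated from the pooled site-pair counts of all pairs;
#' each pairwise distance is then the one-parameter maximum-likelihood branch
#' length under that shared structure. `"TN93"` uses the per-pair closed
#' form; `"K2P"` and `"p"` are the classical formulas.
#'
#' @param msa An `msa` object.
#' @param model One of `"p"`, `"K2P"`, `"TN93"`, `"TN93-MCL"`.
#' @param policy Gap treatment: `"pairwise"` or `"complete"` deletion.
#' @return A `distance_matrix`: symmetric numeric matrix `d` with `taxa`,
#'   `model`, `deletion_policy`, `n_sites` (columns entering the
#'   computation under complete deletion) and, for the composite model,
#'   the pooled `params`.
#' @export
build_distance_matrix <- function(msa,
                                  model = c("TN93-MCL", "TN93", "K2P", "p"),
                                  policy = c("complete", "pairwise")) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  if (length(msa$rows) < 3L) stop("need at least 3 rows")
  work <- if (policy == "complete") msa_complete_deletion(msa) else msa
  taxa <- names(work$rows)
  m <- length(taxa)
  counts <- vector("list", m * (m - 1L) / 2L)
  idx <- 0L
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    idx <- idx + 1L
    counts[[idx]] <- count_site_pairs(work$rows[[i]], work$rows[[j]])
  }
  params <- NULL
  if (model == "TN93-MCL") {
    pooled <- pool_pair_counts(counts, work)
    eg <- rate_matrix_eigen(tn93_rate_matrix(pooled$pi, pooled$k1, pooled$k2))
    dist_fun <- function(c) ml_pair_distance(c, pooled$pi, eg)
    params <- pooled
  } else {
    dist_fun <- switch(model,
                       p = p_distance, K2P = k2p_distance, TN93 = tn93_distance)
  }
  d <- matrix(0, m, m, dimnames = list(taxa, taxa))
  idx <- 0L
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    idx <- idx + 1L
    d[i, j] <- d[j, i] <- dist_fun(counts[[idx]])
  }
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
    stop("saturated pair(s): ",
         paste(taxa[bad[, 1L]], taxa[bad[, 2L]], sep = "-", collapse = ", "))
  }
  structure(list(taxa = taxa, d = d, model = model, deletion_policy = policy,
                 n_sites = nchar(work$rows[[1L]]), params = params),
            class = "distance_matrix")
}

## pooled frequencies and rate ratios for the composite (MCL-style) model:
## frequencies from the whole alignment, k1/k2 by maximizing the multinomial
## likelihood of the pooled site-pair category counts jointly with one
## pooled divergence parameter
pool_pair_counts <- function(counts, msa) {
  ch <- unlist(strsplit(unname(msa$rows), ""), use.names = FALSE)
  base <- c("A", "C", "G", "T")
  tab <- table(factor(ch, base))
  pi <- stats::setNames(as.numeric(tab / sum(tab)), base)
  tot <- c(same = 0, p1 = 0, p2 = 0, q = 0)
  for (c in counts) {
    tot <- tot + c(c$n_sites * (1 - c$P - c$Q), c$n_sites * c$P1,
                   c$n_sites * c$P2, c$n_sites * c$Q)
  }
  nll <- function(par) {
    k1 <- exp(par[1L]); k2 <- exp(par[2L]); t <- exp(par[3L])
    eg <- rate_matrix_eigen(tn93_rate_matrix(pi, k1, k2))
    pr <- pmax(tn93_pair_probs(pi, eg, t), 1e-300)
    -sum(tot * log(pr))
  }
  fit <- stats::optim(log(c(8, 8, max(1e-4, (tot[["p1"]] + tot[["p2"]] +
                                              tot[["q"]]) / sum(tot)))),
                      nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(pi = pi, k1 = exp(fit$par[1L]), k2 = exp(fit$par[2L]),
       pooled_t = exp(fit$par[3L]))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d taxa, model %s, %s deletion (%d sites)\n",
              length(x$taxa), x$model, x$deletion_policy, x$n_sites))
  print(round(x$d, 6))
  invisible(x)
}

#' Write a distance matrix as labeled TSV
#' @param dm A `distance_matrix`.
#' @param file Output path.
#' @export
write_distance_tsv <- function(dm, file) {
  utils::write.table(data.frame(taxon = dm$taxa, dm$d, check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
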