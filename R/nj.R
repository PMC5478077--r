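#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (m-2) d(i,j) - r(i) - r(j)` is joined, pendant branch lengths
#' come from the two-point formulas, and the matrix is reduced with
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in the Q-matrix are broken
#' by the smallest `(i, j)` pair in the original taxon order, making runs
#' bit-reproducible. Negative branch lengths are clamped to zero with the
#' deficit shifted to the sibling branch (the raw values are kept in the
#' `"raw_lengths"` attribute).
#'
#' @param dm A `distance_matrix` (or a plain symmetric matrix with
#'   dimnames).
#' @return An unrooted `phylo` tree (class from \pkg{ape}); for n >= 4 the
#'   root node is trifurcating, as usual for NJ.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  if (any(!is.finite(d))) stop("non-finite distances")
  taxa <- rownames(d)
  m <- nrow(d)
  if (m < 3L) stop("need at least 3 taxa")
  labels <- quote_newick_labels(taxa)
  sub <- labels                       # newick fragment per active node
  raw_negative <- 0L

  fmt <- function(x) sprintf("%.10g", x)
  clamp2 <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0; raw_negative <<- raw_negative + 1L }
    if (vj < 0) { vi <- vi + vj; vj <- 0; raw_negative <<- raw_negative + 1L }
    c(max(vi, 0), max(vj, 0))
  }

  while (nrow(d) > 3L) {
    mm <- nrow(d)
    r <- rowSums(d)
    qm <- (mm - 2) * d - outer(r, r, `+`)
    diag(qm) <- Inf
    best <- which(qm == min(qm), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[[1L]]; j <- best[[2L]]
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (mm - 2))
    vj <- d[i, j] - vi
    v <- clamp2(vi, vj)
    newsub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(v[1L]), sub[j], fmt(v[2L]))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(mm), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], newsub)
    rownames(d) <- colnames(d) <- NULL
  }
  ## final 3-node star, closed form
  x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(x, y, z), 0)
  raw_negative <- raw_negative + sum(c(x, y, z) < 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1L], fmt(lens[1L]),
                 sub[2L], fmt(lens[2L]), sub[3L], fmt(lens[3L]))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- taxa[match(tree$tip.label, labels)]  # restore display names
  attr(tree, "raw_lengths") <- list(n_clamped = raw_negative)
  tree
}

quote_newick_labels <- function(x) {
  bad <- grepl("[][(),;:]", x)
  if (any(bad)) stop("taxon label(s) contain Newick metacharacters: ",
                     paste(x[bad], collapse = ", "))
  gsub(" ", "_", x)
}
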