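# Independent oracles used across the suite. These deliberately use naive,
# transparent algorithms (quadratic DP, exhaustive enumeration, direct
# recounts) so they cannot share bugs with the package implementations.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, pi = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = pi), collapse = "")
}

# mutate a sequence at a given per-site substitution probability (uniform
# target base), returning the mutated string
mutate_dna <- function(s, p) {
  ch <- strsplit(s, "")[[1L]]
  hit <- runif(length(ch)) < p
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1L), "")
  paste(ch, collapse = "")
}

# quadratic-space affine-gap global alignment score (Gotoh), same cost
# convention as align_pair: gap of length L costs open + L * extend
dp_align_score <- function(a, b, match = 1, mismatch = -2,
                           gap_open = 5, gap_extend = 2) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (deletion)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (insertion)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -gap_open - gap_extend * i
  for (j in seq_len(m)) Y[1L, j + 1L] <- -gap_open - gap_extend * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) match else mismatch
    M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                             X[i, j + 1L] - gap_extend)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                             Y[i + 1L, j] - gap_extend)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# all unrooted leaf-labelled topologies on n taxa; n <= 6
all_topologies <- function(taxa) {
  n <- length(taxa)
  stopifnot(n >= 3L, n <= 6L)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  lapply(trees, identity)
}

# least-squares branch lengths of a fixed topology against a distance
# matrix; returns the residual sum of squares (negative lengths allowed)
ls_fit_rss <- function(tree, d) {
  taxa <- rownames(d)
  tree <- ape::unroot(tree)
  ne <- nrow(tree$edge)
  pairs <- t(combn(length(taxa), 2L))
  A <- matrix(0, nrow(pairs), ne)
  ## edge incidence: which edges lie on the path between each pair
  for (p in seq_len(nrow(pairs))) {
    i <- match(taxa[pairs[p, 1L]], tree$tip.label)
    j <- match(taxa[pairs[p, 2L]], tree$tip.label)
    pth <- ape::nodepath(tree, i, j)
    for (q in seq_len(length(pth) - 1L)) {
      e <- which((tree$edge[, 1L] == pth[q] & tree$edge[, 2L] == pth[q + 1L]) |
                 (tree$edge[, 2L] == pth[q] & tree$edge[, 1L] == pth[q + 1L]))
      A[p, e] <- 1
    }
  }
  y <- d[pairs]
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

# patristic distance matrix of a tree, ordered by taxa
tree_distances <- function(tree, taxa = tree$tip.label) {
  d <- ape::cophenetic.phylo(tree)
  d[taxa, taxa]
}

# tiny fixed annotated genome used by several io/selection tests: one CDS
# (plus strand), one CDS on the minus strand, a tRNA and a control region
toy_genome <- function() {
  cr   <- "TTATTATTATTA"                       # 12 nt control region
  cds1 <- "ATGACCCTAAAACGATAA"                 # M T L K R *
  trna <- "GGGGCCCCA"                          # 9 nt
  cds2_gene <- "ATGTTCGCCTAA"                  # M F A * (gene orientation)
  cds2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds2_gene)))
  seqs <- paste0(cr, cds1, trna, cds2)
  ft <- paste(
    "control_region\tCR\t1..12\t+",
    sprintf("CDS\tGENE1\t%d..%d\t+", 13, 12 + nchar(cds1)),
    sprintf("tRNA\ttrnX\t%d..%d\t+", 31, 30 + nchar(trna)),
    sprintf("CDS\tGENE2\t%d..%d\t-", 40, 39 + nchar(cds2)),
    sep = "\n")
  parse_genome(paste0(">toy\n", seqs), ft, circular = TRUE)
}
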