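#' Simulation configuration
#'
#' Study conditions for the synthetic mitogenome evolution simulator: an
#' 11-taxon sample (7 ingroup + 4 outgroup, the shape of a genus-level
#' mitogenome panel with outgroups), ~16.5 kb circular genomes with a
#' vertebrate-mitogenome feature layout (control region, 13 CDS, 22 tRNA,
#' 2 rRNA), region-structured rates (control region fastest, tRNA slowest),
#' strong transition bias, codon-aware CDS evolution targeting a per-gene
#' dN/dS count ratio, optional lineage-rate variation, and Phred-scored
#' reads.
#'
#' Defaults: base frequencies match primate mtDNA composition
#' (A .321, C .259, G .116, T .304); `k1 = k2 = 20` gives a realized
#' transition:transversion count ratio near 10, the bias seen between
#' conspecific mitogenomes; `mean_rate = 0.025` substitutions/site per unit
#' time with ingroup root age 1 and outgroup depth 3 yields ingroup
#' divergences of a few percent; region multipliers are control region 4x,
#' rRNA 1x, CDS 0.8x, tRNA 0.3x; per-gene dN/dS targets 0.3, the mildly
#' purifying regime of mitochondrial protein genes.
#'
#' @param n_taxa Total taxa (ingroup + outgroup).
#' @param n_outgroups Taxa on the outgroup side of the root.
#' @param birth_rate Pure-birth speciation rate.
#' @param root_age Ingroup root age (relative time units).
#' @param outgroup_depth Root-to-tip depth of the whole tree (same units).
#' @param min_split Minimal internal branch duration as a fraction of the
#'   subtree root age; pure-birth draws are rejection-sampled until every
#'   split is at least this well separated, emulating panels of clearly
#'   distinct lineages.
#' @param rate_model `"strict"` clock or `"lognormal"` per-branch rates.
#' @param rate_sigma Log-sd of branch rates under `"lognormal"`.
#' @param mean_rate Substitutions/site per time unit.
#' @param pi,k1,k2 TN93 parameters of the mutation process.
#' @param region_rates Named multipliers for
#'   control_region/CDS/tRNA/rRNA/other_noncoding.
#' @param dnds_target Per-gene target nonsynonymous:synonymous count ratio
#'   (scalar or named per gene).
#' @param n_indels Deletions planted in noncoding regions (0 = none).
#' @param indel_max_len Maximal deletion length (bp).
#' @param read_length,coverage Read simulator geometry.
#' @param p_low_quality Per-base probability of a low-quality (Q <= 7) score.
#' @param scale Shrink the genome layout (e.g. 0.2 for fast tests); CDS
#'   lengths stay multiples of 3.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 11L, n_outgroups = 4L, birth_rate = 1,
                       root_age = 1, outgroup_depth = 3, min_split = 0.08,
                       rate_model = c("strict", "lognormal"),
                       rate_sigma = 0.4, mean_rate = 0.025,
                       pi = c(A = 0.321, C = 0.259, G = 0.116, T = 0.304),
                       k1 = 20, k2 = 20,
                       region_rates = c(control_region = 4, CDS = 0.8,
                                        tRNA = 0.3, rRNA = 1,
                                        other_noncoding = 1),
                       dnds_target = 0.3,
                       n_indels = 0L, indel_max_len = 5L,
                       read_length = 100L, coverage = 10,
                       p_low_quality = 0.05,
                       scale = 1, seed = 1L) {
  rate_model <- match.arg(rate_model)
  stopifnot(n_taxa - n_outgroups >= 3L, n_outgroups >= 1L,
            all(region_rates > 0), abs(sum(pi) - 1) < 1e-8,
            outgroup_depth > root_age)
  layout <- default_feature_layout(scale)
  structure(list(
    n_taxa = as.integer(n_taxa), n_outgroups = as.integer(n_outgroups),
    birth_rate = birth_rate, root_age = root_age,
    outgroup_depth = outgroup_depth, min_split = min_split,
    rate_model = rate_model,
    rate_sigma = rate_sigma, mean_rate = mean_rate,
    pi = pi[c("A", "C", "G", "T")], k1 = k1, k2 = k2,
    region_rates = region_rates, dnds_target = dnds_target,
    n_indels = as.integer(n_indels), indel_max_len = as.integer(indel_max_len),
    read_length = as.integer(read_length), coverage = coverage,
    p_low_quality = p_low_quality,
    features = layout, genome_length = max(layout$end),
    seed = as.integer(seed)
  ), class = "sim_config")
}

## mitogenome-like gene order tiling the genome exactly; minus-strand genes
## where vertebrate mitogenomes have them (ND6 and a subset of tRNAs)
default_feature_layout <- function(scale = 1) {
  spec <- list(
    c("control_region", "CR", 1122, "+"),
    c("tRNA", "trnF", 71, "+"), c("rRNA", "rrn12", 954, "+"),
    c("tRNA", "trnV", 69, "+"), c("rRNA", "rrn16", 1559, "+"),
    c("tRNA", "trnL1", 75, "+"), c("CDS", "ND1", 957, "+"),
    c("tRNA", "trnI", 69, "+"), c("tRNA", "trnQ", 72, "-"),
    c("tRNA", "trnM", 68, "+"), c("CDS", "ND2", 1044, "+"),
    c("tRNA", "trnW", 69, "+"), c("tRNA", "trnA", 69, "-"),
    c("tRNA", "trnN", 73, "-"), c("tRNA", "trnC", 66, "-"),
    c("tRNA", "trnY", 66, "-"), c("CDS", "COX1", 1542, "+"),
    c("tRNA", "trnS1", 72, "-"), c("tRNA", "trnD", 68, "+"),
    c("CDS", "COX2", 684, "+"), c("tRNA", "trnK", 70, "+"),
    c("CDS", "ATP8", 207, "+"), c("CDS", "ATP6", 681, "+"),
    c("CDS", "COX3", 783, "+"), c("tRNA", "trnG", 68, "+"),
    c("CDS", "ND3", 345, "+"), c("tRNA", "trnR", 65, "+"),
    c("CDS", "ND4L", 297, "+"), c("CDS", "ND4", 1377, "+"),
    c("tRNA", "trnH", 69, "+"), c("tRNA", "trnS2", 59, "+"),
    c("tRNA", "trnL2", 71, "+"), c("CDS", "ND5", 1812, "+"),
    c("CDS", "ND6", 525, "-"), c("tRNA", "trnE", 69, "-"),
    c("CDS", "CYTB", 1140, "+"), c("tRNA", "trnT", 66, "+"),
    c("tRNA", "trnP", 69, "-"))
  len <- vapply(spec, function(x) as.integer(x[[3L]]), 0L)
  typ <- vapply(spec, `[[`, "", 1L)
  if (scale != 1) {
    len <- pmax(ifelse(typ == "CDS", 3L * pmax(round(len * scale / 3), 2L),
                       pmax(round(len * scale), 6L)), 6L)
  }
  end <- cumsum(len)
  data.frame(name = vapply(spec, `[[`, "", 2L), ftype = typ,
             start = end - len, end = end,
             strand = vapply(spec, `[[`, "", 4L),
             codon_start = 0L, transl_table = 2L, stringsAsFactors = FALSE)
}

#' Simulate a pure-birth timetree with lineage rates
#'
#' Draws an ultrametric ingroup tree and an outgroup subtree from pure-birth
#' processes, grafts them at a common root so all tips lie at
#' `outgroup_depth`, assigns per-branch rates (strict clock or lognormal),
#' and converts time lengths to substitutions/site via `mean_rate`.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`); pass `NA` to use the current
#'   RNG state.
#' @return List with `time_phylo` (ultrametric, time units), `subs_phylo`
#'   (branch lengths in substitutions/site), `rates` (per edge of
#'   `time_phylo`), `ingroup`, `outgroups` (tip labels).
#' @export
simulate_timetree <- function(cfg, seed = cfg$seed) {
  if (!is.na(seed)) set.seed(seed)
  n_in <- cfg$n_taxa - cfg$n_outgroups
  scale_to <- function(tr, depth) {
    d <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / d
    tr
  }
  ## draw until all splits are clearly separated (see min_split)
  draw_subtree <- function(n) {
    for (i in 1:1000) {
      tr <- scale_to(ape::rphylo(n, cfg$birth_rate, 0), cfg$root_age)
      internal <- tr$edge[, 2L] > n
      if (!any(internal) ||
          min(tr$edge.length[internal]) >= cfg$min_split * cfg$root_age)
        return(tr)
    }
    stop("could not draw a tree satisfying min_split")
  }
  ing <- draw_subtree(n_in)
  ing$tip.label <- sprintf("IG%02d", seq_len(n_in))
  stem <- cfg$outgroup_depth - cfg$root_age
  strip <- function(tr) sub(";$", "", ape::write.tree(tr, digits = 10))
  out_str <- if (cfg$n_outgroups >= 2L) {
    out <- draw_subtree(cfg$n_outgroups)
    out$tip.label <- sprintf("OG%02d", seq_len(cfg$n_outgroups))
    sprintf("%s:%.10g", strip(out), stem)
  } else {
    sprintf("OG01:%.10g", cfg$outgroup_depth)
  }
  time_phylo <- ape::read.tree(
    text = sprintf("(%s:%.10g,%s);", strip(ing), stem, out_str))
  rates <- if (cfg$rate_model == "strict") rep(1, nrow(time_phylo$edge))
           else stats::rlnorm(nrow(time_phylo$edge),
                              -cfg$rate_sigma^2 / 2, cfg$rate_sigma)
  subs_phylo <- time_phylo
  subs_phylo$edge.length <- time_phylo$edge.length * rates * cfg$mean_rate
  list(time_phylo = time_phylo, subs_phylo = subs_phylo, rates = rates,
       ingroup = sprintf("IG%02d", seq_len(n_in)),
       outgroups = sprintf("OG%02d", seq_len(cfg$n_outgroups)))
}

## draw a root genome honoring codon structure: no stop codons inside CDS
draw_root_genome <- function(cfg) {
  base <- c("A", "C", "G", "T")
  n <- cfg$genome_length
  ch <- sample(base, n, replace = TRUE, prob = cfg$pi)
  stops <- c("TAA", "TAG", "AGA", "AGG")
  for (i in which(cfg$features$ftype == "CDS")) {
    f <- cfg$features[i, ]
    pos <- seq.int(f$start + 1L, f$end)      # 1-based genome positions
    if (f$strand == "-") pos <- rev(pos)
    k <- length(pos) %/% 3L
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (cd in seq_len(k)) {
      j <- pos[3L * cd - 2:0]
      repeat {
        codon <- ch[j]
        if (f$strand == "-") codon <- unname(comp[codon])
        if (!(paste(codon, collapse = "") %in% stops) || cd == k) break
        ch[j] <- sample(base, 3L, replace = TRUE, prob = cfg$pi)
      }
    }
  }
  ch
}

## per-gene acceptance probability for nonsynonymous proposals so realized
## nonsyn:syn substitution counts target the configured dN/dS: enumerate the
## 9 single-base mutations of every codon weighted by TN93 rates
nonsyn_accept_prob <- function(ch, cfg) {
  base <- c("A", "C", "G", "T")
  R <- tn93_rate_matrix(cfg$pi, cfg$k1, cfg$k2)
  code <- genetic_code(2L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  targets <- cfg$dnds_target
  cds <- cfg$features[cfg$features$ftype == "CDS", , drop = FALSE]
  out <- stats::setNames(numeric(nrow(cds)), cds$name)
  for (i in seq_len(nrow(cds))) {
    f <- cds[i, ]
    pos <- seq.int(f$start + 1L, f$end)
    if (f$strand == "-") pos <- rev(pos)
    k <- length(pos) %/% 3L
    w_syn <- 0; w_ns <- 0
    for (cd in seq_len(k)) {
      j <- pos[3L * cd - 2:0]
      codon <- ch[j]
      if (f$strand == "-") codon <- unname(comp[codon])
      aa0 <- code[[paste(codon, collapse = "")]]
      for (p in 1:3) for (b in setdiff(base, codon[p])) {
        mut <- codon; mut[p] <- b
        aa1 <- code[[paste(mut, collapse = "")]]
        ## rate of genome-strand change (reverse-complement symmetric in
        ## transition/transversion class; frequencies differ but the ratio
        ## estimate is adequate for targeting)
        w <- R[codon[p], b]
        if (aa1 == "*") next                 # stops are always rejected
        if (aa1 == aa0) w_syn <- w_syn + w else w_ns <- w_ns + w
      }
    }
    omega <- if (length(targets) > 1L) targets[[f$name]] else targets
    rho0 <- if (w_syn > 0) w_ns / w_syn else Inf
    out[f$name] <- min(1, omega / rho0)
  }
  out
}

#' Evolve genomes along a tree
#'
#' Forward TN93 simulation of a ~16.5 kb annotated mitogenome along a tree
#' with branch lengths in substitutions/site. Sites carry region-specific
#' rate multipliers; CDS sites evolve codon-aware -- proposed codon changes
#' creating stops are rejected and nonsynonymous changes are accepted with a
#' per-gene probability calibrated so the realized nonsynonymous:synonymous
#' count ratio targets the configured dN/dS. Optionally, short deletions are
#' planted in noncoding regions of random lineages.
#'
#' @param tree `phylo` with substitutions/site branch lengths (e.g.
#'   `subs_phylo` from [simulate_timetree()]).
#' @param cfg A [sim_config()].
#' @param seed Seed (`cfg$seed + 1L` by default; `NA` = use current state).
#' @return List with `genomes` (named list of `genome_record`), `msa` (the
#'   true alignment, gapped if deletions were planted), `features` (root
#'   annotation), `deletions` (data frame of planted events).
#' @export
evolve_genome <- function(tree, cfg, seed = cfg$seed + 1L) {
  if (!is.na(seed)) set.seed(seed)
  base <- c("A", "C", "G", "T")
  n <- cfg$genome_length
  feats <- cfg$features
  ch0 <- draw_root_genome(cfg)

  ## per-site rate class
  mult_of <- stats::setNames(cfg$region_rates[c("control_region", "CDS",
                                                "tRNA", "rRNA",
                                                "other_noncoding")],
                             c("control_region", "CDS", "tRNA", "rRNA",
                               "other_noncoding"))
  site_type <- rep("other_noncoding", n)
  for (i in seq_len(nrow(feats)))
    site_type[seq.int(feats$start[i] + 1L, feats$end[i])] <- feats$ftype[i]
  site_mult <- unname(mult_of[site_type])
  classes <- sort(unique(site_mult))

  ## CDS bookkeeping for codon-aware acceptance
  accept_ns <- nonsyn_accept_prob(ch0, cfg)
  cds <- feats[feats$ftype == "CDS", , drop = FALSE]
  codon_tab <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i) {
    f <- cds[i, ]
    pos <- seq.int(f$start + 1L, f$end)
    if (f$strand == "-") pos <- rev(pos)
    k <- length(pos) %/% 3L
    data.frame(gene = f$name, strand = f$strand,
               p1 = pos[3L * seq_len(k) - 2L],
               p2 = pos[3L * seq_len(k) - 1L],
               p3 = pos[3L * seq_len(k)], stringsAsFactors = FALSE)
  }))
  codon_of_site <- rep(NA_integer_, n)
  codon_of_site[codon_tab$p1] <- seq_len(nrow(codon_tab))
  codon_of_site[codon_tab$p2] <- seq_len(nrow(codon_tab))
  codon_of_site[codon_tab$p3] <- seq_len(nrow(codon_tab))

  eg <- rate_matrix_eigen(tn93_rate_matrix(cfg$pi, cfg$k1, cfg$k2))
  code <- genetic_code(2L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  stops <- c("TAA", "TAG", "AGA", "AGG")

  mutate_along <- function(parent, t) {
    child <- parent
    if (t <= 0) return(child)
    for (m in classes) {
      P <- transition_probs(eg, t * m)
      idx <- which(site_mult == m)
      pb <- parent[idx]
      u <- stats::runif(length(idx))
      newb <- pb
      for (b in base) {
        sel <- pb == b
        if (!any(sel)) next
        cp <- cumsum(P[b, ])
        newb[sel] <- base[findInterval(u[sel], cp) + 1L]
      }
      child[idx] <- newb
    }
    ## codon-aware filter on CDS changes
    changed <- which(child != parent & !is.na(codon_of_site))
    for (cd in unique(codon_of_site[changed])) {
      row <- codon_tab[cd, ]
      j <- c(row$p1, row$p2, row$p3)
      c_par <- parent[j]; c_chi <- child[j]
      if (row$strand == "-") { c_par <- unname(comp[c_par]); c_chi <- unname(comp[c_chi]) }
      aa0 <- code[[paste(c_par, collapse = "")]]
      aa1 <- code[[paste(c_chi, collapse = "")]]
      reject <- paste(c_chi, collapse = "") %in% stops ||
        (aa1 != aa0 && stats::runif(1L) > accept_ns[[row$gene]])
      if (reject) child[j] <- parent[j]
    }
    child
  }

  ## preorder traversal
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- ch0
  for (k in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[k, 1L]; chi <- po$edge[k, 2L]
    seqs[[chi]] <- mutate_along(seqs[[par]], po$edge.length[k])
  }
  tips <- stats::setNames(seqs[seq_len(ntip)], tree$tip.label)

  ## optional planted deletions (noncoding only, one lineage each)
  mat <- do.call(rbind, tips)
  rownames(mat) <- tree$tip.label
  deletions <- data.frame(taxa = character(), start = integer(),
                          length = integer(), stringsAsFactors = FALSE)
  if (cfg$n_indels > 0L) {
    noncoding <- which(site_type %in% c("control_region", "other_noncoding"))
    bp <- tree_bipartitions_all(tree)
    for (e in seq_len(cfg$n_indels)) {
      len <- sample.int(cfg$indel_max_len, 1L)
      pos <- sample(noncoding[noncoding <= n - len], 1L)
      victim <- bp[[sample.int(length(bp), 1L)]]
      mat[victim, pos:(pos + len - 1L)] <- "-"
      deletions <- rbind(deletions,
                         data.frame(taxa = paste(tree$tip.label[victim],
                                                 collapse = ";"),
                                    start = pos - 1L, length = len,
                                    stringsAsFactors = FALSE))
    }
  }

  rows <- apply(mat, 1L, paste, collapse = "")
  genomes <- lapply(tree$tip.label, function(tx) {
    s <- gsub("-", "", rows[[tx]], fixed = TRUE)
    del_pos <- which(mat[tx, ] == "-")
    f <- feats
    if (length(del_pos)) {
      f$start <- f$start - vapply(f$start, function(p) sum(del_pos <= p), 0L)
      f$end <- f$end - vapply(f$end, function(p) sum(del_pos <= p), 0L)
    }
    genome_record(tx, s, circular = TRUE, features = f, label = tx)
  })
  names(genomes) <- tree$tip.label
  list(genomes = genomes,
       msa = msa_from_rows(rows, center = tree$tip.label[1L]),
       features = feats, deletions = deletions)
}

## tip index sets of every clade (used to pick deletion-sharing lineages)
tree_bipartitions_all <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- c(as.list(seq_len(ntip)), vector("list", tree$Nnode))
  for (k in seq_len(nrow(po$edge)))
    below[[po$edge[k, 1L]]] <- c(below[[po$edge[k, 1L]]],
                                 below[[po$edge[k, 2L]]])
  below[-(ntip + 1L)]                      # every node except the root
}

#' Simulate sequencing reads
#'
#' Fixed-length reads from uniform random circular start positions with
#' i.i.d. qualities from a two-component distribution: with probability
#' `p_low_quality` a score drawn uniformly from 0..7, otherwise from 30..40.
#' The read count is `round(coverage * genome_length / read_length)`.
#'
#' @param g A `genome_record`.
#' @param cfg A [sim_config()].
#' @param seed Seed (`cfg$seed + 2L` by default; `NA` = current state).
#' @return List of `quality_read` objects.
#' @export
simulate_reads <- function(g, cfg, seed = cfg$seed + 2L) {
  if (!is.na(seed)) set.seed(seed)
  stopifnot(cfg$coverage > 0)
  n <- genome_length(g)
  rl <- cfg$read_length
  if (rl > n && !g$circular) stop("read length exceeds linear genome length")
  n_reads <- round(cfg$coverage * n / rl)
  doubled <- paste0(g$sequence, substr(g$sequence, 1L, rl))
  starts <- sample.int(n, n_reads, replace = TRUE)
  lapply(seq_len(n_reads), function(i) {
    q_low <- stats::runif(rl) < cfg$p_low_quality
    quals <- ifelse(q_low, sample(0:7, rl, replace = TRUE),
                    sample(30:40, rl, replace = TRUE))
    structure(list(id = sprintf("read%06d", i),
                   bases = substr(doubled, starts[i], starts[i] + rl - 1L),
                   quals = as.integer(quals)),
              class = "quality_read")
  })
}

#' One-call synthetic dataset
#'
#' Runs [simulate_timetree()], [evolve_genome()] and (optionally)
#' [simulate_reads()] under a single configuration seed.
#'
#' @param cfg A [sim_config()].
#' @param reads Also simulate reads from the first genome?
#' @return List: `cfg`, `tree` (the [simulate_timetree()] result),
#'   `genomes`, `msa`, `features`, `deletions`, and `reads` (or `NULL`).
#' @export
simulate_dataset <- function(cfg = sim_config(), reads = FALSE) {
  tt <- simulate_timetree(cfg)
  ev <- evolve_genome(tt$subs_phylo, cfg)
  rd <- if (reads) simulate_reads(ev$genomes[[1L]], cfg) else NULL
  list(cfg = cfg, tree = tt, genomes = ev$genomes, msa = ev$msa,
       features = ev$features, deletions = ev$deletions, reads = rd)
}
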