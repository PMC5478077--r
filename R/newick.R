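#' Serialize a tree to Newick
#'
#' Writes a `phylo` or `time_tree` with at least 8 significant digits on
#' branch lengths. `decorations = "support"` keeps bootstrap support node
#' labels (as set by [bootstrap_support()]); `decorations = "age"` writes
#' calibrated node ages (2 decimals, Ma) as node labels. Tip labels
#' containing Newick metacharacters are rejected; spaces become underscores.
#'
#' @param tree A `phylo` or `time_tree`.
#' @param decorations One of `"none"`, `"support"`, `"age"`.
#' @param file Optional output path.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, decorations = c("none", "support", "age"),
                         file = NULL) {
  decorations <- match.arg(decorations)
  if (inherits(tree, "time_tree")) {
    phy <- tree$tree
    if (decorations == "age") {
      if (all(is.na(tree$age))) stop("time tree is not calibrated")
      ntip <- length(phy$tip.label)
      phy$node.label <- sprintf("%.2f", tree$age[seq.int(ntip + 1L,
                                                         ntip + phy$Nnode)])
    }
  } else {
    phy <- tree
    if (decorations == "age") stop("'age' decoration requires a time_tree")
  }
  if (decorations == "none") phy$node.label <- NULL
  phy$tip.label <- quote_newick_labels(phy$tip.label)
  txt <- ape::write.tree(phy, digits = 10)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Parse a Newick string or file
#'
#' Thin wrapper over the \pkg{ape} reader returning a `phylo`; underscores
#' in labels are restored to spaces to invert [write_newick()].
#'
#' @param text Newick text (or use `file`).
#' @param file Path to a Newick file.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  tr$tip.label <- gsub("_", " ", tr$tip.label)
  tr
}
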