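#' The packaged euarchontoglire phylogeny
#'
#' A 16-species rooted topology over the superorder Euarchontoglires (human
#' plus eight other primates, treeshrew, four rodents including mouse, and
#' two lagomorphs) with branch lengths on a substitutions/site scale typical
#' of conserved regulatory regions, shipped as a newick fixture. Clade labels
#' (`euarchonta`, `glires`, and singletons for every species) are attached as
#' the `"clades"` attribute.
#'
#' @return a rooted `phylo` object with a `"clades"` attribute.
#' @export
euarchontoglires_tree <- function() {
  path <- system.file("extdata", "euarchontoglires.nwk", package = "icrevo")
  tree <- read_newick(path)
  primates <- c("human", "chimp", "gorilla", "orangutan", "rhesus",
                "marmoset", "tarsier", "mouse_lemur", "bushbaby")
  clades <- list(
    euarchonta = c(primates, "treeshrew"),
    glires = c("mouse", "rat", "guinea_pig", "squirrel", "rabbit", "pika"),
    euarchontoglires = tree$tip.label
  )
  for (sp in tree$tip.label) clades[[sp]] <- sp
  attr(tree, "clades") <- clades
  tree
}

#' Sum of branch lengths for a clade
#'
#' For a singleton clade the sum is that leaf's pendant branch length only;
#' for a multi-species clade it is the sum over all branches of the subtree
#' below the clade's most recent common ancestor (the stem branch leading to
#' the clade is excluded).
#'
#' @param tree a `phylo` with branch lengths, or an `icr_fit` (whose fitted
#'   tree is used).
#' @param clade a clade name (looked up in the tree's `"clades"` attribute)
#'   or a character vector of tip labels.
#' @return branch-length sum in substitutions/site.
#' @export
clade_branch_sum <- function(tree, clade) {
  if (inherits(tree, "icr_fit")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  if (is.character(clade) && length(clade) == 1L && !(clade %in% tree$tip.label)) {
    clades <- attr(tree, "clades")
    if (is.null(clades) || is.null(clades[[clade]])) {
      stop(sprintf("unknown clade '%s'", clade))
    }
    clade <- clades[[clade]]
  }
  tips <- match(clade, tree$tip.label)
  if (anyNA(tips)) {
    stop(sprintf("unknown species: %s", paste(clade[is.na(tips)], collapse = ", ")))
  }
  if (length(tips) == 1L) {
    e <- which(tree$edge[, 2] == tips)
    return(tree$edge.length[e])
  }
  mrca <- ape::getMRCA(tree, tips)
  # all edges in the subtree below the MRCA
  keep <- logical(nrow(tree$edge))
  nodes <- mrca
  repeat {
    new_edges <- which(tree$edge[, 1] %in% nodes & !keep)
    if (length(new_edges) == 0L) break
    keep[new_edges] <- TRUE
    nodes <- tree$edge[keep, 2]
  }
  sum(tree$edge.length[keep])
}
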