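#' Simulate sequence evolution along one branch
#'
#' Exact (Gillespie) simulation of the context-dependent substitution process:
#' each site leaves its current state at the total rate implied by its
#' trinucleotide context; waiting times are exponential in the summed rate
#' over sites; after an event only the affected site and its two neighbours
#' have their rates refreshed. Terminal sites use phantom `A` flanks for rate
#' lookup.
#'
#' @param seq nucleotide string (A/C/G/T) or integer codes 1..4.
#' @param model a `context_model`.
#' @param t branch length (time under the model's rate scale; with a
#'   mean-rate-1 model this is substitutions/site).
#' @param seed optional integer seed (set once before simulating).
#' @return same representation as the input (string in, string out).
#' @export
simulate_branch <- function(seq, model, t, seed = NULL) {
  stopifnot(inherits(model, "context_model"))
  if (!is.null(seed)) set.seed(seed)
  as_string <- is.character(seq)
  codes <- if (as_string) seq_codes(seq) else as.integer(seq)
  if (anyNA(codes)) stop("simulation input must be gap- and N-free")
  arr <- rate_array(model)
  out <- sim_branch_cpp(codes, as.numeric(arr), t)
  if (as_string) codes_to_seq(out) else out
}

#' Simulate a region alignment down a phylogeny
#'
#' Draws a root sequence from the model's trinucleotide root composition and
#' applies [simulate_branch()] recursively along every branch of the rooted
#' tree. No indels are introduced, so columns stay aligned.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @param model a `context_model`.
#' @param root_length root sequence length (>= 3).
#' @param seed optional integer seed.
#' @param id,category passed to [region_alignment()].
#' @return a `region_alignment` over the tree's tips.
#' @export
simulate_alignment <- function(tree, model, root_length, seed = NULL,
                               id = "sim", category = "other") {
  stopifnot(inherits(tree, "phylo"), root_length >= 3)
  if (!is.null(seed)) set.seed(seed)
  arr <- as.numeric(rate_array(model))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  seqs[[root]] <- sample_root(model$root_comp, root_length)
  edges <- tree$edge
  pre <- preorder_edges(tree)
  for (e in pre) {
    p <- edges[e, 1]; v <- edges[e, 2]
    seqs[[v]] <- sim_branch_cpp(seqs[[p]], arr, tree$edge.length[e])
  }
  mat <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(mat) <- tree$tip.label
  region_alignment(mat, id = id, category = category)
}

# edge indices in preorder (every parent's edge precedes its children's)
preorder_edges <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- integer(0)
  stack <- c(root)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    es <- kids[[as.character(node)]]
    if (is.null(es)) next
    out <- c(out, es)
    stack <- c(stack, tree$edge[es, 2])
  }
  out
}
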