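#' Count substitution events by Fitch parsimony
#'
#' An independent, counting-based estimator of context-dependent substitution
#' rates: ancestral states are reconstructed per column by Fitch parsimony
#' (ties broken alphabetically, A<C<G<T), every state change along a branch
#' is counted as one event in the context given by the reconstructed flanking
#' states at the parent node, and exposures accumulate branch length times
#' context occurrences at the parent. Columns with any gap, or with a gapped
#' flanking column, are excluded; region boundaries use phantom `A` flanks.
#'
#' @param alignments a `region_alignment` or list of them.
#' @param tree rooted `phylo` with branch lengths (used for exposures).
#' @param model_type rate-class partition to aggregate into (`"cpg"` or
#'   `"u3s"`), as in [fit_context_model()].
#' @return object of class `parsimony_counts`: per-class event counts and
#'   exposures, normalized relative rates (exposure-weighted mean rate 1),
#'   the per-(context, from, to) event array, the per-(context, state)
#'   exposure matrix, and `summary` aggregates as in [fit_context_model()].
#' @export
count_events_parsimony <- function(alignments, tree, model_type = c("cpg", "u3s")) {
  model_type <- match.arg(model_type)
  if (inherits(alignments, "region_alignment")) alignments <- list(alignments)
  tables <- class_tables(model_type)
  tree <- ape::reorder.phylo(tree, "postorder")
  tip_order <- tree$tip.label
  n_tip <- length(tip_order)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  edges <- tree$edge
  n_edge <- nrow(edges)
  events <- array(0, c(tables$n_qclass, 4, 4))
  exposure <- matrix(0, tables$n_qclass, 4)
  total_cols <- 0L

  for (aln in alignments) {
    stopifnot(inherits(aln, "region_alignment"))
    if (!setequal(rownames(aln$mat), tip_order)) {
      stop(sprintf("alignment '%s': species not on tree", aln$id))
    }
    mat <- aln$mat[tip_order, , drop = FALSE]
    L <- ncol(mat)
    clean <- colSums(is.na(mat)) == 0L
    if (!any(clean)) next
    fr <- fitch_reconstruct(mat, tree)
    states <- fr$states
    # usable columns and their positions among the clean ones
    usable <- clean & c(TRUE, clean[-L]) & c(clean[-1L], TRUE)
    upos <- match(which(usable), fr$clean)
    has_left <- which(usable) > 1L
    has_right <- which(usable) < L
    lpos <- match(which(usable) - 1L, fr$clean)
    rpos <- match(which(usable) + 1L, fr$clean)
    total_cols <- total_cols + length(upos)
    for (e in seq_len(n_edge)) {
      p <- edges[e, 1]; v <- edges[e, 2]
      te <- tree$edge.length[e]
      lf <- ifelse(has_left, states[p, ][lpos], 1L)
      rf <- ifelse(has_right, states[p, ][rpos], 1L)
      q <- tables$qidx[cbind(lf, rf)]
      lfc <- ifelse(has_left, states[v, ][lpos], 1L)
      rfc <- ifelse(has_right, states[v, ][rpos], 1L)
      qc <- tables$qidx[cbind(lfc, rfc)]
      from <- states[p, ][upos]
      to <- states[v, ][upos]
      # midpoint convention: the first half of the branch is spent in the
      # parent's state and context, the second half in the child's (both
      # focal-state changes and flank changes take effect halfway down)
      grp_states <- c(from, to)
      grp_q <- c(q, qc)
      ex <- rowsum(rep(te / 2, 2L * length(upos)),
                   group = grp_q * 10L + grp_states)
      grp <- as.integer(rownames(ex))
      exposure[cbind(grp %/% 10L, grp %% 10L)] <-
        exposure[cbind(grp %/% 10L, grp %% 10L)] + ex[, 1]
      chg <- to != from
      if (any(chg)) {
        ev <- rowsum(rep(1, sum(chg)),
                     group = (q[chg] * 10L + from[chg]) * 10L + to[chg])
        g <- as.integer(rownames(ev))
        idx <- cbind(g %/% 100L, (g %/% 10L) %% 10L, g %% 10L)
        events[idx] <- events[idx] + ev[, 1]
      }
    }
  }
  if (total_cols == 0L) stop("no usable (gap-free) columns")

  # per-class counts and exposures
  fl <- qclass_flags(tables)
  Nk <- numeric(tables$n_class)
  Tk <- numeric(tables$n_class)
  for (i in seq_len(nrow(fl))) {
    k <- fl$class[i]
    Nk[k] <- Nk[k] + events[fl$qclass[i], fl$from[i], fl$to[i]]
    Tk[k] <- Tk[k] + exposure[fl$qclass[i], fl$from[i]]
  }
  mu <- sum(events) / sum(exposure)
  rates <- ifelse(Tk > 0, (Nk / Tk), 0)
  if (mu > 0) rates <- rates / mu
  rates <- setNames(rates, tables$class_names)
  structure(
    list(
      rates = rates, class_events = setNames(Nk, tables$class_names),
      class_exposure = setNames(Tk, tables$class_names),
      events = events, exposure = exposure,
      n_events = sum(events), n_columns = total_cols,
      summary = rate_summary(rates, exposure, model_type),
      type = model_type
    ),
    class = "parsimony_counts"
  )
}

#' @export
print.parsimony_counts <- function(x, ...) {
  cat(sprintf("Parsimony event counts: %d events over %d columns\n",
              round(x$n_events), x$n_columns))
  cat("Normalized relative rates:\n")
  print(round(x$rates, 4))
  invisible(x)
}
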