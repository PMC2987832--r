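#' Gene-set overrepresentation analysis (hypergeometric)
#'
#' For every annotation category whose in-universe size lies in
#' `[min_size, max_size]`, computes the upper-tail hypergeometric probability
#' of observing at least the actual number of selected genes in the category,
#' then corrects across tested categories. Probes are collapsed to genes
#' before counting (a gene is selected if any of its probes is).
#'
#' @param selected character vector of selected gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of gene ids: all annotated, expressed,
#'   filtered genes.
#' @param annotation data.frame `gene_id, category_id, category_name` (see
#'   [read_go_annotation()]); genes outside the universe are ignored.
#' @param min_size,max_size category size limits (in-universe).
#' @param method multiple-testing correction: `"BH"` or `"bonferroni"`.
#' @param parents optional data.frame `child_id, parent_id`; when supplied,
#'   annotations are propagated to ancestor categories before testing.
#' @return data.frame of class `enrichment_result`, one row per tested
#'   category, sorted by p: `category_id, category_name, size, hits, p,
#'   p_adj`.
#' @export
ora <- function(selected, universe, annotation, min_size = 5L, max_size = 200L,
                method = c("BH", "bonferroni"), parents = NULL) {
  method <- match.arg(method)
  if (min_size < 2L) stop("min_size must be >= 2")
  selected <- unique(selected)
  universe <- unique(universe)
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop(sprintf("selected genes outside the universe: %s%s",
                 paste(head(extra, 5L), collapse = ", "),
                 if (length(extra) > 5L) ", ..." else ""))
  }
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  if (!is.null(parents)) ann <- propagate_annotation(ann, parents)
  ann <- unique(ann[, c("gene_id", "category_id")])
  namemap <- unique(annotation[, c("category_id", "category_name")])
  sizes <- table(ann$category_id)
  keep <- names(sizes)[sizes >= min_size & sizes <= max_size]
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(keep, function(cid) {
    members <- ann$gene_id[ann$category_id == cid]
    K <- length(members)
    hits <- sum(members %in% selected)
    p <- stats::phyper(hits - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(category_id = cid,
               category_name = namemap$category_name[match(cid, namemap$category_id)],
               size = K, hits = hits, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(category_id = character(), category_name = character(),
                      size = integer(), hits = integer(), p = numeric(),
                      p_adj = numeric())
  } else {
    out$p_adj <- stats::p.adjust(out$p, method = if (method == "BH") "BH" else "bonferroni")
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# annotate every ancestor of each category (transitive closure)
propagate_annotation <- function(ann, parents) {
  stopifnot(all(c("child_id", "parent_id") %in% names(parents)))
  res <- ann[, c("gene_id", "category_id")]
  frontier <- res
  for (depth in seq_len(50L)) {
    up <- merge(frontier, parents, by.x = "category_id", by.y = "child_id")
    if (nrow(up) == 0L) break
    frontier <- unique(data.frame(gene_id = up$gene_id,
                                  category_id = up$parent_id,
                                  stringsAsFactors = FALSE))
    new <- frontier[!paste(frontier$gene_id, frontier$category_id) %in%
                      paste(res$gene_id, res$category_id), , drop = FALSE]
    if (nrow(new) == 0L) break
    res <- rbind(res, new)
    frontier <- new
  }
  res
}

#' Histogram of corrected enrichment p-values
#'
#' Bins corrected p-values into intervals delimited by the given upper
#' edges (first bin is `(0, edges[1]]`, and so on), and reports the counts of
#' categories significant at 0.1 and 0.01.
#'
#' @param rows an `enrichment_result` (or any data.frame with `p_adj`).
#' @param edges increasing bin edges, ending at 1.
#' @return list with `counts` (named per bin), `n_sig_0.1`, `n_sig_0.01`.
#' @export
pvalue_spectrum <- function(rows, edges = c(0.001, 0.01, 0.1, 1)) {
  if (length(edges) == 0L) stop("empty bin edges")
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be increasing")
  if (nrow(rows) == 0L) stop("no enrichment rows")
  p <- rows$p_adj
  counts <- integer(length(edges))
  labels <- character(length(edges))
  lo <- 0
  for (i in seq_along(edges)) {
    counts[i] <- sum(p > lo & p <= edges[i])
    labels[i] <- sprintf("(%g,%g]", lo, edges[i])
    lo <- edges[i]
  }
  names(counts) <- labels
  list(counts = counts,
       n_sig_0.1 = sum(p < 0.1),
       n_sig_0.01 = sum(p < 0.01))
}
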