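#' Region alignment container
#'
#' A gap-aware multiple sequence alignment of one genomic region across the
#' species of a phylogeny, stored as an integer code matrix (1=A, 2=C, 3=G,
#' 4=T, NA=gap or N) with species as rows.
#'
#' @param x either a character vector of equal-length sequences named by
#'   species, or an integer code matrix with species rownames.
#' @param id region identifier.
#' @param category sequence category label (e.g. `ICR_mat`, `ICR_pat`, `LCP`,
#'   `HICP`, `intergenic`).
#' @return an object of class `region_alignment`.
#' @export
region_alignment <- function(x, id = "region", category = "other") {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named by species")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
    mat <- t(vapply(x, function(s) {
      match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], BASES)
    }, integer(lens[1L])))
    rownames(mat) <- names(x)
  } else if (is.matrix(x)) {
    mat <- x
    if (is.null(rownames(mat))) stop("code matrix must have species rownames")
  } else {
    stop("x must be a named character vector or an integer code matrix")
  }
  structure(list(id = id, category = category, mat = mat),
            class = "region_alignment")
}

#' @export
print.region_alignment <- function(x, ...) {
  cat(sprintf("Region alignment '%s' (%s): %d species x %d columns\n",
              x$id, x$category, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' @export
as.character.region_alignment <- function(x, ...) {
  apply(x$mat, 1L, codes_to_seq)
}

# Fitch parsimony ancestral reconstruction of every gap-free column,
# vectorized over columns with state bitmasks. Ties at the root and in the
# top-down pass are broken alphabetically (A<C<G<T). Returns the n_node x
# n_clean state matrix and the indices of the clean columns. `tree` must be
# in postorder; `mat` rows must follow tree$tip.label.
fitch_reconstruct <- function(mat, tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  edges <- tree$edge
  bit <- c(1L, 2L, 4L, 8L)
  lowbit <- integer(15L)
  for (m in 1:15) lowbit[m] <- which(bitwAnd(m, bit) > 0L)[1L]
  clean <- which(colSums(is.na(mat)) == 0L)
  if (length(clean) == 0L) {
    return(list(states = matrix(0L, n_node, 0L), clean = clean))
  }
  cmat <- mat[, clean, drop = FALSE]
  nc <- ncol(cmat)
  sets <- matrix(0L, n_node, nc)
  sets[seq_len(n_tip), ] <- matrix(bit[cmat], n_tip, nc)
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; v <- edges[e, 2]
    sv <- sets[v, ]; sp <- sets[p, ]
    inter <- bitwAnd(sp, sv)
    sets[p, ] <- ifelse(sp == 0L, sv, ifelse(inter > 0L, inter, bitwOr(sp, sv)))
  }
  states <- matrix(0L, n_node, nc)
  states[root, ] <- lowbit[sets[root, ]]
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1]; v <- edges[e, 2]
    keep <- bitwAnd(sets[v, ], bit[states[p, ]]) > 0L
    states[v, ] <- ifelse(keep, states[p, ], lowbit[sets[v, ]])
  }
  list(states = states, clean = clean)
}

# Midpoint-subdivided tree: every branch is split into an upper half (parent
# -> midpoint) and a lower half (midpoint -> child) so that a column's
# flanking context can follow the reconstructed flank states of both
# endpoints. Edge 2e-1 of the augmented tree is the lower half of original
# postorder edge e; edge 2e is its upper half.
augment_tree <- function(tree) {
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  E <- nrow(edges)
  n_node <- n_tip + tree$Nnode
  mid <- n_node + seq_len(E)
  aug <- matrix(0L, 2L * E, 2L)
  for (e in seq_len(E)) {
    aug[2L * e - 1L, ] <- c(mid[e], edges[e, 2])
    aug[2L * e, ] <- c(edges[e, 1], mid[e])
  }
  list(edge = aug, n_node = n_node + E, root = n_tip + 1L, n_half = 2L * E,
       group = rep(seq_len(E), each = 2L))
}

# Prepare the column-pattern sufficient statistics used by the fitter and the
# bootstrap. A column is usable when it and both flanking columns are gap-free
# in every species; region-boundary sites use phantom 'A' flanks. The flanking
# context of a column is fixed per branch HALF: the upper half of each branch
# uses the parsimony-reconstructed flank states of the parent node, the lower
# half those of the child node (events are placed at branch midpoints, so a
# flank change on the branch takes effect halfway down it).
# Also returns parsimony-count starting values for the EM.
aln_patterns <- function(alignments, tree, tables, split = TRUE,
                         boot_unit = c("block", "region"), block_size = 3L) {
  boot_unit <- match.arg(boot_unit)
  tip_order <- tree$tip.label
  n_tip <- length(tip_order)
  edges <- tree$edge
  n_edge <- nrow(edges)
  n_half <- if (split) 2L * n_edge else n_edge
  nq <- tables$n_qclass
  pow <- 4^(0:(n_tip - 1))
  # chunked encoding of the per-half context vector into exact doubles
  chunk <- max(1L, floor(50 / log2(nq)))
  starts <- seq(1L, n_half, by = chunk)

  keys <- list(); qmats <- list(); rootqs <- list(); rootstates <- list()
  blocks <- list(); regions <- list()
  ev_class <- numeric(tables$n_class)
  occ_state <- matrix(0, nq, 4) # context-state occurrences weighted later
  root_freq <- matrix(0, nq, 4) # root-context x reconstructed root state
  ev_edge <- numeric(n_edge)
  nblocks_per_region <- integer(length(alignments))
  n_usable_total <- 0L

  for (ri in seq_along(alignments)) {
    aln <- alignments[[ri]]
    stopifnot(inherits(aln, "region_alignment"))
    if (!setequal(rownames(aln$mat), tip_order)) {
      missing_sp <- setdiff(tip_order, rownames(aln$mat))
      extra_sp <- setdiff(rownames(aln$mat), tip_order)
      stop(sprintf("alignment '%s': species do not match tree (missing: %s; unknown: %s)",
                   aln$id, paste(missing_sp, collapse = ","),
                   paste(extra_sp, collapse = ",")))
    }
    mat <- aln$mat[tip_order, , drop = FALSE]
    L <- ncol(mat)
    nblocks_per_region[ri] <- if (boot_unit == "region") 1L else
      ceiling(L / block_size)
    clean <- colSums(is.na(mat)) == 0L
    usable <- clean & c(TRUE, clean[-L]) & c(clean[-1L], TRUE)
    if (!any(usable)) next
    fr <- fitch_reconstruct(mat, tree)
    idx <- which(usable)
    upos <- match(idx, fr$clean)
    lpos <- match(idx - 1L, fr$clean) # NA at region boundary
    rpos <- match(idx + 1L, fr$clean)
    nu <- length(idx)
    n_usable_total <- n_usable_total + nu
    qm <- matrix(0L, n_half, nu)
    ctx_of <- function(node) {
      lf <- ifelse(is.na(lpos), 1L, fr$states[node, ][lpos])
      rf <- ifelse(is.na(rpos), 1L, fr$states[node, ][rpos])
      tables$qidx[cbind(lf, rf)]
    }
    if (split) {
      for (e in seq_len(n_edge)) {
        qm[2L * e - 1L, ] <- ctx_of(edges[e, 2]) # lower half: child flanks
        qm[2L * e, ] <- ctx_of(edges[e, 1])      # upper half: parent flanks
      }
    } else {
      for (e in seq_len(n_edge)) qm[e, ] <- ctx_of(edges[e, 1])
    }
    rq <- ctx_of(n_tip + 1L)
    rs <- fr$states[n_tip + 1L, ][upos]
    rootstates[[length(rootstates) + 1L]] <- rs
    rf <- rowsum(rep(1, nu), group = rq * 10L + rs)
    g <- as.integer(rownames(rf))
    root_freq[cbind(g %/% 10L, g %% 10L)] <-
      root_freq[cbind(g %/% 10L, g %% 10L)] + rf[, 1]
    # parsimony starting values: events per edge and per class, with the
    # parent-node context of each original edge
    for (e in seq_len(n_edge)) {
      from <- fr$states[edges[e, 1], ][upos]
      to <- fr$states[edges[e, 2], ][upos]
      qe <- qm[if (split) 2L * e else e, ]
      occ <- rowsum(rep(1, nu), group = qe * 10L + from)
      g <- as.integer(rownames(occ))
      occ_state[cbind(g %/% 10L, g %% 10L)] <-
        occ_state[cbind(g %/% 10L, g %% 10L)] + occ[, 1]
      chg <- which(to != from)
      if (length(chg)) {
        ev_edge[e] <- ev_edge[e] + length(chg)
        kcl <- tables$cmap[cbind(qe[chg], from[chg], to[chg])]
        tb <- tabulate(kcl, nbins = tables$n_class)
        ev_class <- ev_class + tb
      }
    }
    key <- as.vector(crossprod(mat[, idx, drop = FALSE] - 1L, pow))
    qkeys <- vapply(starts, function(s0) {
      rows <- s0:min(s0 + chunk - 1L, n_edge)
      as.vector(crossprod(qm[rows, , drop = FALSE] - 1, nq^(seq_along(rows) - 1)))
    }, numeric(nu))
    if (nu == 1L) qkeys <- matrix(qkeys, nrow = 1L)
    keys[[length(keys) + 1L]] <-
      do.call(paste, c(list(key, rq), as.data.frame(qkeys), list(sep = "|")))
    qmats[[length(qmats) + 1L]] <- qm
    rootqs[[length(rootqs) + 1L]] <- rq
    blocks[[length(blocks) + 1L]] <- if (boot_unit == "region") {
      rep.int(1L, nu)
    } else ceiling(idx / block_size)
    regions[[length(regions) + 1L]] <- rep.int(ri, nu)
  }
  if (n_usable_total == 0L) stop("no usable (gap-free) columns in the alignments")

  keyv <- unlist(keys)
  uid <- match(keyv, unique(keyv))
  U <- max(uid)
  first <- match(seq_len(U), uid)
  qmat_all <- do.call(cbind, qmats)
  rootq_all <- unlist(rootqs)
  # tip-state columns in the same order as the keys were built
  tipcols <- list()
  for (ri in seq_along(alignments)) {
    aln <- alignments[[ri]]
    mat <- aln$mat[tip_order, , drop = FALSE]
    L <- ncol(mat)
    clean <- colSums(is.na(mat)) == 0L
    usable <- clean & c(TRUE, clean[-L]) & c(clean[-1L], TRUE)
    if (!any(usable)) next
    tipcols[[length(tipcols) + 1L]] <- mat[, which(usable), drop = FALSE]
  }
  tips_all <- do.call(cbind, tipcols)

  counts <- as.numeric(tabulate(uid, nbins = U))
  block_local <- unlist(blocks)
  region_of_col <- unlist(regions)
  offsets <- c(0L, cumsum(nblocks_per_region))
  block_global <- block_local + offsets[region_of_col]
  n_block <- offsets[length(offsets)]
  ord <- order(block_global)
  block_col_ptr <- c(0L, cumsum(tabulate(block_global[ord], nbins = n_block)))
  # resampling strata: with region units, all regions form one pool of
  # exchangeable units; with 3-column blocks, blocks are resampled within
  # their own region
  region_block_ptr <- if (boot_unit == "region") c(0L, n_block) else offsets

  # EM starting values from the parsimony counts (per branch half)
  t0 <- if (split) {
    pmax(rep(ev_edge / (2 * n_usable_total), each = 2L), 1e-4)
  } else {
    pmax(ev_edge / n_usable_total, 1e-4)
  }
  Tk <- numeric(tables$n_class)
  fl <- qclass_flags(tables)
  # occ_state sums context occurrences over all edges; scaling by the mean
  # starting branch length turns occurrences into approximate exposures
  texp <- occ_state * mean(t0)
  for (i in seq_len(nrow(fl))) {
    Tk[fl$class[i]] <- Tk[fl$class[i]] + texp[fl$qclass[i], fl$from[i]]
  }
  mu <- sum(ev_class) / max(sum(texp), 1e-12)
  r0 <- ifelse(Tk > 0, ev_class / Tk, 0)
  if (mu > 0) r0 <- r0 / mu
  r0 <- pmax(r0, 0.05)

  list(
    tips = tips_all[, first, drop = FALSE],
    qmat = qmat_all[, first, drop = FALSE],
    rootq = rootq_all[first],
    root_state = unlist(rootstates)[first],
    counts = counts,
    n_tip = n_tip, n_col = length(uid),
    block_col_ptr = as.integer(block_col_ptr),
    block_col_pattern = as.integer(uid[ord]),
    region_block_ptr = as.integer(region_block_ptr),
    init_rates = r0, init_t = t0, root_freq = root_freq
  )
}
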