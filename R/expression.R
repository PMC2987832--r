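#' Filter probe sets for imprinting analysis
#'
#' Drops probe sets that (i) never detect expression (detection p > 0.06 in
#' all three of MP, 0P and 00), (ii) do not map uniquely to the genome,
#' (iii) map to chromosome Y or to the Xist locus (to remove sex-specific
#' effects secondary to the obligate female gender of parthenogenetic
#' embryos), or (iv) are array controls (`AFFX` prefix). Filtering is
#' idempotent.
#'
#' @param probes probe table (see [read_probe_table()]).
#' @param detp_max detection p-value threshold (a probe is kept if at least
#'   one condition is at or below it).
#' @param xist_genes gene symbols treated as the Xist locus.
#' @return the filtered table, with a `"dropped"` attribute giving counts
#'   per filter.
#' @export
filter_probes <- function(probes, detp_max = 0.06, xist_genes = "Xist") {
  stopifnot(is.data.frame(probes))
  n0 <- nrow(probes)
  miss <- is.na(probes$chrom) | is.na(probes$gene_id) | is.na(probes$unique)
  if (any(miss)) {
    warning(sprintf("%d probe(s) lack annotation and were dropped", sum(miss)))
  }
  control <- !miss & grepl("^AFFX", probes$probe_id)
  undetected <- !miss & !control &
    probes$detp_MP > detp_max & probes$detp_0P > detp_max & probes$detp_00 > detp_max
  nonunique <- !miss & !control & !undetected & probes$unique != 1
  chry <- !miss & !control & !undetected & !nonunique &
    probes$chrom %in% c("chrY", "Y")
  xist <- !miss & !control & !undetected & !nonunique & !chry &
    probes$gene_id %in% xist_genes
  drop <- miss | control | undetected | nonunique | chry | xist
  out <- probes[!drop, , drop = FALSE]
  attr(out, "dropped") <- c(
    missing_annotation = sum(miss), control = sum(control),
    undetected = sum(undetected), non_unique = sum(nonunique),
    chrY = sum(chry), xist = sum(xist), total = n0 - nrow(out)
  )
  out
}

#' Score probes for maternal- and paternal-imprint-dependent expression
#'
#' The maternal scheme scores 1 when a probe is significantly changed in both
#' 0P and 00 relative to MP (both lack maternal imprints), in the same
#' direction, and is NOT changed between 00 and 0P. The paternal scheme
#' scores 1 when a probe is significantly changed in 00 relative to both 0P
#' and MP (only 00 lacks paternal imprints), in the same direction, and is
#' NOT changed between 0P and MP. The two patterns are mutually exclusive by
#' construction (each requires significance of a contrast the other requires
#' to be non-significant).
#'
#' @param probes filtered probe table.
#' @param alpha significance threshold for the contrast p-values.
#' @return data.frame `probe_id, gene_id, maternal, paternal, direction,
#'   min_abs_lr` where `direction` is `"up"`, `"down"` or `"none"` and
#'   `min_abs_lr` is the smaller absolute log2 ratio of the two
#'   required-significant contrasts (NA for unscored probes).
#' @export
score_probes <- function(probes, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  m <- probes$p_0PvMP < alpha & probes$p_00vMP < alpha &
    sign(probes$lr_0PvMP) == sign(probes$lr_00vMP) &
    probes$lr_0PvMP != 0 &
    probes$p_00v0P >= alpha
  p <- probes$p_00v0P < alpha & probes$p_00vMP < alpha &
    sign(probes$lr_00v0P) == sign(probes$lr_00vMP) &
    probes$lr_00v0P != 0 &
    probes$p_0PvMP >= alpha
  dir <- rep("none", nrow(probes))
  dir[m] <- ifelse(probes$lr_00vMP[m] > 0, "up", "down")
  dir[p] <- ifelse(probes$lr_00vMP[p] > 0, "up", "down")
  minlr <- rep(NA_real_, nrow(probes))
  minlr[m] <- pmin(abs(probes$lr_0PvMP[m]), abs(probes$lr_00vMP[m]))
  minlr[p] <- pmin(abs(probes$lr_00v0P[p]), abs(probes$lr_00vMP[p]))
  data.frame(
    probe_id = probes$probe_id, gene_id = probes$gene_id,
    maternal = as.integer(m), paternal = as.integer(p),
    direction = dir, min_abs_lr = minlr,
    stringsAsFactors = FALSE
  )
}

#' Break scored probes down by minimally detected fold change
#'
#' For each fold-change threshold, counts the scored probes whose smaller
#' absolute log2 ratio (over the two required-significant contrasts) reaches
#' the threshold: a decrease "to 80%" corresponds to a log2 cutoff of
#' `log2(0.8) = -0.322`, an increase "to 125%" to `+0.322`. Counts are
#' cumulative in the usual sense: a probe halving its expression is included
#' in the "to 80%" bin as well.
#'
#' @param scores output of [score_probes()].
#' @param decrease_to,increase_to fold-change thresholds in (0,1) and
#'   (1, Inf) respectively.
#' @return data.frame with parent, direction, threshold (fold change), the
#'   log2 cutoff and the probe count.
#' @export
fold_change_bins <- function(scores,
                             decrease_to = c(0.8, 2/3, 0.5),
                             increase_to = c(1.25, 1.5, 2)) {
  stopifnot(all(decrease_to > 0 & decrease_to < 1), all(increase_to > 1))
  rows <- list()
  for (parent in c("maternal", "paternal")) {
    sel <- scores[[parent]] == 1L
    for (thr in decrease_to) {
      cutoff <- log2(thr)
      n <- sum(sel & scores$direction == "down" & -scores$min_abs_lr <= cutoff,
               na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        parent = parent, direction = "down", fold = thr,
        log2_cutoff = cutoff, n = n)
    }
    for (thr in increase_to) {
      cutoff <- log2(thr)
      n <- sum(sel & scores$direction == "up" & scores$min_abs_lr >= cutoff,
               na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        parent = parent, direction = "up", fold = thr,
        log2_cutoff = cutoff, n = n)
    }
  }
  do.call(rbind, rows)
}

#' Report expression ratios for a panel of known imprinted genes
#'
#' For each panel gene, reports the three pairwise log2 expression ratios
#' (0P/MP, 00/MP, 00/0P) of its probes with a significance flag (`*`) per
#' contrast at the given threshold. Genes absent from the table are reported
#' as absent rather than erroring.
#'
#' @param probes probe table.
#' @param panel data.frame with columns `gene` and `parent` (parental origin
#'   of the controlling ICR's methylation); defaults to the classic
#'   mouse imprinted-gene panel.
#' @param p_threshold significance threshold for the flags.
#' @return data.frame, one row per panel gene x probe (or a single `absent`
#'   row for missing genes).
#' @export
imprinted_panel_report <- function(probes, panel = imprinted_gene_panel(),
                                   p_threshold = 0.003) {
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    g <- panel$gene[i]
    sel <- which(probes$gene_id == g)
    if (length(sel) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, parent = panel$parent[i], probe_id = NA_character_,
        absent = TRUE, lr_0PvMP = NA_real_, sig_0PvMP = "",
        lr_00vMP = NA_real_, sig_00vMP = "", lr_00v0P = NA_real_,
        sig_00v0P = "", stringsAsFactors = FALSE)
      next
    }
    for (j in sel) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, parent = panel$parent[i], probe_id = probes$probe_id[j],
        absent = FALSE,
        lr_0PvMP = probes$lr_0PvMP[j],
        sig_0PvMP = if (probes$p_0PvMP[j] < p_threshold) "*" else "",
        lr_00vMP = probes$lr_00vMP[j],
        sig_00vMP = if (probes$p_00vMP[j] < p_threshold) "*" else "",
        lr_00v0P = probes$lr_00v0P[j],
        sig_00v0P = if (probes$p_00v0P[j] < p_threshold) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classic mouse imprinted-gene panel
#'
#' Known imprinted genes with the parental origin of the methylation mark on
#' their controlling ICR and the direction of misexpression expected when
#' that mark is absent.
#'
#' @return data.frame with columns gene, parent, direction.
#' @export
imprinted_gene_panel <- function() {
  data.frame(
    gene = c("Airn", "Zac1", "Kcnq1ot1", "Cdkn1c", "Grb10", "Igf2r",
             "H19", "Gtl2", "Igf2", "Dlk1"),
    parent = c(rep("maternal", 6), rep("paternal", 4)),
    direction = c("up", "up", "up", "down", "down", "down",
                  "up", "up", "down", "down"),
    stringsAsFactors = FALSE
  )
}
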