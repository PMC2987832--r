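#' @title CpG composition statistics
#' @name cpg_stats
NULL

# Encode an A/C/G/T/N string (case-insensitive) as integer codes 1..4, NA for N.
# Errors on empty input and on characters outside the alphabet.
seq_codes <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) stop("empty input")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  codes <- match(chars, c(BASES, "N"))
  if (anyNA(codes)) {
    bad <- chars[which(is.na(codes))[1L]]
    stop(sprintf("invalid character '%s' in sequence (alphabet is A,C,G,T,N)", bad))
  }
  codes[codes == 5L] <- NA_integer_
  codes
}

#' Observed/expected CpG statistics of a nucleotide sequence
#'
#' Counts C, G and CG-dinucleotide occurrences and computes the
#' observed/expected CpG ratio `(nCpG * length) / (nC * nG)`
#' (Gardiner-Garden convention, with the ungapped non-N length in the
#' numerator). `N` positions are masked: they contribute neither to `length`
#' nor to the base counts, and a dinucleotide position spanning an `N` is not
#' counted (neither as CpG nor in `n_dinuc`).
#'
#' @param seq a single character string over A,C,G,T,N (case-insensitive).
#' @return a list of class `cpg_stats` with elements `length`, `nC`, `nG`,
#'   `nCpG`, `n_dinuc` (number of counted dinucleotide positions) and
#'   `obs_exp` (0 when `nC * nG == 0`).
#' @examples
#' cpg_stats("ACGCGT")$obs_exp # 3
#' @export
cpg_stats <- function(seq) {
  codes <- seq_codes(seq)
  cpg_stats_codes(codes)
}

cpg_stats_codes <- function(codes) {
  ok <- !is.na(codes)
  len <- sum(ok)
  nC <- sum(codes == 2L, na.rm = TRUE)
  nG <- sum(codes == 3L, na.rm = TRUE)
  n <- length(codes)
  if (n >= 2L) {
    a <- codes[-n]
    b <- codes[-1L]
    valid <- !is.na(a) & !is.na(b)
    n_dinuc <- sum(valid)
    nCpG <- sum(valid & a == 2L & b == 3L)
  } else {
    n_dinuc <- 0L
    nCpG <- 0L
  }
  oe <- if (nC * nG == 0) 0 else (nCpG * len) / (nC * nG)
  structure(
    list(length = len, nC = nC, nG = nG, nCpG = nCpG,
         n_dinuc = n_dinuc, obs_exp = oe),
    class = "cpg_stats"
  )
}

#' @export
print.cpg_stats <- function(x, ...) {
  cat(sprintf(
    "CpG stats: length=%d nC=%d nG=%d nCpG=%d obs/exp=%.4f\n",
    x$length, x$nC, x$nG, x$nCpG, x$obs_exp
  ))
  invisible(x)
}

#' Pooled CpG statistics for a sequence category
#'
#' Pools base and dinucleotide counts across all records of one category and
#' applies the observed/expected formula to the pooled counts. The
#' mean-of-per-record-ratios is also returned for comparison, since a single
#' per-category value can be computed either way; the pooled-count value is
#' the primary one.
#'
#' @param seqs character vector of sequences (all of the same category).
#' @param category optional character vector of per-record category labels;
#'   if supplied, all must be identical.
#' @return list with `pooled` (a `cpg_stats` object on summed counts),
#'   `per_record` (data.frame of per-record stats) and `mean_ratio`.
#' @export
category_ratio <- function(seqs, category = NULL) {
  if (length(seqs) < 1L) stop("need at least one record")
  if (!is.null(category) && length(unique(category)) > 1L) {
    stop("mixed categories: ", paste(unique(category), collapse = ", "))
  }
  per <- lapply(seqs, cpg_stats)
  df <- data.frame(
    length = vapply(per, `[[`, 0L, "length"),
    nC = vapply(per, `[[`, 0L, "nC"),
    nG = vapply(per, `[[`, 0L, "nG"),
    nCpG = vapply(per, `[[`, 0L, "nCpG"),
    n_dinuc = vapply(per, `[[`, 0L, "n_dinuc"),
    obs_exp = vapply(per, `[[`, 0, "obs_exp")
  )
  if (!is.null(names(seqs))) rownames(df) <- names(seqs)
  len <- sum(df$length); nC <- sum(df$nC); nG <- sum(df$nG)
  nCpG <- sum(df$nCpG); nd <- sum(df$n_dinuc)
  oe <- if (nC * nG == 0) 0 else (nCpG * len) / (nC * nG)
  pooled <- structure(
    list(length = len, nC = nC, nG = nG, nCpG = nCpG, n_dinuc = nd, obs_exp = oe),
    class = "cpg_stats"
  )
  list(pooled = pooled, per_record = df, mean_ratio = mean(df$obs_exp))
}

#' Fisher's exact comparison of CpG content between two categories
#'
#' Builds the 2x2 table of CpG versus non-CpG counted dinucleotide positions
#' for the two pooled statistics and applies Fisher's exact test (two-sided,
#' summing the probabilities of tables at most as probable as the observed
#' one).
#'
#' @param statsA,statsB `cpg_stats` objects (pooled or single-sequence).
#' @return list with `odds_ratio` (sample odds ratio of the 2x2 table),
#'   `p` and `table`.
#' @export
fisher_cpg_comparison <- function(statsA, statsB) {
  stopifnot(inherits(statsA, "cpg_stats"), inherits(statsB, "cpg_stats"))
  if (statsA$n_dinuc < 1L || statsB$n_dinuc < 1L) {
    stop("both categories need at least one counted dinucleotide")
  }
  tab <- matrix(
    c(statsA$nCpG, statsA$n_dinuc - statsA$nCpG,
      statsB$nCpG, statsB$n_dinuc - statsB$nCpG),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("A", "B"), c("CpG", "non_CpG"))
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin in 2x2 table")
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = ft$p.value, table = tab)
}

#' Promoter CpG-content class (high / intermediate / low)
#'
#' Assigns the sliding-window promoter classification: 500-bp windows at 5-bp
#' steps; HCP if any window has observed/expected CpG ratio > 0.75 and GC
#' fraction > 0.55; LCP if no window reaches obs/exp > 0.48; ICP otherwise.
#' "HI" promoters are the union of HCP and ICP.
#'
#' @param seq a nucleotide string of length >= 500.
#' @param window,step window size and step in bp.
#' @return one of `"HCP"`, `"ICP"`, `"LCP"`.
#' @export
weber_promoter_class <- function(seq, window = 500L, step = 5L) {
  codes <- seq_codes(seq)
  n <- length(codes)
  if (n < window) stop(sprintf("sequence shorter than one %d-bp window", window))
  ok <- !is.na(codes)
  isC <- ok & codes == 2L
  isG <- ok & codes == 3L
  a <- codes[-n]; b <- codes[-1L]
  isCpG <- c(!is.na(a) & !is.na(b) & a == 2L & b == 3L, FALSE)
  cum <- function(x) c(0, cumsum(x))
  cN <- cum(ok); cC <- cum(isC); cG <- cum(isG); cCpG <- cum(isCpG)
  starts <- seq.int(1L, n - window + 1L, by = step)
  ends <- starts + window - 1L
  wlen <- cN[ends + 1L] - cN[starts]
  wC <- cC[ends + 1L] - cC[starts]
  wG <- cG[ends + 1L] - cG[starts]
  # CpG dinucleotides fully inside the window: start positions start..end-1
  wCpG <- cCpG[ends] - cCpG[starts]
  oe <- ifelse(wC * wG == 0, 0, (wCpG * wlen) / (wC * wG))
  gc <- ifelse(wlen == 0, 0, (wC + wG) / wlen)
  if (any(oe > 0.75 & gc > 0.55)) return("HCP")
  if (all(oe <= 0.48)) return("LCP")
  "ICP"
}

#' Reverse complement of a nucleotide string
#'
#' @param seq character string over A,C,G,T,N.
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan", paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}
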