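#' Fit a strand-symmetric context-dependent substitution model
#'
#' Maximizes the composite likelihood of a set of region alignments on a
#' fixed rooted topology: the likelihood is the product over gap-free columns
#' of the pruning-algorithm likelihood of the central site. Each branch is
#' split at its midpoint; the central site's 4x4 generator on the upper half
#' is selected by the parsimony-reconstructed flank states of the parent
#' node and on the lower half by those of the child node, so a flank change
#' on the branch takes effect halfway down it (on trees of up to three tips,
#' where every flank difference is a reconstruction tie, contexts stay at
#' the parent node). Tied rate classes (strand-symmetric by construction),
#' per-branch lengths and per-context root distributions are alternately
#' updated by closed-form expectation-maximization steps until the log
#' composite likelihood improves by less than `tol` or `max_iter` rounds are
#' reached. On return, rates are rescaled so that the exposure-weighted mean
#' substitution rate is 1; each rate is then the frequency of that
#' substitution relative to all substitutions, and branch lengths are in
#' substitutions per site.
#'
#' @param alignments a `region_alignment` or list of them (one category).
#' @param tree rooted `phylo` topology. Its branch lengths, if any, are used
#'   only as starting values.
#' @param model_type `"cpg"` for the reduced CpG-aware parameterization
#'   (baseline transition, transversion, CpG-deamination and CpG-gain rates)
#'   or `"u3s"` for the full 96-orbit trinucleotide context model.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood improvement).
#' @param init optional `context_model` supplying starting rates.
#' @param root handling of the per-column root distribution. `"freq"` fixes
#'   the per-context root prior at the frequencies of the
#'   parsimony-reconstructed root states; `"fitch"` plugs in each column's
#'   reconstructed root state (lightly smoothed); `"mle"` estimates a free
#'   per-context root distribution by EM. On very shallow (especially
#'   two-taxon) data the root distribution is only weakly identified jointly
#'   with substitution direction, so the free-root likelihood has a ridge;
#'   anchoring the root keeps the direction convention consistent with
#'   [count_events_parsimony()]. The default `"auto"` uses `"fitch"` for
#'   trees of up to 3 tips and `"freq"` otherwise.
#' @return an object of class `icr_fit` with components `model` (fitted
#'   `context_model`), `tree` (with fitted edge lengths), `logCL`, `rates`,
#'   `exposure` (per context class and state), `summary` rate aggregates,
#'   `converged`, `degenerate` and the pattern bookkeeping used by
#'   [bootstrap_rates()].
#' @seealso [cpg_loss_rate()], [cpg_gain_rate()], [bootstrap_rates()],
#'   [count_events_parsimony()]
#' @export
fit_context_model <- function(alignments, tree, model_type = c("cpg", "u3s"),
                              max_iter = 200L, tol = 1e-6, init = NULL,
                              root = c("auto", "fitch", "freq", "mle"),
                              boot_unit = c("block", "region"),
                              block_size = 3L) {
  model_type <- match.arg(model_type)
  if (inherits(alignments, "region_alignment")) alignments <- list(alignments)
  stopifnot(length(alignments) >= 1L, inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("need at least two species")
  tables <- class_tables(model_type)
  tree <- ape::reorder.phylo(tree, "postorder")
  # the midpoint subdivision only carries information when flank changes can
  # be placed on a branch; on two- or three-taxon trees every flank
  # difference is a reconstruction tie, so contexts stay at the parent node
  split <- length(tree$tip.label) > 3L
  prep <- aln_patterns(alignments, tree, tables, split = split,
                       boot_unit = boot_unit, block_size = block_size)
  category <- unique(vapply(alignments, `[[`, "", "category"))

  n_edge <- nrow(tree$edge)
  root_node <- length(tree$tip.label) + 1L
  aug <- if (split) augment_tree(tree) else {
    list(edge = matrix(as.integer(tree$edge), ncol = 2L),
         n_node = length(tree$tip.label) + tree$Nnode,
         root = root_node, n_half = n_edge, group = seq_len(n_edge))
  }

  # starting values: parsimony counting estimates unless supplied
  if (is.null(init)) {
    rates0 <- prep$init_rates
  } else {
    stopifnot(inherits(init, "context_model"), init$type == model_type)
    rates0 <- pmax(unname(init$rates), 1e-6)
  }
  t0 <- prep$init_t
  pi0 <- root_pi(prep)

  root <- match.arg(root)
  if (root == "auto") {
    # the root state is effectively determined by parsimony only on very
    # shallow trees; on deeper trees the pruning posterior handles it
    root <- if (length(tree$tip.label) <= 3L) "fitch" else "freq"
  }
  opts <- em_opts(max_iter = max_iter, tol = tol,
                  estimate_pi = (root == "mle"))
  root_state <- if (root == "fitch") prep$root_state else
    rep(0L, length(prep$root_state))
  # alignments with no variable column carry no substitution signal at all
  no_signal <- !any(col_has_variation(prep$tips))
  if (no_signal) opts$max_iter <- 2L
  fit <- em_fit_cpp(prep$tips, prep$qmat, prep$rootq, as.integer(root_state),
                    prep$counts,
                    as.integer(tables$cmap), tables$n_qclass, tables$n_class,
                    aug$edge, as.integer(aug$group), aug$n_node, root_node,
                    t0, rates0, pi0, opts)
  if (no_signal) {
    fit$degenerate <- TRUE
    fit$edge_length <- rep(0, aug$n_half)
    fit$rates <- rep(NA_real_, tables$n_class)
  }
  if (fit$degenerate) {
    warning("alignment carries no substitution signal; rates are undefined")
  } else if (!fit$converged) {
    warning(sprintf("EM did not converge within %d rounds", max_iter))
  }
  ftree <- tree
  half_len <- as.numeric(fit$edge_length)
  ftree$edge.length <- if (split) {
    half_len[seq(1L, 2L * n_edge, by = 2L)] + half_len[seq(2L, 2L * n_edge, by = 2L)]
  } else half_len
  rates <- setNames(as.numeric(fit$rates), tables$class_names)
  model <- new_context_model(model_type, rates, trinuc_composition())
  expo <- fit$state_exposure
  structure(
    list(
      model = model, tree = ftree, logCL = fit$logCL,
      rates = rates, exposure = expo, pi = fit$pi,
      class_events = setNames(as.numeric(fit$class_events), tables$class_names),
      class_exposure = setNames(as.numeric(fit$class_exposure), tables$class_names),
      summary = rate_summary(rates, expo, model_type),
      iterations = fit$iterations, converged = fit$converged,
      degenerate = fit$degenerate,
      category = if (length(category) == 1L) category else "mixed",
      n_columns = sum(prep$counts), n_patterns = ncol(prep$tips),
      prep = prep, tables = tables, aug = aug, half_lengths = half_len,
      opts = opts, root_mode = root
    ),
    class = "icr_fit"
  )
}

em_opts <- function(max_iter = 200L, tol = 1e-6, min_rate = 1e-12,
                    min_t = 1e-10, estimate_pi = FALSE, renormalize = TRUE,
                    inner_iter = 8L) {
  list(max_iter = as.integer(max_iter), tol = tol, min_rate = min_rate,
       min_t = min_t, estimate_pi = estimate_pi, renormalize = renormalize,
       inner_iter = as.integer(inner_iter))
}

# TRUE for pattern columns with more than one tip state
col_has_variation <- function(tips) {
  colSums(tips != tips[rep(1L, nrow(tips)), , drop = FALSE]) > 0L
}

# root prior per context: smoothed frequencies of the reconstructed root states
root_pi <- function(prep) {
  rf <- prep$root_freq + 0.5
  rf / rowSums(rf)
}

# ---- rate aggregates -----------------------------------------------------

# Exposure-weighted aggregates over sets of context-substitutions.
# Numerator: sum over set members of exposure(qclass, from) * rate(class);
# denominator: exposure summed once per distinct (qclass, from) in the set.
rate_summary <- function(rates, state_exposure, type) {
  tables <- class_tables(type)
  fl <- qclass_flags(tables)
  expo <- state_exposure[cbind(fl$qclass, fl$from)]
  r <- rates[fl$class]
  agg <- function(sel) {
    if (!any(sel)) return(NA_real_)
    num <- sum(expo[sel] * r[sel])
    states <- unique(fl[sel, c("qclass", "from")])
    den <- sum(state_exposure[cbind(states$qclass, states$from)])
    if (den <= 0) return(NA_real_)
    num / den
  }
  loss_deam <- agg(fl$loss_deam)
  loss_total <- agg(fl$loss_any)
  gain_tpg <- agg(fl$gain_tpg)
  gain_total <- agg(fl$gain_any)
  baseline_ts <- agg(fl$transition & fl$neutral_cpg)
  baseline_tv <- agg(!fl$transition & fl$neutral_cpg)
  c(
    loss_deam = loss_deam, loss_total = loss_total,
    gain_tpg = gain_tpg, gain_total = gain_total,
    baseline_ts = baseline_ts, baseline_tv = baseline_tv,
    loss_vs_baseline = loss_deam / baseline_ts,
    gain_vs_baseline = gain_tpg / baseline_ts
  )
}

#' CpG loss rate of a fitted model
#'
#' The primary value is the deamination component: the exposure-weighted
#' relative rate of C>T substitution with a G on the right (identically, G>A
#' with a C on the left, by strand symmetry). The secondary value aggregates
#' every substitution that destroys an existing CpG. `vs_baseline` expresses
#' the deamination rate relative to the category's own baseline (CpG-neutral)
#' transition rate; this contrast is invariant to the category's overall
#' substitution intensity and is the quantity compared across categories.
#'
#' @param fit an `icr_fit`.
#' @return named vector `c(deam, total, vs_baseline)`.
#' @export
cpg_loss_rate <- function(fit) {
  stopifnot(inherits(fit, "icr_fit"))
  s <- fit$summary
  c(deam = unname(s["loss_deam"]), total = unname(s["loss_total"]),
    vs_baseline = unname(s["loss_vs_baseline"]))
}

#' CpG gain rate of a fitted model
#'
#' The primary value aggregates all substitutions that create a CpG where
#' none existed; `tpg_cpa` is the restricted TpG>CpG / CpA>CpG (transition)
#' variant; `vs_baseline` is the restricted variant relative to the baseline
#' transition rate.
#'
#' @param fit an `icr_fit`.
#' @return named vector `c(all, tpg_cpa, vs_baseline)`.
#' @export
cpg_gain_rate <- function(fit) {
  stopifnot(inherits(fit, "icr_fit"))
  s <- fit$summary
  c(all = unname(s["gain_total"]), tpg_cpa = unname(s["gain_tpg"]),
    vs_baseline = unname(s["gain_vs_baseline"]))
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.icr_fit <- function(x, ...) {
  cat(sprintf("Context-dependent substitution model fit (%s), category '%s'\n",
              x$model$type, x$category))
  cat(sprintf("  %d columns (%d unique patterns), %d species\n",
              round(x$n_columns), x$n_patterns, length(x$tree$tip.label)))
  cat(sprintf("  log composite likelihood: %.2f (%d EM rounds%s)\n",
              x$logCL, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  if (x$degenerate) {
    cat("  no substitution signal; rates undefined\n")
    return(invisible(x))
  }
  s <- x$summary
  cat(sprintf("  CpG loss (deamination): %.4f   CpG gain (TpG/CpA): %.4f\n",
              s["loss_deam"], s["gain_tpg"]))
  cat(sprintf("  relative to baseline transitions: loss %.2fx, gain %.2fx\n",
              s["loss_vs_baseline"], s["gain_vs_baseline"]))
  cat(sprintf("  total tree length: %.4f subs/site\n", sum(x$tree$edge.length)))
  invisible(x)
}

#' @export
summary.icr_fit <- function(object, ...) {
  out <- list(
    category = object$category,
    rates = object$rates,
    aggregates = object$summary,
    tree_length = sum(object$tree$edge.length),
    logCL = object$logCL,
    converged = object$converged
  )
  class(out) <- "summary.icr_fit"
  out
}

#' @export
print.summary.icr_fit <- function(x, ...) {
  cat("Rate aggregates (relative, exposure-weighted mean rate = 1):\n")
  print(round(x$aggregates, 4))
  cat(sprintf("Total tree length: %.4f subs/site; logCL = %.2f\n",
              x$tree_length, x$logCL))
  invisible(x)
}

#' @export
coef.icr_fit <- function(object, ...) object$rates

#' @export
logLik.icr_fit <- function(object, ...) {
  structure(object$logCL, df = length(object$rates) + nrow(object$tree$edge),
            class = "logLik")
}

#' Simulate alignments from a fitted model
#'
#' @param object an `icr_fit`.
#' @param nsim number of region alignments.
#' @param seed optional seed.
#' @param root_length root sequence length.
#' @param ... unused.
#' @return list of `region_alignment`s simulated under the fitted rates and
#'   branch lengths.
#' @export
simulate.icr_fit <- function(object, nsim = 1, seed = NULL,
                             root_length = 1000L, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_alignment(object$tree, object$model, root_length,
                       id = sprintf("sim_%03d", i), category = object$category)
  })
}

#' @export
plot.icr_fit <- function(x, ...) {
  s <- x$summary[c("loss_deam", "gain_tpg", "baseline_ts", "baseline_tv")]
  graphics::barplot(s, ylab = "relative substitution rate",
                    names.arg = c("CpG loss\n(deamination)", "CpG gain\n(TpG/CpA)",
                                  "transition", "transversion"),
                    main = sprintf("Fitted context-dependent rates (%s)", x$category),
                    ...)
  invisible(x)
}
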