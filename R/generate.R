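#' Scenario for synthetic sequence-category evolution
#'
#' Defines the forward model used to emulate the comparative-genomics stage:
#' per-category substitution parameters (baseline transition/transversion
#' rates, CpG-deamination and CpG-gain multipliers), a root CpG composition,
#' and the sampling scale. The defaults encode the study conditions: a
#' paternal-like category whose CpG-deamination rate is 1.5-fold that of a
#' maternal-like category (multipliers 15 versus 10 over the baseline
#' transition rate, the classical tenfold elevation of methylated-CpG
#' deamination), 50 regions of 2 kb per category on the packaged 16-species
#' euarchontoglire tree.
#'
#' @param tree rooted `phylo`; defaults to [euarchontoglires_tree()].
#' @param regions regions per category.
#' @param length region length (bp).
#' @param categories named list; each element has `deam`, `gain`, `ts`, `tv`,
#'   `gc` and `cpg_obs_exp` entries (missing entries take the defaults
#'   `ts=1, tv=0.25, gain=2, gc=0.5, cpg_obs_exp=0.5`).
#' @return a `sequence_scenario` list.
#' @export
sequence_scenario <- function(tree = NULL, regions = 50L, length = 2000L,
                              categories = list(
                                paternal_like = list(deam = 15),
                                maternal_like = list(deam = 10)
                              )) {
  stopifnot(regions >= 1L, length >= 3L, base::length(categories) >= 1L)
  defaults <- list(ts = 1, tv = 0.25, deam = 10, gain = 2,
                   gc = 0.5, cpg_obs_exp = 0.5)
  categories <- lapply(categories, function(p) {
    p <- utils::modifyList(defaults, p)
    stopifnot(p$deam > 0, p$gain > 0, p$ts > 0)
    p
  })
  structure(list(tree = tree, regions = as.integer(regions),
                 length = as.integer(length), categories = categories),
            class = "sequence_scenario")
}

#' Generate evolved sequence categories with known rates
#'
#' Draws root sequences with category-appropriate CpG density, evolves them
#' along the tree under a reduced CpG-aware context model (scaled to unit
#' mean substitution rate at the root composition, so branch lengths read as
#' substitutions/site), and records the exact relative rates implied by the
#' generating parameters: the CpG-deamination and CpG-gain multipliers over
#' the baseline transition rate, per category, and every pairwise
#' deamination-rate ratio.
#'
#' @param scenario a [sequence_scenario()].
#' @param seed integer seed (required: the generator is a pure function of
#'   scenario + seed).
#' @return list with `alignments` (named list of `region_alignment` lists),
#'   `models` (the generating `context_model`s, unscaled), `truth`
#'   (data.frame of per-category true multipliers), `loss_ratios`
#'   (named vector of pairwise deamination ratios) and `tree`.
#' @export
gen_sequence_categories <- function(scenario, seed) {
  stopifnot(inherits(scenario, "sequence_scenario"))
  set.seed(seed)
  tree <- scenario$tree
  if (is.null(tree)) tree <- euarchontoglires_tree()
  out_aln <- list(); models <- list()
  for (nm in names(scenario$categories)) {
    p <- scenario$categories[[nm]]
    comp <- trinuc_composition(gc = p$gc, cpg_obs_exp = p$cpg_obs_exp)
    model <- cpg_context_model(ts = p$ts, tv = p$tv,
                               deam = p$deam * p$ts, gain = p$gain * p$ts,
                               root_comp = comp)
    smodel <- scale_to_unit_rate(model)
    out_aln[[nm]] <- lapply(seq_len(scenario$regions), function(i) {
      simulate_alignment(tree, smodel, scenario$length,
                         id = sprintf("%s_%03d", nm, i), category = nm)
    })
    models[[nm]] <- model
  }
  truth <- data.frame(
    category = names(scenario$categories),
    deam_multiplier = vapply(scenario$categories, function(p) p$deam, 0),
    gain_multiplier = vapply(scenario$categories, function(p) p$gain, 0),
    row.names = NULL
  )
  ratios <- c()
  nms <- names(scenario$categories)
  if (length(nms) >= 2L) {
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i == j) next
      ratios[sprintf("%s/%s", nms[i], nms[j])] <-
        scenario$categories[[i]]$deam / scenario$categories[[j]]$deam
    }
  }
  list(alignments = out_aln, models = models, truth = truth,
       loss_ratios = ratios, tree = tree, seed = seed)
}

# rescale a model so the mean substitution rate at its root composition is 1
scale_to_unit_rate <- function(model) {
  arr <- rate_array(model)
  f <- unclass(model$root_comp)
  mu <- 0
  for (l in 1:4) for (x in 1:4) for (r in 1:4) {
    mu <- mu + f[l, x, r] * sum(arr[l, x, r, ])
  }
  scaled <- model
  scaled$rates <- model$rates / mu
  scaled
}

#' Scenario for a synthetic three-epigenotype expression dataset
#'
#' Emulates the probe-level summary table of an MP / 0P / 00 microarray
#' comparison: maternal-imprint-dependent probes shift identically in 0P and
#' 00 relative to MP; paternal-imprint-dependent probes shift in 00 only.
#' Contrast p-values come from an exact signed-rank test over simulated
#' probe-pair differences, as a stand-in for probe-level comparison
#' analysis. Defaults follow the study scale: 45,101 probe sets of 11 probe
#' pairs, 1695 maternal- and 1582 paternal-affected probe sets.
#'
#' @param n_probes,n_maternal,n_paternal probe-set counts.
#' @param effect_min,effect_shape,effect_scale |log2 fold change| of affected
#'   probes is `effect_min + Gamma(effect_shape, scale = effect_scale)`.
#' @param noise_sd per-probe-pair intensity noise (log2 scale); 0 gives a
#'   noise-free, perfectly separable dataset.
#' @param pairs probe pairs per probe set (signed-rank sample size).
#' @param frac_indirect fraction of the maternal-affected set modelled as
#'   downstream (indirect) targets: they follow the maternal pattern but are
#'   flagged `indirect` in the truth table.
#' @param frac_expressed fraction of unaffected probes that are expressed.
#' @return an `expression_scenario` list.
#' @export
expression_scenario <- function(n_probes = 45101L, n_maternal = 1695L,
                                n_paternal = 1582L, effect_min = 0.3,
                                effect_shape = 1.2, effect_scale = 0.4,
                                noise_sd = 0.12, pairs = 11L,
                                frac_indirect = 0.3, frac_expressed = 0.6) {
  stopifnot(n_maternal + n_paternal <= n_probes, noise_sd >= 0, pairs >= 5L)
  structure(
    list(n_probes = as.integer(n_probes), n_maternal = as.integer(n_maternal),
         n_paternal = as.integer(n_paternal), effect_min = effect_min,
         effect_shape = effect_shape, effect_scale = effect_scale,
         noise_sd = noise_sd, pairs = as.integer(pairs),
         frac_indirect = frac_indirect, frac_expressed = frac_expressed),
    class = "expression_scenario"
  )
}

#' Generate a synthetic probe-level expression dataset with ground truth
#'
#' @param scenario an [expression_scenario()].
#' @param seed integer seed.
#' @return list with `probes` (a probe table as in [read_probe_table()]) and
#'   `truth` (probe_id, label in maternal/paternal/none, direct flag,
#'   direction, effect size).
#' @export
gen_expression_dataset <- function(scenario, seed) {
  stopifnot(inherits(scenario, "expression_scenario"))
  set.seed(seed)
  n <- scenario$n_probes
  panel <- imprinted_gene_panel()
  npanel <- nrow(panel)
  # ids and annotation
  probe_id <- sprintf("ps_%05d_at", seq_len(n))
  gene_id <- sprintf("g%05d", seq_len(n))
  dup <- sample.int(n, max(1L, round(0.03 * n))) # some genes carry two probes
  gene_id[dup] <- gene_id[pmax(dup - 1L, 1L)]
  chrom <- sample(paste0("chr", 1:19), n, replace = TRUE)
  uniq <- rep(1L, n)
  # special probes exercising the filters
  special <- sample.int(n, npanel + 10L)
  panel_idx <- special[seq_len(npanel)]
  gene_id[panel_idx] <- panel$gene
  chry_idx <- special[npanel + 1:3]; chrom[chry_idx] <- "chrY"
  xist_idx <- special[npanel + 4L]; gene_id[xist_idx] <- "Xist"; chrom[xist_idx] <- "chrX"
  nonuniq_idx <- special[npanel + 5:6]; uniq[nonuniq_idx] <- 0L
  ctrl_idx <- special[npanel + 7:10]
  probe_id[ctrl_idx] <- sprintf("AFFX-ctrl_%02d", seq_along(ctrl_idx))
  excluded <- c(chry_idx, xist_idx, nonuniq_idx, ctrl_idx)

  # imprint labels (panel probes keep their published direction)
  eligible <- setdiff(seq_len(n), c(panel_idx, excluded))
  mat_extra <- sample(eligible,
                      max(0L, scenario$n_maternal - sum(panel$parent == "maternal")))
  pat_extra <- sample(setdiff(eligible, mat_extra),
                      max(0L, scenario$n_paternal - sum(panel$parent == "paternal")))
  label <- rep("none", n)
  label[mat_extra] <- "maternal"; label[pat_extra] <- "paternal"
  label[panel_idx] <- panel$parent
  direct <- label != "none"
  ind <- sample(mat_extra, round(scenario$frac_indirect * length(mat_extra)))
  direct[ind] <- FALSE
  direction <- ifelse(runif(n) < 0.5, 1, -1)
  direction[panel_idx] <- ifelse(panel$direction == "up", 1, -1)
  affected <- label != "none"
  effect <- numeric(n)
  effect[affected] <- (scenario$effect_min +
    rgamma(sum(affected), shape = scenario$effect_shape,
           scale = scenario$effect_scale)) * direction[affected]

  # expression status and signals
  expressed <- affected | (runif(n) < scenario$frac_expressed)
  expressed[excluded] <- runif(length(excluded)) < scenario$frac_expressed
  mu <- ifelse(expressed, rnorm(n, 7, 1), rnorm(n, 2.5, 0.5))
  shift <- matrix(0, n, 3, dimnames = list(NULL, c("MP", "0P", "00")))
  m <- label == "maternal"; p <- label == "paternal"
  shift[m, "0P"] <- effect[m]; shift[m, "00"] <- effect[m]
  shift[p, "00"] <- effect[p]
  signal <- 2^(mu + shift + matrix(rnorm(3 * n, 0, scenario$noise_sd / 2), n, 3))
  # detection p-values: driven by expression status
  detp <- matrix(runif(3 * n, 0.07, 1), n, 3)
  detp[expressed, ] <- matrix(rbeta(3 * sum(expressed), 1, 40), sum(expressed), 3)

  # probe-pair contrasts via exact signed-rank
  contrast <- function(d_true) {
    D <- matrix(d_true, n, scenario$pairs) +
      matrix(rnorm(n * scenario$pairs, 0, scenario$noise_sd * sqrt(2)),
             n, scenario$pairs)
    list(p = signed_rank_p(D), lr = rowMeans(D))
  }
  c1 <- contrast(shift[, "0P"] - shift[, "MP"])
  c2 <- contrast(shift[, "00"] - shift[, "MP"])
  c3 <- contrast(shift[, "00"] - shift[, "0P"])

  probes <- data.frame(
    probe_id = probe_id, gene_id = gene_id, chrom = chrom, unique = uniq,
    signal_MP = signal[, "MP"], signal_0P = signal[, "0P"], signal_00 = signal[, "00"],
    detp_MP = detp[, 1], detp_0P = detp[, 2], detp_00 = detp[, 3],
    p_0PvMP = c1$p, lr_0PvMP = c1$lr,
    p_00vMP = c2$p, lr_00vMP = c2$lr,
    p_00v0P = c3$p, lr_00v0P = c3$lr,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    probe_id = probe_id, gene_id = gene_id, label = label, direct = direct,
    direction = ifelse(affected, ifelse(direction > 0, "up", "down"), "none"),
    effect = effect, expressed = expressed, stringsAsFactors = FALSE
  )
  list(probes = probes, truth = truth, seed = seed)
}

# Exact two-sided signed-rank p-values, one per row of the difference matrix.
# Zero differences are dropped (noise-free generators produce them); ties
# among nonzero |d| have probability zero under continuous noise.
signed_rank_p <- function(D) {
  n <- nrow(D); k <- ncol(D)
  nz <- rowSums(D != 0)
  p <- rep(1, n)
  full <- nz == k
  if (any(full)) {
    A <- abs(D[full, , drop = FALSE])
    ranks <- matrix(1, nrow(A), k) # midranks, so exact ties are handled
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j) next
        ranks[, i] <- ranks[, i] + (A[, j] < A[, i]) + 0.5 * (A[, j] == A[, i])
      }
    }
    W <- rowSums(ranks * (D[full, , drop = FALSE] > 0))
    pl <- psignrank(W, k)
    pu <- psignrank(W - 1, k, lower.tail = FALSE)
    p[full] <- pmin(1, 2 * pmin(pl, pu))
  }
  part <- which(nz > 0 & nz < k)
  for (i in part) {
    d <- D[i, ]; d <- d[d != 0]
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    m <- length(d)
    p[i] <- min(1, 2 * min(psignrank(W, m), psignrank(W - 1, m, lower.tail = FALSE)))
  }
  p
}

#' Generate a synthetic gene-to-category annotation with planted enrichment
#'
#' Background categories draw members uniformly from the gene universe;
#' enriched categories oversample genes carrying the stated imprint label by
#' the stated fold.
#'
#' @param genes character vector of gene ids (the universe).
#' @param labels per-gene labels (`"maternal"`, `"paternal"`, `"none"`),
#'   parallel to `genes`.
#' @param n_categories number of background categories.
#' @param enriched list of lists with `category` (id), `fold` (>= 1) and
#'   `side` (`"maternal"` or `"paternal"`).
#' @param size_range category sizes are drawn uniformly from this range.
#' @param seed integer seed.
#' @return list with `annotation` (gene_id, category_id, category_name) and
#'   `truth` (data.frame of planted categories: id, fold, side).
#' @export
gen_go_annotation <- function(genes, labels, n_categories = 100L,
                              enriched = list(), size_range = c(5L, 200L),
                              seed) {
  stopifnot(length(genes) == length(labels),
            all(vapply(enriched, function(e) e$fold >= 1, TRUE)))
  set.seed(seed)
  ng <- length(genes)
  rows <- list()
  for (i in seq_len(n_categories)) {
    sz <- sample(seq(size_range[1], min(size_range[2], ng)), 1L)
    members <- sample(genes, sz)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = members, category_id = sprintf("GO:bg%04d", i),
      category_name = sprintf("background process %d", i),
      stringsAsFactors = FALSE)
  }
  for (e in enriched) {
    sz <- sample(seq(size_range[1], min(size_range[2], ng)), 1L)
    w <- ifelse(labels == e$side, e$fold, 1)
    members <- sample(genes, sz, prob = w)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = members, category_id = e$category,
      category_name = sprintf("planted %s process", e$side),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(enriched)) {
    data.frame(category_id = vapply(enriched, `[[`, "", "category"),
               fold = vapply(enriched, `[[`, 0, "fold"),
               side = vapply(enriched, `[[`, "", "side"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(category_id = character(), fold = numeric(), side = character())
  }
  list(annotation = do.call(rbind, rows), truth = truth, seed = seed)
}
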