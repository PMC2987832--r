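test_that("identical sequences give a degenerate fit with zero branch lengths", {
  tr2 <- two_taxon_tree()
  aln <- region_alignment(c(A = "ACGTACGTAC", B = "ACGTACGTAC"), category = "t")
  expect_warning(fit <- fit_context_model(aln, tr2), "no substitution signal")
  expect_true(fit$degenerate)
  expect_true(all(fit$tree$edge.length < 1e-8))
})

test_that("fitted models are exactly strand symmetric", {
  tr4 <- four_taxon_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr4, regions = 4, length = 600,
                      categories = list(t = list(deam = 8))), seed = 2)
  for (type in c("cpg", "u3s")) {
    fit <- quiet_fit(dat$alignments$t, tr4, model_type = type)
    expect_true(is_strand_symmetric(rate_array(fit$model)))
  }
})

test_that("EM improves the composite likelihood over its starting point", {
  tr4 <- four_taxon_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr4, regions = 4, length = 500,
                      categories = list(t = list(deam = 10))), seed = 8)
  fit1 <- quiet_fit(dat$alignments$t, tr4, max_iter = 1)
  fit <- quiet_fit(dat$alignments$t, tr4)
  expect_gte(fit$logCL, fit1$logCL - 1e-9)
})

test_that("the exposure-weighted mean fitted rate is 1", {
  tr4 <- four_taxon_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr4, regions = 4, length = 600,
                      categories = list(t = list(deam = 10))), seed = 12)
  fit <- quiet_fit(dat$alignments$t, tr4)
  # class exposures count each state's time once per exit substitution (3)
  mean_rate <- 3 * sum(fit$rates * fit$class_exposure) / sum(fit$class_exposure)
  expect_equal(mean_rate, 1, tolerance = 1e-9)
})

test_that("the reduced model recovers its generating multipliers", {
  tr <- euarchontoglires_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(regions = 10, length = 1000,
                      categories = list(t = list(deam = 10, gain = 2))), seed = 7)
  fit <- quiet_fit(dat$alignments$t, tr)
  expect_lt(abs(fit$summary[["loss_vs_baseline"]] / 10 - 1), 0.2)
  expect_lt(abs(fit$summary[["gain_vs_baseline"]] / 2 - 1), 0.2)
})

test_that("the full trinucleotide model recovers a tenfold deamination elevation", {
  tr <- euarchontoglires_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(regions = 25, length = 1200,
                      categories = list(t = list(deam = 10))), seed = 5)
  fit <- quiet_fit(dat$alignments$t, tr, model_type = "u3s")
  expect_lt(abs(fit$summary[["loss_vs_baseline"]] / 10 - 1), 0.2)
})

test_that("total branch length is recovered", {
  tr <- euarchontoglires_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(regions = 30, length = 1500,
                      categories = list(t = list(deam = 10))), seed = 9)
  fit <- quiet_fit(dat$alignments$t, tr)
  expect_lt(abs(sum(fit$tree$edge.length) / sum(tr$edge.length) - 1), 0.1)
})

test_that("estimation error decreases with data size", {
  tr <- euarchontoglires_tree()
  err <- vapply(c(2, 8, 32), function(R) {
    mean(vapply(1:3, function(s) {
      d <- gen_sequence_categories(
        sequence_scenario(regions = R, length = 600,
                          categories = list(t = list(deam = 10))),
        seed = 100 * R + s)
      f <- quiet_fit(d$alignments$t, tr)
      abs(f$summary[["loss_vs_baseline"]] - 10)
    }, 0))
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("rate contrasts are invariant to a category's overall speed", {
  # same process on a tree twice as long: the baseline-relative deamination
  # rate (and within-category relative rates) should be unchanged
  tr4 <- four_taxon_tree(0.02)
  tr4b <- four_taxon_tree(0.04)
  sc <- function(tr) sequence_scenario(tree = tr, regions = 30, length = 800,
                                       categories = list(t = list(deam = 10)))
  f1 <- quiet_fit(gen_sequence_categories(sc(tr4), seed = 14)$alignments$t, tr4)
  f2 <- quiet_fit(gen_sequence_categories(sc(tr4b), seed = 15)$alignments$t, tr4b)
  expect_lt(abs(f1$summary[["loss_vs_baseline"]] /
                  f2$summary[["loss_vs_baseline"]] - 1), 0.15)
  # while the fitted tree lengths differ about twofold
  expect_gt(sum(f2$tree$edge.length) / sum(f1$tree$edge.length), 1.6)
})

test_that("oracle equivalence holds per class on shallow multi-species data", {
  tr <- euarchontoglires_tree()
  tr$edge.length <- tr$edge.length * 0.125
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr, regions = 8, length = 1500,
                      categories = list(t = list(deam = 10))), seed = 21)
  fit <- quiet_fit(dat$alignments$t, tr)
  pc <- count_events_parsimony(dat$alignments$t, tr)
  for (k in names(fit$rates)) {
    if (pc$class_events[k] >= 50) {
      expect_lt(abs(fit$rates[[k]] / pc$rates[[k]] - 1), 0.1)
    }
  }
})

test_that("fit methods expose coefficients, likelihood and summaries", {
  tr4 <- four_taxon_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr4, regions = 3, length = 400,
                      categories = list(t = list(deam = 10))), seed = 6)
  fit <- quiet_fit(dat$alignments$t, tr4)
  expect_named(coef(fit), c("ts", "tv", "deam", "gain"))
  expect_s3_class(logLik(fit), "logLik")
  expect_output(print(fit), "CpG loss")
  expect_output(print(summary(fit)), "Rate aggregates")
  lr <- cpg_loss_rate(fit)
  gr <- cpg_gain_rate(fit)
  expect_named(lr, c("deam", "total", "vs_baseline"))
  expect_named(gr, c("all", "tpg_cpa", "vs_baseline"))
  expect_gte(lr[["total"]], lr[["deam"]] * 0.5) # total includes transversions
})
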