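test_that("bootstrap intervals are deterministic under a fixed seed", {
  tr4 <- four_taxon_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr4, regions = 4, length = 500,
                      categories = list(t = list(deam = 10))), seed = 3)
  fit <- quiet_fit(dat$alignments$t, tr4)
  b1 <- bootstrap_rates(fit, B = 100, seed = 5)
  b2 <- bootstrap_rates(fit, B = 100, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci["2.5%", ] <= b1$ci["97.5%", ], na.rm = TRUE))
  expect_error(bootstrap_rates(fit, B = 50), ">= 100")
})

test_that("point estimates lie inside their bootstrap intervals", {
  tr4 <- four_taxon_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr4, regions = 5, length = 600,
                      categories = list(t = list(deam = 10))), seed = 13)
  fit <- quiet_fit(dat$alignments$t, tr4)
  bt <- bootstrap_rates(fit, B = 100, seed = 2)
  for (k in c("loss_deam", "gain_tpg", "loss_vs_baseline")) {
    expect_gte(fit$summary[[k]], bt$ci["2.5%", k])
    expect_lte(fit$summary[[k]], bt$ci["97.5%", k])
  }
})

test_that("interval width shrinks when the column count is quadrupled", {
  tr4 <- four_taxon_tree()
  widths <- vapply(1:8, function(s) {
    vapply(c(3, 12), function(R) {
      d <- gen_sequence_categories(
        sequence_scenario(tree = tr4, regions = R, length = 400,
                          categories = list(t = list(deam = 10))),
        seed = 50 * R + s)
      f <- quiet_fit(d$alignments$t, tr4)
      bt <- bootstrap_rates(f, B = 100, seed = s)
      diff(bt$ci[, "loss_vs_baseline"])
    }, 0)
  }, numeric(2))
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
})

test_that("category comparison reports ratio intervals and significance", {
  tr <- euarchontoglires_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(regions = 8, length = 800), seed = 4)
  fp <- quiet_fit(dat$alignments$paternal_like, tr)
  fm <- quiet_fit(dat$alignments$maternal_like, tr)
  cmp <- compare_cpg_rates(fp, fm, B = 100, seed = 9)
  expect_true(cmp$ratio_ci["2.5%", "loss_vs_baseline"] <
                cmp$ratio_ci["97.5%", "loss_vs_baseline"])
  expect_gt(cmp$ratio[["loss_vs_baseline"]], 1) # paternal-like loses faster
  expect_output(print(cmp), "CpG-loss ratio")
})
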