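test_that("zero branch length returns the input sequence", {
  m <- cpg_context_model()
  expect_identical(simulate_branch("ACGTACGTAC", m, 0), "ACGTACGTAC")
  expect_error(simulate_branch("ACGTACGTAC", m, -0.1), "negative")
  expect_error(simulate_branch("AC", m, 0.1))
})

test_that("simulation is deterministic under a fixed seed", {
  tr <- euarchontoglires_tree()
  m <- test_model()
  a <- simulate_alignment(tr, m, 200, seed = 11)
  b <- simulate_alignment(tr, m, 200, seed = 11)
  expect_identical(a$mat, b$mat)
  c <- simulate_alignment(tr, m, 200, seed = 12)
  expect_false(identical(a$mat, c$mat))
})

test_that("all-zero branch lengths reproduce the root everywhere", {
  tr <- euarchontoglires_tree()
  tr$edge.length[] <- 0
  a <- simulate_alignment(tr, test_model(), 100, seed = 4)
  expect_true(all(apply(a$mat, 2, function(col) length(unique(col)) == 1L)))
})

test_that("single-CpG survival matches the closed form", {
  # deamination-only process: the CpG leaves its state at rate
  # rho_CT + rho_GA; survival after t is exp(-(rho_CT+rho_GA) t)
  m <- cpg_context_model(ts = 0, tv = 0, deam = 3, gain = 0)
  arr <- as.numeric(rate_array(m))
  t <- 0.05
  seq0 <- icrevo:::seq_codes("AACGAA")
  set.seed(31)
  n <- 3000
  surv <- 0
  for (i in seq_len(n)) {
    out <- icrevo:::sim_branch_cpp(seq0, arr, t)
    if (out[3] == 2L && out[4] == 3L) surv <- surv + 1
  }
  expect_equal(surv / n, exp(-6 * t), tolerance = 0.03)
})

test_that("context-independent uniform rates converge to uniform composition", {
  m <- cpg_context_model(ts = 1, tv = 1, deam = 1, gain = 1) # all rates equal
  set.seed(7)
  seq0 <- sample.int(4L, 1e5, replace = TRUE, prob = c(0.55, 0.1, 0.1, 0.25))
  out <- icrevo:::sim_branch_cpp(seq0, as.numeric(rate_array(m)), 2)
  freqs <- tabulate(out, 4) / length(out)
  expect_true(all(abs(freqs - 0.25) < 0.01))
})

test_that("two-taxon divergence matches the matrix-exponential expectation", {
  m <- icrevo:::scale_to_unit_rate(
    cpg_context_model(ts = 1, tv = 0.25, deam = 1, gain = 1)
  ) # context-independent two-parameter model
  tr2 <- two_taxon_tree(0.05)
  set.seed(9)
  a <- simulate_alignment(tr2, m, 50000)
  pdiff <- mean(a$mat["A", ] != a$mat["B", ])
  arr <- rate_array(m)
  Q <- matrix(0, 4, 4)
  for (x in 1:4) for (y in 1:4) if (x != y) Q[x, y] <- arr[1, x, 1, y]
  diag(Q) <- -rowSums(Q)
  P <- ape::matexpo(Q * 0.1)
  expect_equal(pdiff, 1 - mean(diag(P)), tolerance = 0.05)
})

test_that("simulate() on a fitted model returns alignments on its tree", {
  tr4 <- four_taxon_tree()
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr4, regions = 3, length = 400,
                      categories = list(t = list(deam = 10))), seed = 5)
  fit <- quiet_fit(dat$alignments$t, tr4)
  sims <- simulate(fit, nsim = 2, seed = 1, root_length = 120)
  expect_length(sims, 2)
  expect_setequal(rownames(sims[[1]]$mat), tr4$tip.label)
  expect_equal(ncol(sims[[1]]$mat), 120)
})
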