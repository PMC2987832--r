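test_that("observed/expected CpG ratio matches hand counts", {
  s <- cpg_stats("ACGCGT")
  expect_equal(s$nC, 2)
  expect_equal(s$nG, 2)
  expect_equal(s$nCpG, 2)
  expect_equal(s$obs_exp, 3)

  expect_equal(cpg_stats("AAAA")$nCpG, 0)
  expect_equal(cpg_stats("AAAA")$obs_exp, 0)

  expect_equal(cpg_stats("TTCGA")$obs_exp, cpg_stats("TCGAA")$obs_exp)
})

test_that("N positions are masked from all counts", {
  s <- cpg_stats("ACNGT")
  expect_equal(s$length, 4)      # N excluded
  expect_equal(s$n_dinuc, 2)     # AC and GT; CN and NG span an N
  expect_equal(s$nCpG, 0)
  # an N breaking a would-be CpG removes it
  expect_equal(cpg_stats("ACNGACGT")$nCpG, 1)
})

test_that("invalid sequences are rejected with informative errors", {
  expect_error(cpg_stats(""), "empty")
  expect_error(cpg_stats("ACGU"), "U")
  expect_error(cpg_stats("ACG!T"), "!")
})

test_that("category ratios pool counts before forming the ratio", {
  two <- category_ratio(c("ACGCGT", "ACGCGT"))
  expect_equal(two$pooled$obs_exp, 3)

  mix <- category_ratio(c("ACGCGT", "AAAA"))
  expect_equal(mix$pooled$obs_exp, 5)          # (2*10)/(2*2)
  expect_equal(mix$mean_ratio, 1.5)            # documents the difference

  one <- category_ratio("ACGCGT")
  expect_equal(one$pooled$obs_exp, cpg_stats("ACGCGT")$obs_exp)

  expect_equal(mix$pooled$nCpG, sum(mix$per_record$nCpG))
  expect_equal(mix$pooled$length, sum(mix$per_record$length))

  expect_error(category_ratio(c("AC", "GT"), category = c("LCP", "HICP")),
               "mixed")
})

test_that("Fisher comparison reproduces exact enumeration on toy tables", {
  mk <- function(nCpG, n_dinuc) {
    structure(list(nCpG = nCpG, n_dinuc = n_dinuc), class = "cpg_stats")
  }
  r <- fisher_cpg_comparison(mk(2, 10), mk(8, 10))
  expect_equal(r$p, 4252 / 184756, tolerance = 1e-10)

  same <- fisher_cpg_comparison(mk(3, 9), mk(3, 9))
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p, 1)

  r2 <- fisher_cpg_comparison(mk(5, 5), mk(0, 5))
  expect_equal(r2$p, 2 / 252, tolerance = 1e-10)

  expect_error(fisher_cpg_comparison(mk(0, 4), mk(0, 6)), "margin")
})

test_that("Fisher p equals enumeration for all small tables", {
  mk <- function(nCpG, n_dinuc) {
    structure(list(nCpG = nCpG, n_dinuc = n_dinuc), class = "cpg_stats")
  }
  for (n in 4:16) {
    for (a in 0:n) for (c in 0:(n - a)) {
      b <- n - a; d <- n - c
      # margins: rows (a,b), (c,d); skip zero-margin tables
      if (a + c == 0 || b + d == 0) next
      got <- fisher_cpg_comparison(mk(a, a + b), mk(c, c + d))$p
      want <- fisher_p_enum(a, b, c, d)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("promoter CpG classes follow the window criteria", {
  expect_equal(weber_promoter_class(strrep("ACGT", 125)), "ICP") # GC too low for HCP
  expect_equal(weber_promoter_class(strrep("A", 500)), "LCP")
  expect_equal(weber_promoter_class(strrep("CG", 250)), "HCP")
  expect_error(weber_promoter_class(strrep("ACGT", 100)), "window")
})

test_that("obs/exp of a uniform random sequence is near 1", {
  set.seed(101)
  seq <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE), collapse = "")
  expect_lt(abs(cpg_stats(seq)$obs_exp - 1), 0.05)
})

test_that("obs/exp is reverse-complement invariant on random sequences", {
  set.seed(202)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200,
                      replace = TRUE, prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    expect_equal(cpg_stats(s)$obs_exp, cpg_stats(revcomp(s))$obs_exp)
  }
})
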