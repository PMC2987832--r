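mk_annotation <- function(members, id = "GO:x", name = "cat x") {
  data.frame(gene_id = members, category_id = id, category_name = name,
             stringsAsFactors = FALSE)
}

test_that("hypergeometric p matches the combinatorial value on toys", {
  universe <- sprintf("g%02d", 1:20)
  ann <- mk_annotation(universe[1:5])
  res <- ora(universe[1:5], universe, ann, min_size = 2)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$hits, 5)

  # selecting the whole universe makes every category exhaust its size
  res2 <- ora(universe, universe, ann, min_size = 2)
  expect_equal(res2$p, 1)

  # hits = 0 gives p = P(X >= 0) = 1
  res3 <- ora(universe[6:10], universe, ann, min_size = 2)
  expect_equal(res3$hits, 0)
  expect_equal(res3$p, 1)

  expect_error(ora(c(universe[1], "novel"), universe, ann), "outside the universe")
})

test_that("ORA p equals brute-force enumeration on small universes", {
  set.seed(5)
  for (rep in 1:40) {
    N <- sample(8:25, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    universe <- sprintf("u%02d", 1:N)
    ann <- mk_annotation(universe[1:K])
    selected <- sample(universe, n)
    res <- ora(selected, universe, ann, min_size = 2, max_size = N)
    hits <- sum(universe[1:K] %in% selected)
    expect_equal(res$p, hyper_upper_enum(hits, K, N, n), tolerance = 1e-10)
  }
})

test_that("BH correction is monotone and never below the raw p", {
  set.seed(9)
  universe <- sprintf("g%03d", 1:200)
  ann <- do.call(rbind, lapply(1:15, function(i) {
    mk_annotation(sample(universe, sample(5:60, 1)), id = sprintf("GO:%02d", i))
  }))
  res <- ora(sample(universe, 40), universe, ann)
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_true(all(diff(res$p_adj) >= -1e-12)) # sorted by p; adj p non-decreasing
  bon <- ora(sample(universe, 40), universe, ann, method = "bonferroni")
  expect_true(all(bon$p_adj >= bon$p - 1e-12))
})

test_that("adding an in-category gene to the selection never increases its p", {
  set.seed(21)
  universe <- sprintf("g%03d", 1:100)
  members <- universe[1:20]
  ann <- mk_annotation(members)
  for (i in 1:10) {
    sel <- sample(universe[21:100], sample(5:40, 1))
    extra <- sample(members, 1)
    p0 <- ora(sel, universe, ann)$p
    p1 <- ora(c(sel, extra), universe, ann)$p
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("annotation propagation feeds ancestor categories", {
  ann <- rbind(mk_annotation(c("g1", "g2", "g3", "g4", "g5"), id = "GO:child"),
               mk_annotation(c("g6", "g7", "g8", "g9", "g10"), id = "GO:other"))
  parents <- data.frame(child_id = "GO:child", parent_id = "GO:parent")
  universe <- sprintf("g%d", 1:20)
  res <- ora(c("g1", "g2", "g3"), universe, ann, parents = parents)
  expect_true("GO:parent" %in% res$category_id)
  expect_equal(res$hits[res$category_id == "GO:parent"],
               res$hits[res$category_id == "GO:child"])
  # off by default
  res0 <- ora(c("g1", "g2", "g3"), universe, ann)
  expect_false("GO:parent" %in% res0$category_id)
})

test_that("the p-value spectrum bins corrected p-values as documented", {
  rows <- data.frame(p_adj = c(0.0005, 0.05, 0.5))
  sp <- pvalue_spectrum(rows)
  expect_equal(unname(sp$counts), c(1, 0, 1, 1))
  expect_equal(sp$n_sig_0.1, 2)
  expect_equal(sp$n_sig_0.01, 1)

  expect_error(pvalue_spectrum(rows, edges = numeric(0)), "empty")
  all1 <- pvalue_spectrum(data.frame(p_adj = rep(1, 5)))
  expect_equal(unname(all1$counts), c(0, 0, 0, 5))
})
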