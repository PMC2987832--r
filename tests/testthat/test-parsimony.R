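test_that("identical alignments yield zero events", {
  tr2 <- two_taxon_tree()
  aln <- region_alignment(c(A = "ACGTACGT", B = "ACGTACGT"), category = "t")
  pc <- count_events_parsimony(aln, tr2)
  expect_equal(pc$n_events, 0)
})

test_that("a single C>T difference is counted once, in its A_G context", {
  tr2 <- two_taxon_tree(0.1)
  aln <- region_alignment(c(A = "ACGT", B = "ATGT"), category = "t")
  pc <- count_events_parsimony(aln, tr2)
  expect_equal(pc$n_events, 1)
  tb <- icrevo:::class_tables("cpg")
  q <- tb$qidx[1, 3] # left A, right G
  expect_equal(pc$events[q, 2, 4], 1) # C -> T
  expect_equal(sum(pc$events), 1)
  # the context has a right G, so this is a deamination-class event
  expect_equal(unname(pc$class_events["deam"]), 1)
})

test_that("species missing from the tree are rejected", {
  tr2 <- two_taxon_tree()
  aln <- region_alignment(c(A = "ACGT", X = "ACGT"), category = "t")
  expect_error(count_events_parsimony(aln, tr2), "species")
})

test_that("gap columns and their neighbours are excluded", {
  tr2 <- two_taxon_tree()
  aln <- region_alignment(c(A = "AC-TACGT", B = "ACGTACGT"), category = "t")
  pc <- count_events_parsimony(aln, tr2)
  # columns 2..4 unusable (gap or gapped flank); no differences elsewhere
  expect_equal(pc$n_columns, 5)
})

test_that("counting recovers the simulating deamination elevation at low divergence", {
  tr <- euarchontoglires_tree()
  tr$edge.length <- tr$edge.length * 0.125 # total ~0.05 subs/site
  dat <- gen_sequence_categories(
    sequence_scenario(tree = tr, regions = 10, length = 2000,
                      categories = list(t = list(deam = 10))), seed = 3)
  pc <- count_events_parsimony(dat$alignments$t, tr)
  expect_lt(abs(pc$summary[["loss_vs_baseline"]] / 10 - 1), 0.1)
})
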