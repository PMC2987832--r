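test_that("sequence generation is a pure function of scenario and seed", {
  tr4 <- four_taxon_tree()
  scn <- sequence_scenario(tree = tr4, regions = 2, length = 300)
  a <- gen_sequence_categories(scn, seed = 4)
  b <- gen_sequence_categories(scn, seed = 4)
  expect_identical(lapply(a$alignments, lapply, `[[`, "mat"),
                   lapply(b$alignments, lapply, `[[`, "mat"))
  c <- gen_sequence_categories(scn, seed = 5)
  expect_false(identical(a$alignments[[1]][[1]]$mat, c$alignments[[1]][[1]]$mat))
})

test_that("the ground truth records the generating multipliers and ratios", {
  scn <- sequence_scenario(tree = four_taxon_tree(), regions = 1, length = 300)
  dat <- gen_sequence_categories(scn, seed = 1)
  expect_equal(dat$truth$deam_multiplier, c(15, 10))
  expect_equal(unname(dat$loss_ratios["paternal_like/maternal_like"]), 1.5)
  same <- sequence_scenario(tree = four_taxon_tree(), regions = 1, length = 300,
                            categories = list(a = list(deam = 10),
                                              b = list(deam = 10)))
  expect_equal(unname(gen_sequence_categories(same, seed = 1)$loss_ratios["a/b"]), 1)
})

test_that("root sequences track the requested CpG density", {
  scn <- sequence_scenario(tree = four_taxon_tree(), regions = 6, length = 2000,
                           categories = list(
                             rich = list(deam = 10, cpg_obs_exp = 0.9),
                             poor = list(deam = 10, cpg_obs_exp = 0.2)))
  dat <- gen_sequence_categories(scn, seed = 6)
  oe <- function(alns) {
    category_ratio(vapply(alns, function(a)
      icrevo:::codes_to_seq(a$mat[1, ]), ""))$pooled$obs_exp
  }
  expect_gt(oe(dat$alignments$rich), oe(dat$alignments$poor) + 0.3)
})

test_that("expression generation is deterministic and labelled", {
  scn <- expression_scenario(n_probes = 2000, n_maternal = 60, n_paternal = 50)
  a <- gen_expression_dataset(scn, seed = 3)
  b <- gen_expression_dataset(scn, seed = 3)
  expect_identical(a$probes, b$probes)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$label == "maternal"), 60)
  expect_equal(sum(a$truth$label == "paternal"), 50)
  # indirect targets are maternal-affected but not flagged direct
  ind <- a$truth$label == "maternal" & !a$truth$direct
  expect_gt(sum(ind), 0)
})

test_that("noise-free expression data are perfectly classified", {
  scn <- expression_scenario(n_probes = 1500, n_maternal = 60, n_paternal = 50,
                             noise_sd = 0)
  dat <- gen_expression_dataset(scn, seed = 8)
  sc <- score_probes(filter_probes(dat$probes), alpha = 0.01)
  lab <- dat$truth$label[match(sc$probe_id, dat$truth$probe_id)]
  expect_setequal(sc$probe_id[sc$maternal == 1], sc$probe_id[lab == "maternal"])
  expect_setequal(sc$probe_id[sc$paternal == 1], sc$probe_id[lab == "paternal"])
})

test_that("zero effects and zero noise give empty scored sets at any alpha", {
  scn <- expression_scenario(n_probes = 800, n_maternal = 30, n_paternal = 30,
                             noise_sd = 0, effect_min = 0, effect_scale = 0)
  dat <- gen_expression_dataset(scn, seed = 2)
  for (a in c(0.5, 0.1, 0.01)) {
    sc <- score_probes(filter_probes(dat$probes), alpha = a)
    expect_equal(sum(sc$maternal) + sum(sc$paternal), 0)
  }
})

test_that("the generated panel genes carry their published directions", {
  dat <- gen_expression_dataset(
    expression_scenario(n_probes = 3000, n_maternal = 100, n_paternal = 90),
    seed = 12)
  panel <- imprinted_gene_panel()
  pr <- dat$probes[match(panel$gene, dat$probes$gene_id), ]
  up <- panel$direction == "up"
  expect_true(all(sign(pr$lr_00vMP[up]) == 1))
  expect_true(all(sign(pr$lr_00vMP[!up]) == -1))
  # maternal panel genes shift already in 0P, paternal only in 00
  mat <- panel$parent == "maternal"
  expect_true(all(abs(pr$lr_0PvMP[mat]) > 0.2))
  expect_true(all(abs(pr$lr_0PvMP[!mat]) < 0.2))
})

test_that("GO annotation generation is deterministic with valid sizes", {
  genes <- sprintf("g%03d", 1:300)
  labels <- sample(c("maternal", "paternal", "none"), 300, replace = TRUE)
  a <- gen_go_annotation(genes, labels, n_categories = 20, seed = 9)
  b <- gen_go_annotation(genes, labels, n_categories = 20, seed = 9)
  expect_identical(a$annotation, b$annotation)
  sizes <- table(a$annotation$category_id)
  expect_true(all(sizes >= 5 & sizes <= 200))
  expect_error(gen_go_annotation(genes, labels, enriched =
    list(list(category = "GO:x", fold = 0.5, side = "maternal")), seed = 1))
})

test_that("a planted maternal category is found only under the maternal scheme", {
  set.seed(33)
  genes <- sprintf("g%04d", 1:1500)
  labels <- sample(c(rep("maternal", 120), rep("paternal", 110),
                     rep("none", 1270)))
  gg <- gen_go_annotation(genes, labels, n_categories = 60,
                          enriched = list(list(category = "GO:planted",
                                               fold = 10, side = "maternal")),
                          seed = 14)
  rm_ <- ora(genes[labels == "maternal"], genes, gg$annotation)
  rp_ <- ora(genes[labels == "paternal"], genes, gg$annotation)
  expect_lt(rm_$p_adj[rm_$category_id == "GO:planted"], 0.1)
  expect_gt(rp_$p_adj[rp_$category_id == "GO:planted"], 0.1)
})
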