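mk_probe <- function(p1, p2, p3, l1 = 1, l2 = 1, l3 = 0,
                     detp = c(0.01, 0.01, 0.01), chrom = "chr1",
                     gene = "gX", unique = 1L, id = "pX") {
  data.frame(probe_id = id, gene_id = gene, chrom = chrom, unique = unique,
             signal_MP = 100, signal_0P = 100, signal_00 = 100,
             detp_MP = detp[1], detp_0P = detp[2], detp_00 = detp[3],
             p_0PvMP = p1, lr_0PvMP = l1,
             p_00vMP = p2, lr_00vMP = l2,
             p_00v0P = p3, lr_00v0P = l3,
             stringsAsFactors = FALSE)
}

test_that("probe filtering applies the detection, mapping and locus rules", {
  tab <- rbind(
    mk_probe(0.5, 0.5, 0.5, detp = c(0.5, 0.2, 0.07), id = "undetected"),
    mk_probe(0.5, 0.5, 0.5, detp = c(0.5, 0.2, 0.05), id = "kept"),
    mk_probe(0.5, 0.5, 0.5, chrom = "chrY", id = "on_y"),
    mk_probe(0.5, 0.5, 0.5, gene = "Xist", chrom = "chrX", id = "xist"),
    mk_probe(0.5, 0.5, 0.5, unique = 0L, id = "multi"),
    mk_probe(0.5, 0.5, 0.5, id = "AFFX-b2")
  )
  out <- filter_probes(tab)
  expect_identical(out$probe_id, "kept")
  d <- attr(out, "dropped")
  expect_equal(unname(d[c("undetected", "chrY", "xist", "non_unique", "control")]),
               c(1, 1, 1, 1, 1))
  # idempotent
  out2 <- filter_probes(out)
  expect_identical(out2$probe_id, out$probe_id)
  expect_equal(unname(attr(out2, "dropped")["total"]), 0)
})

test_that("maternal scoring requires both no-maternal-imprint contrasts", {
  p <- mk_probe(0.001, 0.002, 0.5, 0.8, 0.7, 0.05)
  s <- score_probes(p, 0.01)
  expect_equal(s$maternal, 1L)
  expect_equal(s$paternal, 0L)
  expect_equal(s$direction, "up")

  # changed between 00 and 0P: excluded
  expect_equal(score_probes(mk_probe(0.001, 0.002, 0.001), 0.01)$maternal, 0L)
  # not significant in 00 vs MP
  expect_equal(score_probes(mk_probe(0.001, 0.5, 0.5), 0.01)$maternal, 0L)
  # discordant directions are not a consistent imprint pattern
  expect_equal(score_probes(mk_probe(0.001, 0.002, 0.5, l1 = 1, l2 = -1), 0.01)$maternal, 0L)
})

test_that("paternal scoring requires both no-paternal-imprint contrasts", {
  p <- mk_probe(0.6, 0.004, 0.002, l1 = 0, l2 = 0.9, l3 = 0.8)
  s <- score_probes(p, 0.01)
  expect_equal(s$paternal, 1L)
  expect_equal(s$maternal, 0L)
  # a maternal-pattern probe never scores paternal
  pm <- mk_probe(0.001, 0.002, 0.5, 0.8, 0.7, 0.05)
  expect_equal(score_probes(pm, 0.01)$paternal, 0L)
  # nothing significant
  expect_equal(sum(unlist(score_probes(mk_probe(0.5, 0.5, 0.5), 0.01)[, c("maternal", "paternal")])), 0)
})

test_that("the two schemes are mutually exclusive and monotone in alpha", {
  # note: the "unchanged" clause compares against the same alpha, so for very
  # liberal alphas a probe can in principle enter the set as alpha decreases
  # past its no-change p-value; over the working range used here the sets are
  # nested
  tab <- random_probe_table(1000, seed = 77)
  alphas <- c(0.05, 0.01, 0.005, 0.001)
  prev_m <- prev_p <- NULL
  for (a in alphas) {
    s <- score_probes(tab, a)
    expect_equal(sum(s$maternal & s$paternal), 0)
    if (!is.null(prev_m)) {
      # decreasing alpha never adds probes
      expect_true(all(s$probe_id[s$maternal == 1] %in% prev_m))
      expect_true(all(s$probe_id[s$paternal == 1] %in% prev_p))
    }
    prev_m <- s$probe_id[s$maternal == 1]
    prev_p <- s$probe_id[s$paternal == 1]
  }
})

test_that("fold-change bins use the documented log2 cutoffs", {
  bins <- fold_change_bins(data.frame(
    probe_id = c("a", "b"), gene_id = c("a", "b"),
    maternal = c(1L, 1L), paternal = c(0L, 0L),
    direction = c("down", "down"), min_abs_lr = c(0.5, 0.2)
  ))
  expect_equal(unique(bins$log2_cutoff[bins$fold == 0.8]), log2(0.8))
  expect_equal(round(log2(0.8), 3), -0.322)
  expect_equal(unique(bins$log2_cutoff[bins$fold == 0.5]), -1)
  # only the probe reaching -0.322 counts at the 80% threshold
  expect_equal(bins$n[bins$parent == "maternal" & bins$fold == 0.8], 1)
  expect_equal(bins$n[bins$parent == "maternal" & bins$fold == 0.5], 0)
  expect_true(all(bins$n[bins$parent == "paternal"] == 0))
})

test_that("the imprinted panel report flags contrasts at the panel threshold", {
  tab <- rbind(
    mk_probe(0.0001, 0.0005, 0.6, 0.9, 0.8, 0.02, gene = "Zac1", id = "zac1"),
    mk_probe(0.9, 0.8, 0.7, 0.01, 0.01, 0, gene = "Cdkn1c", id = "flat")
  )
  rep <- imprinted_panel_report(tab, p_threshold = 0.003)
  z <- rep[rep$gene == "Zac1" & !rep$absent, ]
  expect_equal(z$sig_0PvMP, "*")
  expect_equal(z$sig_00vMP, "*")
  expect_equal(z$sig_00v0P, "")
  f <- rep[rep$gene == "Cdkn1c" & !rep$absent, ]
  expect_equal(paste0(f$sig_0PvMP, f$sig_00vMP, f$sig_00v0P), "")
  expect_true(all(rep$absent[rep$gene == "Airn"]))
})
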