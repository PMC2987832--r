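test_that("rate classes tie strand-symmetric substitutions", {
  arr <- rate_array(cpg_context_model(ts = 1, tv = 0.3, deam = 8, gain = 1.7))
  expect_true(is_strand_symmetric(arr))

  # deamination: C>T with right G, and its mirror G>A with left C
  expect_equal(arr[1, 2, 3, 4], 8)  # A[C>T]G
  expect_equal(arr[2, 3, 2, 1], 8)  # C[G>A]C
  # gain: T>C with right G / A>G with left C
  expect_equal(arr[4, 4, 3, 2], 1.7)
  expect_equal(arr[2, 1, 4, 3], 1.7)
  # plain transition and transversion
  expect_equal(arr[1, 1, 1, 3], 1)
  expect_equal(arr[1, 1, 1, 2], 0.3)
})

test_that("the full trinucleotide model has 96 strand-symmetry orbits", {
  tb <- icrevo:::class_tables("u3s")
  expect_equal(tb$n_class, 96L)
  m <- u3s_context_model(rates = seq(0.01, 0.96, by = 0.01))
  expect_true(is_strand_symmetric(rate_array(m)))
})

test_that("reduced model expands consistently to U3S", {
  m <- cpg_context_model(ts = 1.2, tv = 0.4, deam = 9, gain = 2.5)
  expect_equal(rate_array(as_u3s(m)), rate_array(m))
})

test_that("substitution flags classify CpG loss and gain correctly", {
  # C>A with right G destroys a CpG but is not deamination
  fl <- icrevo:::sub_flags(1L, 2L, 1L, 3L)
  expect_true(fl$loss_any); expect_false(fl$loss_deam)
  # A>C with right G creates a CpG but is not the TpG/CpA transition route
  fl <- icrevo:::sub_flags(1L, 1L, 2L, 3L)
  expect_true(fl$gain_any); expect_false(fl$gain_tpg)
  # T>C with right G is both
  fl <- icrevo:::sub_flags(1L, 4L, 2L, 3L)
  expect_true(fl$gain_any); expect_true(fl$gain_tpg)
  # A>G away from any CpG is neutral
  fl <- icrevo:::sub_flags(1L, 1L, 3L, 4L)
  expect_true(fl$neutral_cpg); expect_true(fl$transition)
})

test_that("trinucleotide compositions are normalized and symmetric", {
  f <- trinuc_composition(gc = 0.42, cpg_obs_exp = 0.5)
  expect_equal(sum(f), 1)
  # reverse-complement symmetry: f(a,b,c) = f(comp(c), comp(b), comp(a))
  comp <- c(4L, 3L, 2L, 1L)
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    expect_equal(f[a, b, cc], f[comp[cc], comp[b], comp[a]])
  }
})

test_that("unit-rate scaling gives mean substitution rate 1 at the root", {
  m <- test_model()
  arr <- rate_array(m)
  f <- unclass(m$root_comp)
  mu <- 0
  for (l in 1:4) for (x in 1:4) for (r in 1:4) {
    mu <- mu + f[l, x, r] * sum(arr[l, x, r, ])
  }
  expect_equal(mu, 1, tolerance = 1e-12)
})

test_that("model JSON round-trips", {
  m <- cpg_context_model(deam = 7)
  path <- tempfile(fileext = ".json")
  write_context_model(m, path)
  m2 <- read_context_model(path)
  expect_equal(unname(m2$rates), unname(m$rates))
  expect_equal(unclass(m2$root_comp), unclass(m$root_comp), tolerance = 1e-12)
})
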