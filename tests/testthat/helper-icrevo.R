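# shared fixtures, all built in code

two_taxon_tree <- function(t = 0.025) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", t, t))
}

four_taxon_tree <- function(t = 0.02) {
  ape::read.tree(text = sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g);",
                                t, t, t, t, t, t))
}

# unit-mean-rate CpG-aware model used by most simulation-based tests
test_model <- function(deam = 10, gain = 2, cpg_obs_exp = 0.6) {
  icrevo:::scale_to_unit_rate(
    cpg_context_model(deam = deam, gain = gain,
                      root_comp = trinuc_composition(gc = 0.5,
                                                     cpg_obs_exp = cpg_obs_exp))
  )
}

quiet_fit <- function(...) suppressWarnings(fit_context_model(...))

# brute-force two-sided Fisher p for a 2x2 table, by enumeration of all
# tables with the observed margins (probability-ordering definition)
fisher_p_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1)
  }, 0)
  obs <- probs[match(a, ks)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force upper-tail hypergeometric by combinatorial sums
hyper_upper_enum <- function(hits, K, N, n) {
  ks <- hits:min(K, n)
  sum(vapply(ks, function(k) {
    choose(K, k) * choose(N - K, n - k) / choose(N, n)
  }, 0))
}

# random probe-record table used by the property tests
random_probe_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    probe_id = sprintf("p%05d", seq_len(n)),
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = sample(paste0("chr", 1:19), n, replace = TRUE),
    unique = 1L,
    signal_MP = runif(n, 50, 5000), signal_0P = runif(n, 50, 5000),
    signal_00 = runif(n, 50, 5000),
    detp_MP = runif(n), detp_0P = runif(n), detp_00 = runif(n),
    p_0PvMP = runif(n), lr_0PvMP = rnorm(n),
    p_00vMP = runif(n), lr_00vMP = rnorm(n),
    p_00v0P = runif(n), lr_00v0P = rnorm(n),
    stringsAsFactors = FALSE
  )
}
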