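test_that("composition distributions are exact empirical frequencies", {
  roster <- tiny_roster()
  same <- matrix(rep(c(1, 1, 0, 0, 0), each = 4), 4,
                 dimnames = list(NULL, c("A", "B", "C", "D", "E")))
  d1 <- composition_distribution(scan_dataset(roster, same, rep("A", 4)))
  expect_equal(d1$support_size, 1L)
  expect_equal(unname(d1$prob), 1)
  ds <- tiny_dataset()   # counts {2, 1, 1}
  d2 <- composition_distribution(ds)
  expect_equal(sort(unname(d2$prob)), c(0.25, 0.25, 0.5))
  d3 <- composition_distribution(c(a = 3, b = 1))
  expect_equal(unname(d3$prob), c(0.75, 0.25))
})

test_that("Shannon entropy matches hand-computed values", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(round(shannon_entropy(c(0.75, 0.25)), 4), 0.8113)
  # nats when base = e
  expect_equal(shannon_entropy(c(0.5, 0.5), base = exp(1)), log(2))
})

test_that("entropy ratio conventions at the boundaries", {
  expect_equal(entropy_ratio(2, 2), 1)
  expect_equal(entropy_ratio(0, 3), 0)
  expect_equal(entropy_ratio(0, 0), 1)
  expect_error(entropy_ratio(1, 0), "expected entropy 0")
  # the reference season's numbers: 11.83 / 11.84 rounds to 1
  expect_equal(round(entropy_ratio(11.83, 11.84), 2), 1)
})

test_that("KL divergence: closed form, smoothing, and Gibbs' inequality", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(round(kl_divergence(c(0.5, 0.5), c(0.75, 0.25)), 4), 0.2075)
  expect_error(kl_divergence(c(a = 0.5, b = 0.5), c(a = 1)), "epsilon")
  expect_gt(kl_divergence(c(a = 0.5, b = 0.5), c(a = 1), epsilon = 1e-6), 0)
  set.seed(2)
  for (i in 1:20) {
    p <- prop.table(runif(6)); q <- prop.table(runif(6))
    expect_gte(kl_divergence(p, q), 0)
  }
})

test_that("JS distance: identity, disjoint supports, symmetry", {
  expect_equal(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_distance(c(a = 0.5, b = 0.5), c(c = 0.5, d = 0.5)), 1)
  set.seed(3)
  for (i in 1:20) {
    p <- prop.table(runif(5)); q <- prop.table(runif(5))
    expect_equal(js_distance(p, q), js_distance(q, p))
    expect_true(js_distance(p, q) >= 0 && js_distance(p, q) <= 1)
  }
})

test_that("expected entropy is the mean over realizations, with B = 1 boundary", {
  set.seed(5)
  ds <- random_dataset(n_ids = 6L, n_scans = 40L)
  ens <- build_ensemble(ds, B = 20L, seed = 2L)
  ee <- expected_entropy(ens)
  expect_equal(unname(ee["mean"]), mean(ens$entropy))
  e1 <- build_ensemble(ds, B = 1L, seed = 2L)
  expect_warning(ee1 <- expected_entropy(e1), "B = 1")
  expect_equal(unname(ee1["sd"]), 0)
})

test_that("entropy reports satisfy the structural invariants", {
  set.seed(6)
  ds <- random_dataset(n_ids = 7L, n_scans = 60L)
  ens <- build_ensemble(ds, B = 30L, seed = 4L)
  rep_ <- entropy_report(ds, ens)
  expect_lte(rep_$h_obs, log2(nrow(ds$present)))
  expect_lte(rep_$h_obs, log2(rep_$unique_obs) + 1e-12)
  expect_lte(rep_$unique_obs, nrow(ds$present))
  expect_gte(rep_$ratio, 0)
  expect_gte(rep_$kl, 0)
  expect_true(rep_$js >= 0 && rep_$js <= 1)
  # concavity: entropy of the pooled distribution >= mean realization entropy
  pooled_h <- shannon_entropy(composition_distribution(ens$pooled_counts))
  expect_gte(pooled_h, mean(ens$entropy) - 1e-12)
  # all-identical dataset: H_obs 0, unique fraction 1/n
  roster <- tiny_roster()
  same <- matrix(rep(c(1, 1, 0, 0, 0), each = 5), 5,
                 dimnames = list(NULL, c("A", "B", "C", "D", "E")))
  cds <- scan_dataset(roster, same, rep("A", 5))
  crep <- entropy_report(cds, build_ensemble(cds, B = 10L, seed = 1L))
  expect_equal(crep$h_obs, 0)
  expect_equal(crep$unique_frac, 1 / 5)
  # JSON export
  p <- withr::local_tempfile(fileext = ".json")
  write_entropy_report(rep_, p)
  expect_equal(jsonlite::read_json(p)$h_obs, rep_$h_obs)
})

test_that("an all-unique forced design gives ratio 1 exactly", {
  # every scan is focal alone with one distinct partner; sizes 2, weights
  # uniform: observed and permuted datasets both have all-unique scans only
  # when compositions happen to be distinct, so use the degenerate 1-member
  # subgroup design where permutation cannot change anything
  roster <- tiny_roster()
  present <- diag(5) == 1
  colnames(present) <- c("A", "B", "C", "D", "E")
  ds <- scan_dataset(roster, present, c("A", "B", "C", "D", "E"))
  ens <- build_ensemble(ds, B = 10L, seed = 3L)
  rep_ <- entropy_report(ds, ens)
  expect_equal(rep_$h_obs, log2(5))
  expect_equal(rep_$h_exp, log2(5))
  expect_equal(rep_$ratio, 1)
})

test_that("the bias experiment table is seeded and structured", {
  tab <- bias_experiment(group_sizes = c(6L, 10L), scan_counts = c(80L, 160L),
                         replicates = 1L, B = 15L, seed = 12L)
  tab2 <- bias_experiment(group_sizes = c(6L, 10L), scan_counts = c(80L, 160L),
                          replicates = 1L, B = 15L, seed = 12L)
  expect_identical(tab, tab2)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("n", "n_scans", "ratio", "kl", "js") %in% names(tab)))
  expect_true(all(is.finite(tab$ratio)))
})
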