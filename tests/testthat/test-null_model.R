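test_that("runs are maximal blocks of identical composition and focal", {
  roster <- tiny_roster()
  X <- c(1, 1, 0, 0, 0); Y <- c(1, 0, 1, 0, 0)
  ids <- c("A", "B", "C", "D", "E")
  present <- rbind(X, X, Y)
  colnames(present) <- ids
  runs <- collapse_runs(scan_dataset(roster, present, c("A", "A", "A")))
  expect_equal(runs$length, c(2L, 1L))
  # same composition but focal changes -> two runs
  XX <- rbind(X, X); colnames(XX) <- ids
  runs2 <- collapse_runs(scan_dataset(roster, XX, c("A", "B")))
  expect_equal(runs2$length, c(1L, 1L))
  # all distinct -> n runs of length 1
  ds <- tiny_dataset()
  runs3 <- collapse_runs(ds)
  expect_equal(runs3$length, c(2L, 1L, 1L))
  expect_equal(sum(runs3$length), nrow(ds$present))
})

test_that("permuted datasets preserve size, focal, and zero-weight exclusion", {
  set.seed(8)
  ds <- random_dataset(n_ids = 7L, n_scans = 40L)
  # cap subgroup sizes at 5 so excluding one candidate stays feasible
  for (i in seq_len(nrow(ds$present))) {
    extra <- setdiff(which(ds$present[i, ]),
                     match(ds$focal[i], colnames(ds$present)))
    if (length(extra) > 4L)
      ds$present[i, extra[-(1:4)]] <- FALSE
  }
  w <- occurrence_frequency(ds)
  w["G"] <- 0   # forbid G as a non-focal member
  perm <- permute_dataset(ds, weights = w, seed = 11L)
  expect_equal(rowSums(perm$present), rowSums(ds$present))
  expect_identical(perm$focal, ds$focal)
  expect_identical(perm$timestamp, ds$timestamp)
  g_rows <- which(perm$present[, "G"])
  expect_true(all(perm$focal[g_rows] == "G"))
  # run structure: permuted data constant within observed runs
  runs <- collapse_runs(ds)
  keys <- scansoc:::composition_keys(perm$present)
  for (r in seq_len(runs$n_runs)) {
    idx <- runs$start[r] + seq_len(runs$length[r]) - 1L
    expect_length(unique(keys[idx]), 1L)
  }
})

test_that("a subgroup larger than the positive-weight pool is an error", {
  set.seed(1)
  ds <- random_dataset(n_ids = 4L, n_scans = 6L)
  w <- occurrence_frequency(ds)
  w[] <- 0
  w["A"] <- 1
  expect_error(permute_dataset(ds, weights = w, seed = 1L), "candidates")
})

test_that("ensembles are reproducible and differ from the observed data", {
  set.seed(21)
  ds <- random_dataset(n_ids = 8L, n_scans = 120L)
  e1 <- build_ensemble(ds, B = 5L, seed = 99L, keep_realizations = TRUE)
  e2 <- build_ensemble(ds, B = 5L, seed = 99L, keep_realizations = TRUE)
  expect_identical(e1$sri, e2$sri)
  expect_identical(e1$entropy, e2$entropy)
  expect_identical(e1$realizations, e2$realizations)
  # collision bound: with 120 scans a realization reproducing the observed
  # composition sequence is overwhelmingly unlikely
  obs_keys <- scansoc:::composition_keys(ds$present)
  runs <- collapse_runs(ds)
  obs_run_keys <- obs_keys[runs$start]
  same <- vapply(e1$realizations, function(comps) {
    keys <- vapply(comps, function(x) paste(sort(x), collapse = ","), "")
    obs <- vapply(runs$comp, function(x) paste(sort(x), collapse = ","), "")
    identical(keys, obs)
  }, TRUE)
  expect_false(any(same))
  expect_true(all(validate_ensemble(e1, ds) == TRUE))
})

test_that("ensemble occurrence frequencies match an independent scan-level sampler", {
  # Monte-Carlo oracle: draw each scan's composition independently (no run
  # machinery) under the same weighted-sampling contract and compare mean
  # occurrence frequencies
  cfg <- synthetic_config(n_individuals = 12L, n_matrilines = 12L,
                          n_scans = 400L, seed = 13L)
  ds <- generate_scan_dataset(cfg)$dataset
  w <- occurrence_frequency(ds)
  B <- 60L
  ens <- build_ensemble(ds, B = B, seed = 7L)
  occ_ens <- matrix(NA_real_, B, ncol(ds$present))
  for (b in seq_len(B))
    occ_ens[b, ] <- colMeans(permute_dataset(ds, seed = 1000L + b)$present)
  sizes <- rowSums(ds$present)
  f_idx <- match(ds$focal, colnames(ds$present))
  set.seed(42)
  R <- 60L
  occ_oracle <- matrix(0, R, ncol(ds$present))
  for (r in seq_len(R)) {
    m <- matrix(FALSE, nrow(ds$present), ncol(ds$present))
    for (i in seq_len(nrow(ds$present))) {
      cand <- setdiff(which(w > 0), f_idx[i])
      pick <- if (sizes[i] > 1L)
        cand[sample.int(length(cand), sizes[i] - 1L, prob = w[cand])]
      else integer(0)
      m[i, c(f_idx[i], pick)] <- TRUE
    }
    occ_oracle[r, ] <- colMeans(m)
  }
  d <- colMeans(occ_ens) - colMeans(occ_oracle)
  se <- sqrt(apply(occ_ens, 2, var) / B + apply(occ_oracle, 2, var) / R)
  expect_true(all(abs(d) < 3.5 * se + 1e-12))
})

test_that("a two-member roster forces SRI_exp = 1 and zero expected entropy", {
  roster <- season_roster("s", data.frame(id = c("A", "B"),
                                          sex = c("female", "male"),
                                          stringsAsFactors = FALSE))
  present <- matrix(1, 6, 2, dimnames = list(NULL, c("A", "B")))
  ds <- scan_dataset(roster, present, rep(c("A", "B"), 3))
  ens <- build_ensemble(ds, B = 10L, seed = 1L)
  expect_equal(unname(expected_sri(ens)$mean), 1)
  expect_equal(unname(expected_entropy(ens)["mean"]), 0)
})

test_that("scan bootstrap SDs behave: zero for constant data, shrink with replication", {
  roster <- tiny_roster()
  rep5 <- matrix(rep(c(1, 1, 1, 0, 0), each = 5), 5,
                 dimnames = list(NULL, c("A", "B", "C", "D", "E")))
  const <- scan_dataset(roster, rep5, rep("A", 5))
  b <- bootstrap_scans(const, R = 50L, seed = 1L)
  expect_equal(b$max_sd, 0)
  set.seed(3)
  ds <- random_dataset(n_ids = 6L, n_scans = 20L)
  sds <- vapply(c(1L, 4L, 16L), function(k) {
    rep_present <- ds$present[rep(seq_len(nrow(ds$present)), k), ]
    big <- scan_dataset(ds$roster, rep_present, rep(ds$focal, k))
    bootstrap_scans(big, R = 200L, seed = 5L)$max_sd
  }, 0)
  expect_true(sds[2] < sds[1] && sds[3] < sds[2])
})
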