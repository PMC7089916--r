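test_that("Elo updates follow the logistic expectation and conserve rating", {
  sup <- data.frame(date = c("2015-01-01", "2015-01-02"),
                    winner = c("A", "A"), loser = c("B", "B"))
  st <- elo_ratings(sup[1, ], ids = c("A", "B"), k = 16, initial = 1000)
  expect_equal(unname(st$ratings), c(1008, 992))   # equal ratings: +/- k/2
  st2 <- elo_ratings(sup, ids = c("A", "B"), k = 100)
  expect_equal(sum(st2$ratings), 2000)             # conservation
  # a near-certain winner gains almost nothing: after a long winning streak
  # the per-update change approaches zero
  many <- data.frame(date = sprintf("2015-01-%02d", 1:25),
                     winner = "A", loser = "B")
  st3 <- elo_ratings(many, ids = c("A", "B"), k = 200)
  last_gain <- unname(st3$traj[25, "A"] - st3$traj[24, "A"])
  first_gain <- unname(st3$traj[1, "A"] - 1000)
  expect_equal(first_gain, 100)          # even match: k * 0.5
  expect_lt(last_gain, first_gain / 20)  # foregone conclusion barely moves
  expect_error(elo_ratings(sup, ids = c("A")), "unknown")
  expect_error(elo_ratings(data.frame(date = "d", winner = "A", loser = "A")))
  # conservation across a random sequence
  set.seed(4)
  rs <- data.frame(date = sprintf("2015-01-%02d", 1:20),
                   winner = sample(LETTERS[1:5], 20, TRUE),
                   loser = sample(LETTERS[1:5], 20, TRUE))
  rs <- rs[rs$winner != rs$loser, ]
  str_ <- elo_ratings(rs, ids = LETTERS[1:5], initial = 1000)
  expect_equal(sum(str_$ratings), 5000)
})

test_that("ordinal standardization maps top rank to 1 with tie handling", {
  sup <- data.frame(date = c("2015-01-01", "2015-01-02"),
                    winner = c("A", "B"), loser = c("B", "C"))
  st <- elo_ratings(sup, ids = c("A", "B", "C"))
  r <- standardized_ordinal_rank(st)
  expect_equal(sort(unname(r), decreasing = TRUE), c(1, 0.5, 0))
  expect_equal(names(sort(r, decreasing = TRUE))[1], "A")
  # before any interaction all ratings tie at the initial score
  r0 <- standardized_ordinal_rank(st, date = "2014-12-31")
  expect_equal(unname(r0), rep(0.5, 3))
  # single individual convention
  expect_equal(unname(standardized_ordinal_rank(st, ids = "A")), 1)
})

test_that("season ranks are plain means over daily values", {
  daily <- data.frame(id = c("A", "A", "B"), rank = c(1, 0.5, 0.2))
  yr <- yearly_rank(daily)
  expect_equal(unname(yr["A"]), 0.75)
  expect_equal(unname(yr["B"]), 0.2)
  expect_equal(yearly_rank(daily[c(3, 1, 2), ]), yr)
  expect_error(yearly_rank(daily, ids = c("A", "B", "C")), "C")
})

test_that("dyad rows carry the stated covariates and reference levels", {
  roster <- tiny_roster()
  ds <- tiny_dataset()
  ens <- build_ensemble(ds, B = 10L, seed = 1L)
  tab <- dyad_table(ds, ens)
  ranks <- setNames(c(0.9, 0.4, 0.1, 0.6, 0.3), c("A", "B", "C", "D", "E"))
  rows <- build_dyad_rows(list("2014/5" = tab), list("2014/5" = roster),
                          list("2014/5" = ranks), z_rank = FALSE)
  expect_equal(nrow(rows), choose(5, 2))
  ab <- rows[rows$dyad == "A-B", ]   # mother-offspring
  expect_equal(ab$kinship, 1L)
  bc <- rows[rows$dyad == "B-C", ]   # maternal siblings
  expect_equal(bc$kinship, 1L)
  expect_equal(rows[rows$dyad == "A-D", "kinship"], 0L)
  # two adult females with ranks 0.9 and 0.4
  ad <- rows[rows$dyad == "A-D", ]
  expect_equal(as.character(ad$sex_combo), "female_female")
  expect_equal(as.character(ad$age_combo), "adult_adult")
  expect_equal(unname(ad$rank_diff), 0.3)
  expect_equal(as.character(ad$infant_combo), "yes_yes")
  expect_equal(levels(rows$sex_combo)[1], "female_female")
  expect_equal(levels(rows$age_combo)[1], "adult_adult")
  expect_equal(levels(rows$infant_combo)[1], "no_no")
  # three seasons -> three rows per dyad
  rows3 <- build_dyad_rows(
    setNames(rep(list(tab), 3), c("y1", "y2", "y3")),
    setNames(rep(list(roster), 3), c("y1", "y2", "y3")),
    setNames(rep(list(ranks), 3), c("y1", "y2", "y3")))
  expect_equal(sum(rows3$dyad == "A-B"), 3L)
})

test_that("submodel enumeration respects marginality and counts", {
  subs <- enumerate_submodels()
  expect_length(subs, 52L)
  for (m in subs) {
    for (int in m[grepl(":", m)]) {
      expect_true(all(strsplit(int, ":")[[1]] %in% m))
    }
  }
  expect_true(any(vapply(subs, length, 1L) == 0L))              # null model
  expect_true(any(vapply(subs, function(m)
    setequal(m, scansoc:::full_model_terms), TRUE)))            # full model
  # p main effects without interactions -> 2^p models
  expect_length(enumerate_submodels(c("a", "b", "c")), 8L)
})

test_that("AICc, Akaike weights, and confidence sets match closed forms", {
  # AIC 100 with k = 2, n = 10
  ll <- -(100 - 2 * 2) / 2
  expect_equal(round(aicc(ll, 2, 10), 3), 101.714)
  expect_equal(aicc(ll, 2, 1e9), -2 * ll + 4, tolerance = 1e-6)
  expect_error(aicc(ll, 9, 10), "undefined")
  expect_gt(aicc(ll, 3, 10), aicc(ll, 2, 10))
  w <- akaike_weights(c(100, 102))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(akaike_weights(c(0, 2)), w)     # shift invariance
  expect_equal(sum(akaike_weights(runif(7, 90, 110))), 1)
  expect_equal(akaike_weights(42), 1)
  expect_equal(confidence_set(c(0.6, 0.3, 0.08, 0.02)), c(1L, 2L, 3L))
  expect_equal(confidence_set(1), 1L)
  expect_length(confidence_set(rep(1 / 20, 20)), 19L)
})

test_that("predictor weights sum model evidence and expected shares", {
  models <- list(character(0), "a", "b", c("a", "b"))
  w <- rep(0.25, 4)
  pw <- predictor_weights(models, w)
  expect_equal(pw$summed_weight[pw$term == "a"], 0.5)
  expect_equal(pw$expected_weight[pw$term == "a"], 0.5)
  pw2 <- predictor_weights(list("a", c("a", "b")), c(0.7, 0.3))
  expect_equal(pw2$summed_weight[pw2$term == "a"], 1)
})

test_that("injected kin and rank effects are recovered by the binomial model", {
  set.seed(101)
  est <- replicate(3, {
    rows <- make_recovery_rows()
    fit_model(rows, family = "binomial")$estimates[c("kinship", "rank_diff")]
  })
  expect_true(all(est["kinship", ] > 0))
  expect_true(all(est["rank_diff", ] < 0))
  expect_lt(abs(mean(est["kinship", ]) - 1), 0.3)
})

test_that("pure-noise Gaussian fits estimate zero effects", {
  set.seed(55)
  rows <- make_recovery_rows()
  rows$response_pav <- rnorm(nrow(rows))
  fit <- fit_model(rows, family = "gaussian")
  se <- coef(summary(fit$fit))[, "Std. Error"]
  est <- fit$estimates
  expect_true(all(abs(est[-1]) < 3 * se[-1]))
  null_fit <- fit_model(rows, character(0), family = "gaussian")
  expect_true(is.finite(null_fit$logLik))
  expect_equal(null_fit$k, 2)   # intercept + residual variance
})

test_that("the mixed-model route fits the stated random-effects structure", {
  set.seed(77)
  rows <- make_recovery_rows(n_ind = 16L, seasons = 2L)
  fit <- fit_model(rows, c("kinship", "rank_diff"), family = "gaussian",
                   random_effects = TRUE)
  expect_s4_class(fit$fit, "lmerMod")
  re <- names(lme4::ranef(fit$fit))
  expect_setequal(re, c("id1", "id2", "dyad", "year"))
  expect_true(is.finite(fit$logLik))
  expect_gt(fit$k, 3)
  r2 <- r2_mixed(fit)
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_lte(r2["marginal"], r2["conditional"] + 1e-12)
})

test_that("multimodel inference weights sum to one and flag the null model", {
  set.seed(31)
  rows <- make_recovery_rows()
  mm <- multimodel_inference(rows, family = "binomial")
  expect_equal(nrow(mm$table), 52L)
  expect_equal(sum(mm$table$weight, na.rm = TRUE), 1)
  expect_false(mm$null_in_confidence_set)   # strong injected effects
  expect_true(all(mm$predictors$summed_weight >= 0 &
                    mm$predictors$summed_weight <= 1))
  # the strongly injected continuous effect dominates; kinship beats its
  # equal-performance share
  rd_w <- mm$predictors$summed_weight[mm$predictors$term == "rank_diff"]
  expect_gt(rd_w, 0.9)
  kin <- mm$predictors[mm$predictors$term == "kinship", ]
  expect_gt(kin$summed_weight, kin$expected_weight)
})

test_that("null data keep summed predictor weights near their expected share", {
  set.seed(91)
  excess <- replicate(5, {
    rows <- make_recovery_rows(beta = c(intercept = -1.5, kinship = 0,
                                        rank_diff = 0))
    mm <- multimodel_inference(rows, family = "binomial")
    max(mm$predictors$summed_weight - mm$predictors$expected_weight)
  })
  expect_lt(mean(excess), 0.15)
})

test_that("dyad-flip resampling is seeded and a no-op for fixed-effects fits", {
  set.seed(12)
  rows <- make_recovery_rows(n_ind = 14L, seasons = 2L)
  f1 <- dyad_flip_inference(rows, family = "binomial", n_selections = 4L,
                            seed = 5L)
  f2 <- dyad_flip_inference(rows, family = "binomial", n_selections = 4L,
                            seed = 5L)
  expect_identical(f1$mean_estimates, f2$mean_estimates)
  expect_identical(f1$mean_summed_weights, f2$mean_summed_weights)
  # without random effects the flip cannot change the fit
  single <- fit_model(rows, family = "binomial")
  expect_equal(f1$mean_estimates, single$estimates, tolerance = 1e-12)
  # restricted mode: only the full model is refit per selection
  f3 <- dyad_flip_inference(rows, family = "binomial", n_selections = 2L,
                            seed = 5L, refit_subsets = FALSE)
  expect_equal(f3$mean_estimates, single$estimates, tolerance = 1e-12)
})

test_that("VIFs hit the closed forms and detect collinearity", {
  set.seed(66)
  n <- 400L
  x1 <- rnorm(n); e <- rnorm(n)
  x2 <- as.numeric(scale(x1)) + as.numeric(scale(resid(lm(e ~ x1))))
  df <- data.frame(x1 = x1, x2 = x2, x3 = rnorm(n))
  # cor(x1, x2)^2 = 0.5 by construction -> VIF exactly 2 in the pair model
  v2 <- vif(df, c("x1", "x2"))
  expect_equal(v2$gvif, c(2, 2), tolerance = 1e-8)
  v <- vif(df, c("x1", "x2", "x3"))
  expect_equal(v$gvif[v$term == "x1"], 2, tolerance = 0.05)
  expect_lt(v$gvif[v$term == "x3"], 1.05)
  # orthogonal designed predictors -> exactly 1
  a <- rep(c(-1, 1), each = 4); b <- rep(c(-1, 1), 4)
  vo <- vif(data.frame(a = a, b = b), c("a", "b"))
  expect_equal(vo$gvif, c(1, 1))
  # perfect collinearity -> infinite
  vc <- vif(data.frame(u = x1, v = 2 * x1, w = rnorm(n)), c("u", "v", "w"))
  expect_true(any(!is.finite(vc$gvif)))
})

test_that("R2 decomposition matches the closed form", {
  expect_equal(unname(r2_mixed(c(1, 1, 2))), c(0.25, 0.5))
  expect_equal(unname(r2_mixed(c(2, 0, 2))), c(0.5, 0.5))  # no RE: marg = cond
  set.seed(8)
  rows <- make_recovery_rows(n_ind = 14L, seasons = 2L)
  fit <- fit_model(rows, family = "binomial")
  r2 <- r2_mixed(fit)
  expect_equal(unname(r2["marginal"]), unname(r2["conditional"]))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("influence checks: zero shift for duplicated seasons, errors when scarce", {
  set.seed(19)
  one <- make_recovery_rows(n_ind = 12L, seasons = 1L)
  dup <- do.call(rbind, lapply(c("y1", "y2", "y3"), function(y) {
    d <- one; d$year <- y; d
  }))
  ic <- influence_check(dup, c("kinship", "rank_diff"), family = "binomial",
                        effects = "year")
  expect_lt(max(ic$max_shift), 1e-6)
  expect_error(influence_check(one, c("kinship"), family = "binomial",
                               effects = "year"), "3 seasons")
  ic2 <- influence_check(dup, c("kinship", "rank_diff"), family = "binomial",
                         effects = "individual")
  expect_true(all(is.finite(ic2$max_shift)))
})
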