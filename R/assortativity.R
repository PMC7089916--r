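# Assortativity analysis: what makes dyads preferred associates.
#
# Dominance ranks come from sequential Elo ratings on feeding supplants,
# standardized daily to ordinal [0, 1] and averaged per season. Dyad-year
# rows carry the covariates (kinship, rank difference, sex / age / infant
# combinations); binomial models explain the significant-associate flag and
# Gaussian models the pairwise affinity value. Inference is all-subsets AICc
# multimodel inference (marginality respected), with dyad-flip resampling to
# remove the arbitrary labelling of a dyad's members in the random-effects
# structure.

# ---- Elo ratings ----------------------------------------------------------

#' Sequential Elo ratings from supplant interactions
#'
#' Standard Elo updating: the winner gains `k * (1 - p_exp)` where `p_exp =
#' 1 / (1 + 10^((r_loser - r_winner) / 400))` is the logistic expectation of
#' the observed outcome; the loser loses the same amount, so total rating is
#' conserved.
#'
#' @param supplants Data frame with columns `date`, `winner`, `loser`
#'   (chronologically sortable; winner != loser).
#' @param ids Optional character vector of all individuals (defaults to those
#'   appearing in `supplants`); unknown winners/losers are an error.
#' @param k Update constant (default 100).
#' @param initial Starting score (default 1000).
#' @return Object of class `elo_state`: final `ratings`, the per-interaction
#'   rating trajectory (`dates`, `traj` matrix with one row per update), and
#'   the parameters.
#' @export
elo_ratings <- function(supplants, ids = NULL, k = 100, initial = 1000) {
  supplants <- as.data.frame(supplants)
  stopifnot(all(c("date", "winner", "loser") %in% names(supplants)))
  if (any(supplants$winner == supplants$loser))
    stop("winner and loser must differ")
  if (is.null(ids)) ids <- sort(unique(c(supplants$winner, supplants$loser)))
  unknown <- setdiff(c(supplants$winner, supplants$loser), ids)
  if (length(unknown))
    stop("unknown individual(s) in supplants: ",
         paste(unique(unknown), collapse = ", "))
  ord <- order(as.character(supplants$date))
  supplants <- supplants[ord, , drop = FALSE]
  r <- stats::setNames(rep(initial, length(ids)), ids)
  traj <- matrix(NA_real_, nrow(supplants), length(ids),
                 dimnames = list(NULL, ids))
  for (i in seq_len(nrow(supplants))) {
    w <- supplants$winner[i]; l <- supplants$loser[i]
    p_exp <- 1 / (1 + 10^((r[l] - r[w]) / 400))
    delta <- k * (1 - p_exp)
    r[w] <- r[w] + delta
    r[l] <- r[l] - delta
    traj[i, ] <- r
  }
  structure(list(ratings = r, dates = as.character(supplants$date),
                 traj = traj, k = k, initial = initial, ids = ids),
            class = "elo_state")
}

#' Standardized ordinal ranks at a date
#'
#' Individuals are ordered by their Elo rating as of `date` (ratings after
#' the last interaction on or before it; the initial score before any);
#' ordinal positions are standardized linearly so the top-rated individual
#' maps to 1 and the bottom to 0. Rating ties share the mean ordinal
#' position. A single individual gets 1 by convention.
#'
#' @param state An [elo_ratings()] result.
#' @param date Date (comparable as text to the supplant dates); `NULL` means
#'   the final ratings.
#' @param ids Optional subset of individuals to rank (e.g. a season roster).
#' @return Named numeric vector in `[0, 1]`.
#' @export
standardized_ordinal_rank <- function(state, date = NULL, ids = NULL) {
  stopifnot(inherits(state, "elo_state"))
  r <- if (is.null(date)) state$ratings else {
    i <- sum(state$dates <= as.character(date))
    if (i == 0L) stats::setNames(rep(state$initial, length(state$ids)), state$ids)
    else stats::setNames(state$traj[i, ], state$ids)
  }
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, names(r))
    if (length(missing_ids))
      stop("no ratings for: ", paste(missing_ids, collapse = ", "))
    r <- r[ids]
  }
  n <- length(r)
  if (n == 1L) return(stats::setNames(1, names(r)))
  (rank(r, ties.method = "average") - 1) / (n - 1)
}

#' Season-mean rank per individual
#'
#' @param daily Data frame with columns `id` and `rank` (one row per
#'   individual per day it was ranked).
#' @param ids Optional ids that must all be present; an individual with no
#'   daily values is an error.
#' @return Named numeric vector of arithmetic mean ranks.
#' @export
yearly_rank <- function(daily, ids = NULL) {
  stopifnot(all(c("id", "rank") %in% names(daily)))
  out <- tapply(daily$rank, daily$id, mean)
  out <- stats::setNames(as.numeric(out), names(out))
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, names(out))
    if (length(missing_ids))
      stop("no daily ranks for: ", paste(missing_ids, collapse = ", "))
    out <- out[ids]
  }
  out
}

# ---- Dyad-year rows -------------------------------------------------------

sex_combo_levels <- c("female_female", "female_male", "male_male")
age_combo_levels <- c("adult_adult", "adult_subadult", "subadult_subadult")
infant_combo_levels <- c("no_no", "yes_no", "yes_yes")

#' Assemble the dyad-year modelling table
#'
#' One row per dyad per season both members were present, carrying the
#' responses (significant-associate flag, pairwise affinity value) and the
#' covariates: kinship (mother-offspring or maternal siblings), sex
#' combination, age combination, absolute difference of season-mean
#' standardized ranks, and newborn-infant combination. Reference levels are
#' `female_female`, `adult_adult`, `no_no`.
#'
#' @param dyads Named list (season -> [dyad_table()] output).
#' @param rosters Named list (season -> [season_roster()]); same names.
#' @param ranks Named list (season -> named numeric of season-mean
#'   standardized ranks covering the roster).
#' @param z_rank If `TRUE` (default), the pooled `rank_diff` column is
#'   z-standardized for model fitting; the raw values are kept in
#'   `rank_diff_raw`.
#' @return Data frame with columns `id1`, `id2`, `dyad`, `year`,
#'   `response_sig`, `response_pav`, `kinship`, `sex_combo`, `age_combo`,
#'   `infant_combo`, `rank_diff`, `rank_diff_raw`.
#' @export
build_dyad_rows <- function(dyads, rosters, ranks, z_rank = TRUE) {
  seasons <- names(dyads)
  stopifnot(!is.null(seasons), identical(sort(seasons), sort(names(rosters))),
            identical(sort(seasons), sort(names(ranks))))
  rows <- lapply(seasons, function(s) {
    dt <- dyads[[s]]
    mem <- rosters[[s]]$members
    rk <- ranks[[s]]
    miss <- setdiff(unique(c(dt$id_a, dt$id_b)), names(rk))
    if (length(miss)) stop("missing rank for: ", paste(miss, collapse = ", "))
    ia <- match(dt$id_a, mem$id); ib <- match(dt$id_b, mem$id)
    if (anyNA(ia) || anyNA(ib))
      stop("dyad member missing from season ", s, " roster")
    kin <- kin_matrix(rosters[[s]])
    sex_a <- mem$sex[ia]; sex_b <- mem$sex[ib]
    age_a <- mem$age_class[ia]; age_b <- mem$age_class[ib]
    inf_a <- ifelse(mem$infant[ia], "yes", "no")
    inf_b <- ifelse(mem$infant[ib], "yes", "no")
    sexc <- ifelse(sex_a == sex_b, paste(sex_a, sex_b, sep = "_"),
                   "female_male")
    agec <- ifelse(age_a == age_b, paste(age_a, age_b, sep = "_"),
                   "adult_subadult")
    infc <- ifelse(inf_a == inf_b, paste(inf_a, inf_b, sep = "_"), "yes_no")
    data.frame(
      id1 = dt$id_a, id2 = dt$id_b,
      dyad = paste(pmin(dt$id_a, dt$id_b), pmax(dt$id_a, dt$id_b), sep = "-"),
      year = s,
      response_sig = as.integer(dt$significant),
      response_pav = dt$pav,
      kinship = as.integer(kin[cbind(ia, ib)]),
      sex_combo = factor(sexc, levels = sex_combo_levels),
      age_combo = factor(agec, levels = age_combo_levels),
      infant_combo = factor(infc, levels = infant_combo_levels),
      rank_diff_raw = abs(rk[dt$id_a] - rk[dt$id_b]),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$rank_diff <- if (z_rank)
    as.numeric(scale(out$rank_diff_raw)) else out$rank_diff_raw
  out
}

# ---- Model fitting --------------------------------------------------------

full_model_terms <- c("kinship", "rank_diff", "sex_combo", "age_combo",
                      "infant_combo", "sex_combo:rank_diff",
                      "sex_combo:age_combo")

re_formula_text <- paste("(1 + rank_diff | id1) + (1 + rank_diff | id2)",
                         "+ (1 | dyad) + (1 + rank_diff | year)")

#' Fit one dyadic association model
#'
#' Binomial models explain whether a dyad-year was a significant associate;
#' Gaussian models explain the pairwise affinity value. With
#' `random_effects = TRUE` the model is a (G)LMM (lme4) with random
#' intercepts for both individuals, the dyad, and the year, plus random
#' slopes for the rank difference in the individual identities and year —
#' the same structure for every submodel. The fixed-effects-only fit
#' (`random_effects = FALSE`, the default) is the documented fallback for
#' data whose random-effect variance is zero (e.g. the synthetic generator's
#' output) and for the resampling-heavy machinery.
#'
#' @param rows [build_dyad_rows()] output.
#' @param spec Character vector of fixed-effect terms (a subset of the full
#'   model's); `character(0)` is the intercept-only model.
#' @param family `"binomial"` or `"gaussian"`.
#' @param random_effects Use the mixed-model structure above.
#' @return Object of class `assoc_fit`: `estimates` (fixed effects, link
#'   scale), `logLik`, `k` (parameters), `n` (rows), `converged`, `family`,
#'   `spec`, and the underlying `fit`.
#' @export
fit_model <- function(rows, spec = full_model_terms,
                      family = c("binomial", "gaussian"),
                      random_effects = FALSE) {
  family <- match.arg(family)
  response <- if (family == "binomial") "response_sig" else "response_pav"
  fixed <- if (length(spec)) paste(spec, collapse = " + ") else "1"
  converged <- TRUE
  if (random_effects) {
    fml <- stats::as.formula(paste(response, "~", fixed, "+", re_formula_text))
    fit <- withCallingHandlers(
      if (family == "binomial")
        lme4::glmer(fml, data = rows, family = stats::binomial())
      else
        lme4::lmer(fml, data = rows, REML = FALSE),
      warning = function(w) {
        if (grepl("converge|singular", conditionMessage(w), ignore.case = TRUE))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (length(fit@optinfo$conv$lme4$messages)) converged <- FALSE
    est <- lme4::fixef(fit)
  } else {
    fml <- stats::as.formula(paste(response, "~", fixed))
    fit <- if (family == "binomial")
      stats::glm(fml, data = rows, family = stats::binomial())
    else
      stats::lm(fml, data = rows)
    if (family == "binomial") converged <- fit$converged
    est <- stats::coef(fit)
  }
  ll <- stats::logLik(fit)
  structure(list(estimates = est, logLik = as.numeric(ll),
                 k = attr(ll, "df"), n = nrow(rows), converged = converged,
                 family = family, spec = spec,
                 random_effects = random_effects, fit = fit),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("%s %s fit: %d fixed term(s), logLik %.2f, k = %d, n = %d%s\n",
              if (x$random_effects) "Mixed" else "Fixed-effects",
              x$family, length(x$spec), x$logLik, x$k, x$n,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Enumerate marginality-respecting submodels
#'
#' All subsets of the full model's terms in which every interaction is
#' accompanied by both of its main effects; includes the intercept-only
#' model and the full model. The reference full model (kinship, rank
#' difference, sex, age, infant combos, sex x rank and sex x age
#' interactions) yields 52 submodels.
#'
#' @param full Character vector of terms; interactions written `"a:b"`.
#' @return List of character vectors (each a `spec` for [fit_model()]).
#' @export
enumerate_submodels <- function(full = full_model_terms) {
  ints <- full[grepl(":", full, fixed = TRUE)]
  mains <- setdiff(full, ints)
  parents <- lapply(strsplit(ints, ":", fixed = TRUE), identity)
  out <- list()
  for (i in 0:(2^length(mains) - 1)) {
    m_in <- mains[bitwAnd(i, bitwShiftL(1L, seq_along(mains) - 1L)) > 0]
    ok_ints <- ints[vapply(parents, function(p) all(p %in% m_in), TRUE)]
    for (j in 0:(2^length(ok_ints) - 1)) {
      i_in <- ok_ints[bitwAnd(j, bitwShiftL(1L, seq_along(ok_ints) - 1L)) > 0]
      out[[length(out) + 1L]] <- c(m_in, i_in)
    }
  }
  out
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size (dyad-year rows).
#' @return AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined for n <= k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with `delta_i = AICc_i
#' - min(AICc)`; invariant to adding a constant to all AICc values.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' 95\% best-model confidence set
#'
#' The smallest set of top-weighted models whose cumulative Akaike weight
#' reaches `level`.
#'
#' @param weights Akaike weights.
#' @param level Cumulative weight threshold (default 0.95).
#' @return Integer indices (into `weights`) of the confidence-set members,
#'   in decreasing weight order.
#' @export
confidence_set <- function(weights, level = 0.95) {
  ord <- order(weights, decreasing = TRUE)
  keep <- seq_len(which(cumsum(weights[ord]) >= level - 1e-12)[1L])
  ord[keep]
}

#' Summed and expected Akaike weight per predictor
#'
#' The summed weight of a predictor is the total Akaike weight of the models
#' containing it; the expected weight is its share under the assumption that
#' all models perform equally well, here the fraction of models containing
#' the predictor (the default, documented definition; see the methods
#' vignette for alternatives).
#'
#' @param models List of term vectors (from [enumerate_submodels()]).
#' @param weights Akaike weights, same length.
#' @return Data frame: `term`, `summed_weight`, `expected_weight`.
#' @export
predictor_weights <- function(models, weights) {
  stopifnot(length(models) == length(weights))
  terms_ <- unique(unlist(models))
  has <- vapply(terms_, function(t)
    vapply(models, function(m) t %in% m, TRUE), logical(length(models)))
  data.frame(term = terms_,
             summed_weight = as.numeric(crossprod(has, weights)),
             expected_weight = colMeans(has),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' All-subsets AICc multimodel inference
#'
#' Fits every marginality-respecting submodel of `full`, computes AICc,
#' Akaike weights, the 95\% best-model confidence set, and per-predictor
#' summed weights. Non-convergent fits are dropped from the weight
#' normalization (with a message). Per-predictor weights are meaningful only
#' when the intercept-only model is outside the confidence set; the flag
#' `null_in_confidence_set` records this guard.
#'
#' @inheritParams fit_model
#' @param full Full model terms.
#' @param level Confidence-set level.
#' @return Object of class `multimodel_result`: `table` (one row per
#'   submodel: terms, logLik, k, n, AICc, delta, weight, confidence-set and
#'   convergence flags), `predictors` ([predictor_weights()] output),
#'   `null_in_confidence_set`, `full_fit` (the full model's [fit_model()]
#'   result), `models`.
#' @export
multimodel_inference <- function(rows, full = full_model_terms,
                                 family = c("binomial", "gaussian"),
                                 random_effects = FALSE, level = 0.95) {
  family <- match.arg(family)
  models <- enumerate_submodels(full)
  fits <- lapply(models, function(m)
    fit_model(rows, m, family = family, random_effects = random_effects))
  conv <- vapply(fits, `[[`, TRUE, "converged")
  if (any(!conv))
    message(sum(!conv), " submodel fit(s) did not converge; dropped from weights")
  ll <- vapply(fits, `[[`, 0, "logLik")
  k <- vapply(fits, function(f) as.numeric(f$k), 0)
  n <- nrow(rows)
  aiccs <- aicc(ll, k, n)
  w <- rep(NA_real_, length(models))
  w[conv] <- akaike_weights(aiccs[conv])
  cs <- rep(FALSE, length(models))
  cs[which(conv)[confidence_set(w[conv], level)]] <- TRUE
  null_idx <- which(vapply(models, length, 1L) == 0L)
  tab <- data.frame(
    model = vapply(models, function(m)
      if (length(m)) paste(m, collapse = " + ") else "(intercept only)", ""),
    logLik = ll, k = k, n = n, aicc = aiccs,
    delta = aiccs - min(aiccs[conv]), weight = w,
    in_confidence_set = cs, converged = conv, stringsAsFactors = FALSE)
  pred <- predictor_weights(models[conv], w[conv])
  full_idx <- which(vapply(models, function(m) setequal(m, full), TRUE))[1L]
  structure(list(table = tab[order(-ifelse(is.na(w), -Inf, w)), ],
                 predictors = pred,
                 null_in_confidence_set = cs[null_idx],
                 full_fit = fits[[full_idx]],
                 models = models, family = family, level = level),
            class = "multimodel_result")
}

#' @export
print.multimodel_result <- function(x, ...) {
  cat("Multimodel inference (", x$family, "): ", nrow(x$table),
      " submodels, ", sum(x$table$in_confidence_set),
      " in the ", 100 * x$level, "% confidence set\n", sep = "")
  if (x$null_in_confidence_set)
    cat("NOTE: the intercept-only model is in the confidence set;\n",
        "      predictor weights should not be interpreted\n")
  print(x$predictors, digits = 3)
  invisible(x)
}

#' Dyad-flip resampling around the multimodel inference
#'
#' The assignment of a dyad's two members to the `id1`/`id2` random-effect
#' slots is arbitrary but can affect mixed-model estimates. Each selection
#' randomly flips every dyad's member labels, refits the full model (for
#' effect sizes) and — by default — reruns the all-subsets inference (for
#' summed weights). Reported values are means over converged selections.
#'
#' @inheritParams multimodel_inference
#' @param n_selections Number of random label assignments (reference
#'   analysis: 1000).
#' @param seed Integer seed.
#' @param refit_subsets If `FALSE`, only the full model is refit per
#'   selection and summed weights come from a single multimodel pass on the
#'   unflipped data.
#' @return Object of class `dyad_flip_result`: `mean_estimates`,
#'   `mean_summed_weights` (data frame `term`, `summed_weight`,
#'   `expected_weight`), `n_selections`, `n_converged`,
#'   `null_in_confidence_set_frac`.
#' @export
dyad_flip_inference <- function(rows, full = full_model_terms,
                                family = c("binomial", "gaussian"),
                                n_selections = 1000L, seed = 1L,
                                random_effects = FALSE,
                                refit_subsets = TRUE, level = 0.95) {
  family <- match.arg(family)
  set.seed(seed)
  dyad_ids <- unique(rows$dyad)
  all_terms <- unique(unlist(enumerate_submodels(full)))
  est_sum <- NULL; est_n <- 0L
  w_sum <- stats::setNames(numeric(length(all_terms)), all_terms)
  w_cnt <- w_sum
  w_expected <- NULL
  w_n <- 0L; null_cs <- 0L
  base_mm <- if (!refit_subsets)
    multimodel_inference(rows, full, family, random_effects, level) else NULL
  for (s in seq_len(n_selections)) {
    flip <- stats::setNames(stats::runif(length(dyad_ids)) < 0.5, dyad_ids)
    r2 <- rows
    do_flip <- flip[rows$dyad]
    r2$id1[do_flip] <- rows$id2[do_flip]
    r2$id2[do_flip] <- rows$id1[do_flip]
    if (refit_subsets) {
      mm <- suppressMessages(
        multimodel_inference(r2, full, family, random_effects, level))
      fit <- mm$full_fit
      pw <- mm$predictors
      w_sum[pw$term] <- w_sum[pw$term] + pw$summed_weight
      w_cnt[pw$term] <- w_cnt[pw$term] + 1L
      if (is.null(w_expected))
        w_expected <- stats::setNames(pw$expected_weight, pw$term)
      w_n <- w_n + 1L
      null_cs <- null_cs + mm$null_in_confidence_set
    } else {
      fit <- fit_model(r2, full, family, random_effects = random_effects)
    }
    if (fit$converged) {
      est_sum <- if (is.null(est_sum)) fit$estimates
                 else est_sum + fit$estimates
      est_n <- est_n + 1L
    }
  }
  if (!refit_subsets) {
    pw <- base_mm$predictors
    w_sum[pw$term] <- pw$summed_weight
    w_cnt[pw$term] <- 1L
    w_expected <- stats::setNames(pw$expected_weight, pw$term)
    null_cs <- base_mm$null_in_confidence_set
    w_n <- 1L
  }
  if (est_n == 0L) stop("no selection converged")
  keep <- w_cnt > 0
  structure(list(
    mean_estimates = est_sum / est_n,
    mean_summed_weights = data.frame(term = all_terms[keep],
                                     summed_weight = (w_sum / pmax(w_cnt, 1))[keep],
                                     expected_weight = unname(
                                       w_expected[all_terms[keep]]),
                                     stringsAsFactors = FALSE),
    n_selections = n_selections, n_converged = est_n,
    null_in_confidence_set_frac = null_cs / max(w_n, 1L),
    family = family), class = "dyad_flip_result")
}

#' @export
print.dyad_flip_result <- function(x, ...) {
  cat("Dyad-flip resampling (", x$family, "): ", x$n_converged, "/",
      x$n_selections, " selections converged\n", sep = "")
  print(x$mean_summed_weights, digits = 3, row.names = FALSE)
  cat("mean full-model estimates:\n")
  print(round(x$mean_estimates, 3))
  invisible(x)
}

# ---- Diagnostics ----------------------------------------------------------

#' Generalized variance inflation factors
#'
#' Collinearity check on the fixed-effects design, excluding random effects
#' and interactions. For a 1-df predictor this is the classical
#' `1 / (1 - R^2)` from regressing it on the others; multi-df (categorical)
#' predictors use the generalized VIF determinant convention
#' `det(R_11) det(R_22) / det(R)` (Fox-Monette), with `GVIF^(1/(2 df))` also
#' reported for comparison across df.
#'
#' @param rows Data frame of predictors.
#' @param predictors Character vector of main-effect names (>= 2).
#' @return Data frame: `term`, `gvif`, `df`, `gvif_adj`. Perfect collinearity
#'   yields `Inf`.
#' @export
vif <- function(rows, predictors) {
  stopifnot(length(predictors) >= 2L)
  mm <- stats::model.matrix(stats::reformulate(predictors), rows)
  asgn <- attr(mm, "assign")[-1L]
  X <- mm[, -1L, drop = FALSE]
  R <- stats::cor(X)
  detR <- det(R)
  out <- lapply(seq_along(predictors), function(j) {
    sub <- which(asgn == j)
    g <- if (detR <= .Machine$double.eps) Inf else
      det(R[sub, sub, drop = FALSE]) *
      det(R[-sub, -sub, drop = FALSE]) / detR
    data.frame(term = predictors[j], gvif = g, df = length(sub),
               gvif_adj = g^(1 / (2 * length(sub))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Marginal and conditional R-squared
#'
#' Nakagawa-style variance decomposition: marginal R2 is the fixed-effects
#' variance share, conditional R2 the fixed-plus-random share, both over
#' `var_fixed + var_random + var_residual`. For binomial (logit) models the
#' residual variance is the distribution-specific `pi^2 / 3`; for Gaussian
#' models the estimated residual variance. Random-slope contributions are
#' approximated as the slope variance times the covariate variance.
#'
#' @param fit An [fit_model()] result, or a numeric vector
#'   `c(fixed, random, residual)` of variance components.
#' @return Named numeric: `marginal`, `conditional`.
#' @export
r2_mixed <- function(fit) {
  if (is.numeric(fit)) {
    stopifnot(length(fit) == 3L)
    vf <- fit[[1L]]; vr <- fit[[2L]]; ve <- fit[[3L]]
  } else {
    stopifnot(inherits(fit, "assoc_fit"))
    m <- fit$fit
    if (fit$random_effects) {
      X <- lme4::getME(m, "X")
      vf <- stats::var(as.vector(X %*% lme4::fixef(m)))
      dat <- m@frame
      vr <- sum(vapply(lme4::VarCorr(m), function(vc) {
        vars <- diag(vc)
        covs <- names(vars)
        sum(vapply(seq_along(vars), function(i) {
          if (covs[i] == "(Intercept)") vars[i]
          else vars[i] * stats::var(dat[[covs[i]]])
        }, 0))
      }, 0))
      ve <- if (fit$family == "gaussian") stats::sigma(m)^2 else pi^2 / 3
    } else {
      # linear predictor on the link scale; robust to NA coefficients from
      # rank-deficient fixtures
      vf <- stats::var(as.numeric(stats::predict(m)))
      vr <- 0
      ve <- if (fit$family == "gaussian")
        sum(stats::residuals(m)^2) / stats::df.residual(m) else pi^2 / 3
    }
  }
  tot <- vf + vr + ve
  c(marginal = vf / tot, conditional = (vf + vr) / tot)
}

#' Influence of single random-effect levels
#'
#' Refits the full model with each year and each individual excluded in turn
#' and reports, per predictor, the maximum absolute shift of its estimate —
#' a check that no single season or individual drives the results.
#'
#' @inheritParams fit_model
#' @param effects Which level sets to drop: `"year"`, `"individual"`, or
#'   both. Each requested effect must have at least 3 levels.
#' @return List: `shifts` (matrix, dropped level x predictor, absolute
#'   estimate shifts) and `max_shift` (named vector, per-predictor maximum).
#' @export
influence_check <- function(rows, spec = full_model_terms,
                            family = c("binomial", "gaussian"),
                            random_effects = FALSE,
                            effects = c("year", "individual")) {
  family <- match.arg(family)
  effects <- match.arg(effects, several.ok = TRUE)
  base <- fit_model(rows, spec, family = family,
                    random_effects = random_effects)
  levels_ <- character(0)
  subsets <- list()
  if ("year" %in% effects) {
    yrs <- unique(rows$year)
    if (length(yrs) < 3L) stop("need at least 3 seasons to drop seasons")
    for (y in yrs) {
      levels_ <- c(levels_, paste0("year:", y))
      subsets[[length(subsets) + 1L]] <- rows[rows$year != y, , drop = FALSE]
    }
  }
  if ("individual" %in% effects) {
    inds <- unique(c(rows$id1, rows$id2))
    if (length(inds) < 3L) stop("need at least 3 individuals")
    for (i in inds) {
      levels_ <- c(levels_, paste0("id:", i))
      subsets[[length(subsets) + 1L]] <-
        rows[rows$id1 != i & rows$id2 != i, , drop = FALSE]
    }
  }
  shifts <- t(vapply(subsets, function(sub) {
    f <- fit_model(sub, spec, family = family,
                   random_effects = random_effects)
    abs(f$estimates[names(base$estimates)] - base$estimates)
  }, base$estimates))
  rownames(shifts) <- levels_
  list(shifts = shifts, max_shift = apply(shifts, 2L, max))
}
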