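# Dyad-level association statistics.
#
# The simple ratio index (SRI) is the proportion of sampling periods in which
# a dyad was seen together out of all periods in which either member was
# seen: SRI = P_AB / (P_A + P_B + P_AB), with P_A and P_B the counts of scans
# where only one member was seen. (Read literally with P_A including joint
# sightings the index could never reach 1; the standard simple-ratio
# definition is used, with a strict-literal mode behind `literal = TRUE`.)

#' Dyadic sighting counts
#'
#' @param ds A [scan_dataset()].
#' @return Data frame with one row per unordered dyad: `id_a`, `id_b`,
#'   `n_together` (scans with both), `n_a_only`, `n_b_only`, `n_scans`.
#' @export
dyad_counts <- function(ds) {
  M <- ds$present
  n <- ncol(M)
  dy <- dyad_pairs(n)
  X <- crossprod(M)
  together <- X[dy]
  tot <- colSums(M)
  data.frame(id_a = colnames(M)[dy[, 1L]], id_b = colnames(M)[dy[, 2L]],
             n_together = as.integer(together),
             n_a_only = as.integer(tot[dy[, 1L]] - together),
             n_b_only = as.integer(tot[dy[, 2L]] - together),
             n_scans = nrow(M), stringsAsFactors = FALSE)
}

#' Simple ratio index
#'
#' @param counts Data frame from [dyad_counts()] (or any frame with
#'   `n_together`, `n_a_only`, `n_b_only` columns).
#' @param literal If `TRUE`, use the literal reading in which the lone-count
#'   terms include joint sightings (bounds the index below 1; not
#'   recommended, provided for comparison only).
#' @return Numeric vector of SRI values in `[0, 1]`; 0 when a dyad was never
#'   seen at all (zero denominator).
#' @export
sri <- function(counts, literal = FALSE) {
  den <- counts$n_a_only + counts$n_b_only + counts$n_together
  if (literal)
    den <- den + 2 * counts$n_together
  ifelse(den > 0, counts$n_together / den, 0)
}

#' Permutation-expected SRI
#'
#' @param ens A [build_ensemble()] result.
#' @return List: `mean` (per-dyad expected SRI, the mean over realizations),
#'   `perm` (B x n_dyads matrix of permuted SRI values), `dyads` (id pairs).
#' @export
expected_sri <- function(ens) {
  stopifnot(inherits(ens, "perm_ensemble"))
  list(mean = colMeans(ens$sri), perm = ens$sri, dyads = ens$dyads)
}

#' Pairwise affinity value
#'
#' Observed SRI minus permutation-expected SRI, in `[-1, 1]`: above 0 the
#' dyad associated more than expected under the constrained null, below 0
#' less.
#'
#' @param sri_obs,sri_exp Numeric vectors in `[0, 1]`.
#' @return `sri_obs - sri_exp`.
#' @export
pav <- function(sri_obs, sri_exp) {
  stopifnot(all(sri_obs >= 0 & sri_obs <= 1), all(sri_exp >= 0 & sri_exp <= 1))
  sri_obs - sri_exp
}

#' Permutation significance of a dyad's association
#'
#' A dyad is a significant associate when its observed SRI is strictly higher
#' than more than `(1 - alpha) * B` of the permuted values (for B = 1000 and
#' alpha = 0.05: higher than 950 of the 1000 randomizations, i.e. rank 951
#' or more). Ties count against significance.
#'
#' @param sri_obs Observed SRI (scalar).
#' @param permuted Numeric vector of B permuted SRI values.
#' @param alpha Significance level.
#' @return List: `p_rank` (number of permuted values strictly below the
#'   observed) and `significant` (logical).
#' @export
significance <- function(sri_obs, permuted, alpha = 0.05) {
  B <- length(permuted)
  stopifnot(B >= 1L)
  p_rank <- sum(sri_obs > permuted)
  list(p_rank = p_rank, significant = p_rank > (1 - alpha) * B)
}

#' Dyadic association table
#'
#' One row per unordered dyad: observed and expected SRI, pairwise affinity
#' value, permutation rank and significance flag, and (optionally) the
#' bootstrap SD of the SRI.
#'
#' @param ds A [scan_dataset()].
#' @param ens The [build_ensemble()] result for `ds`.
#' @param boot Optional [bootstrap_scans()] result for `ds`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `id_a`, `id_b`, `season`, `sri_obs`,
#'   `sri_exp`, `pav`, `p_rank`, `significant`, `sri_sd_boot`.
#' @export
dyad_table <- function(ds, ens, boot = NULL, alpha = 0.05) {
  stopifnot(inherits(ens, "perm_ensemble"))
  counts <- dyad_counts(ds)
  if (!identical(counts$id_a, ens$dyads$id_a) ||
      !identical(counts$id_b, ens$dyads$id_b))
    stop("ensemble was built on a different roster than `ds`")
  sri_obs <- sri(counts)
  exp_ <- expected_sri(ens)
  p_rank <- colSums(ens$sri < rep(sri_obs, each = ens$B))
  out <- data.frame(id_a = counts$id_a, id_b = counts$id_b,
                    season = ds$roster$season,
                    sri_obs = sri_obs, sri_exp = exp_$mean,
                    pav = pav(sri_obs, exp_$mean),
                    p_rank = as.integer(p_rank),
                    significant = p_rank > (1 - alpha) * ens$B,
                    sri_sd_boot = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "sri_bootstrap"))
    key <- paste(out$id_a, out$id_b)
    out$sri_sd_boot <- boot$dyads$sri_sd[match(key, paste(boot$dyads$id_a,
                                                          boot$dyads$id_b))]
  }
  out
}
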