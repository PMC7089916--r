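# Shared fixtures, all built in code.

# five-member roster with known kinship: B is A's offspring, C is A's
# offspring (so B-C are maternal siblings), D and E unrelated
tiny_roster <- function(season = "2014/5") {
  season_roster(season, data.frame(
    id = c("A", "B", "C", "D", "E"),
    sex = c("female", "female", "male", "female", "male"),
    age_class = c("adult", "subadult", "subadult", "adult", "adult"),
    mother_id = c(NA, "A", "A", NA, NA),
    infant = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE))
}

# handcrafted 4-scan dataset on the tiny roster
tiny_dataset <- function(roster = tiny_roster()) {
  present <- rbind(
    c(1, 1, 0, 0, 0),   # A B
    c(1, 1, 0, 0, 0),   # A B   (run of 2 with focal A)
    c(1, 0, 1, 1, 0),   # A C D
    c(0, 0, 1, 1, 1))   # C D E
  colnames(present) <- c("A", "B", "C", "D", "E")
  scan_dataset(roster, present, focal = c("A", "A", "A", "C"))
}

# random small scan dataset for brute-force comparisons
random_dataset <- function(n_ids = 5L, n_scans = 8L) {
  ids <- LETTERS[seq_len(n_ids)]
  roster <- season_roster("r", data.frame(
    id = ids, sex = sample(c("female", "male"), n_ids, replace = TRUE),
    stringsAsFactors = FALSE))
  present <- matrix(runif(n_scans * n_ids) < 0.45, n_scans, n_ids,
                    dimnames = list(NULL, ids))
  focal <- ids[sample.int(n_ids, n_scans, replace = TRUE)]
  present[cbind(seq_len(n_scans), match(focal, ids))] <- TRUE
  scan_dataset(roster, present, focal)
}

# Generative dyad-year rows with known fixed effects and zero random-effect
# variance: n_ind individuals with attributes, all dyads over `seasons`
# seasons, responses drawn from the stated linear predictors.
make_recovery_rows <- function(n_ind = 32L, seasons = 3L,
                               beta = c(intercept = -1.5, kinship = 1,
                                        rank_diff = -1),
                               sigma_pav = 0.1, pav_scale = 0.05) {
  ids <- sprintf("I%02d", seq_len(n_ind))
  sex <- sample(c("female", "male"), n_ind, replace = TRUE, prob = c(.6, .4))
  age <- sample(c("adult", "subadult"), n_ind, replace = TRUE, prob = c(.7, .3))
  inf <- ifelse(sex == "female" & age == "adult", runif(n_ind) < 0.4, FALSE)
  kin_mother <- sample(c(NA_character_, ids), n_ind, replace = TRUE,
                       prob = c(0.2, rep(0.8 / n_ind, n_ind)))
  kin_mother[kin_mother == ids] <- NA
  rank <- setNames(runif(n_ind), ids)
  dy <- t(combn(n_ind, 2))
  rows <- do.call(rbind, lapply(seq_len(seasons), function(s) {
    data.frame(
      id1 = ids[dy[, 1]], id2 = ids[dy[, 2]],
      dyad = paste(ids[dy[, 1]], ids[dy[, 2]], sep = "-"),
      year = paste0("y", s),
      kinship = as.integer(
        (!is.na(kin_mother[dy[, 1]]) & kin_mother[dy[, 1]] == ids[dy[, 2]]) |
        (!is.na(kin_mother[dy[, 2]]) & kin_mother[dy[, 2]] == ids[dy[, 1]]) |
        (!is.na(kin_mother[dy[, 1]]) & !is.na(kin_mother[dy[, 2]]) &
           kin_mother[dy[, 1]] == kin_mother[dy[, 2]])),
      sex_combo = factor(ifelse(sex[dy[, 1]] == sex[dy[, 2]],
                                paste(sex[dy[, 1]], sex[dy[, 2]], sep = "_"),
                                "female_male"),
                         levels = c("female_female", "female_male", "male_male")),
      age_combo = factor(ifelse(age[dy[, 1]] == age[dy[, 2]],
                                paste(age[dy[, 1]], age[dy[, 2]], sep = "_"),
                                "adult_subadult"),
                         levels = c("adult_adult", "adult_subadult",
                                    "subadult_subadult")),
      infant_combo = factor(ifelse(inf[dy[, 1]] == inf[dy[, 2]],
                                   ifelse(inf[dy[, 1]], "yes_yes", "no_no"),
                                   "yes_no"),
                            levels = c("no_no", "yes_no", "yes_yes")),
      rank_diff_raw = abs(rank[dy[, 1]] - rank[dy[, 2]]),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  rows$rank_diff <- as.numeric(scale(rows$rank_diff_raw))
  eta <- beta[["intercept"]] + beta[["kinship"]] * rows$kinship +
    beta[["rank_diff"]] * rows$rank_diff
  rows$response_sig <- as.integer(runif(nrow(rows)) < plogis(eta))
  rows$response_pav <- pav_scale * eta + rnorm(nrow(rows), 0, sigma_pav)
  rows
}
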