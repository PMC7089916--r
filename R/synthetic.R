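# Synthetic scan-data generator.
#
# The study system is an empirical one; this generator is a package artifact
# that emulates its data structure (focal-follow blocks, 15-min scans,
# temporal autocorrelation, heterogeneous gregariousness, subgroup sizes with
# mean ~6 and max ~17) with injectable dyadic affinity so that null
# calibration and parameter recovery can be tested against known truth.

#' Configuration for the synthetic scan generator
#'
#' Defaults describe one season of the kind of dataset the package targets: a
#' group of about 30 weaned individuals (majority female), ~5000 scans taken
#' every 15 minutes in 1-h focal follows (blocks of 4), subgroup sizes with
#' mean 6 and maximum around 17, moderate temporal autocorrelation, and no
#' built-in dyadic preference (all affinity effects zero) so that the default
#' world is a null world.
#'
#' @param n_individuals Roster size.
#' @param sex_ratio Proportion female.
#' @param n_matrilines Number of matrilines; members of a matriline share a
#'   mother link, so same-matriline dyads are kin. `n_matrilines =
#'   n_individuals` yields no kin dyads.
#' @param prop_subadult Proportion of the roster classed subadult.
#' @param prop_mothers_with_infant Proportion of adult females with a newborn
#'   infant in the season.
#' @param n_scans Number of scans to generate.
#' @param follow_block Scans per focal follow (the focal cycles through the
#'   roster between blocks).
#' @param size_distribution List `(mu, size, max_size)`: subgroup size is
#'   `1 + NegBinom(mu, size)` truncated at `max_size` (and at the roster
#'   size). Defaults hit mean ~6, max ~17 at a few thousand scans.
#' @param gregariousness_sd SD of per-individual log-weights for being in a
#'   subgroup (0 = homogeneous).
#' @param autocorr_prob Probability that a scan within a follow block repeats
#'   the previous scan's composition exactly.
#' @param affinity_effects Named list of log-weight effect sizes:
#'   `kin`, `rank_similarity`, `same_sex_subadult`, `mixed_sex_adult`,
#'   `both_infants`. See [build_affinity()].
#' @param seed Integer seed; generation is deterministic given the config.
#' @param season Season label for the roster.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 30L,
                             sex_ratio = 0.65,
                             n_matrilines = 8L,
                             prop_subadult = 0.25,
                             prop_mothers_with_infant = 0.4,
                             n_scans = 5000L,
                             follow_block = 4L,
                             size_distribution = list(mu = 5, size = 8,
                                                      max_size = 17L),
                             gregariousness_sd = 0.5,
                             autocorr_prob = 0.3,
                             affinity_effects = list(),
                             seed = 1L,
                             season = "synthetic") {
  if (missing(size_distribution))   # default cap cannot exceed the roster
    size_distribution$max_size <- min(17L, as.integer(n_individuals))
  eff <- list(kin = 0, rank_similarity = 0, same_sex_subadult = 0,
              mixed_sex_adult = 0, both_infants = 0)
  unknown <- setdiff(names(affinity_effects), names(eff))
  if (length(unknown))
    stop("unknown affinity effect(s): ", paste(unknown, collapse = ", "))
  eff[names(affinity_effects)] <- affinity_effects
  cfg <- list(n_individuals = as.integer(n_individuals),
              sex_ratio = sex_ratio, n_matrilines = as.integer(n_matrilines),
              prop_subadult = prop_subadult,
              prop_mothers_with_infant = prop_mothers_with_infant,
              n_scans = as.integer(n_scans),
              follow_block = as.integer(follow_block),
              size_distribution = size_distribution,
              gregariousness_sd = gregariousness_sd,
              autocorr_prob = autocorr_prob,
              affinity_effects = eff, seed = as.integer(seed),
              season = season)
  props <- c(cfg$sex_ratio, cfg$prop_subadult, cfg$prop_mothers_with_infant,
             cfg$autocorr_prob)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$n_scans < 1L) stop("n_scans must be >= 1")
  if (cfg$follow_block < 1L) stop("follow_block must be >= 1")
  if (cfg$n_matrilines > cfg$n_individuals)
    stop("n_matrilines cannot exceed n_individuals")
  if (!all(is.finite(unlist(eff)))) stop("affinity effects must be finite")
  structure(cfg, class = "synthetic_config")
}

#' Read a synthetic configuration from JSON
#' @param path JSON file with (a subset of) the [synthetic_config()] fields.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$size_distribution))
    raw$size_distribution <- as.list(raw$size_distribution)
  if (!is.null(raw$affinity_effects))
    raw$affinity_effects <- as.list(raw$affinity_effects)
  do.call(synthetic_config, raw)
}

#' Generate a roster with ground-truth attributes
#'
#' Assigns sex, age class, matriline (kinship via shared mother links),
#' standardized dominance rank (uniform spacing on `[0, 1]`, shuffled), and
#' infant flags. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return List with elements `roster` (a [season_roster()]), `rank` (named
#'   vector, the true standardized ranks), and `matriline` (named integer).
#' @export
generate_roster <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  ids <- sprintf("M%02d", seq_len(n))
  n_f <- round(n * cfg$sex_ratio)
  sex <- sample(rep(c("female", "male"), c(n_f, n - n_f)))
  n_sub <- round(n * cfg$prop_subadult)
  age_class <- sample(rep(c("subadult", "adult"), c(n_sub, n - n_sub)))
  matriline <- sample(rep_len(seq_len(cfg$n_matrilines), n))
  mother_id <- rep(NA_character_, n)
  for (m in unique(matriline)) {
    mem <- which(matriline == m)
    if (length(mem) < 2L) next
    fem <- mem[sex[mem] == "female"]
    matriarch <- if (length(fem)) fem[1L] else NA_integer_
    if (is.na(matriarch)) next
    mother_id[setdiff(mem, matriarch)] <- ids[matriarch]
  }
  infant <- rep(FALSE, n)
  af <- which(sex == "female" & age_class == "adult")
  n_inf <- round(length(af) * cfg$prop_mothers_with_infant)
  if (n_inf > 0L) infant[sample(af, n_inf)] <- TRUE
  rank <- sample(seq(0, 1, length.out = n))
  names(rank) <- ids
  names(matriline) <- ids
  roster <- season_roster(cfg$season,
                          data.frame(id = ids, sex = sex,
                                     age_class = age_class,
                                     mother_id = mother_id, infant = infant,
                                     stringsAsFactors = FALSE))
  list(roster = roster, rank = rank, matriline = matriline)
}

#' Maternal kinship matrix of a roster
#'
#' Dyads are kin when they are a mother-offspring pair or maternal siblings
#' (shared known mother), following the binary kinship definition used in the
#' dyadic models.
#'
#' @param roster A [season_roster()].
#' @return Symmetric logical matrix (ids as dimnames), `FALSE` diagonal.
#' @export
kin_matrix <- function(roster) {
  mem <- roster$members
  n <- nrow(mem)
  mo <- outer(mem$mother_id, mem$id, "==")        # i's mother is j
  mo[is.na(mo)] <- FALSE
  sib <- outer(mem$mother_id, mem$mother_id, "==") # shared known mother
  sib[is.na(sib)] <- FALSE
  k <- mo | t(mo) | sib
  diag(k) <- FALSE
  dimnames(k) <- list(mem$id, mem$id)
  k
}

#' Latent dyadic affinity matrix
#'
#' Builds the symmetric matrix of log-weight affinities used by the
#' generator: `kin * 1[kin dyad] + rank_similarity * (1 - |rank_i - rank_j|)
#' + same_sex_subadult * 1[both subadult, same sex] + mixed_sex_adult *
#' 1[both adult, opposite sex] + both_infants * 1[both mothers of newborns]`.
#'
#' @param truth Output of [generate_roster()] (roster plus true ranks).
#' @param effects Named list of effect sizes (missing entries default to 0).
#' @return Symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
build_affinity <- function(truth, effects = list()) {
  eff <- list(kin = 0, rank_similarity = 0, same_sex_subadult = 0,
              mixed_sex_adult = 0, both_infants = 0)
  eff[names(effects)] <- effects
  mem <- truth$roster$members
  n <- nrow(mem)
  kin <- kin_matrix(truth$roster)
  rsim <- 1 - abs(outer(truth$rank, truth$rank, "-"))
  same_sex <- outer(mem$sex, mem$sex, "==")
  both_sub <- outer(mem$age_class == "subadult", mem$age_class == "subadult", "&")
  both_ad <- outer(mem$age_class == "adult", mem$age_class == "adult", "&")
  both_inf <- outer(mem$infant, mem$infant, "&")
  a <- eff$kin * kin +
    eff$rank_similarity * rsim +
    eff$same_sex_subadult * (both_sub & same_sex) +
    eff$mixed_sex_adult * (both_ad & !same_sex) +
    eff$both_infants * both_inf
  diag(a) <- 0
  dimnames(a) <- list(mem$id, mem$id)
  a
}

#' Generate a synthetic scan dataset with ground truth
#'
#' Scans are produced in focal-follow blocks (the focal cycles through the
#' roster). Within a block, each scan repeats the previous composition with
#' probability `autocorr_prob`; otherwise a subgroup size `s` is drawn from
#' the (shifted, truncated) size distribution, the focal is included, and the
#' remaining `s - 1` members are filled by sequential weighted sampling
#' without replacement with `weight(j) = exp(gregariousness_j + mean affinity
#' of j to the members already selected)`.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `dataset` (a [scan_dataset()]) and `truth` (roster
#'   attributes, true ranks, affinity matrix, gregariousness weights, and the
#'   config) for parameter-recovery tests.
#' @export
generate_scan_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  truth <- generate_roster(cfg)   # seeds the stream with cfg$seed
  n <- cfg$n_individuals
  aff <- build_affinity(truth, cfg$affinity_effects)
  greg <- stats::rnorm(n, 0, cfg$gregariousness_sd)
  names(greg) <- roster_ids(truth$roster)
  sd_ <- cfg$size_distribution
  max_size <- min(sd_$max_size, n)
  if (sd_$max_size > n)
    warning("size distribution max_size truncated to roster size ", n)
  present <- matrix(FALSE, cfg$n_scans, n,
                    dimnames = list(NULL, roster_ids(truth$roster)))
  focal_idx <- integer(cfg$n_scans)
  focal_cycle <- rep(seq_len(n),
                     length.out = ceiling(cfg$n_scans / cfg$follow_block))
  for (t in seq_len(cfg$n_scans)) {
    block <- (t - 1L) %/% cfg$follow_block + 1L
    f <- focal_cycle[block]
    focal_idx[t] <- f
    in_block <- (t - 1L) %% cfg$follow_block > 0L
    if (in_block && stats::runif(1) < cfg$autocorr_prob) {
      present[t, ] <- present[t - 1L, ]
      next
    }
    repeat {
      s <- 1L + stats::rnbinom(1L, mu = sd_$mu, size = sd_$size)
      if (s <= max_size) break
    }
    sel <- f
    while (length(sel) < s) {
      cand <- setdiff(seq_len(n), sel)
      w <- exp(greg[cand] + rowMeans(aff[cand, sel, drop = FALSE]))
      pick <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L, prob = w)]
      sel <- c(sel, pick)
    }
    present[t, sel] <- TRUE
  }
  ds <- scan_dataset(truth$roster, present,
                     roster_ids(truth$roster)[focal_idx])
  list(dataset = ds,
       truth = list(roster = truth$roster, rank = truth$rank,
                    matriline = truth$matriline, affinity = aff,
                    gregariousness = greg, config = cfg))
}

#' Write ground truth to JSON
#' @param truth `truth` element of [generate_scan_dataset()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(season = truth$roster$season,
              members = truth$roster$members,
              rank = as.list(truth$rank),
              matriline = as.list(truth$matriline),
              gregariousness = as.list(truth$gregariousness),
              affinity = truth$affinity,
              config = unclass(truth$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
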