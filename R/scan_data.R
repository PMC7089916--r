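# Data model and I/O for scan-sampled subgroup composition data.
#
# A scan is an instantaneous record of which group members were visible
# around a focal individual. Internally a dataset is a logical matrix
# (scans x roster members) plus the focal identity and timestamp of each
# scan; all downstream statistics are computed from this representation.

#' Construct a season roster
#'
#' A roster fixes the set of individuals eligible for one observation season
#' together with the attributes used downstream: sex, age class (adult vs
#' subadult), maternal identity (for kinship), and whether the individual had
#' a newborn infant that season.
#'
#' @param season Season label, e.g. `"2014/5"`.
#' @param individuals Data frame with columns `id` (unique character labels),
#'   `sex` (`"female"` or `"male"`), and optionally `age_class` (`"adult"` or
#'   `"subadult"`, default adult), `mother_id` (character or `NA`; when
#'   present and not `NA` it may name a roster member or a known absent dam),
#'   and `infant` (logical, default `FALSE`).
#' @return An object of class `season_roster`.
#' @seealso [assign_age_class()] to derive age classes from birth years.
#' @export
season_roster <- function(season, individuals) {
  stopifnot(is.character(season) || is.factor(season), length(season) == 1L)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (!all(c("id", "sex") %in% names(individuals)))
    stop("`individuals` must have columns `id` and `sex`")
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id))
    stop("duplicate individual ids in roster: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  if (!all(individuals$sex %in% c("female", "male")))
    stop("`sex` must be \"female\" or \"male\" for every individual")
  if (is.null(individuals$age_class)) individuals$age_class <- "adult"
  if (!all(individuals$age_class %in% c("adult", "subadult")))
    stop("`age_class` must be \"adult\" or \"subadult\"")
  if (is.null(individuals$mother_id)) individuals$mother_id <- NA_character_
  individuals$mother_id <- as.character(individuals$mother_id)
  if (is.null(individuals$infant)) individuals$infant <- FALSE
  individuals$infant <- as.logical(individuals$infant)
  rownames(individuals) <- NULL
  structure(list(season = as.character(season),
                 members = individuals[, c("id", "sex", "age_class",
                                           "mother_id", "infant")]),
            class = "season_roster")
}

#' @export
print.season_roster <- function(x, ...) {
  cat("Season roster", x$season, "-", nrow(x$members), "individuals (",
      sum(x$members$sex == "female"), "females,",
      sum(x$members$sex == "male"), "males;",
      sum(x$members$age_class == "subadult"), "subadults )\n")
  invisible(x)
}

roster_ids <- function(roster) roster$members$id

#' Derive age classes from birth years
#'
#' Individuals enter the analysis once weaned (older than 3 years at season
#' start). Females older than 5 and males older than 7 at season start are
#' classed adult, otherwise subadult.
#'
#' @param sex Character vector, `"female"`/`"male"`.
#' @param birth_year Integer vector of birth years.
#' @param season_start_year Integer; calendar year the season starts in.
#' @return Character vector: `"adult"`, `"subadult"`, or `NA` for individuals
#'   aged 3 or younger (ineligible).
#' @export
assign_age_class <- function(sex, birth_year, season_start_year) {
  age <- season_start_year - birth_year
  out <- ifelse(age > ifelse(sex == "female", 5, 7), "adult", "subadult")
  out[age <= 3] <- NA_character_
  out
}

#' Construct a scan dataset
#'
#' @param roster A [season_roster()].
#' @param present Logical or 0/1 matrix, one row per scan, columns named by
#'   roster ids (any order; reordered internally). `present[s, i]` records
#'   whether individual i was in the focal's subgroup at scan s.
#' @param focal Character vector of focal ids, one per scan. Scans where the
#'   focal is not marked present are repaired (the focal is added) with a
#'   warning: the subgroup is defined around the focal, so the focal is a
#'   member of its own subgroup by construction.
#' @param timestamp Optional character/POSIXct vector (ISO-8601 sorts
#'   correctly as text). Defaults to a 15-minute grid. Scans are ordered by
#'   timestamp.
#' @param scan_id Optional integer ids; defaults to `1:n`.
#' @return An object of class `scan_dataset`.
#' @export
scan_dataset <- function(roster, present, focal, timestamp = NULL,
                         scan_id = NULL) {
  stopifnot(inherits(roster, "season_roster"))
  ids <- roster_ids(roster)
  present <- as.matrix(present)
  if (is.null(colnames(present)))
    stop("`present` must have column names (roster ids)")
  unknown <- setdiff(colnames(present), ids)
  if (length(unknown))
    stop("unknown member id(s) in scan data: ", paste(unknown, collapse = ", "))
  if (!all(present %in% c(0, 1)))
    stop("`present` cells must be 0/1 (or logical)")
  m <- matrix(FALSE, nrow(present), length(ids), dimnames = list(NULL, ids))
  m[, colnames(present)] <- present == 1
  n <- nrow(m)
  focal <- as.character(focal)
  if (length(focal) != n) stop("`focal` must have one entry per scan")
  if (!all(focal %in% ids))
    stop("unknown focal id(s): ", paste(setdiff(focal, ids), collapse = ", "))
  if (is.null(timestamp)) {
    timestamp <- format(as.POSIXct("2014-10-01 06:00:00", tz = "UTC") +
                          900 * (seq_len(n) - 1L), "%Y-%m-%dT%H:%M:%S")
  }
  timestamp <- as.character(timestamp)
  if (is.null(scan_id)) scan_id <- seq_len(n)
  scan_id <- as.integer(scan_id)
  ord <- order(timestamp, scan_id)
  m <- m[ord, , drop = FALSE]
  focal <- focal[ord]; timestamp <- timestamp[ord]; scan_id <- scan_id[ord]
  fix <- !m[cbind(seq_len(n), match(focal, ids))]
  if (any(fix)) {
    warning(sum(fix), " scan(s) did not mark the focal present; repaired")
    m[cbind(which(fix), match(focal[fix], ids))] <- TRUE
  }
  structure(list(roster = roster, present = m, focal = focal,
                 timestamp = timestamp, scan_id = scan_id),
            class = "scan_dataset")
}

#' @export
print.scan_dataset <- function(x, ...) {
  cat("Scan dataset:", nrow(x$present), "scans,",
      ncol(x$present), "roster members, season", x$roster$season, "\n")
  cat("  mean subgroup size", round(mean(rowSums(x$present)), 2),
      "| max", max(rowSums(x$present)), "\n")
  invisible(x)
}

n_scans <- function(ds) nrow(ds$present)

# Composition keys: one canonical string per scan, used for run detection,
# entropy, and distribution alignment. For rosters of up to 49 members the
# composition bitmask sum(2^(i-1)) is an exact integer below 2^49 < 2^53, so
# the key is a single matrix-vector product; larger rosters fall back to
# index strings.
composition_keys <- function(present) {
  n <- ncol(present)
  if (n <= 49L)
    sprintf("%.0f", as.vector(present %*% 2^(seq_len(n) - 1L)))
  else
    apply(present, 1L, function(r) paste(which(r), collapse = ","))
}

#' Read scan data from CSV
#'
#' Two dialects are supported. Wide (canonical): columns `scan_id`,
#' `timestamp`, `focal`, then one 0/1 column per roster member. Long: columns
#' `scan_id`, `timestamp`, `focal`, `member`, one row per present member.
#' The dialect is auto-detected from the header unless declared.
#'
#' @param path CSV file path (UTF-8, comma-separated).
#' @param roster A [season_roster()]; member columns/ids are validated
#'   against it.
#' @param dialect `"auto"`, `"wide"`, or `"long"`.
#' @param drop_unknown If `TRUE`, member ids absent from the roster are
#'   silently dropped instead of raising an error (for datasets containing
#'   unidentifiable individuals).
#' @return A [scan_dataset()].
#' @export
read_scans <- function(path, roster, dialect = c("auto", "wide", "long"),
                       drop_unknown = FALSE) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("scan_id", "timestamp", "focal")
  if (!all(fixed %in% names(df)))
    stop("scan CSV must have columns scan_id, timestamp, focal")
  if (dialect == "auto")
    dialect <- if ("member" %in% names(df)) "long" else "wide"
  ids <- roster_ids(roster)
  if (dialect == "wide") {
    member_cols <- setdiff(names(df), fixed)
    unknown <- setdiff(member_cols, ids)
    if (length(unknown)) {
      if (drop_unknown) member_cols <- intersect(member_cols, ids)
      else stop("unknown member column(s): ", paste(unknown, collapse = ", "))
    }
    cells <- as.matrix(df[, member_cols, drop = FALSE])
    if (!all(cells %in% c(0, 1)))
      stop("non-0/1 cell(s) in member columns of ", path)
    present <- cells
    colnames(present) <- member_cols
    scan_dataset(roster, present, df$focal, df$timestamp, df$scan_id)
  } else {
    unknown <- setdiff(df$member, ids)
    if (length(unknown)) {
      if (drop_unknown) df <- df[df$member %in% ids, , drop = FALSE]
      else stop("unknown member id(s): ", paste(unknown, collapse = ", "))
    }
    meta <- unique(df[, fixed])
    if (anyDuplicated(meta$scan_id))
      stop("inconsistent timestamp/focal within scan_id in ", path)
    present <- matrix(FALSE, nrow(meta), length(ids),
                      dimnames = list(NULL, ids))
    present[cbind(match(df$scan_id, meta$scan_id), match(df$member, ids))] <- TRUE
    scan_dataset(roster, present, meta$focal, meta$timestamp, meta$scan_id)
  }
}

#' Write scan data to CSV
#'
#' Inverse of [read_scans()]: `read_scans(write_scans(ds))` reproduces `ds`.
#'
#' @param ds A [scan_dataset()].
#' @param path Output CSV path.
#' @param dialect `"wide"` (0/1 column per member, canonical) or `"long"`
#'   (one row per present member).
#' @return `path`, invisibly.
#' @export
write_scans <- function(ds, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    out <- data.frame(scan_id = ds$scan_id, timestamp = ds$timestamp,
                      focal = ds$focal, check.names = FALSE)
    out <- cbind(out, as.data.frame(ds$present * 1L, check.names = FALSE))
  } else {
    idx <- which(ds$present, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    out <- data.frame(scan_id = ds$scan_id[idx[, 1L]],
                      timestamp = ds$timestamp[idx[, 1L]],
                      focal = ds$focal[idx[, 1L]],
                      member = colnames(ds$present)[idx[, 2L]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a scan dataset to season-eligible individuals
#'
#' Individuals not present for the whole season (or too young) are excluded
#' from analysis: their presences are removed from every scan. Scans whose
#' subgroup becomes empty, or whose focal is not eligible, are dropped (the
#' number dropped is reported via a message).
#'
#' @param ds A [scan_dataset()] (possibly built on a superset roster).
#' @param roster A [season_roster()] listing the season-eligible members.
#' @return A [scan_dataset()] on `roster`. Idempotent.
#' @export
filter_season <- function(ds, roster) {
  keep_ids <- intersect(colnames(ds$present), roster_ids(roster))
  m <- ds$present[, keep_ids, drop = FALSE]
  ok_focal <- ds$focal %in% roster_ids(roster)
  ok_nonempty <- rowSums(m) > 0
  keep <- ok_focal & ok_nonempty
  if (any(!keep))
    message("filter_season: dropped ", sum(!keep), " scan(s) (",
            sum(!ok_focal), " ineligible focal, ",
            sum(ok_focal & !ok_nonempty), " emptied)")
  scan_dataset(roster, m[keep, , drop = FALSE], ds$focal[keep],
               ds$timestamp[keep], ds$scan_id[keep])
}

#' Individual occurrence frequencies
#'
#' The proportion of scans in which each roster member appears; these are the
#' gregariousness weights used by the constrained permutation null model.
#'
#' @param ds A [scan_dataset()].
#' @return Named numeric vector in `[0, 1]`, one entry per roster member.
#' @export
occurrence_frequency <- function(ds) {
  if (n_scans(ds) == 0L) stop("empty dataset: occurrence frequency undefined")
  colMeans(ds$present)
}

#' Summary statistics of a scan dataset
#'
#' @param ds A [scan_dataset()].
#' @return A list (class `scan_summary`): number of scans, mean and maximum
#'   subgroup size, proportion of scans containing at least one male /
#'   female, mean number of males and females per scan, number and
#'   proportion of unique subgroup compositions.
#' @export
summarize_dataset <- function(ds) {
  sizes <- rowSums(ds$present)
  sex <- ds$roster$members$sex[match(colnames(ds$present), roster_ids(ds$roster))]
  males <- ds$present[, sex == "male", drop = FALSE]
  females <- ds$present[, sex == "female", drop = FALSE]
  keys <- composition_keys(ds$present)
  uniq <- length(unique(keys))
  structure(list(
    season = ds$roster$season,
    n_scans = n_scans(ds),
    n_individuals = ncol(ds$present),
    mean_size = mean(sizes),
    max_size = max(sizes),
    prop_with_male = mean(rowSums(males) > 0),
    prop_with_female = mean(rowSums(females) > 0),
    mean_males = mean(rowSums(males)),
    mean_females = mean(rowSums(females)),
    unique_compositions = uniq,
    prop_unique = uniq / n_scans(ds)
  ), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("Season", x$season, ":", x$n_scans, "scans,", x$n_individuals,
      "individuals\n")
  cat(sprintf("  subgroup size mean %.2f, max %d\n", x$mean_size, x$max_size))
  cat(sprintf("  %.0f%% of scans with >=1 male (mean %.1f), %.0f%% with >=1 female (mean %.1f)\n",
              100 * x$prop_with_male, x$mean_males,
              100 * x$prop_with_female, x$mean_females))
  cat(sprintf("  %d unique compositions (%.0f%%)\n",
              x$unique_compositions, 100 * x$prop_unique))
  invisible(x)
}
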