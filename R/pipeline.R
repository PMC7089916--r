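# End-to-end orchestration: data -> permutation null -> entropy -> dyadic
# association -> assortativity, with persisted artifacts and a run log.

#' Run the full association-pattern analysis
#'
#' Stages, in order: load or generate the scan dataset; build the constrained
#' permutation ensemble; entropy report; SRI scan bootstrap; dyadic
#' association table; assortativity (dyad rows, dyad-flip multimodel
#' inference for the binomial and Gaussian responses, VIF, R-squared).
#' Every artifact is stamped with the config hash and seed.
#'
#' @param config A list, or path to a JSON file, with fields:
#'   \describe{
#'     \item{synthetic}{list of [synthetic_config()] arguments (synthetic
#'       mode), or}
#'     \item{scans, attributes, season}{paths to a scan CSV and an attribute
#'       CSV (`id, sex, age_class, mother_id, infant`) plus a season label
#'       (real-data mode); optional `supplants` CSV (`date, winner, loser`)
#'       for Elo ranks.}
#'     \item{B}{permutations (default 1000)}
#'     \item{R_boot}{bootstrap replicates (default 1000)}
#'     \item{n_selections}{dyad-flip selections (default 1000)}
#'     \item{alpha}{significance level (default 0.05)}
#'     \item{seed}{master seed (required; no silent nondeterminism)}
#'     \item{random_effects}{use mixed models (default FALSE, see
#'       [fit_model()])}
#'     \item{do_assort}{run the assortativity stage (default TRUE; needs
#'       ranks, i.e. synthetic truth or supplants)}
#'     \item{out_dir}{optional output directory for CSV/JSON artifacts}
#'   }
#' @return Object of class `pipeline_bundle` with elements `summary`,
#'   `entropy`, `dyads`, `boot`, `assort`, `log`, `config`, `config_hash`,
#'   `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(B = 1000L, R_boot = 1000L, n_selections = 1000L,
                   alpha = 0.05, random_effects = FALSE, do_assort = TRUE,
                   refit_subsets = TRUE, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$seed)) stop("config must set `seed`")
  config$seed <- as.integer(config$seed)
  hash <- config_hash(config)
  log_lines <- character(0)
  stamp <- function(stage, t0) {
    line <- sprintf("[%s] %s: %.2fs", format(Sys.time(), "%H:%M:%S"),
                    stage, as.numeric(Sys.time()) - t0)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE))
    stamp(stage, t0)
    out
  }

  ranks <- NULL
  data_stage <- run_stage("scan_data", {
    if (!is.null(config$synthetic)) {
      args <- as.list(config$synthetic)
      args$seed <- if (is.null(args$seed)) config$seed else args$seed
      gen <- generate_scan_dataset(do.call(synthetic_config, args))
      ranks <- gen$truth$rank
      list(ds = gen$dataset, roster = gen$truth$roster, ranks = ranks)
    } else {
      if (is.null(config$scans) || is.null(config$attributes))
        stop("config needs either `synthetic` or `scans` + `attributes`")
      for (p in c(config$scans, config$attributes, config$supplants))
        if (!file.exists(p)) stop("input file not found: ", p)
      attrs <- utils::read.csv(config$attributes, stringsAsFactors = FALSE)
      roster <- season_roster(config$season %||% "season-1", attrs)
      ds <- read_scans(config$scans, roster)
      ds <- filter_season(ds, roster)
      ranks <- NULL
      if (!is.null(config$supplants)) {
        sup <- utils::read.csv(config$supplants, stringsAsFactors = FALSE)
        state <- elo_ratings(sup, ids = union(roster_ids(roster),
                                              unique(c(sup$winner, sup$loser))))
        daily <- do.call(rbind, lapply(unique(state$dates), function(d) {
          rk <- standardized_ordinal_rank(state, d, roster_ids(roster))
          data.frame(date = d, id = names(rk), rank = rk)
        }))
        ranks <- yearly_rank(daily, roster_ids(roster))
      }
      list(ds = ds, roster = roster, ranks = ranks)
    }
  })
  ds <- data_stage$ds
  ranks <- data_stage$ranks
  summary_ <- summarize_dataset(ds)

  ens <- run_stage("null_model",
                   build_ensemble(ds, B = config$B, seed = config$seed))
  entropy <- run_stage("group_entropy", entropy_report(ds, ens))
  boot <- run_stage("bootstrap",
                    bootstrap_scans(ds, R = config$R_boot,
                                    seed = config$seed + 1L))
  dyads <- run_stage("dyadic_association",
                     dyad_table(ds, ens, boot, alpha = config$alpha))

  assort <- NULL
  if (isTRUE(config$do_assort)) {
    if (is.null(ranks)) {
      message("assortativity stage skipped: no ranks available ",
              "(provide `supplants` or use synthetic mode)")
    } else {
      assort <- run_stage("assortativity", {
        season <- ds$roster$season
        rows <- build_dyad_rows(stats::setNames(list(dyads), season),
                                stats::setNames(list(ds$roster), season),
                                stats::setNames(list(ranks), season))
        fits <- lapply(c(binomial = "binomial", gaussian = "gaussian"),
          function(fam) {
            flip <- dyad_flip_inference(
              rows, family = fam, n_selections = config$n_selections,
              seed = config$seed + 2L,
              random_effects = config$random_effects,
              refit_subsets = config$refit_subsets)
            full <- fit_model(rows, family = fam,
                              random_effects = config$random_effects)
            list(flip = flip, r2 = r2_mixed(full))
          })
        vifs <- vif(rows, c("kinship", "rank_diff", "sex_combo",
                            "age_combo", "infant_combo"))
        list(rows = rows, binomial = fits$binomial,
             gaussian = fits$gaussian, vif = vifs)
      })
    }
  }

  bundle <- structure(list(summary = summary_, entropy = entropy,
                           dyads = dyads, boot = boot, assort = assort,
                           log = log_lines, config = config,
                           config_hash = hash, seed = config$seed),
                      class = "pipeline_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config[order(names(config))]
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = bundle$config_hash, seed = bundle$seed)
  utils::write.csv(bundle$dyads, file.path(out_dir, "dyad_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(unclass(bundle$entropy), stamp),
                       file.path(out_dir, "entropy_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(unclass(bundle$summary), stamp),
                       file.path(out_dir, "dataset_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$assort)) {
    tab1 <- multimodel_summary(bundle)
    jsonlite::write_json(c(list(terms = tab1), stamp),
                         file.path(out_dir, "multimodel_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(c(paste("config_hash:", bundle$config_hash),
               paste("seed:", bundle$seed), bundle$log),
             file.path(out_dir, "run_log.txt"))
  writeLines(pipeline_report(bundle), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

# first coefficient belonging to a model term (reference-level contrast);
# interaction components may appear in either order in coefficient names
term_coef <- function(term, estimates) {
  tparts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  for (nm in names(estimates)) {
    nparts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (length(nparts) != length(tparts)) next
    if (all(vapply(tparts, function(tp) any(startsWith(nparts, tp)), TRUE)))
      return(unname(estimates[nm]))
  }
  NA_real_
}

# Table-1-style layout: term, expected weight, estimate and summed weight
# per response family
multimodel_summary <- function(bundle) {
  b <- bundle$assort$binomial$flip
  g <- bundle$assort$gaussian$flip
  df <- b$mean_summed_weights[, c("term", "expected_weight")]
  df$estimate_binomial <- vapply(df$term, term_coef, 0, b$mean_estimates)
  df$summed_weight_binomial <- b$mean_summed_weights$summed_weight
  df$estimate_gaussian <- vapply(df$term, term_coef, 0, g$mean_estimates)
  df$summed_weight_gaussian <- g$mean_summed_weights$summed_weight
  df
}

#' Human-readable analysis report
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of markdown lines (rendered deterministically
#'   from the bundle).
#' @export
pipeline_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  s <- bundle$summary; e <- bundle$entropy
  lines <- c(
    "# Association-pattern analysis",
    "",
    sprintf("Season **%s**: %d scans, %d individuals (config %s, seed %d).",
            s$season, s$n_scans, s$n_individuals,
            substr(bundle$config_hash, 1, 8), bundle$seed),
    "",
    "## Subgroup entropy",
    "",
    sprintf("- Observed entropy: %.4f bits; expected under the constrained null: %.4f bits (B = %d).",
            e$h_obs, e$h_exp, e$B),
    sprintf("- Observed/expected entropy ratio: **%.4f** (1 = composition as random as the null allows).",
            e$ratio),
    sprintf("- Unique compositions: %d of %d scans (%.0f%%).",
            e$unique_obs, e$n_scans, 100 * e$unique_frac),
    sprintf("- KL vs pooled null: %.4f bits; JS distance: %.4f.", e$kl, e$js),
    "",
    "## Dyadic association",
    "",
    sprintf("- %d dyads; %.1f%% significant associates at alpha = %.2f.",
            nrow(bundle$dyads), 100 * mean(bundle$dyads$significant),
            bundle$config$alpha),
    sprintf("- Max bootstrap SD of SRI: %.4f (%d replicates).",
            bundle$boot$max_sd, bundle$boot$R))
  if (!is.null(bundle$assort)) {
    tab <- multimodel_summary(bundle)
    lines <- c(lines, "", "## Assortativity (dyad-flip multimodel inference)",
               "",
               "| term | expected w | est (binom) | sum w (binom) | est (gauss) | sum w (gauss) |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %.2f | %.2f | %.2f | %.2f | %.2f |",
                       tab$term, tab$expected_weight, tab$estimate_binomial,
                       tab$summed_weight_binomial, tab$estimate_gaussian,
                       tab$summed_weight_gaussian),
               "",
               sprintf("Marginal / conditional R2: binomial %.2f / %.2f; gaussian %.2f / %.2f.",
                       bundle$assort$binomial$r2["marginal"],
                       bundle$assort$binomial$r2["conditional"],
                       bundle$assort$gaussian$r2["marginal"],
                       bundle$assort$gaussian$r2["conditional"]),
               sprintf("Max VIF: %.2f.", max(bundle$assort$vif$gvif)))
  }
  lines
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
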