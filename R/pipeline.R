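#' Default analysis configuration
#'
#' Settings for the full pipeline: either a simulation config (`sim`) or
#' input file paths (`pedigree_file`, `breeding_file`, `census_file`);
#' the founder cohort window; gene-drop replicates and seed; and the
#' decision points that the method leaves open, surfaced as config keys —
#' the de-lifing offspring weight, the reproductive-value reference
#' population, and whether lineage survival is genealogical or
#' allele-based.
#'
#' @param ... named overrides; `sim` itself can be overridden with a
#'   [default_config()] object or `NULL` (file input).
#' @return named list of class `analysis_config`.
#' @export
default_analysis_config <- function(...) {
  cfg <- list(
    sim = default_config(),
    pedigree_file = NULL, breeding_file = NULL, census_file = NULL,
    cohort_window = NULL,        # default: first 4 cohorts incl. pre-study founders
    n_reps = 10000L,
    seed = 1L,
    final_year = NULL,           # default: last census year
    delifing_weight = 1,
    rv_reference = "alive",      # or "adults"
    survival_definition = "genealogical"  # or "allele"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) stop("unknown analysis config field(s): ",
                                 paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The file may set any [default_analysis_config()] key; keys under `sim`
#' override the simulation defaults.
#'
#' @param path YAML file path.
#' @return `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_over <- raw$sim
  raw$sim <- NULL
  cfg <- do.call(default_analysis_config, raw)
  if (!is.null(sim_over)) cfg$sim <- do.call(default_config, sim_over)
  cfg
}

#' Run the full fitness-proxy validation analysis
#'
#' Pipeline: obtain data (simulate, or read the three input files) ->
#' identify the founder cohort -> gene-drop to estimate reproductive
#' values, allele survival and lineage fate -> compute the short-term
#' fitness proxies -> compare proxies against long-term fitness
#' (correlations among surviving lineages; logistic regressions of
#' lineage survival on each z-scored metric over all analysed founders)
#' -> stabilisation diagnostics. Deterministic given the config seed.
#'
#' @param config an `analysis_config` from [default_analysis_config()].
#' @return object of class `analysis_report`: list with `founders` (the
#'   joined fitness/RV table), `correlations`, `age_class_correlations`,
#'   `regressions`, `stabilisation`, `summary` (per-metric mean/SD),
#'   `counts` (founders in/excluded/analysed), `truth` (synthetic runs),
#'   and `meta`.
#' @export
run_full_analysis <- function(config = default_analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  simulated <- is.null(config$pedigree_file)
  if (simulated) {
    sim <- simulate_population(config$sim)
    ped <- sim$pedigree; breeding <- sim$breeding; census <- sim$census
    truth <- sim$truth
  } else {
    ped <- read_pedigree(config$pedigree_file)
    breeding <- read_breeding(config$breeding_file, ped)
    census <- read_census(config$census_file)
    truth <- NULL
  }
  final_year <- if (is.null(config$final_year)) max(census$year) else config$final_year
  window <- if (is.null(config$cohort_window)) {
    c(min(census$year) - 1L, min(census$year) + 3L)
  } else config$cohort_window

  roster <- identify_founders(ped, window)
  if (nrow(roster) == 0L) stop("stage identify_founders: empty cohort roster")

  gd <- run_gene_drop(ped, roster, n_reps = config$n_reps, seed = config$seed,
                      years = census$year, reference = config$rv_reference)
  gds <- gene_drop_summary(gd, ped, roster, final_year)
  if (config$survival_definition == "allele") {
    gds$survived <- gds$allele_survival > 0
  }

  ft <- fitness_table(ped, breeding, census, roster, final_year,
                      offspring_weight = config$delifing_weight)
  excluded <- attr(ft, "excluded")
  founders <- merge(ft, gds, by = "id", sort = TRUE)

  metrics <- c(paste0("lrs_", STAGES),
               paste0("igr_", setdiff(STAGES, "broods")),
               "delifed_lifetime")

  # correlations with RV among lineages that survived to the final year
  surv <- founders[founders$survived, , drop = FALSE]
  correlations <- do.call(rbind, lapply(metrics, function(m) {
    est <- tryCatch(pearson_ci(surv[[m]], surv$rv_final), error = function(e) NULL)
    if (is.null(est)) {
      return(data.frame(metric = m, stage = metric_stage(m), r = NA, n = nrow(surv),
                        ci_low = NA, ci_high = NA, p = NA, significant = NA))
    }
    data.frame(metric = m, stage = metric_stage(m), r = est$r, n = est$n,
               ci_low = est$ci_low, ci_high = est$ci_high, p = est$p,
               significant = est$p < 0.05)
  }))

  age_cols <- grep("^delifed_age", names(founders), value = TRUE)
  age_class_correlations <- do.call(rbind, lapply(age_cols, function(col) {
    a <- as.integer(sub("delifed_age", "", col))
    ok <- surv[!is.na(surv[[col]]), , drop = FALSE]
    est <- tryCatch(pearson_ci(ok[[col]], ok$rv_final), error = function(e) NULL)
    if (is.null(est)) {
      return(data.frame(age = a, n = nrow(ok), r = NA, ci_low = NA,
                        ci_high = NA, p = NA))
    }
    data.frame(age = a, n = est$n, r = est$r, ci_low = est$ci_low,
               ci_high = est$ci_high, p = est$p)
  }))

  # logistic regressions of lineage survival on each z-scored metric
  regressions <- do.call(rbind, lapply(metrics, function(m) {
    fit <- tryCatch(logistic_fit(founders$survived, founders[[m]]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(variable = m, slope = NA, ci_low = NA, ci_high = NA,
                        p = NA, separation = NA))
    }
    data.frame(variable = m, slope = fit$slope, ci_low = fit$ci_low,
               ci_high = fit$ci_high, p = fit$p, separation = fit$separation)
  }))

  stab <- stabilisation_curve(gd, final_year)
  counts <- c(roster = nrow(roster), excluded = nrow(excluded),
              analysed = nrow(founders), survived = sum(founders$survived))

  structure(list(
    founders = founders,
    correlations = correlations,
    age_class_correlations = age_class_correlations,
    regressions = regressions,
    stabilisation = stab,
    summary = summarize_metrics(founders[, c(metrics, age_cols)]),
    counts = counts,
    excluded = excluded,
    truth = truth,
    meta = list(seed = config$seed, n_reps = config$n_reps,
                final_year = final_year, cohort_window = window,
                delifing_weight = config$delifing_weight,
                rv_reference = config$rv_reference,
                survival_definition = config$survival_definition,
                simulated = simulated)
  ), class = "analysis_report")
}

metric_stage <- function(m) {
  if (grepl("^delifed", m)) return("recruits")
  sub("^(lrs|igr)_", "", m)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Fitness-proxy analysis:", x$counts["analysed"], "founders analysed (",
      x$counts["excluded"], "excluded ),", x$counts["survived"],
      "lineages survived\n")
  invisible(x)
}

#' Per-metric mean and standard deviation
#'
#' Column-wise mean and sample SD of a fitness table (NAs removed
#' per column); with a single observation the SD is undefined and
#' reported as `NA`.
#'
#' @param ft data frame of numeric metric columns.
#' @return data frame with columns `metric`, `mean`, `sd`, `n`.
#' @export
summarize_metrics <- function(ft) {
  if (nrow(ft) == 0L) stop("empty fitness table")
  num <- names(ft)[vapply(ft, is.numeric, logical(1))]
  do.call(rbind, lapply(num, function(col) {
    v <- ft[[col]][!is.na(ft[[col]])]
    data.frame(metric = col, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v))
  }))
}

#' Write an analysis report as CSV/JSON files
#'
#' Writes `founders.csv`, `correlations.csv`, `age_class_correlations.csv`,
#' `regressions.csv`, `stabilisation.csv`, `summary.csv`, `run_meta.json`
#' and, for simulated runs, `truth.json`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "NA",
                     quote = FALSE)
  }
  wr(report$founders, "founders.csv")
  wr(report$correlations, "correlations.csv")
  wr(report$age_class_correlations, "age_class_correlations.csv")
  wr(report$regressions, "regressions.csv")
  wr(report$stabilisation, "stabilisation.csv")
  wr(report$summary, "summary.csv")
  meta <- report$meta
  meta$counts <- as.list(report$counts)
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$truth)) {
    truth <- report$truth
    truth$census <- NULL
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
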