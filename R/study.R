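#' Wilson score interval for a binomial proportion
#'
#' @param successes number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `ci_low`, `ci_high`.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, ci_low = max(0, center - half),
       ci_high = min(1, center + half))
}

evaluated_rows <- function(results) {
  results[results$achieved & !results$failed, , drop = FALSE]
}

#' ITM success probability with Wilson 95% interval
#'
#' The denominator is the set of evaluated compounds (therapeutic dose
#' achievable, no solver failure), optionally restricted by a filter.
#'
#' @param results per-compound results table (from [run_study()] or
#'   [evaluate_compound()] rows).
#' @param filter optional logical vector over `results` rows, or a predicate
#'   function `results -> logical`.
#' @param conf confidence level.
#' @return list with `estimate`, `ci_low`, `ci_high`, `successes`, `n`.
#' @examples
#' res <- data.frame(itm_success = c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
#'                   achieved = TRUE, failed = FALSE)
#' success_probability(res)  # 0.3, Wilson CI ~ [0.108, 0.603]
#' @export
success_probability <- function(results, filter = NULL, conf = 0.95) {
  keep <- evaluated_rows(results)
  if (!is.null(filter)) {
    sel <- if (is.function(filter)) filter(keep) else filter[results$achieved &
                                                              !results$failed]
    keep <- keep[which(sel), , drop = FALSE]
  }
  if (nrow(keep) == 0) {
    stop("success probability undefined: no evaluated compounds in filter",
         call. = FALSE)
  }
  ci <- wilson_ci(sum(keep$itm_success), nrow(keep), conf)
  c(ci, list(successes = sum(keep$itm_success), n = nrow(keep)))
}

# evaluate every compound of a population under one trial configuration
evaluate_population <- function(pop, physiology = itm_physiology(),
                                config = trial_config(), cores = 1L) {
  cmpds <- population_compounds(pop)
  eval_one <- function(cm) evaluate_compound(cm, physiology, config)
  rows <- if (cores > 1L) {
    parallel::mclapply(cmpds, eval_one, mc.cores = cores)
  } else {
    lapply(cmpds, eval_one)
  }
  trial <- do.call(rbind, rows)
  params <- as.data.frame(pop)
  params$id <- NULL
  res <- cbind(trial, params)
  class(res) <- "data.frame"
  res
}

#' Run the Monte Carlo ITM feasibility study
#'
#' Samples a population of virtual compounds and runs the full per-compound
#' procedure (therapeutic-dose finding, microdose derivation, intra-target
#' simulation) for each, then aggregates the success probability. Per-compound
#' evaluation is deterministic, so parallel execution is identical to serial.
#'
#' @param n number of virtual compounds.
#' @param seed integer seed driving all sampling.
#' @param config a [trial_config()].
#' @param generation_config a [default_generation_config()]-style list.
#' @param physiology an [itm_physiology()].
#' @param cores number of worker processes for compound evaluation.
#' @return An object of class `itm_study`: list with `results` (per-compound
#'   table: trial outcomes, linear clearances and all sampled parameters),
#'   `n_compounds`, `n_evaluated`, `n_unachievable`, `n_failed`,
#'   `success_probability` (with Wilson 95% CI), `seed` and the config
#'   snapshots.
#' @export
run_study <- function(n, seed, config = trial_config(),
                      generation_config = default_generation_config(),
                      physiology = itm_physiology(), cores = 1L) {
  pop <- sample_compounds(n, seed, generation_config, physiology)
  results <- evaluate_population(pop, physiology, config, cores)
  ev <- evaluated_rows(results)
  prob <- if (nrow(ev) > 0) success_probability(results) else
    list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         successes = 0L, n = 0L)
  structure(list(
    results = results,
    n_compounds = n,
    n_evaluated = nrow(ev),
    n_unachievable = sum(!results$achieved & !results$failed),
    n_failed = sum(results$failed),
    success_probability = prob,
    seed = seed,
    trial_config = config,
    generation_config = generation_config,
    physiology = physiology
  ), class = "itm_study")
}

#' @export
print.itm_study <- function(x, ...) {
  cat("ITM Monte Carlo study:", x$n_compounds, "virtual compounds\n")
  cat(sprintf("  evaluated: %d (unachievable dose: %d, solver failures: %d)\n",
              x$n_evaluated, x$n_unachievable, x$n_failed))
  p <- x$success_probability
  cat(sprintf("  ITM success: %d/%d = %.1f%% (Wilson 95%% CI %.1f-%.1f%%)\n",
              p$successes, p$n, 100 * p$estimate, 100 * p$ci_low,
              100 * p$ci_high))
  invisible(x)
}

#' Decile subgroup table of ITM success
#'
#' Splits the evaluated compounds into ten equal-count bins by the empirical
#' deciles of a variable (stable sort by value then id, so bins get exactly
#' `floor(n/10)` or `ceiling(n/10)` members) and tabulates the success
#' probability per bin.
#'
#' @param results per-compound results table.
#' @param variable numeric column to bin by, typically
#'   `"therapeutic_dose_umol"`, `"CLh"` or `"CL_target"`.
#' @return data frame of class `itm_subgroups`: `bin`, `lower`, `upper`
#'   (observed value range per bin), `n`, `successes`, `probability`,
#'   `ci_low`, `ci_high`.
#' @export
decile_subgroups <- function(results, variable) {
  ev <- evaluated_rows(results)
  if (!variable %in% names(ev)) {
    stop("variable '", variable, "' not found in results", call. = FALSE)
  }
  n <- nrow(ev)
  if (n < 10) stop("need at least 10 evaluated compounds", call. = FALSE)
  ord <- order(ev[[variable]], ev$id)
  ev <- ev[ord, , drop = FALSE]
  sizes <- rep(n %/% 10, 10) + c(rep(1, n %% 10), rep(0, 10 - n %% 10))
  bin <- rep(seq_len(10), times = sizes)
  out <- do.call(rbind, lapply(seq_len(10), function(b) {
    rows <- ev[bin == b, , drop = FALSE]
    ci <- wilson_ci(sum(rows$itm_success), nrow(rows))
    data.frame(bin = b,
               lower = min(rows[[variable]]),
               upper = max(rows[[variable]]),
               n = nrow(rows),
               successes = sum(rows$itm_success),
               probability = ci$estimate,
               ci_low = ci$ci_low, ci_high = ci$ci_high)
  }))
  attr(out, "variable") <- variable
  class(out) <- c("itm_subgroups", "data.frame")
  out
}

default_sweep_values <- function(parameter,
                                 config = default_generation_config(),
                                 physiology = itm_physiology(),
                                 n_values = 7) {
  if (parameter == "Qt") {
    # two decades either side of the reference target perfusion
    return(exp(seq(log(physiology$Qt / 100), log(physiology$Qt * 100),
                   length.out = n_values)))
  }
  sp <- config$specs[[parameter]]
  qs <- stats::qlnorm(c(0.01, 0.99), meanlog = log(sp$median),
                      sdlog = sp$sigma_log)
  exp(seq(log(qs[1]), log(qs[2]), length.out = n_values))
}

#' Fixed-value sensitivity sweep of one model parameter
#'
#' For each of (by default seven) fixed values of the parameter, a fresh
#' population is sampled with the parameter pinned (all other parameters
#' re-drawn from their distributions) and the full per-compound procedure is
#' run, giving the success probability as a function of the parameter.
#'
#' @param parameter `"Qt"` (target blood flow, a physiological parameter),
#'   `"Kd"` or `"X_TotalR"` (pinned sampling distributions).
#' @param values numeric vector of fixed values; default seven log-spaced
#'   points (the sampled 1st-99th percentile range, or 0.01-100x the
#'   reference flow for `Qt`).
#' @param n_per_value compounds per value.
#' @param seed base seed; each value gets its own derived substream.
#' @param config,generation_config,physiology,cores as in [run_study()].
#' @return data frame of class `itm_sweep`: `parameter`, `value`, `n`,
#'   `successes`, `probability`, `ci_low`, `ci_high`, `n_evaluated`.
#' @export
parameter_sweep <- function(parameter = c("Qt", "Kd", "X_TotalR"),
                            values = NULL, n_per_value = 1000, seed = 1,
                            config = trial_config(),
                            generation_config = default_generation_config(),
                            physiology = itm_physiology(), cores = 1L) {
  parameter <- match.arg(parameter)
  if (is.null(values)) {
    values <- default_sweep_values(parameter, generation_config, physiology)
  }
  out <- do.call(rbind, lapply(seq_along(values), function(i) {
    v <- values[i]
    sub_seed <- substream_seed(seed, paste0("sweep_", parameter, "_", i))
    if (parameter == "Qt") {
      phys_i <- itm_physiology(physiology$weight, Qt_override = v)
      gen_i <- generation_config
    } else {
      phys_i <- physiology
      gen_i <- generation_config
      gen_i$specs[[parameter]] <- lognormal_spec(v, 0)
    }
    st <- run_study(n_per_value, sub_seed, config, gen_i, phys_i, cores)
    p <- st$success_probability
    data.frame(parameter = parameter, value = v, n = n_per_value,
               n_evaluated = st$n_evaluated,
               successes = p$successes, probability = p$estimate,
               ci_low = p$ci_low, ci_high = p$ci_high,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("itm_sweep", "data.frame")
  out
}

#' Success probability as a function of the required occupancy level
#'
#' Re-runs the full per-compound procedure (the therapeutic dose depends on
#' the required occupancy) on one shared population for every threshold.
#'
#' @param thresholds required average-occupancy levels, fractions in (0, 1).
#' @param n population size.
#' @param seed population seed (shared across thresholds).
#' @param config,generation_config,physiology,cores as in [run_study()].
#' @return data frame with `threshold`, `n_evaluated`, `successes`,
#'   `probability`, `ci_low`, `ci_high`.
#' @export
ro_threshold_sweep <- function(thresholds, n, seed,
                               config = trial_config(),
                               generation_config = default_generation_config(),
                               physiology = itm_physiology(), cores = 1L) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("'thresholds' must lie in (0, 1)", call. = FALSE)
  }
  pop <- sample_compounds(n, seed, generation_config, physiology)
  do.call(rbind, lapply(thresholds, function(th) {
    cfg <- config
    cfg$target_avg_ro <- th
    results <- evaluate_population(pop, physiology, cfg, cores)
    p <- success_probability(results)
    data.frame(threshold = th, n_evaluated = p$n, successes = p$successes,
               probability = p$estimate, ci_low = p$ci_low,
               ci_high = p$ci_high)
  }))
}

# small stable hash of a configuration for output provenance
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", h)
}

#' Write study artifacts to a directory
#'
#' Writes `study_results.csv` (per-compound table) and `summary.json`
#' (probabilities, confidence interval, seed, config hash).
#'
#' @param study an `itm_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_outputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res_path <- file.path(dir, "study_results.csv")
  utils::write.csv(study$results, res_path, row.names = FALSE)
  p <- study$success_probability
  summary <- list(
    n_compounds = study$n_compounds,
    n_evaluated = study$n_evaluated,
    n_unachievable = study$n_unachievable,
    n_failed = study$n_failed,
    successes = p$successes,
    success_probability = p$estimate,
    ci_low = p$ci_low,
    ci_high = p$ci_high,
    seed = study$seed,
    config_hash = config_hash(list(study$trial_config,
                                   study$generation_config))
  )
  sum_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA)
  invisible(c(res_path, sum_path))
}

#' Write a decile subgroup table as `subgroups_<variable>.csv`
#'
#' @param tab an `itm_subgroups` table from [decile_subgroups()].
#' @param dir output directory (created if needed).
#' @return invisibly, the path written.
#' @export
write_subgroups_csv <- function(tab, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0("subgroups_", attr(tab, "variable"), ".csv"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Write a parameter sweep table as `sweep_<parameter>.csv`
#'
#' @param sweep an `itm_sweep` table from [parameter_sweep()].
#' @param dir output directory (created if needed).
#' @return invisibly, the path written.
#' @export
write_sweep_csv <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0("sweep_", sweep$parameter[1], ".csv"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
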