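#' Serialise / load a generation configuration as YAML
#'
#' @param config a generation configuration
#'   ([default_generation_config()]-style list).
#' @param path YAML file path.
#' @return `read_generation_config()` returns a validated
#'   `generation_config`.
#' @name config-io
NULL

#' @rdname config-io
#' @export
write_generation_config <- function(config, path) {
  raw <- list(
    specs = lapply(config$specs, function(s) {
      list(median = s$median, sigma_log = s$sigma_log)
    }),
    joint = list(
      B = list(median = config$joint$B$median,
               sigma_log = config$joint$B$sigma_log),
      CLr = list(median = config$joint$CLr$median,
                 sigma_log = config$joint$CLr$sigma_log),
      Vss = list(median = config$joint$Vss$median,
                 sigma_log = config$joint$Vss$sigma_log),
      corr = as.vector(config$joint$corr)
    ),
    molar_mass = config$molar_mass,
    kp_floor = config$kp_floor
  )
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @rdname config-io
#' @export
read_generation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    specs = lapply(raw$specs, function(s) {
      lognormal_spec(s$median, s$sigma_log)
    }),
    joint = list(
      B = lognormal_spec(raw$joint$B$median, raw$joint$B$sigma_log),
      CLr = lognormal_spec(raw$joint$CLr$median, raw$joint$CLr$sigma_log),
      Vss = lognormal_spec(raw$joint$Vss$median, raw$joint$Vss$sigma_log),
      corr = matrix(unlist(raw$joint$corr), 3, 3)
    ),
    molar_mass = raw$molar_mass,
    kp_floor = raw$kp_floor
  )
  class(cfg) <- "generation_config"
  validate_generation_config(cfg)
  cfg
}

# hand-tuned demonstration compounds: a high-affinity, low-abundance compound
# with moderate disposition (ITM should succeed) and a compound whose receptor
# pool (0.5 umol) exceeds the 0.25 umol microdose cap (ITM cannot succeed)
fixture_success_compound <- function() {
  itm_compound(
    Vmax_uptake = 100, Km_uptake = 1, Vmax_met = 250, Km_met = 10,
    PSdif_inf = 30, Vmax_targetUptake = 0.192, Km_targetUptake = 1,
    PSdiff_target = 0.115, Vmax_targetMet = 0.192, Km_targetMet = 10,
    Kd = 0.0003, koff = 0.5, X_TotalR = 0.01, fub = 0.5, CLr = 5,
    Kp_scaling = 4, id = "fixture-expected-success"
  )
}

fixture_failure_compound <- function() {
  itm_compound(
    Vmax_uptake = 100, Km_uptake = 1, Vmax_met = 250, Km_met = 10,
    PSdif_inf = 30, Vmax_targetUptake = 0.192, Km_targetUptake = 1,
    PSdiff_target = 0.115, Vmax_targetMet = 0.192, Km_targetMet = 10,
    Kd = 0.006, koff = 4, X_TotalR = 0.5, fub = 0.2, CLr = 3,
    Kp_scaling = 8, id = "fixture-expected-failure"
  )
}

#' Generate the on-disk fixture set
#'
#' Writes a small reproducible set of example inputs: a 20-compound sampled
#' population (CSV), a hand-tuned high-affinity compound expected to achieve
#' ITM success and a high-receptor-abundance compound expected to fail (YAML),
#' and a template for user-supplied reference compound lists.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the sampled population.
#' @return invisibly, the paths written.
#' @export
generate_fixtures <- function(dir, seed = 20){
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  pop <- sample_compounds(20, seed)
  p <- file.path(dir, "population_20.csv")
  write_population_csv(pop, p); paths <- c(paths, p)

  p <- file.path(dir, "compound_expected_success.yaml")
  write_compound_yaml(fixture_success_compound(), p); paths <- c(paths, p)

  p <- file.path(dir, "compound_expected_failure.yaml")
  write_compound_yaml(fixture_failure_compound(), p); paths <- c(paths, p)

  template <- data.frame(
    compound = c("example_drug_1", "example_drug_2"),
    value = c(0.001, 0.02),
    parameter = c("Kd_uM", "Kd_uM"),
    stringsAsFactors = FALSE
  )
  p <- file.path(dir, "reference_template.csv")
  utils::write.csv(template, p, row.names = FALSE); paths <- c(paths, p)

  invisible(paths)
}
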