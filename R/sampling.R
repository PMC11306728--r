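#' Log-normal specification from an interquartile range
#'
#' The kinetic-parameter distributions are specified by their interquartile
#' ranges. For a log-normal variable the quartiles are
#' `median * exp(-z75 * sigma)` and `median * exp(+z75 * sigma)` with
#' `z75 = qnorm(0.75) = 0.67448975`, so the IQR inverts to
#' `median = sqrt(q25 * q75)` and `sigma_log = log(q75 / median) / z75`.
#'
#' @param q25,q75 lower and upper quartile in natural units (`0 < q25 <= q75`).
#' @return a `lognormal_spec`: list with `median` and `sigma_log` (sd of the
#'   natural log).
#' @examples
#' lognormal_from_iqr(1 / 3, 3)   # median 1, sigma_log ~ 1.629
#' @export
lognormal_from_iqr <- function(q25, q75) {
  if (!is.finite(q25) || !is.finite(q75) || q25 <= 0 || q75 < q25) {
    stop("quartiles must satisfy 0 < q25 <= q75", call. = FALSE)
  }
  med <- sqrt(q25 * q75)
  structure(list(median = med,
                 sigma_log = log(q75 / med) / stats::qnorm(0.75)),
            class = "lognormal_spec")
}

lognormal_spec <- function(median, sigma_log) {
  if (median <= 0 || sigma_log < 0) {
    stop("need median > 0 and sigma_log >= 0", call. = FALSE)
  }
  structure(list(median = median, sigma_log = sigma_log),
            class = "lognormal_spec")
}

# interquartile ranges of the independently sampled kinetic parameters
independent_param_iqrs <- function() {
  list(
    Vmax_uptake       = c(10, 1000),
    Km_uptake         = c(1 / 3, 3),
    Vmax_met          = c(25, 2500),
    Km_met            = c(10 / 3, 30),
    PSdif_inf         = c(3, 300),
    Vmax_targetUptake = c(0.0192, 1.92),
    Km_targetUptake   = c(1 / 3, 3),
    PSdiff_target     = c(0.0115, 1.15),
    Vmax_targetMet    = c(0.0192, 1.92),
    Km_targetMet      = c(10 / 3, 30),
    Kd                = c(0.0003, 0.006),
    koff              = c(0.25, 4),
    X_TotalR          = c(0.001, 0.1)
  )
}

#' Default Monte Carlo generation configuration
#'
#' Independent log-normal marginals for the kinetic and binding parameters
#' (from their interquartile ranges) plus a joint log-scale multivariate
#' normal for the protein-binding ratio `B = nPt/Kd_protein` (which drives
#' the unbound fraction `fub = 1/(1 + B)`), renal clearance `CLr` and the
#' volume of distribution `Vss` from which the tissue partition scaling is
#' derived. The joint marginals (B: median 1, sigma_log 1.5; CLr: median 3
#' L/h, sigma_log 1.5; Vss: median 50 L, sigma_log 1.0; zero pairwise
#' correlations) are a documented approximation of the literature
#' correlation structure and can be overridden.
#'
#' @return a `generation_config` list with elements `specs` (named list of
#'   `lognormal_spec`s), `joint` (marginals `B`, `CLr`, `Vss` and a 3x3
#'   log-scale correlation matrix), `molar_mass` and `kp_floor`.
#' @export
default_generation_config <- function() {
  specs <- lapply(independent_param_iqrs(),
                  function(q) lognormal_from_iqr(q[1], q[2]))
  cfg <- list(
    specs = specs,
    joint = list(
      B = lognormal_spec(1, 1.5),
      CLr = lognormal_spec(3, 1.5),
      Vss = lognormal_spec(50, 1.0),
      corr = diag(3)
    ),
    molar_mass = 400,
    kp_floor = 0.01
  )
  class(cfg) <- "generation_config"
  validate_generation_config(cfg)
  cfg
}

#' @keywords internal
validate_generation_config <- function(cfg) {
  stopifnot(is.list(cfg$specs), length(cfg$specs) > 0)
  for (nm in names(cfg$specs)) {
    sp <- cfg$specs[[nm]]
    if (!is.list(sp) || sp$median <= 0 || sp$sigma_log < 0) {
      stop("invalid log-normal spec for ", nm, call. = FALSE)
    }
  }
  R <- cfg$joint$corr
  if (!is.matrix(R) || any(dim(R) != 3) ||
      max(abs(R - t(R))) > 1e-12 || any(abs(diag(R) - 1) > 1e-12)) {
    stop("joint correlation matrix must be symmetric 3x3 with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("joint correlation matrix must be positive semi-definite",
         call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic per-parameter substream seed: a rolling string hash folded
# with the base seed, so adding a parameter never perturbs the draws of the
# others. All arithmetic stays below 2^53, results below 2^31.
substream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 10007) %% 2147483647)
}

draw_lognormal <- function(n, spec, seed, name) {
  set.seed(substream_seed(seed, name))
  exp(stats::rnorm(n, mean = log(spec$median), sd = spec$sigma_log))
}

#' Sample a population of virtual compounds
#'
#' Draws `n` virtual compounds: one independent log-normal substream per
#' kinetic parameter, a correlated multivariate log-normal triple for
#' (`B`, `CLr`, `Vss`), and the derived fields `fub = 1/(1 + B)`,
#' `Kp_scaling = max((Vss - Vb) / (0.1 Va + 0.2 Vm + 0.5 Vs), kp_floor)`,
#' `Kpa/Kpm/Kps = 0.1/0.2/0.5 * Kp_scaling` and `kon = koff/Kd`. Sampling is
#' reproducible bit-for-bit given `(seed, config)`.
#'
#' @param n number of compounds (>= 1).
#' @param seed integer seed.
#' @param config a [default_generation_config()]-style list; individual specs
#'   may be replaced (e.g. pinned to a point mass with `sigma_log = 0`) for
#'   sensitivity sweeps.
#' @param physiology an [itm_physiology()]; supplies `Vb`, `Va`, `Vm`, `Vs`
#'   for the partition-coefficient derivation.
#' @return An `itm_population`: a data frame with one row per compound,
#'   columns named by the parameter symbols plus derived columns `fub`,
#'   `Kp_scaling`, `Kpa`, `Kpm`, `Kps`, `kon` and the sampled `B` and `Vss`;
#'   attributes `seed` and `config` snapshot the generation inputs.
#' @examples
#' pop <- sample_compounds(5, seed = 1)
#' pop$Kd
#' @export
sample_compounds <- function(n, seed, config = default_generation_config(),
                             physiology = itm_physiology()) {
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  validate_generation_config(config)

  draws <- lapply(names(config$specs), function(nm) {
    draw_lognormal(n, config$specs[[nm]], seed, nm)
  })
  names(draws) <- names(config$specs)

  # correlated (B, CLr, Vss) on the log scale
  jt <- config$joint
  sd_log <- c(jt$B$sigma_log, jt$CLr$sigma_log, jt$Vss$sigma_log)
  mu_log <- log(c(jt$B$median, jt$CLr$median, jt$Vss$median))
  Sigma <- diag(sd_log) %*% jt$corr %*% diag(sd_log)
  set.seed(substream_seed(seed, "joint_B_CLr_Vss"))
  Z <- MASS::mvrnorm(n, mu = mu_log, Sigma = Sigma)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  B <- exp(Z[, 1]); CLr <- exp(Z[, 2]); Vss <- exp(Z[, 3])

  fub <- 1 / (1 + B)
  kp_den <- 0.1 * physiology$Va + 0.2 * physiology$Vm + 0.5 * physiology$Vs
  Kp_scaling <- pmax((Vss - physiology$Vb) / kp_den, config$kp_floor)

  pop <- data.frame(
    id = sprintf("vc%06d", seq_len(n)),
    as.data.frame(draws),
    fub = fub, CLr = CLr, Kp_scaling = Kp_scaling,
    Kpa = 0.1 * Kp_scaling, Kpm = 0.2 * Kp_scaling, Kps = 0.5 * Kp_scaling,
    molar_mass = config$molar_mass,
    B = B, Vss = Vss,
    stringsAsFactors = FALSE
  )
  pop$kon <- pop$koff / pop$Kd
  attr(pop, "seed") <- seed
  attr(pop, "config") <- config
  class(pop) <- c("itm_population", "data.frame")
  pop
}

#' Materialise population rows as compound objects
#'
#' @param pop an `itm_population` (or compatible data frame).
#' @return list of [itm_compound()]s.
#' @export
population_compounds <- function(pop) {
  lapply(seq_len(nrow(pop)), function(i) compound_from_row(pop[i, ]))
}

#' Compare a sample against a reference distribution (ECDF)
#'
#' Evaluates the empirical cumulative distribution functions of a simulated
#' sample and a user-supplied reference list of marketed-compound values on
#' their merged support, and reports the Kolmogorov-Smirnov sup-distance.
#'
#' @param samples numeric vector of simulated values.
#' @param reference numeric vector of reference values (user-supplied;
#'   reference compilations are not bundled with the package).
#' @return list of class `itm_ecdf_compare` with `table` (columns `value`,
#'   `ecdf_sample`, `ecdf_reference`) ready for step plotting, and
#'   `ks_distance`.
#' @export
ecdf_compare <- function(samples, reference) {
  samples <- samples[is.finite(samples)]
  reference <- reference[is.finite(reference)]
  if (length(samples) == 0) stop("'samples' is empty", call. = FALSE)
  if (length(reference) == 0) {
    stop("'reference' is empty: reference compound lists are user-supplied",
         call. = FALSE)
  }
  Fs <- stats::ecdf(samples)
  Fr <- stats::ecdf(reference)
  support <- sort(unique(c(samples, reference)))
  tab <- data.frame(value = support,
                    ecdf_sample = Fs(support),
                    ecdf_reference = Fr(support))
  structure(list(table = tab,
                 ks_distance = max(abs(tab$ecdf_sample - tab$ecdf_reference))),
            class = "itm_ecdf_compare")
}

#' @export
print.itm_ecdf_compare <- function(x, ...) {
  cat("ECDF comparison on", nrow(x$table), "support points;",
      sprintf("KS distance %.4f\n", x$ks_distance))
  invisible(x)
}

#' Read a reference compound list
#'
#' Expects a CSV with header `compound,value,parameter`; `parameter` is one
#' of `Kd_uM`, `koff_per_h`, `fu`, `CL_L_per_h`, `bioavailable_dose_mg`.
#'
#' @param path CSV path.
#' @param parameter optional filter on the `parameter` column.
#' @return data frame (filtered if `parameter` given).
#' @export
read_reference_csv <- function(path, parameter = NULL) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "value", "parameter")
  if (!all(need %in% names(ref))) {
    stop("reference CSV must have columns compound,value,parameter",
         call. = FALSE)
  }
  if (!is.null(parameter)) ref <- ref[ref$parameter == parameter, ]
  ref
}
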