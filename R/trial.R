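#' Trial configuration
#'
#' Settings of the per-compound ITM feasibility procedure: the required
#' average receptor occupancy, the regulatory microdose rule (the lesser of
#' 1/100 of the therapeutic dose and 100 ug), the occupancy evaluation
#' window, and the dose-search controls.
#'
#' @param target_avg_ro required average receptor occupancy (fraction in
#'   (0, 1), default 0.60).
#' @param microdose_cap_mass absolute microdose cap (ug, default 100).
#' @param microdose_fraction fraction of the therapeutic dose allowed as a
#'   microdose (default 1/100).
#' @param ro_window occupancy averaging window (h, default `c(0, 24)`).
#' @param dose_bounds IV bolus search bounds (umol); must span at least 8
#'   orders of magnitude.
#' @param dose_rel_tol relative tolerance of the located minimal dose
#'   (default 0.01).
#' @param n_grid number of bracketing points on the log-dose grid.
#' @param receptor_site receptor compartment passed to the simulator.
#' @return a `trial_config` list.
#' @export
trial_config <- function(target_avg_ro = 0.60, microdose_cap_mass = 100,
                         microdose_fraction = 1 / 100, ro_window = c(0, 24),
                         dose_bounds = c(1e-4, 1e5), dose_rel_tol = 0.01,
                         n_grid = 13,
                         receptor_site = c("intracellular",
                                           "extracellular")) {
  receptor_site <- match.arg(receptor_site)
  if (target_avg_ro <= 0 || target_avg_ro >= 1) {
    stop("'target_avg_ro' must lie in (0, 1)", call. = FALSE)
  }
  if (microdose_cap_mass < 0 || microdose_fraction <= 0) {
    stop("microdose cap and fraction must be positive", call. = FALSE)
  }
  if (dose_bounds[2] / dose_bounds[1] < 1e8) {
    stop("'dose_bounds' must span at least 8 orders of magnitude",
         call. = FALSE)
  }
  structure(list(target_avg_ro = target_avg_ro,
                 microdose_cap_mass = microdose_cap_mass,
                 microdose_fraction = microdose_fraction,
                 ro_window = ro_window,
                 dose_bounds = dose_bounds,
                 dose_rel_tol = dose_rel_tol,
                 n_grid = n_grid,
                 receptor_site = receptor_site),
            class = "trial_config")
}

iv_avg_ro <- function(dose, compound, physiology, config) {
  sim <- simulate_pbpk(compound, physiology,
                       doses = list(dose_event(0, dose, "iv_blood")),
                       duration = config$ro_window[2],
                       receptor_site = config$receptor_site)
  if (inherits(sim, "itm_sim_failure")) return(NA_real_)
  average_ro(sim, config$ro_window)
}

#' Find the estimated therapeutic IV dose
#'
#' Locates the minimal single IV bolus whose average receptor occupancy over
#' the evaluation window reaches the required level: the log-dose grid is
#' scanned upward to bracket the threshold crossing, then bisection in log
#' dose narrows the bracket to the configured relative tolerance. The upper
#' bracket end is returned, so the reported dose always satisfies the
#' occupancy criterion.
#'
#' @inheritParams pbpk_derivatives
#' @param config a [trial_config()].
#' @return list of class `itm_dose_search`: `dose` (umol, `NA` if the upper
#'   search bound cannot reach the criterion), `achieved` (logical),
#'   `avg_ro` at the returned dose, `failed` (solver failure flag) and
#'   `n_sims` (number of PBPK evaluations spent).
#' @export
find_therapeutic_dose <- function(compound, physiology = itm_physiology(),
                                  config = trial_config()) {
  grid <- exp(seq(log(config$dose_bounds[1]), log(config$dose_bounds[2]),
                  length.out = config$n_grid))
  n_sims <- 0L
  res <- function(dose, achieved, ro, failed = FALSE) {
    structure(list(dose = dose, achieved = achieved, avg_ro = ro,
                   failed = failed, n_sims = n_sims),
              class = "itm_dose_search")
  }

  lo <- NA_real_; hi <- NA_real_; ro_hi <- NA_real_
  for (d in grid) {
    ro <- iv_avg_ro(d, compound, physiology, config)
    n_sims <- n_sims + 1L
    if (is.na(ro)) return(res(NA_real_, FALSE, NA_real_, failed = TRUE))
    if (ro >= config$target_avg_ro) {
      hi <- d; ro_hi <- ro
      break
    }
    lo <- d
  }
  if (is.na(hi)) return(res(NA_real_, FALSE, NA_real_))
  if (is.na(lo)) {
    # already achieved at the lower bound: report it (cannot bracket below)
    return(res(hi, TRUE, ro_hi))
  }
  # bisection in log dose down to the relative tolerance
  for (i in seq_len(25L)) {
    if (hi / lo <= 1 + config$dose_rel_tol) break
    mid <- sqrt(lo * hi)
    ro <- iv_avg_ro(mid, compound, physiology, config)
    n_sims <- n_sims + 1L
    if (is.na(ro)) return(res(NA_real_, FALSE, NA_real_, failed = TRUE))
    if (ro >= config$target_avg_ro) {
      hi <- mid; ro_hi <- ro
    } else {
      lo <- mid
    }
  }
  res(hi, TRUE, ro_hi)
}

#' Microdose from the estimated therapeutic dose
#'
#' The regulatory microdose is the lesser of 1/100 of the therapeutic dose
#' and 100 ug; at a molar mass of 400 g/mol the mass cap corresponds to
#' 0.25 umol, which binds for therapeutic doses above 25 umol (10 mg).
#'
#' @param therapeutic_dose estimated therapeutic dose (umol); `NA` (dose
#'   unachievable) propagates to `NA`.
#' @param molar_mass g/mol.
#' @param config a [trial_config()].
#' @return microdose (umol).
#' @examples
#' compute_microdose(25, 400)    # 0.25 umol = 100 ug
#' compute_microdose(5, 400)     # 0.05 umol: 1/100 rule binds
#' compute_microdose(1000, 400)  # 0.25 umol: mass cap binds
#' @export
compute_microdose <- function(therapeutic_dose, molar_mass = 400,
                              config = trial_config()) {
  if (is.na(therapeutic_dose)) return(NA_real_)
  if (therapeutic_dose <= 0) stop("'therapeutic_dose' must be positive",
                                  call. = FALSE)
  pmin(therapeutic_dose * config$microdose_fraction,
       config$microdose_cap_mass / molar_mass)
}

#' Simulate intra-target microdose administration
#'
#' Delivers the whole microdose as a bolus into the extracellular
#' (interstitial) space of the target tissue at time zero and evaluates the
#' occupancy criterion over the configured window.
#'
#' @inheritParams find_therapeutic_dose
#' @param microdose dose (umol) administered into the target interstitium.
#' @return list with `sim` (an `itm_sim` or `itm_sim_failure`), `avg_ro` and
#'   `success` (average occupancy at or above the required level).
#' @export
run_itm <- function(compound, physiology = itm_physiology(), microdose,
                    config = trial_config()) {
  if (is.na(microdose)) {
    return(list(sim = NULL, avg_ro = NA_real_, success = FALSE))
  }
  sim <- simulate_pbpk(compound, physiology,
                       doses = list(dose_event(0, microdose,
                                               "intra_target_extracellular")),
                       duration = config$ro_window[2],
                       receptor_site = config$receptor_site)
  if (inherits(sim, "itm_sim_failure")) {
    return(list(sim = sim, avg_ro = NA_real_, success = FALSE))
  }
  ro <- average_ro(sim, config$ro_window)
  list(sim = sim, avg_ro = ro, success = ro >= config$target_avg_ro)
}

#' Run the full per-compound ITM feasibility procedure
#'
#' Chains the three steps: find the estimated therapeutic IV dose, derive
#' the microdose, and simulate intra-target administration; attaches the
#' linear-limit clearance summaries.
#'
#' @inheritParams find_therapeutic_dose
#' @return one-row data frame of class `itm_trial`: `id`,
#'   `therapeutic_dose_umol` (`NA` when unachievable), `microdose_umol`,
#'   `avg_ro_iv`, `avg_ro_itm`, `itm_success`, `achieved`, `failed`, `CLh`,
#'   `CL_target`, `CL_total`, `n_sims`.
#' @export
evaluate_compound <- function(compound, physiology = itm_physiology(),
                              config = trial_config()) {
  cl <- linear_clearances(compound, physiology)
  ds <- find_therapeutic_dose(compound, physiology, config)
  md <- compute_microdose(ds$dose, compound$molar_mass, config)
  itm <- if (ds$achieved) run_itm(compound, physiology, md, config)
         else list(avg_ro = NA_real_, success = FALSE, sim = NULL)
  failed <- ds$failed || inherits(itm$sim, "itm_sim_failure")
  out <- data.frame(
    id = compound$id,
    therapeutic_dose_umol = ds$dose,
    microdose_umol = md,
    avg_ro_iv = ds$avg_ro,
    avg_ro_itm = itm$avg_ro,
    itm_success = isTRUE(itm$success),
    achieved = ds$achieved,
    failed = failed,
    CLh = cl$CLh,
    CL_target = cl$CL_target,
    CL_total = cl$CL_total,
    n_sims = ds$n_sims,
    stringsAsFactors = FALSE
  )
  class(out) <- c("itm_trial", "data.frame")
  out
}
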