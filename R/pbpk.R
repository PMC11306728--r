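#' @useDynLib itmsim
#' @importFrom deSolve lsoda
NULL

pbpk_compartments <- function() {
  c("blood", "adipose", "muscle", "skin", "liver_ec", "liver_ic",
    "target_ec", "target_ic_free", "receptor_complex")
}

#' Dosing event
#'
#' @param time administration time (h, >= 0).
#' @param amount dose amount (umol, >= 0).
#' @param route `"iv_blood"` for an intravenous bolus into the blood pool or
#'   `"intra_target_extracellular"` for direct administration into the
#'   interstitial (extracellular) space of the target tissue.
#' @return a `dose_event` list.
#' @export
dose_event <- function(time, amount, route = c("iv_blood",
                                               "intra_target_extracellular")) {
  route <- match.arg(route)
  if (!is.finite(time) || time < 0) stop("dose time must be >= 0", call. = FALSE)
  if (!is.finite(amount) || amount < 0) stop("dose amount must be >= 0", call. = FALSE)
  structure(list(time = time, amount = amount, route = route),
            class = "dose_event")
}

dose_compartment <- function(route) {
  switch(route,
         iv_blood = "blood",
         intra_target_extracellular = "target_ec",
         stop("unknown dose route: ", route, call. = FALSE))
}

# Parameter vector in the order expected by the compiled RHS (src/pbpk_model.c)
pbpk_parms <- function(compound, physiology,
                       receptor_site = c("intracellular", "extracellular"),
                       infusion_rate = 0, infusion_window = c(0, Inf)) {
  receptor_site <- match.arg(receptor_site)
  p <- physiology
  cm <- compound
  c(Qa = p$Qa, Qh = p$Qh, Qm = p$Qm, Qs = p$Qs, Qt = p$Qt,
    Va = p$Va, Vm = p$Vm, Vs = p$Vs,
    Vhe = p$Vhe, Vhic = p$Vh - p$Vhe, Vt = p$Vt, Vtic = p$Vt_ic, Vb = p$Vb,
    Kpa = cm$Kpa, Kpm = cm$Kpm, Kps = cm$Kps,
    fub = cm$fub,
    Vmax_uptake = cm$Vmax_uptake, Km_uptake = cm$Km_uptake,
    Vmax_met = cm$Vmax_met, Km_met = cm$Km_met, PSdif_inf = cm$PSdif_inf,
    Vmax_targetUptake = cm$Vmax_targetUptake,
    Km_targetUptake = cm$Km_targetUptake,
    PSdiff_target = cm$PSdiff_target,
    Vmax_targetMet = cm$Vmax_targetMet, Km_targetMet = cm$Km_targetMet,
    kon = cm$kon, koff = cm$koff, X_TotalR = cm$X_TotalR,
    CLr = cm$CLr,
    receptor_ec = as.numeric(receptor_site == "extracellular"),
    inf_rate = infusion_rate,
    inf_t0 = infusion_window[1], inf_t1 = infusion_window[2])
}

#' PBPK-RO model right-hand side (reference implementation)
#'
#' Computes the instantaneous rates of change (umol/h) for the nine model
#' compartments. This pure-R version defines the model; the solver normally
#' uses an equivalent compiled version for speed, and the two are held in
#' agreement by the test suite.
#'
#' @param state named or unnamed non-negative numeric vector of length 9 in
#'   the order `blood, adipose, muscle, skin, liver_ec, liver_ic, target_ec,
#'   target_ic_free, receptor_complex` (amounts, umol).
#' @param compound an [itm_compound()].
#' @param physiology an [itm_physiology()].
#' @param receptor_site compartment holding the receptor: target
#'   intracellular space (default) or target extracellular space.
#' @param t time (h), only relevant when an infusion is active.
#' @param infusion_rate zero-order input rate into blood (umol/h).
#' @param infusion_window `c(t0, t1)` during which the infusion runs.
#' @return named numeric vector of rates (umol/h).
#'
#' @details Blood is a single well-mixed pool receiving all venous returns.
#'   Adipose, muscle and skin are flow-limited with partition coefficients
#'   `Kpa`, `Kpm`, `Kps`. Liver and target are permeability-limited pairs:
#'   blood perfuses the extracellular space; saturable (Michaelis-Menten in
#'   the local unbound concentration) plus passive uptake moves drug into the
#'   intracellular space, where metabolism and - in the target - receptor
#'   binding (`kon * C_free * R_free - koff * RC`, `kon = koff/Kd`) occur.
#'   The unbound fraction is `fub` in blood and extracellular water and 1
#'   intracellularly.
#' @export
pbpk_derivatives <- function(state, compound, physiology,
                             receptor_site = c("intracellular",
                                               "extracellular"),
                             t = 0, infusion_rate = 0,
                             infusion_window = c(0, Inf)) {
  receptor_site <- match.arg(receptor_site)
  if (length(state) != 9L) stop("'state' must have length 9", call. = FALSE)
  if (any(!is.finite(state)) || any(state < -1e-9)) {
    stop("integration failure: non-finite or negative state", call. = FALSE)
  }
  p <- physiology; cm <- compound
  y <- unname(state)

  Cb <- y[1] / p$Vb
  Ca <- y[2] / p$Va; Cm <- y[3] / p$Vm; Cs <- y[4] / p$Vs
  dAa <- p$Qa * (Cb - Ca / cm$Kpa)
  dAm <- p$Qm * (Cb - Cm / cm$Kpm)
  dAs <- p$Qs * (Cb - Cs / cm$Kps)

  Ce <- y[5] / p$Vhe
  Cu_ec <- cm$fub * Ce
  Cic <- y[6] / (p$Vh - p$Vhe)
  uptake <- cm$Vmax_uptake * Cu_ec / (cm$Km_uptake + Cu_ec) +
    cm$PSdif_inf * Cu_ec
  efflux <- cm$PSdif_inf * Cic
  met <- cm$Vmax_met * Cic / (cm$Km_met + Cic)
  dAhe <- p$Qh * (Cb - Ce) - uptake + efflux
  dAhi <- uptake - efflux - met

  Cte <- y[7] / p$Vt
  Cu_te <- cm$fub * Cte
  Ctic <- y[8] / p$Vt_ic
  uptake_t <- cm$Vmax_targetUptake * Cu_te / (cm$Km_targetUptake + Cu_te) +
    cm$PSdiff_target * Cu_te
  efflux_t <- cm$PSdiff_target * Ctic
  met_t <- cm$Vmax_targetMet * Ctic / (cm$Km_targetMet + Ctic)
  Rfree <- cm$X_TotalR - y[9]
  Cbind <- if (receptor_site == "extracellular") Cu_te else Ctic
  bind <- cm$kon * Cbind * Rfree - cm$koff * y[9]

  if (receptor_site == "extracellular") {
    dAte <- p$Qt * (Cb - Cte) - uptake_t + efflux_t - bind
    dAti <- uptake_t - efflux_t - met_t
  } else {
    dAte <- p$Qt * (Cb - Cte) - uptake_t + efflux_t
    dAti <- uptake_t - efflux_t - met_t - bind
  }

  inf <- if (infusion_rate > 0 && t >= infusion_window[1] &&
             t < infusion_window[2]) infusion_rate else 0
  dAb <- p$Qa * (Ca / cm$Kpa - Cb) + p$Qm * (Cm / cm$Kpm - Cb) +
    p$Qs * (Cs / cm$Kps - Cb) + p$Qh * (Ce - Cb) + p$Qt * (Cte - Cb) -
    cm$CLr * Cb + inf

  stats::setNames(c(dAb, dAa, dAm, dAs, dAhe, dAhi, dAte, dAti, bind),
                  pbpk_compartments())
}

#' Simulate the PBPK-RO model for a dosing schedule
#'
#' Integrates the model with the stiff-capable `lsoda` solver, applying bolus
#' doses as instantaneous amount jumps in the dosed compartment, and returns
#' the amount trajectories together with the receptor-occupancy time course
#' and its 24-h average.
#'
#' @inheritParams pbpk_derivatives
#' @param doses list of [dose_event()]s, sorted by time.
#' @param duration simulated span (h).
#' @param dt output grid spacing (h); receptor-occupancy averages use
#'   trapezoidal quadrature on this grid.
#' @param rtol,atol relative / absolute (umol) solver tolerances.
#' @param compiled use the compiled right-hand side (default) or the R
#'   reference implementation.
#' @return An object of class `itm_sim`: list with `times` (h), `amounts`
#'   (matrix, one column per compartment, umol), `ro` (receptor occupancy,
#'   fraction), `avg_ro` (mean occupancy over the first 24 h or the full span
#'   if shorter), and the `receptor_site` used. On solver failure an object
#'   of class `itm_sim_failure` carrying the compound id is returned instead
#'   of an error.
#' @examples
#' cmpd <- itm_compound(
#'   Vmax_uptake = 100, Km_uptake = 1, Vmax_met = 250, Km_met = 10,
#'   PSdif_inf = 30, Vmax_targetUptake = 0.192, Km_targetUptake = 1,
#'   PSdiff_target = 0.115, Vmax_targetMet = 0.192, Km_targetMet = 10,
#'   Kd = 0.00134, koff = 1, X_TotalR = 0.01, fub = 0.5, CLr = 3,
#'   Kp_scaling = 4
#' )
#' sim <- simulate_pbpk(cmpd, itm_physiology(),
#'                      doses = list(dose_event(0, 10, "iv_blood")))
#' sim$avg_ro
#' @export
simulate_pbpk <- function(compound, physiology = itm_physiology(),
                          doses = list(), duration = 24, dt = 0.05,
                          receptor_site = c("intracellular", "extracellular"),
                          infusion_rate = 0, infusion_window = c(0, Inf),
                          rtol = 1e-8, atol = 1e-12, compiled = TRUE) {
  receptor_site <- match.arg(receptor_site)
  if (!is.finite(duration) || duration <= 0) {
    stop("'duration' must be positive", call. = FALSE)
  }
  if (inherits(doses, "dose_event")) doses <- list(doses)
  dtimes <- vapply(doses, `[[`, numeric(1), "time")
  if (is.unsorted(dtimes)) stop("doses must be sorted by time", call. = FALSE)

  comps <- pbpk_compartments()
  y0 <- stats::setNames(numeric(9), comps)
  ev <- NULL
  for (d in doses) {
    if (d$time <= 0) {
      y0[dose_compartment(d$route)] <- y0[dose_compartment(d$route)] + d$amount
    } else {
      ev <- rbind(ev, data.frame(var = dose_compartment(d$route),
                                 time = d$time, value = d$amount,
                                 method = "add"))
    }
  }
  times <- seq(0, duration, by = dt)
  if (!is.null(ev)) times <- sort(unique(c(times, ev$time)))

  parms <- pbpk_parms(compound, physiology, receptor_site,
                      infusion_rate, infusion_window)

  # capture.output silences the solver's C-level diagnostic prints
  log_txt <- utils::capture.output(
  out <- tryCatch(withCallingHandlers({
    if (compiled) {
      deSolve::lsoda(y = y0, times = times, func = "pbpk_derivs",
                     parms = parms, dllname = "itmsim",
                     initfunc = "pbpk_initmod",
                     events = if (is.null(ev)) NULL else list(data = ev),
                     rtol = rtol, atol = atol, maxsteps = 50000)
    } else {
      rhs <- function(t, y, parms) {
        list(unname(pbpk_derivatives(pmax(y, 0), compound, physiology,
                                     receptor_site, t = t,
                                     infusion_rate = infusion_rate,
                                     infusion_window = infusion_window)))
      }
      deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                     events = if (is.null(ev)) NULL else list(data = ev),
                     rtol = rtol, atol = atol, maxsteps = 50000)
    }
  }, warning = function(w) invokeRestart("muffleWarning")),
  error = function(e) e))

  bad <- inherits(out, "condition") || nrow(out) < length(times) ||
    anyNA(out[, -1]) ||
    (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
  if (bad) {
    return(structure(list(compound_id = compound$id,
                          message = if (inherits(out, "condition"))
                            conditionMessage(out) else "incomplete solver output"),
                     class = "itm_sim_failure"))
  }

  amounts <- out[, comps, drop = FALSE]
  ro <- pmin(pmax(amounts[, "receptor_complex"] / compound$X_TotalR, 0), 1)
  sim <- structure(list(times = out[, "time"], amounts = amounts, ro = ro,
                        receptor_site = receptor_site,
                        compound_id = compound$id,
                        X_TotalR = compound$X_TotalR),
                   class = "itm_sim")
  sim$avg_ro <- average_ro(sim, window = c(0, min(24, duration)))
  sim
}

#' Windowed average receptor occupancy
#'
#' Trapezoidal area under the receptor-occupancy curve over a time window,
#' divided by the window length.
#'
#' @param sim an `itm_sim`, or any list with numeric `times` and `ro`.
#' @param window `c(t0, t1)` in hours, inside the simulated span.
#' @return average occupancy in `[0, 1]`.
#' @export
average_ro <- function(sim, window = c(0, 24)) {
  if (!is.numeric(window) || length(window) != 2L || window[2] <= window[1]) {
    stop("'window' must be an increasing pair of times", call. = FALSE)
  }
  tt <- sim$times; ro <- sim$ro
  if (window[1] < min(tt) - 1e-9 || window[2] > max(tt) + 1e-9) {
    stop("'window' must lie inside the simulated span", call. = FALSE)
  }
  # exact endpoints by linear interpolation, then trapezoid on the grid
  inside <- tt > window[1] & tt < window[2]
  xs <- c(window[1], tt[inside], window[2])
  ys <- c(stats::approx(tt, ro, xout = window[1])$y, ro[inside],
          stats::approx(tt, ro, xout = window[2])$y)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  min(max(auc / (window[2] - window[1]), 0), 1)
}

#' Linear-limit organ clearances
#'
#' Scalar clearance summaries at the linear (low-concentration) limit using
#' the extended clearance concept: the hepatic intrinsic clearance combines
#' active plus passive sinusoidal uptake with the metabolic intrinsic
#' clearance and passive backflux,
#' `CLint = (Vmax_up/Km_up + PS) * CLmet / (PS + CLmet)` with
#' `CLmet = Vmax_met/Km_met`, and the organ blood clearance follows the
#' well-stirred form `CL = Q * fub * CLint / (Q + fub * CLint)`. The target
#' tissue is treated identically with its own flow and parameters.
#'
#' @inheritParams pbpk_derivatives
#' @return An object of class `itm_clearances`: list with `CLh`, `CL_target`
#'   and `CL_total = CLh + CLr + CL_target` (L/h).
#' @export
linear_clearances <- function(compound, physiology = itm_physiology()) {
  cm <- compound
  well_stirred <- function(Q, fub, CLint) {
    if (Q <= 0 || CLint <= 0) return(0)
    Q * fub * CLint / (Q + fub * CLint)
  }
  extended_clint <- function(Vmax_up, Km_up, PS, Vmax_met, Km_met) {
    CLmet <- Vmax_met / Km_met
    if (PS + CLmet <= 0) return(0)
    (Vmax_up / Km_up + PS) * CLmet / (PS + CLmet)
  }
  CLint_h <- extended_clint(cm$Vmax_uptake, cm$Km_uptake, cm$PSdif_inf,
                            cm$Vmax_met, cm$Km_met)
  CLint_t <- extended_clint(cm$Vmax_targetUptake, cm$Km_targetUptake,
                            cm$PSdiff_target, cm$Vmax_targetMet,
                            cm$Km_targetMet)
  CLh <- well_stirred(physiology$Qh, cm$fub, CLint_h)
  CL_target <- well_stirred(physiology$Qt, cm$fub, CLint_t)
  structure(list(CLh = CLh, CL_target = CL_target,
                 CL_total = CLh + cm$CLr + CL_target),
            class = "itm_clearances")
}

#' @export
print.itm_sim <- function(x, ...) {
  cat("PBPK-RO simulation:", length(x$times), "time points over",
      sprintf("%.4g h\n", max(x$times)))
  cat(sprintf("  receptor site: %s; average RO (first 24 h): %.4f\n",
              x$receptor_site, x$avg_ro))
  invisible(x)
}

#' Tidy long-format view of a simulation
#'
#' @param sim an `itm_sim`.
#' @return data frame with columns `time`, `compartment`, `amount`, `ro`
#'   (occupancy repeated per compartment for plotting convenience).
#' @export
sim_as_tidy <- function(sim) {
  comps <- colnames(sim$amounts)
  data.frame(
    time = rep(sim$times, times = length(comps)),
    compartment = rep(comps, each = length(sim$times)),
    amount = as.vector(sim$amounts),
    ro = rep(sim$ro, times = length(comps)),
    stringsAsFactors = FALSE
  )
}
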