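#' Physiological parameters for the PBPK model
#'
#' Builds the fixed anatomical volumes and blood flows for a subject of the
#' given body weight. Whole-body tissues (adipose, liver, muscle, skin) are
#' scaled allometrically from reference-human values; the target tissue is a
#' small, permeability-limited organ of 5 mL total volume with its own blood
#' supply, split into an extracellular and an intracellular space.
#'
#' @param weight body mass in kg (default 75, the reference subject).
#' @param Qt_override optional blood flow to the target tissue (L/h), used by
#'   sensitivity sweeps that pin the target perfusion; `NULL` keeps the
#'   default.
#'
#' @return An object of class `itm_physiology`: a named list with blood flows
#'   `Qa`, `Qh`, `Qm`, `Qs`, `Qt` (L/h), volumes `Va`, `Vh`, `Vhe`, `Vm`,
#'   `Vs` (L), target volumes `Vt` (extracellular) and `Vt_ic`
#'   (intracellular, L), blood volume `Vb` (L) and `weight` (kg).
#'
#' @details Blood volume uses the reference-human 79 mL/kg. The target-organ
#'   geometry corresponds to a 5 mL solid tissue with extracellular and
#'   intracellular volume fractions of 0.500 (0.204 + 0.296) and 0.500, and a
#'   perfusion of 0.686 mL/min per 5 mL of tissue.
#'
#' @examples
#' phys <- itm_physiology()
#' phys$Qh   # 93.15 L/h at 75 kg
#' @export
itm_physiology <- function(weight = 75, Qt_override = NULL) {
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("'weight' must be a single positive number (kg)", call. = FALSE)
  }
  phys <- list(
    weight = weight,
    Qa = 3.72 * weight * 60 / 1000,
    Qh = 20.7 * weight * 60 / 1000,
    Qm = 10.7 * weight * 60 / 1000,
    Qs = 4.28 * weight * 60 / 1000,
    Qt = 0.686 * 60 / 1000 * 5,
    Va = 142 * weight / 1000,
    Vh = 17.4 * weight / 1000,
    Vhe = 6.69 * weight / 1000,
    Vm = 429 * weight / 1000,
    Vs = 111 * weight / 1000,
    Vt = 5 / 1000 * (0.204 + 0.296),
    Vt_ic = 5 / 1000 * (1 - 0.204 - 0.296),
    Vb = 79 * weight / 1000
  )
  if (!is.null(Qt_override)) phys$Qt <- Qt_override
  class(phys) <- "itm_physiology"
  validate_physiology(phys)
  phys
}

#' @keywords internal
validate_physiology <- function(phys) {
  flows <- c("Qa", "Qh", "Qm", "Qs", "Qt")
  vols <- c("Va", "Vh", "Vhe", "Vm", "Vs", "Vt", "Vt_ic", "Vb")
  vals <- unlist(phys[c(flows, vols)])
  if (any(!is.finite(vals))) {
    stop("physiology contains non-finite values", call. = FALSE)
  }
  # zero flows are allowed (reduced-model analyses); volumes must be positive
  if (any(unlist(phys[flows]) < 0)) {
    stop("blood flows must be non-negative", call. = FALSE)
  }
  if (any(unlist(phys[vols]) <= 0)) {
    stop("volumes must be strictly positive", call. = FALSE)
  }
  if (phys$Vhe >= phys$Vh) {
    stop("liver extracellular space must be smaller than the liver", call. = FALSE)
  }
  if (phys$Vt + phys$Vt_ic > 5 / 1000 + 1e-12) {
    stop("target extracellular + intracellular volume exceeds the 5 mL organ",
         call. = FALSE)
  }
  invisible(phys)
}

#' @export
print.itm_physiology <- function(x, ...) {
  cat("PBPK physiology (", x$weight, " kg subject)\n", sep = "")
  cat(sprintf("  blood flows (L/h): Qa=%.3f Qh=%.3f Qm=%.3f Qs=%.3f Qt=%.4f\n",
              x$Qa, x$Qh, x$Qm, x$Qs, x$Qt))
  cat(sprintf("  volumes (L): Va=%.3f Vh=%.3f (Vhe=%.3f) Vm=%.3f Vs=%.3f Vb=%.3f\n",
              x$Va, x$Vh, x$Vhe, x$Vm, x$Vs, x$Vb))
  cat(sprintf("  target (L): Vt=%.4f (extracellular) Vt_ic=%.4f (intracellular)\n",
              x$Vt, x$Vt_ic))
  invisible(x)
}
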