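#' Kinetic, binding and distribution parameters of one compound
#'
#' Constructs and validates the parameter set describing a single (virtual or
#' real) small molecule: hepatic active uptake and metabolism, passive
#' membrane permeabilities, target-tissue uptake and metabolism, receptor
#' binding kinetics, plasma protein binding, renal clearance and tissue
#' partitioning.
#'
#' @param Vmax_uptake maximum rate of active hepatic uptake (umol/h).
#' @param Km_uptake Michaelis constant of hepatic uptake (uM).
#' @param Vmax_met maximum rate of hepatic metabolism (umol/h).
#' @param Km_met Michaelis constant of hepatic metabolism (uM).
#' @param PSdif_inf passive hepatic permeability-surface product (L/h),
#'   symmetric influx/efflux.
#' @param Vmax_targetUptake maximum rate of active uptake into the target
#'   cells (umol/h).
#' @param Km_targetUptake Michaelis constant of target uptake (uM).
#' @param PSdiff_target passive target permeability-surface product (L/h),
#'   influx = efflux.
#' @param Vmax_targetMet maximum rate of intracellular target metabolism
#'   (umol/h).
#' @param Km_targetMet Michaelis constant of target metabolism (uM).
#' @param Kd equilibrium dissociation constant of the drug-receptor complex
#'   (uM).
#' @param koff dissociation rate constant of the drug-receptor complex (1/h);
#'   the association rate is derived as `kon = koff / Kd`.
#' @param X_TotalR total molar receptor abundance in the target tissue (umol).
#' @param fub unbound fraction in blood and plasma (fp = fb).
#' @param CLr renal blood clearance (L/h).
#' @param Kp_scaling scaling factor for the flow-limited tissue partition
#'   coefficients: `Kpa = 0.1 * Kp_scaling`, `Kpm = 0.2 * Kp_scaling`,
#'   `Kps = 0.5 * Kp_scaling`.
#' @param molar_mass molar mass (g/mol), fixed at 400 for virtual compounds.
#' @param id optional compound identifier.
#'
#' @return An object of class `itm_compound`: a named list including the
#'   derived fields `kon` (1/uM/h) and `Kpa`, `Kpm`, `Kps`.
#' @examples
#' cmpd <- itm_compound(
#'   Vmax_uptake = 100, Km_uptake = 1, Vmax_met = 250, Km_met = 10,
#'   PSdif_inf = 30, Vmax_targetUptake = 0.192, Km_targetUptake = 1,
#'   PSdiff_target = 0.115, Vmax_targetMet = 0.192, Km_targetMet = 10,
#'   Kd = 0.00134, koff = 1, X_TotalR = 0.01, fub = 0.5, CLr = 3,
#'   Kp_scaling = 4
#' )
#' cmpd$kon
#' @export
itm_compound <- function(Vmax_uptake, Km_uptake, Vmax_met, Km_met, PSdif_inf,
                         Vmax_targetUptake, Km_targetUptake, PSdiff_target,
                         Vmax_targetMet, Km_targetMet,
                         Kd, koff, X_TotalR, fub, CLr, Kp_scaling,
                         molar_mass = 400, id = NA_character_) {
  cmpd <- list(
    id = as.character(id),
    Vmax_uptake = Vmax_uptake, Km_uptake = Km_uptake,
    Vmax_met = Vmax_met, Km_met = Km_met, PSdif_inf = PSdif_inf,
    Vmax_targetUptake = Vmax_targetUptake,
    Km_targetUptake = Km_targetUptake,
    PSdiff_target = PSdiff_target,
    Vmax_targetMet = Vmax_targetMet, Km_targetMet = Km_targetMet,
    Kd = Kd, koff = koff, X_TotalR = X_TotalR,
    fub = fub, CLr = CLr, Kp_scaling = Kp_scaling,
    Kpa = 0.1 * Kp_scaling, Kpm = 0.2 * Kp_scaling, Kps = 0.5 * Kp_scaling,
    molar_mass = molar_mass,
    kon = koff / Kd
  )
  class(cmpd) <- "itm_compound"
  validate_compound(cmpd)
  cmpd
}

# numeric fields that must be present in any compound record
compound_param_names <- function() {
  c("Vmax_uptake", "Km_uptake", "Vmax_met", "Km_met", "PSdif_inf",
    "Vmax_targetUptake", "Km_targetUptake", "PSdiff_target",
    "Vmax_targetMet", "Km_targetMet", "Kd", "koff", "X_TotalR",
    "fub", "CLr", "Kp_scaling", "molar_mass")
}

#' @keywords internal
validate_compound <- function(cmpd) {
  need <- compound_param_names()
  vals <- unlist(cmpd[need])
  if (length(vals) != length(need) || any(!is.finite(vals))) {
    stop("compound has missing or non-finite parameters", call. = FALSE)
  }
  # Vmax terms may be exactly zero (pathway absent); rate/affinity constants
  # and volumes of distribution must be positive
  nonneg <- c("Vmax_uptake", "Vmax_met", "Vmax_targetUptake", "Vmax_targetMet",
              "PSdif_inf", "PSdiff_target", "CLr")
  pos <- setdiff(need, nonneg)
  if (any(unlist(cmpd[nonneg]) < 0)) {
    stop("rate parameters must be non-negative", call. = FALSE)
  }
  if (any(unlist(cmpd[pos]) <= 0)) {
    stop("affinity, binding and partition parameters must be strictly positive",
         call. = FALSE)
  }
  if (cmpd$fub > 1) stop("'fub' must lie in (0, 1]", call. = FALSE)
  if (!is.finite(cmpd$kon) || cmpd$kon <= 0) {
    stop("derived kon = koff/Kd must be finite and positive", call. = FALSE)
  }
  invisible(cmpd)
}

#' @export
print.itm_compound <- function(x, ...) {
  cat("Virtual compound", if (!is.na(x$id)) x$id else "<unnamed>", "\n")
  cat(sprintf("  binding: Kd=%.3g uM, koff=%.3g /h, kon=%.3g /uM/h, X_TotalR=%.3g umol\n",
              x$Kd, x$koff, x$kon, x$X_TotalR))
  cat(sprintf("  liver: Vmax_up=%.3g, Km_up=%.3g, Vmax_met=%.3g, Km_met=%.3g, PSdif=%.3g\n",
              x$Vmax_uptake, x$Km_uptake, x$Vmax_met, x$Km_met, x$PSdif_inf))
  cat(sprintf("  target: Vmax_up=%.3g, Km_up=%.3g, PSdiff=%.3g, Vmax_met=%.3g, Km_met=%.3g\n",
              x$Vmax_targetUptake, x$Km_targetUptake, x$PSdiff_target,
              x$Vmax_targetMet, x$Km_targetMet))
  cat(sprintf("  disposition: fub=%.3g, CLr=%.3g L/h, Kp_scaling=%.3g, MW=%g\n",
              x$fub, x$CLr, x$Kp_scaling, x$molar_mass))
  invisible(x)
}

#' Convert a compound to a one-row data frame
#'
#' @param x an `itm_compound`.
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return a one-row `data.frame` with the kinetic parameter columns plus
#'   `id`, the derived partition coefficients and `kon`.
#' @export
as.data.frame.itm_compound <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  cols <- c("id", compound_param_names(), "Kpa", "Kpm", "Kps", "kon")
  out <- as.data.frame(x[cols], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rebuild a compound from a one-row data frame or named list
#'
#' Inverse of [as.data.frame.itm_compound()]; derived columns, if present,
#' are ignored and re-derived.
#'
#' @param x a one-row data frame or named list with the Table-style parameter
#'   columns.
#' @return an `itm_compound`.
#' @export
compound_from_row <- function(x) {
  x <- as.list(x)
  do.call(itm_compound, c(
    x[compound_param_names()],
    list(id = if (!is.null(x$id)) x$id else NA_character_)
  ))
}

#' Read or write compounds as CSV / YAML
#'
#' Populations are serialised as CSV with one row per compound and columns
#' named by the kinetic parameter symbols; single compounds as flat YAML
#' records.
#'
#' @param x an `itm_compound` (YAML) or a population data frame (CSV).
#' @param path file path.
#' @return `read_compound_yaml()` returns an `itm_compound`;
#'   `read_population_csv()` a data frame of parameters (one row per
#'   compound).
#' @name compound-io
NULL

#' @rdname compound-io
#' @export
write_compound_yaml <- function(x, path) {
  stopifnot(inherits(x, "itm_compound"))
  rec <- x[c("id", compound_param_names())]
  yaml::write_yaml(rec, path, precision = 15)
  invisible(path)
}

#' @rdname compound-io
#' @export
read_compound_yaml <- function(path) {
  compound_from_row(yaml::read_yaml(path))
}

#' @rdname compound-io
#' @export
write_population_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname compound-io
#' @export
read_population_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
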