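#' Assay conditions for a chymotrypsin-coupled PPIase reaction
#'
#' Bundles every concentration and physical constant that defines one run of
#' the coupled isomerase assay: Suc-AAPF-pNA is held mostly in the trans
#' conformation, chymotrypsin cleaves p-nitroaniline from the trans isomer
#' only, and the slow cis to trans conversion (uncatalysed or
#' cyclophilin-accelerated) appears as a first-order absorbance phase at
#' 390 nm.
#'
#' All concentrations are molar (SI); rates are per second. The catalysed
#' acceleration is modelled as first-order in enzyme, i.e. the assay is
#' assumed to operate in the kcat/Km regime (cis substrate, roughly 8 uM,
#' well below Km), so `catalytic_efficiency` (kcat/Km) is the only catalytic
#' parameter.
#'
#' @param substrate_total Total Suc-AAPF-pNA concentration, mol/L.
#'   Default `80e-6` (the standard assay load).
#' @param cis_fraction Fraction of substrate with the Ala-Pro bond in cis at
#'   equilibrium, in (0, 1). Default 0.10, the conventional aqueous value for
#'   this peptide; it is never hard-coded in downstream formulas.
#' @param enzyme Cyclophilin concentration, mol/L.
#' @param uncat_rate Uncatalysed cis to trans relaxation rate \eqn{k_u},
#'   1/s. Default 0.015.
#' @param catalytic_efficiency kcat/Km of the isomerase, 1/(M s). Default is
#'   the value implied by a rate increase from 0.015 to 0.036 1/s at 4.34 nM
#'   enzyme.
#' @param protease_rate Pseudo-first-order cleavage rate of the trans isomer
#'   by chymotrypsin, 1/s. If `NULL`, computed as
#'   `protease_conc * protease_coeff`.
#' @param protease_conc Chymotrypsin load, mg/mL. Default 0.3 (300 ug/mL).
#' @param protease_coeff Proportionality constant turning the chymotrypsin
#'   load into a pseudo-first-order rate, 1/s per mg/mL. Default 33.4, which
#'   puts the cleavage rate near 10/s, two orders of magnitude above typical
#'   observed isomerisation rates.
#' @param extinction_coeff Molar absorptivity of released p-nitroaniline at
#'   390 nm, 1/(M cm). Default 13300; affects only the absorbance scale,
#'   never a fitted rate constant.
#' @param path_length Cuvette path length, cm.
#' @param baseline_abs Constant absorbance offset, AU.
#' @param temperature Assay temperature, degrees C (metadata only).
#' @param duration Observation window, s. Default 360.
#'
#' @return An object of class `assay_conditions` (a named list).
#' @examples
#' cond <- assay_conditions(enzyme = 4.34e-9)
#' cond
#' @export
assay_conditions <- function(substrate_total = 80e-6,
                             cis_fraction = 0.10,
                             enzyme = 0,
                             uncat_rate = 0.015,
                             catalytic_efficiency = (0.036 - 0.015) / 4.34e-9,
                             protease_rate = NULL,
                             protease_conc = 0.3,
                             protease_coeff = 33.4,
                             extinction_coeff = 13300,
                             path_length = 1,
                             baseline_abs = 0,
                             temperature = 15,
                             duration = 360) {
  if (is.null(protease_rate)) {
    protease_rate <- protease_conc * protease_coeff
  }
  x <- list(
    substrate_total = substrate_total,
    cis_fraction = cis_fraction,
    enzyme = enzyme,
    uncat_rate = uncat_rate,
    catalytic_efficiency = catalytic_efficiency,
    protease_rate = protease_rate,
    protease_conc = protease_conc,
    protease_coeff = protease_coeff,
    extinction_coeff = extinction_coeff,
    path_length = path_length,
    baseline_abs = baseline_abs,
    temperature = temperature,
    duration = duration
  )
  class(x) <- "assay_conditions"
  validate_assay_conditions(x)
}

validate_assay_conditions <- function(x) {
  num <- c("substrate_total", "cis_fraction", "enzyme", "uncat_rate",
           "catalytic_efficiency", "protease_rate", "extinction_coeff",
           "path_length", "baseline_abs", "duration")
  for (f in num) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("assay_conditions: field '", f, "' must be a finite number",
           call. = FALSE)
    }
  }
  nonneg <- c("substrate_total", "enzyme", "uncat_rate",
              "catalytic_efficiency", "protease_rate", "extinction_coeff",
              "path_length")
  for (f in nonneg) {
    if (x[[f]] < 0) {
      stop("assay_conditions: field '", f, "' must be >= 0", call. = FALSE)
    }
  }
  if (x$cis_fraction <= 0 || x$cis_fraction >= 1) {
    stop("assay_conditions: cis_fraction must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (x$duration <= 0) {
    stop("assay_conditions: duration must be > 0", call. = FALSE)
  }
  x
}

#' @export
print.assay_conditions <- function(x, ...) {
  cat("Coupled PPIase assay conditions\n")
  cat(sprintf("  substrate_total : %.4g M (cis fraction %.3g)\n",
              x$substrate_total, x$cis_fraction))
  cat(sprintf("  enzyme          : %.4g M\n", x$enzyme))
  cat(sprintf("  uncat_rate (ku) : %.4g /s\n", x$uncat_rate))
  cat(sprintf("  kcat/Km         : %.4g /M/s\n", x$catalytic_efficiency))
  cat(sprintf("  protease k_p    : %.4g /s\n", x$protease_rate))
  cat(sprintf("  optics          : eps %.4g /M/cm, path %.3g cm, baseline %.4g AU\n",
              x$extinction_coeff, x$path_length, x$baseline_abs))
  cat(sprintf("  temperature     : %.3g C, duration %.4g s\n",
              x$temperature, x$duration))
  invisible(x)
}

#' Progress curve of absorbance at 390 nm
#'
#' Constructs a validated time/absorbance series together with the
#' [assay_conditions()] it was recorded (or simulated) under.
#'
#' @param times Time points in seconds; strictly increasing, first >= 0.
#' @param absorbances Absorbance at 390 nm (AU), same length as `times`.
#' @param conditions An [assay_conditions()] object.
#' @param provenance One of `"simulated-closed-form"`, `"simulated-ode"`,
#'   `"measured"`.
#'
#' @return Object of class `progress_curve` with fields `times`,
#'   `absorbances`, `conditions`, `provenance`.
#' @examples
#' pc <- closed_form_trace(assay_conditions(), k_obs = 0.036, n_points = 10)
#' pc
#' @export
progress_curve <- function(times, absorbances, conditions,
                           provenance = c("measured",
                                          "simulated-closed-form",
                                          "simulated-ode")) {
  provenance <- match.arg(provenance)
  if (!inherits(conditions, "assay_conditions")) {
    stop("conditions must be an assay_conditions object", call. = FALSE)
  }
  times <- as.numeric(times)
  absorbances <- as.numeric(absorbances)
  if (length(times) != length(absorbances)) {
    stop("times and absorbances must have equal length", call. = FALSE)
  }
  if (length(times) < 4L) {
    stop("a progress curve needs at least 4 points ",
         "(3-parameter fit with 1 residual df)", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(absorbances))) {
    stop("times and absorbances must be finite", call. = FALSE)
  }
  if (times[1L] < 0) {
    stop("first time point must be >= 0", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(times = times, absorbances = absorbances,
         conditions = conditions, provenance = provenance),
    class = "progress_curve"
  )
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("Progress curve (%s): %d points, t = %.4g..%.4g s, A = %.4g..%.4g AU\n",
              x$provenance, length(x$times), min(x$times), max(x$times),
              min(x$absorbances), max(x$absorbances)))
  invisible(x)
}
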