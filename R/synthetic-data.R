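#' Gaussian noise specification for synthetic data
#'
#' All generators in the package are pure functions of their arguments and a
#' mandatory seed carried in this object, so every synthetic dataset is
#' reproducible by construction.
#'
#' @param sd Standard deviation of additive Gaussian noise. Interpreted in
#'   AU when applied to absorbance traces and in 1/s when applied to rate
#'   constants.
#' @param seed Integer seed; required even when `sd = 0` so determinism is
#'   part of the call signature, not an afterthought.
#' @return Object of class `noise_spec`.
#' @examples
#' noise_spec(0.001, seed = 42)
#' @export
noise_spec <- function(sd, seed) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    stop("noise_spec: sd must be a single finite number >= 0", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("noise_spec: an integer seed is required", call. = FALSE)
  }
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_spec")
}

#' Simulate a noisy absorbance progress curve
#'
#' The closed-form coupled-assay trace plus i.i.d. additive Gaussian noise
#' on absorbance. With `sd = 0` the output equals [closed_form_trace()]
#' exactly; identical seeds give identical series.
#'
#' @inheritParams closed_form_trace
#' @param noise A [noise_spec()]; `sd` in AU.
#' @return A [progress_curve()].
#' @examples
#' cond <- assay_conditions(enzyme = 4.34e-9)
#' tr <- generate_trace(cond, k_obs = 0.036, noise = noise_spec(1e-3, seed = 1))
#' @export
generate_trace <- function(conditions, k_obs = NULL,
                           noise = noise_spec(0, seed = 1L),
                           n_points = 361L) {
  stopifnot(inherits(noise, "noise_spec"))
  tr <- closed_form_trace(conditions, k_obs = k_obs, n_points = n_points)
  if (noise$sd > 0) {
    tr$absorbances <- tr$absorbances +
      withr::with_seed(noise$seed,
                       stats::rnorm(length(tr$absorbances), 0, noise$sd))
  }
  tr
}

#' Design of an inhibitor titration experiment
#'
#' Describes one dose-response series: which inhibitor, at which
#' concentrations, against how much enzyme, with which true (generating)
#' inhibition constant and rate-constant anchors. Rate-constant noise is
#' additive Gaussian, reflecting scatter of fitted first-order constants
#' across replicate assays.
#'
#' @param inhibitor_name Label, e.g. `"CsA"` or `"Cu2+"`.
#' @param concentrations Inhibitor concentrations, mol/L; all >= 0 and at
#'   least 4 strictly positive.
#' @param true_ki Generating inhibition constant, mol/L.
#' @param enzyme Active-enzyme concentration, mol/L.
#' @param k0 Uninhibited catalysed rate constant, 1/s.
#' @param ku Uncatalysed rate constant, 1/s; `k0 > ku >= 0` required.
#' @param noise A [noise_spec()] applied to the rate constants (1/s).
#' @param replicates Replicates per concentration (default 3, the usual
#'   triplicate design; set to 1 for a single noiseless series).
#' @return Object of class `titration_design`.
#' @seealso [design_csa()], [design_cu_atcyp19_3()], [design_cu_tacypa_1()]
#'   for the bundled presets.
#' @export
titration_design <- function(inhibitor_name, concentrations, true_ki, enzyme,
                             k0 = 0.036, ku = 0.015,
                             noise = noise_spec(0, seed = 1L),
                             replicates = 3L) {
  if (any(concentrations < 0)) {
    stop("titration_design: concentrations must be >= 0", call. = FALSE)
  }
  if (sum(concentrations > 0) < 4L) {
    stop("titration_design: need at least 4 strictly positive concentrations",
         call. = FALSE)
  }
  if (!(true_ki > 0)) stop("titration_design: true_ki must be > 0", call. = FALSE)
  if (!(enzyme > 0)) stop("titration_design: enzyme must be > 0", call. = FALSE)
  if (!(k0 > ku) || ku < 0) {
    stop("titration_design: require k0 > ku >= 0", call. = FALSE)
  }
  stopifnot(inherits(noise, "noise_spec"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(
    list(inhibitor_name = inhibitor_name,
         concentrations = as.numeric(concentrations),
         true_ki = true_ki, enzyme = enzyme, k0 = k0, ku = ku,
         noise = noise, replicates = replicates),
    class = "titration_design"
  )
}

#' Generate an inhibitor titration under the tight-binding model
#'
#' For each inhibitor concentration I the fractional enzymatic activity
#' a(E, I, Ki) is computed from the Morrison quadratic
#' ([morrison_fraction()]), the observed rate constant is
#' \eqn{k(I) = k_u + a \cdot (k_0 - k_u)}, and additive Gaussian noise is
#' applied per replicate under the design's seed. This is exactly the data a
#' Henderson plot consumes, so on noiseless output [henderson_fit()]
#' recovers `true_ki` and `enzyme` to machine precision.
#'
#' @param design A [titration_design()].
#' @return An [inhibition_series()]; when `replicates > 1` the per-replicate
#'   rate constants are kept in `$replicate_k` (a matrix, one row per
#'   concentration) and `$points$k` holds the replicate means.
#' @examples
#' s <- generate_titration(design_csa(noise = noise_spec(0, seed = 1),
#'                                    replicates = 1))
#' henderson_fit(s)
#' @export
generate_titration <- function(design) {
  stopifnot(inherits(design, "titration_design"))
  a <- morrison_fraction(design$enzyme, design$concentrations, design$true_ki)
  k_true <- design$ku + a * (design$k0 - design$ku)
  n <- length(k_true)
  r <- design$replicates
  if (design$noise$sd > 0) {
    eps <- withr::with_seed(design$noise$seed,
                            stats::rnorm(n * r, 0, design$noise$sd))
    k_rep <- matrix(k_true, nrow = n, ncol = r) +
      matrix(eps, nrow = n, ncol = r)
  } else {
    k_rep <- matrix(k_true, nrow = n, ncol = r)
  }
  inhibition_series(
    inhibitor_name = design$inhibitor_name,
    conc = design$concentrations,
    k = rowMeans(k_rep),
    k0 = design$k0, ku = design$ku,
    replicate_k = if (r > 1L) k_rep else NULL
  )
}

#' Generate a covalent-inactivation time course
#'
#' Models loss of PPIase activity during pre-incubation with a thiol
#' reagent (e.g. N-ethylmaleimide) as single-exponential decay of the
#' enzymatic rate component:
#' \deqn{k(t) = k_u + (k_0 - k_u) e^{-k_{inact} t}.}
#' `k_inact = 0` reproduces the NEM-insensitive phenotype (a flat time
#' course); a positive `k_inact` reproduces progressive inactivation such as
#' the 80 percent activity loss of TaCypA-1 after one hour.
#'
#' @param k_inact Inactivation rate constant, 1/s; >= 0.
#' @param times Incubation times, s.
#' @param k0 Initial catalysed rate constant, 1/s.
#' @param ku Uncatalysed rate constant, 1/s.
#' @param noise A [noise_spec()] on the rate constants.
#' @return `data.frame` with columns `time_s` and `k_per_s`.
#' @examples
#' generate_inactivation_timecourse(0, times = c(0, 300, 3600),
#'                                  k0 = 0.036, ku = 0.015,
#'                                  noise = noise_spec(0, seed = 1))
#' @export
generate_inactivation_timecourse <- function(k_inact, times, k0, ku,
                                             noise = noise_spec(0, seed = 1L)) {
  if (!(k_inact >= 0)) stop("k_inact must be >= 0", call. = FALSE)
  stopifnot(inherits(noise, "noise_spec"))
  k <- ku + (k0 - ku) * exp(-k_inact * times)
  if (noise$sd > 0) {
    k <- k + withr::with_seed(noise$seed,
                              stats::rnorm(length(k), 0, noise$sd))
  }
  data.frame(time_s = as.numeric(times), k_per_s = k)
}

# ---- bundled titration presets -------------------------------------------

#' Preset titration designs for the AtCyp19-3 / TaCypA-1 assay regimes
#'
#' Three ready-made [titration_design()]s matching the characterised
#' regimes: cyclosporin A against AtCyp19-3 (tight binding, Ki 18.75 nM,
#' enzyme 4.34 nM, doses 5-120 nM), Cu2+ against AtCyp19-3 (loose binding,
#' Ki 11.16 uM, enzyme 22 nM, doses 1-100 uM) and Cu2+ against TaCypA-1
#' (tight binding, Ki 3.83 nM, enzyme 22 nM, doses 1-200 nM). Rate anchors
#' default to k0 = 0.036, ku = 0.015 1/s.
#'
#' @param noise A [noise_spec()] on rate constants.
#' @param replicates Replicates per concentration.
#' @return A [titration_design()].
#' @name titration_presets
NULL

#' @rdname titration_presets
#' @export
design_csa <- function(noise = noise_spec(0, seed = 1L), replicates = 1L) {
  titration_design("CsA",
                   concentrations = c(5, 10, 20, 40, 60, 80, 100, 120) * 1e-9,
                   true_ki = 18.75e-9, enzyme = 4.34e-9,
                   k0 = 0.036, ku = 0.015,
                   noise = noise, replicates = replicates)
}

#' @rdname titration_presets
#' @export
design_cu_atcyp19_3 <- function(noise = noise_spec(0, seed = 1L),
                                replicates = 1L) {
  titration_design("Cu2+",
                   concentrations = c(1, 2, 5, 10, 20, 40, 70, 100) * 1e-6,
                   true_ki = 11.16e-6, enzyme = 22e-9,
                   k0 = 0.036, ku = 0.015,
                   noise = noise, replicates = replicates)
}

#' @rdname titration_presets
#' @export
design_cu_tacypa_1 <- function(noise = noise_spec(0, seed = 1L),
                               replicates = 1L) {
  titration_design("Cu2+",
                   concentrations = c(1, 2, 5, 10, 25, 50, 100, 200) * 1e-9,
                   true_ki = 3.83e-9, enzyme = 22e-9,
                   k0 = 0.036, ku = 0.015,
                   noise = noise, replicates = replicates)
}
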