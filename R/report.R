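#' Reference kinetic constants for AtCyp19-3 and TaCypA-1
#'
#' The published kinetic constants of the AtCyp19-3 characterisation that
#' this package's estimators are checked against: uncatalysed and catalysed
#' first-order rate constants (0.015 and 0.036 1/s at 4.34 nM enzyme),
#' catalytic efficiency (4.88e6 1/(M s)), the CsA inhibition constant
#' (18.75 nM) and the Cu2+ inhibition constants of AtCyp19-3 (11.16 uM) and
#' TaCypA-1 (3.83 nM).
#'
#' @return `data.frame` with columns `quantity`, `value`, `units`.
#' @export
reference_constants <- function() {
  data.frame(
    quantity = c("k_uncat", "k_cat_4.34nM", "catalytic_efficiency",
                 "ki_csa", "enzyme_active", "ki_cu_atcyp19_3",
                 "ki_cu_tacypa_1"),
    value = c(0.015, 0.036, 4.88e6, 18.75e-9, 4.34e-9, 11.16e-6, 3.83e-9),
    units = c("1/s", "1/s", "1/(M s)", "M", "M", "M", "M"),
    stringsAsFactors = FALSE
  )
}

#' Default run configuration
#'
#' A single structured list holding the seeds, default assay conditions,
#' noise defaults and titration presets used by the command-line interface
#' and the reproduction report. CLI flags override individual entries.
#'
#' @param seed Master seed for all stochastic generators.
#' @return Object of class `run_config`.
#' @export
default_config <- function(seed = 20150828L) {
  structure(
    list(
      seed = as.integer(seed),
      conditions = assay_conditions(),
      enzyme_for_efficiency = 4.34e-9,
      noise = list(trace_sd_abs = 0.001, rate_sd_per_s = 0),
      n_points = 361L,
      presets = list(
        csa = design_csa(noise = noise_spec(0, seed = seed), replicates = 1L),
        cu_atcyp19_3 = design_cu_atcyp19_3(noise = noise_spec(0, seed = seed),
                                           replicates = 1L),
        cu_tacypa_1 = design_cu_tacypa_1(noise = noise_spec(0, seed = seed),
                                         replicates = 1L)
      )
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("cyclofit run configuration\n")
  cat(sprintf("  seed            : %d\n", x$seed))
  cat(sprintf("  trace noise sd  : %.4g AU\n", x$noise$trace_sd_abs))
  cat(sprintf("  rate noise sd   : %.4g /s\n", x$noise$rate_sd_per_s))
  cat(sprintf("  trace points    : %d\n", x$n_points))
  cat(sprintf("  presets         : %s\n", paste(names(x$presets), collapse = ", ")))
  cat("  default conditions:\n")
  print(x$conditions)
  invisible(x)
}

resolve_preset <- function(config, name) {
  if (!name %in% names(config$presets)) {
    stop("unknown titration preset '", name, "'; available: ",
         paste(names(config$presets), collapse = ", "), call. = FALSE)
  }
  config$presets[[name]]
}

#' Reproduction report of the full pipeline
#'
#' Runs the whole pipeline on generated fixtures and compares every
#' computed quantity with its published reference value: noiseless traces
#' at the uncatalysed and catalysed rates are simulated and re-fitted, the
#' catalytic efficiency is computed from the fitted constants, and the
#' three preset titrations (CsA, Cu2+ against AtCyp19-3, Cu2+ against
#' TaCypA-1) are generated under the tight-binding model and analysed with
#' the Henderson estimator. Deterministic under the configuration's seeds.
#'
#' @param config A [default_config()] object.
#' @return Object of class `repro_report`: a `data.frame` with columns
#'   `quantity`, `computed`, `reference`, `units`, `rel_error`.
#' @examples
#' run_reproduction_report(default_config())
#' @export
run_reproduction_report <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("reproduction report failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  refs <- reference_constants()
  ref <- function(q) refs$value[refs$quantity == q]

  cond <- config$conditions
  fit_u <- stage("fit-uncatalysed-trace", {
    fit_first_order(closed_form_trace(cond, k_obs = cond$uncat_rate,
                                      n_points = config$n_points))
  })
  k_cat_true <- observed_rate_constant(cond$uncat_rate,
                                       cond$catalytic_efficiency,
                                       config$enzyme_for_efficiency)
  fit_c <- stage("fit-catalysed-trace", {
    fit_first_order(closed_form_trace(cond, k_obs = k_cat_true,
                                      n_points = config$n_points))
  })
  eff <- stage("catalytic-efficiency", {
    catalytic_efficiency(fit_c$k, fit_u$k, config$enzyme_for_efficiency)
  })
  hend <- lapply(c(csa = "csa", cu_atcyp19_3 = "cu_atcyp19_3",
                   cu_tacypa_1 = "cu_tacypa_1"), function(p) {
    stage(paste0("henderson-", p), {
      henderson_fit(generate_titration(resolve_preset(config, p)))
    })
  })

  out <- data.frame(
    quantity = c("k_uncat", "k_cat_4.34nM", "catalytic_efficiency",
                 "ki_csa", "enzyme_active", "ki_cu_atcyp19_3",
                 "ki_cu_tacypa_1"),
    computed = c(fit_u$k, fit_c$k, as.numeric(eff),
                 hend$csa$ki, hend$csa$enzyme_est,
                 hend$cu_atcyp19_3$ki, hend$cu_tacypa_1$ki),
    stringsAsFactors = FALSE
  )
  out$reference <- vapply(out$quantity, ref, numeric(1))
  out$units <- refs$units[match(out$quantity, refs$quantity)]
  out$rel_error <- abs(out$computed - out$reference) / abs(out$reference)
  class(out) <- c("repro_report", "data.frame")
  out
}

#' Render a reproduction report as fixed-format text
#'
#' @param report A [run_reproduction_report()] result.
#' @return Character vector of report lines (deterministic: two runs under
#'   the same seeds render byte-identical bodies).
#' @export
format_repro_report <- function(report) {
  stopifnot(inherits(report, "repro_report"))
  c(
    "cyclofit reproduction report",
    sprintf("%-22s %14s %14s %-8s %10s",
            "quantity", "computed", "reference", "units", "rel.error"),
    sprintf("%-22s %14.6g %14.6g %-8s %10.3g",
            report$quantity, report$computed, report$reference,
            report$units, report$rel_error)
  )
}

#' @export
print.repro_report <- function(x, ...) {
  writeLines(format_repro_report(x))
  invisible(x)
}
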