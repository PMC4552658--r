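test_that("morrison_fraction matches the brute-force binding quadratic", {
  # frozen from the brute-force oracle: (4.34 nM, 120 nM, 18.75 nM) -> 0.1389
  expect_equal(morrison_fraction(4.34e-9, 120e-9, 18.75e-9), 0.1388758,
               tolerance = 1e-6)
  for (case in list(c(4.34e-9, 20e-9, 18.75e-9),
                    c(22e-9, 11.16e-6, 11.16e-6),
                    c(22e-9, 50e-9, 3.83e-9),
                    c(1e-7, 1e-7, 1e-9))) {
    expect_equal(morrison_fraction(case[1], case[2], case[3]),
                 brute_fraction(case[1], case[2], case[3]),
                 tolerance = 1e-9)
  }

  expect_equal(morrison_fraction(4.34e-9, 0, 18.75e-9), 1)
  # classical dilute-enzyme limit: a -> Ki/(Ki + I)
  expect_equal(morrison_fraction(1e-15, 18.75e-9, 18.75e-9), 0.5,
               tolerance = 1e-6)
  # monotone decreasing in I
  a <- morrison_fraction(4.34e-9, seq(1, 200, by = 1) * 1e-9, 18.75e-9)
  expect_true(all(diff(a) < 0))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(morrison_fraction(-1, 1, 1), "require")
})

test_that("Henderson fit exactly inverts noiseless Morrison data in both published regimes", {
  # CsA regime: Ki 18.75 nM, E 4.34 nM
  s <- generate_titration(design_csa(noise = noise_spec(0, seed = 1),
                                     replicates = 1))
  h <- henderson_fit(s)
  expect_equal(h$ki, 18.75e-9, tolerance = 1e-12)
  expect_equal(h$enzyme_est, 4.34e-9, tolerance = 1e-12)
  expect_equal(h$r_squared, 1, tolerance = 1e-12)
  expect_identical(h$variant, "enzymatic")

  # Cu2+ regimes: loose binding 11.16 uM and tight binding 3.83 nM at 22 nM
  h_at <- henderson_fit(generate_titration(
    design_cu_atcyp19_3(noise = noise_spec(0, seed = 1), replicates = 1)))
  expect_equal(h_at$ki, 11.16e-6, tolerance = 1e-12)
  h_ta <- henderson_fit(generate_titration(
    design_cu_tacypa_1(noise = noise_spec(0, seed = 1), replicates = 1)))
  expect_equal(h_ta$ki, 3.83e-9, tolerance = 1e-12)
})

test_that("Henderson recovery is exact across Ki/E from 1e-2 to 1e3", {
  e <- 22e-9
  for (ratio in 10^seq(-2, 3)) {
    ki <- e * ratio
    d <- titration_design("x", c(0.25, 0.5, 1, 2, 4, 8) * (ki + e),
                          true_ki = ki, enzyme = e,
                          noise = noise_spec(0, seed = 1), replicates = 1)
    h <- henderson_fit(generate_titration(d))
    expect_lt(abs(h$ki - ki) / ki, 1e-9)
    expect_lt(abs(h$enzyme_est - e) / e, 1e-6)
  }
})

test_that("Henderson slope agrees with an independent direct Morrison fit", {
  d <- design_csa(noise = noise_spec(0, seed = 1), replicates = 1)
  s <- generate_titration(d)
  h <- henderson_fit(s)
  a_obs <- (s$points$k - d$ku) / (d$k0 - d$ku)
  direct <- direct_morrison_fit(s$points$conc, a_obs,
                                ki_start = 1e-8, enzyme_start = 1e-8)
  expect_lt(abs(h$ki - direct[1L]) / direct[1L], 0.01)
})

test_that("raw-rate variant is recorded and biased upward by the background", {
  s <- generate_titration(design_csa(noise = noise_spec(0, seed = 1),
                                     replicates = 1))
  h_raw <- henderson_fit(s, variant = "raw")
  expect_identical(h_raw$variant, "raw")
  # with a 0.015 of 0.036 /s uncatalysed background the raw plot overstates Ki
  expect_gt(h_raw$ki, 18.75e-9 * 1.2)
})

test_that("Henderson fit rejects series without an inhibition signal", {
  flat <- inhibition_series("FK506", c(1, 5, 10, 20) * 1e-6,
                            rep(0.036, 4), k0 = 0.036, ku = 0.015)
  expect_warning(expect_error(henderson_fit(flat), "usable points"),
                 "excluded")
  # I = 0 points are dropped with a warning, remaining fit still exact
  d0 <- titration_design("CsA", c(0, 5, 10, 20, 40, 80) * 1e-9,
                         true_ki = 18.75e-9, enzyme = 4.34e-9,
                         noise = noise_spec(0, seed = 1), replicates = 1)
  s0 <- generate_titration(d0)
  expect_warning(h <- henderson_fit(s0), "excluded 1")
  expect_equal(h$ki, 18.75e-9, tolerance = 1e-12)
  expect_identical(h$n_used, 5L)
})

test_that("Henderson Ki is robust to 2% rate noise (median over 500 seeded reps)", {
  # 2% Gaussian noise on each measured rate constant (sd = 0.02 k)
  d <- design_csa(replicates = 1)
  a <- morrison_fraction(d$enzyme, d$concentrations, d$true_ki)
  k_true <- d$ku + a * (d$k0 - d$ku)
  kis <- vapply(1:500, function(i) {
    withr::with_seed(20000L + i, {
      k_noisy <- k_true * (1 + rnorm(length(k_true), 0, 0.02))
      s <- inhibition_series("CsA", d$concentrations, k_noisy, d$k0, d$ku)
      suppressWarnings(henderson_fit(s)$ki)
    })
  }, numeric(1))
  expect_lt(abs(median(kis) - 18.75e-9) / 18.75e-9, 0.05)
})

test_that("residual activity percentages and the dose-response table behave", {
  expect_equal(as.numeric(percent_residual_activity(0.036, 0.036, 0.015)), 100)
  expect_equal(as.numeric(percent_residual_activity(0.015, 0.036, 0.015)), 0)
  # 80% activity loss leaves 20%
  expect_equal(
    as.numeric(percent_residual_activity(0.015 + 0.2 * 0.021, 0.036, 0.015)),
    20)
  out <- percent_residual_activity(c(0.010, 0.040), 0.036, 0.015)
  expect_equal(as.numeric(out), c(0, 100))
  expect_identical(attr(out, "clipped"), c(TRUE, TRUE))
  expect_error(percent_residual_activity(0.02, 0.015, 0.015), "k0 > ku")

  d <- design_csa(noise = noise_spec(0, seed = 1), replicates = 1)
  s <- generate_titration(d)
  tab <- dose_response_table(s)
  expect_equal(tab$residual_pct,
               100 * morrison_fraction(d$enzyme, d$concentrations, d$true_ki))
  # residual activity strictly decreasing in dose under the model
  expect_true(all(diff(tab$residual_pct) < 0))

  # equal replicates give sd = 0; noiseless replicate matrix is equal rows
  d3 <- design_csa(noise = noise_spec(0, seed = 1), replicates = 3)
  tab3 <- dose_response_table(generate_titration(d3))
  expect_equal(tab3$sd_pct, rep(0, 8))
  expect_identical(tab3$n, rep(3L, 8))
})
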