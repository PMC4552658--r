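test_that("trace generator is exact at sd = 0 and deterministic under a seed", {
  cond <- assay_conditions(enzyme = 4.34e-9)
  clean <- closed_form_trace(cond, k_obs = 0.036)
  g0 <- generate_trace(cond, k_obs = 0.036, noise = noise_spec(0, seed = 7))
  expect_identical(g0$absorbances, clean$absorbances)

  g1 <- generate_trace(cond, k_obs = 0.036, noise = noise_spec(1e-3, seed = 7))
  g2 <- generate_trace(cond, k_obs = 0.036, noise = noise_spec(1e-3, seed = 7))
  g3 <- generate_trace(cond, k_obs = 0.036, noise = noise_spec(1e-3, seed = 8))
  expect_identical(g1$absorbances, g2$absorbances)
  expect_false(identical(g1$absorbances, g3$absorbances))

  # generator does not disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(generate_trace(cond, k_obs = 0.036,
                           noise = noise_spec(1e-3, seed = 7)))
  expect_identical(rnorm(1), before)
})

test_that("a noisy generated trace re-fits to within 5% of the generating k", {
  cond <- assay_conditions(enzyme = 4.34e-9)
  tr <- generate_trace(cond, k_obs = 0.036, noise = noise_spec(1e-3, seed = 11))
  fit <- fit_first_order(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$k - 0.036) / 0.036, 0.05)
})

test_that("titration generator obeys the tight-binding model at its anchors", {
  d <- design_csa(noise = noise_spec(0, seed = 1), replicates = 1)
  s <- generate_titration(d)
  expect_s3_class(s, "inhibition_series")
  # noiseless values satisfy the model equation exactly
  a <- morrison_fraction(d$enzyme, d$concentrations, d$true_ki)
  expect_equal(s$points$k, d$ku + a * (d$k0 - d$ku))

  # I = 0 -> k = k0 when noiseless
  d0 <- titration_design("CsA", c(0, 5, 10, 20, 40) * 1e-9,
                         true_ki = 18.75e-9, enzyme = 4.34e-9,
                         noise = noise_spec(0, seed = 1), replicates = 1)
  s0 <- generate_titration(d0)
  expect_equal(s0$points$k[1L], d0$k0)

  # I >> Ki and I >> E -> k -> ku (full inhibition)
  dbig <- titration_design("CsA", c(1e-5, 2e-5, 5e-5, 1e-4),
                           true_ki = 18.75e-9, enzyme = 4.34e-9,
                           noise = noise_spec(0, seed = 1), replicates = 1)
  sbig <- generate_titration(dbig)
  expect_equal(sbig$points$k[4L], dbig$ku, tolerance = 1e-3)

  # replicate noise is seeded and reproducible
  dn <- design_csa(noise = noise_spec(5e-4, seed = 3), replicates = 3)
  s1 <- generate_titration(dn)
  s2 <- generate_titration(dn)
  expect_identical(s1$replicate_k, s2$replicate_k)
  expect_equal(dim(s1$replicate_k), c(8L, 3L))
})

test_that("titration_design validates its invariants", {
  expect_error(titration_design("x", c(1, 2, 3) * 1e-9, 1e-9, 1e-9,
                                noise = noise_spec(0, seed = 1)),
               "4 strictly positive")
  expect_error(titration_design("x", c(1, 2, 3, 4) * 1e-9, -1e-9, 1e-9,
                                noise = noise_spec(0, seed = 1)),
               "true_ki")
  expect_error(titration_design("x", c(1, 2, 3, 4) * 1e-9, 1e-9, 1e-9,
                                k0 = 0.01, ku = 0.015,
                                noise = noise_spec(0, seed = 1)),
               "k0 > ku")
  expect_error(noise_spec(0.1), "seed")
  expect_error(noise_spec(-0.1, seed = 1), ">= 0")
})

test_that("inactivation time course follows the exponential-decay model", {
  tc0 <- generate_inactivation_timecourse(0, times = c(0, 600, 3600),
                                          k0 = 0.036, ku = 0.015,
                                          noise = noise_spec(0, seed = 1))
  # no inactivation: flat at k0 (the NEM-insensitive phenotype)
  expect_equal(tc0$k_per_s, rep(0.036, 3))

  # t = 0 gives k0 exactly
  tc <- generate_inactivation_timecourse(1e-3, times = c(0, 100),
                                         k0 = 0.036, ku = 0.015,
                                         noise = noise_spec(0, seed = 1))
  expect_equal(tc$k_per_s[1L], 0.036)

  # rate chosen to leave 20% residual activity after one hour does so
  # (inverting the exponential: k_inact = ln(5)/3600)
  k_inact <- log(5) / 3600
  tc20 <- generate_inactivation_timecourse(k_inact, times = 3600,
                                           k0 = 0.036, ku = 0.015,
                                           noise = noise_spec(0, seed = 1))
  expect_equal(
    as.numeric(percent_residual_activity(tc20$k_per_s, 0.036, 0.015)),
    20, tolerance = 1e-12)
})
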