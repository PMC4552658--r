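# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Brute-force tight-binding fractional activity: solve the binding
# quadratic (E - x)(I - x) = Ki * x numerically for the complex x.
brute_fraction <- function(enzyme, inhibitor, ki) {
  if (inhibitor == 0) return(1)
  f <- function(x) (enzyme - x) * (inhibitor - x) - ki * x
  x <- uniroot(f, c(0, min(enzyme, inhibitor)), tol = 1e-15)$root
  1 - x / enzyme
}

# Independent direct nonlinear least-squares fit of the tight-binding
# fractional-activity model to (I, a) pairs; returns c(ki, enzyme).
direct_morrison_fit <- function(conc, a, ki_start, enzyme_start) {
  obj <- function(p) {
    ki <- exp(p[1L]); e <- exp(p[2L])
    a_hat <- vapply(conc, brute_fraction, numeric(1), enzyme = e, ki = ki)
    sum((a_hat - a)^2)
  }
  fit <- optim(log(c(ki_start, enzyme_start)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  exp(fit$par)
}

# Idealised amphiphilic window: hydrophobic residues on the wheel half
# facing +x (cos > 0), alternating charged residues on the other face.
make_amphiphile <- function(window = 18L, angle_per_residue = 100) {
  ang <- ((seq_len(window) - 1L) * angle_per_residue) %% 360
  rad <- ang * pi / 180
  res <- ifelse(cos(rad) > 0, "L", rep_len(c("K", "E"), window))
  paste(res, collapse = "")
}

# Seeded random polar sequence (used to embed a planted amphiphile).
random_polar <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("S", "T", "N", "Q", "G"), n,
                                      replace = TRUE), collapse = ""))
}
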