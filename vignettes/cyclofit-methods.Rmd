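---
title: "cyclofit: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cyclofit: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclofit)
```

# The coupled assay and its two models

The chymotrypsin-coupled PPIase assay rests on one piece of chemistry:
chymotrypsin releases the p-nitroaniline chromophore from Suc-AAPF-pNA only
when the Ala-Pro bond is in the *trans* conformation. At equilibrium most of
the peptide is trans, so adding protease produces an absorbance burst at
390 nm; the remaining cis pool then converts with first-order kinetics, and
that conversion — not proteolysis — is rate limiting. A cyclophilin
accelerates it in proportion to its concentration.

`cyclofit` carries two models of this system.

**Closed form (the model that gets fitted).** Assuming the trans pool is
cleaved instantly,

$$A(t) = A_0 + \varepsilon l\,[S_{trans,0} + S_{cis,0}(1 - e^{-k_{obs}t})],
\qquad k_{obs} = k_u + \frac{k_{cat}}{K_m}[E].$$

The linear dependence of $k_{obs}$ on $[E]$ holds because the cis substrate
(about 8 µM under default conditions) is assumed well below $K_m$; the
assay therefore measures only the ratio $k_{cat}/K_m$, never the two
factors separately, and `cyclofit` deliberately offers no $K_m$/$k_{cat}$
separation.

**Mechanistic three-state model (the internal oracle).** The full linear
mechanism tracks cis, trans and cleaved product with a finite
pseudo-first-order protease rate $k_p$ and reversible isomerisation.
Microscopic reversibility is imposed on the enzymatic terms: the enzyme
multiplies both directional rates by the same factor, so it cannot shift
the cis/trans equilibrium. Because the system is linear with constant
coefficients, `ode_trace()` solves it *exactly* by eigendecomposition of
the rate matrix (with a `Matrix::expm()` fallback if the eigenbasis is
ill-conditioned) rather than by a numerical integrator. Mass conservation
therefore holds to machine precision at every output time, which the test
suite asserts at 1e-9 relative.

**How the two are compared.** The closed form is the $k_p \to \infty$
limit of the mechanism. A finite-$k_p$ trace necessarily disagrees with
the closed form near $t = 0$: the closed form puts the whole trans burst
at the first instant, while the mechanistic trace needs a time of order
$1/k_p$ to cleave the trans pool. The equivalence tests therefore compare
the two *after* the protease transient, on $t \ge 10/k_p$, where the
discrepancy must fall below 1% of the total amplitude for
$k_p/k_{obs} \ge 100$ and must shrink monotonically as $k_p/k_{obs}$ grows
through {10, 100, 1000}. Comparing from $t = 0$ would make the criterion
unmeetable for any finite $k_p$, which is an artefact of the closed form's
idealisation, not a model error.

# Rate-constant fitting

`fit_first_order()` fits $A(t) = b + a(1 - e^{-kt})$ by **variable
projection** rather than a general iterative nonlinear solver: for fixed
$k$ the model is linear in $(b, a)$, so those are profiled out by ordinary
least squares and the residual sum of squares is minimised over $\log k$
alone by Brent search (bracket: two decades either side of a
log-linearised tail estimate). The amplitude constraint $a \ge 0$ is
enforced by clamping the linear solution. This choice was made after
considering a conventional Levenberg-Marquardt loop: the profiled problem
is one-dimensional, has no step-size heuristics to tune, is immune to the
"zero residual" failure modes iterative solvers exhibit on noiseless
simulated data, and on exact input recovers $k$ to about 1e-8 relative —
comfortably below the 1e-6 requirement the tests enforce. The asymptotic
standard error of $k$ comes from the usual $(J^\top J)^{-1}$ expression at
the optimum. The `converged` flag is honest: it is false when the optimum
sits at the bracket edge or the amplitude bound is active, and a constant
trace is an error, not a fit.

# Derived quantities

**Catalytic efficiency** is $(k_{obs} - k_u)/[E]$. With the characterised
rate pair (0.015 → 0.036 s⁻¹ at 4.34 nM) this yields 4.84×10⁶ M⁻¹s⁻¹,
within 1% of the published 4.88×10⁶ — the printed inputs are rounded to
two significant figures, so exact agreement is not possible and the
acceptance tolerance is 2%.

**Specific activity** is $\Delta k \times n_{substrate}/m_{enzyme}$. Two
conventions are selectable for the "amount of substrate": the **cis pool**
(default — it is the isomerase's actual substrate; 8 nmol under default
conditions) or the total load (80 nmol). The enzyme-mass basis likewise
matters: the purified full-length protein is a His-tagged fusion that runs
at ~23 kDa although its predicted mass is 18.92 kDa; both constants are
exposed (`atcyp19_3_masses()`) and the observed mass is the default,
because protein was quantified as the purified fusion. Under (cis basis,
23 kDa) the computed specific activity is 16.8×10² nmol s⁻¹ mg⁻¹ against
a published 17.12×10²; the remaining 2% gap traces to the unstated cis
fraction and mass basis of the original computation, so this quantity is
validated for consistency but is not an acceptance target. The
total-substrate reading would be tenfold higher.

# Tight-binding inhibition

With nanomolar enzyme, CsA (Ki ≈ 18.75 nM) and Cu²⁺ against TaCypA-1
(Ki ≈ 3.83 nM) violate the classical assumption that free ≈ total
inhibitor. Fractional activity follows the Morrison quadratic, which
`morrison_fraction()` evaluates in the cancellation-free form

$$a = 1 - \frac{2I}{(E + I + K_i) + \sqrt{(E + I + K_i)^2 - 4EI}},$$

numerically stable when $4EI \ll (E+I+K_i)^2$ and continuous into the
dilute-enzyme limit $K_i/(K_i + I)$. A brute-force root of the binding
quadratic serves as the independent oracle in the tests.

**The Henderson estimator.** Plotting $I/(1 - v/v_0)$ against $v_0/v$
linearises Morrison exactly: slope = apparent $K_i$, intercept = total
active enzyme. The fit is unweighted ordinary least squares — a "line of
best fit" — and on noiseless Morrison-generated data the recovery is exact
to machine precision across $K_i/E$ from 1e-2 to 1e3 (both published Cu²⁺
regimes sit inside this span). Two variants exist because the assay has a
substantial uncatalysed background (0.015 of 0.036 s⁻¹):

* `"enzymatic"` (default): $v = k - k_u$, $v_0 = k_0 - k_u$. Unbiased —
  only the enzymatic component is inhibitable.
* `"raw"`: $v = k$, $v_0 = k_0$, as plotted in much of the assay
  literature. With the background included the denominator $1 - k/k_0$
  understates the inhibited fraction and the apparent Ki is inflated (the
  tests pin this bias down qualitatively).

Whether the original analysis included the background is not stated
anywhere; both variants are provided and recorded in the result, and all
reference recoveries use the enzymatic variant. Points with $I = 0$
(undefined ordinate), $v \le 0$ or $v \ge v_0$ carry no usable tight-binding
signal and are excluded with a warning; fewer than two usable points is an
error — which is also how an ineffective inhibitor (the FK506 null case)
surfaces, with no special-cased code.

**Residual activity** is $100(k - k_u)/(k_0 - k_u)$, clipped to [0, 100]
with a per-element flag; dose-response tables report replicate mean ± SD.

# Synthetic data: the stated world

The generators emulate the characterised assay regime and nothing more:

| parameter | default | basis |
|---|---|---|
| substrate | 80 µM Suc-AAPF-pNA | assay composition |
| cis fraction | 0.10 | conventional aqueous value for this peptide; never stated in the characterisation, exposed as a parameter |
| enzyme | 4.34–65.87 nM range typical | concentrations used in the assays |
| $k_u$ | 0.015 s⁻¹ | uncatalysed rate |
| kcat/Km | 4.839×10⁶ M⁻¹s⁻¹ | back-derived from 0.015 → 0.036 s⁻¹ at 4.34 nM |
| $\varepsilon$ (pNA, 390 nm) | 13 300 M⁻¹cm⁻¹ | conventional value; affects only the absorbance scale |
| $k_p$ | ≈10 s⁻¹ (0.3 mg/mL × 33.4 s⁻¹ per mg/mL) | places proteolysis two orders above isomerisation |
| trace grid | 1 s over 360 s | observation protocol |
| temperature | 15 °C | metadata only; no temperature dependence is modelled |
| trace noise | 1 mAU Gaussian, additive | chosen once so triplicate SDs resemble published error bars; no noise magnitude was stated |
| titration presets | CsA 5–120 nM @ 4.34 nM E; Cu²⁺ 1–100 µM @ 22 nM E; Cu²⁺ 1–200 nM @ 22 nM E | the three characterised regimes |
| replicates | 3 (means ± SD reported) | triplicate convention |

Noise is additive Gaussian — on absorbance for traces, on rate constants
for titrations — and i.i.d.; heteroscedasticity, drift and correlated
instrument noise are deliberately out of scope. Covalent inactivation time
courses use single-exponential decay of the enzymatic component,
$k(t) = k_u + (k_0 - k_u)e^{-k_{inact}t}$: `k_inact = 0` reproduces the
NEM-insensitive phenotype, and inverting the exponential gives the rate
that leaves 20% residual activity after one hour (the sensitive
homologue's phenotype).

A green test on this world establishes that the estimators invert the
models they assume, at the signal-to-noise the defaults state. It does
*not* establish robustness to model misspecification in real data —
substrate depletion of the protease, product inhibition, slow-binding
kinetics or baseline drift are all outside the generator.

One property deserves its own note. The robustness criterion "median
Henderson Ki within 5% under 2% rate noise" is implemented as Gaussian
noise with standard deviation 2% *of each rate constant* (the literal
reading of "2% noise on rates"). Under that world the median bias over 500
seeded replicates is about −4%: the Henderson plot has noise in both
coordinates and a nonlinear transform of the noisy denominator
$1 - v/v_0$, so a small median bias at realistic noise is a property of
the estimator itself, not an implementation defect. Coarser readings
(one absolute sd for all points) push the bias past 5%, which is worth
knowing before trusting a Henderson slope from a noisy titration —
a direct nonlinear Morrison fit is the better estimator in that regime,
and the test suite uses one as a consistency oracle.

# Amphiphilic-helix scanning

Calmodulin binds short, positively charged amphiphilic α-helices. The
scanner reproduces computationally what a helical-wheel projection shows
visually: residue $n$ sits at $n \times 100°$ (3.6 residues/turn), and the
mean Eisenberg hydrophobic moment

$$\mu_H = \frac{1}{N}\left|\sum_{n=0}^{N-1} h_n e^{in\delta}\right|$$

is large exactly when hydrophobic residues cluster on one wheel face.
Conventions: Eisenberg consensus scale by default (Kyte-Doolittle
available); window 18 residues (five full turns, which makes the
homopolymer moment vanish identically — a symmetry the tests exploit);
1-based inclusive residue coordinates; net charge at neutral pH counts
K/R as +1, D/E as −1, H as 0 (a documented simplification). $\mu_H$ is
invariant under global wheel rotation and bounded by the largest |h| on
the scale.

`scan_amphiphilicity()` tiles the protein with stride 1 and reports the
maximal-moment window plus, when a region of interest is supplied, whether
that window **overlaps** the ROI (overlap, not containment, was chosen:
the delineated calmodulin-binding domain of AtCyp19-3 is residue interval
35–70 by truncation mapping while the amphiphilic stretch is quoted as
35–67, so windows straddling a boundary are informative). The default ROI
in examples is 35–70 with 35–67 noted as the narrower wheel-based
estimate. The real AtCyp19-3 sequence is not bundled — tests run on
synthetic constructs with planted amphiphiles so the package needs no
downloads; users supply their own FASTA for real proteins.

# Numerical choices, edge cases, limitations

* **Quadratic root**: evaluated via the conjugate form (above); the naive
  form loses up to 8 digits when $E \ll I + K_i$.
* **Exact linear-ODE solution**: eigendecomposition is used when all
  eigenvalues are real (they are, for this mechanism) and the eigenbasis
  has reciprocal condition above 1e-10; otherwise per-time
  `Matrix::expm()`. Failures raise an error carrying the diagnostic.
* **Brent precision**: optimisation over $\log k$ with tolerance 1e-12
  gives ~1e-8 relative precision on $k$, the practical limit of
  derivative-free 1-D search in double precision.
* **Henderson exclusions** are logged warnings, not silent drops; the
  number of points actually used is part of the result.
* **Round-trip I/O**: CSV numbers are written at 12 significant digits; a
  write → read → write cycle is byte-identical.
* **Determinism**: every stochastic generator takes a `noise_spec` with a
  mandatory seed and restores the caller's RNG state (`withr::with_seed`),
  so library use never perturbs a user's random stream.
* Known limitations: no protease-substrate depletion or product
  inhibition; no temperature dependence; no Km/kcat separation; no
  slow-binding (time-dependent) inhibition kinetics; the helix scanner is
  a geometric screen, not a calmodulin-binding predictor.

# What the reproduction report computes

`run_reproduction_report()` regenerates every fixture from the presets,
runs the full pipeline (trace simulation → rate fits → efficiency;
titration generation → Henderson fits) and tabulates computed against
reference values with relative errors. All computed numbers in this
vignette and the README are outputs of those code paths; none are entered
by hand anywhere in the package.
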