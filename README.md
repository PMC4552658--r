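# cyclofit

Kinetic analysis of chymotrypsin-coupled peptidyl-prolyl cis-trans
isomerase (PPIase) assays.

## The problem

Cyclophilins accelerate rotation about Xaa-Pro peptide bonds. Their
activity is measured spectrophotometrically with a coupled protease assay:
chymotrypsin cleaves p-nitroaniline from the test peptide Suc-AAPF-pNA only
when the Ala-Pro bond is *trans*, so the trans pool is consumed in a burst
and the slow cis→trans conversion — uncatalysed or enzyme-accelerated —
appears as a first-order rise in absorbance at 390 nm:

    A(t) = A0 + εl [ S_trans,0 + S_cis,0 (1 − e^(−k_obs t)) ]
    k_obs = k_u + (kcat/Km) [E]

From paired catalysed/uncatalysed fits one obtains the catalytic efficiency
kcat/Km = (k_obs − k_u)/[E] and the specific activity Δk × n_substrate /
m_enzyme. Cyclophilin inhibitors (cyclosporin A, Cu²⁺) act in the
tight-binding regime where free ≠ total inhibitor; fractional activity
follows the Morrison quadratic

    a = 1 − [ (E + I + Ki) − sqrt((E + I + Ki)² − 4 E I) ] / (2E)

whose exact linearisation is the Henderson plot: I/(1 − v/v₀) against
v₀/v is a straight line with slope Ki and intercept the total active
enzyme. `cyclofit` implements the whole chain — mechanistic simulation,
rate-constant fitting, efficiency/activity summaries, Henderson Ki
estimation, dose-response tables — plus a sliding-window hydrophobic-moment
scanner (Eisenberg μH at 100°/residue) for delineating the amphiphilic
calmodulin-binding helix of cyclophilins such as *Arabidopsis* AtCyp19-3.
Seeded generators emulate the characterised assay regime (80 μM substrate,
nanomolar enzyme, 360 s traces at 15 °C, k_u ≈ 0.015 s⁻¹), so every
estimator can be exercised and validated without laboratory data.

It is intended for enzymologists running coupled PPIase assays and for
anyone needing a reference implementation of tight-binding (Morrison /
Henderson) inhibition analysis.

## Worked example

```r
library(cyclofit)

# simulate a catalysed trace at 4.34 nM enzyme with 1 mAU noise, refit it
cond  <- assay_conditions(enzyme = 4.34e-9)
trace <- generate_trace(cond, noise = noise_spec(0.001, seed = 1))
fit   <- fit_first_order(trace)
fit
#> First-order fit: k = 0.0360888 /s (se 0.000194), amplitude 0.1063 AU, baseline 0.9577 AU
#>   rss = 0.0003424 AU^2 over 361 points; converged: TRUE (ok)

# pair with the uncatalysed trace and summarise
uncat <- fit_first_order(closed_form_trace(assay_conditions(), k_obs = 0.015))
kinetics_summary(fit$k, uncat$k, enzyme = 4.34e-9)
#> PPIase kinetics summary
#>   k (catalysed)       : 0.03609 /s
#>   k (uncatalysed)     : 0.015 /s
#>   delta k             : 0.02109 /s
#>   catalytic efficiency: 4.859e+06 /M/s
#>   specific activity   : 1690 nmol/s/mg (cis substrate basis)

# cyclosporin A titration under the tight-binding model, Henderson analysis
csa <- generate_titration(design_csa(noise = noise_spec(0, seed = 1),
                                     replicates = 1))
henderson_fit(csa)
#> Henderson fit (enzymatic variant): Ki = 1.875e-08 M, active enzyme = 4.34e-09 M
#>   R^2 = 1.000000 on 8 points

# amphiphilic-helix scan of a synthetic construct with a planted helix
prot <- paste0(strrep("S", 34), "LKKLLKLLKKLLKLLKKL", strrep("S", 12))
scan_amphiphilicity(prot, roi = c(35, 70))
#> Amphiphilicity scan: 47 windows of 18 residues
#>   max muH = 0.8066 at residues 35-52 (LKKLLKLLKKLLKLLKKL)
#>   region of interest 35-70: best window overlaps
```

The fitted k (0.0361 s⁻¹) recovers the generating 0.036 s⁻¹ within the
noise; the efficiency 4.86×10⁶ M⁻¹s⁻¹ is the rate-enhancement per molar
enzyme; the Henderson slope returns the generating Ki (18.75 nM) and the
intercept the active-enzyme concentration (4.34 nM) exactly, because the
Henderson plot is an algebraic rearrangement of the Morrison model.

## Command line

```sh
exec/cyclofit simulate-trace --k 0.036 --enzyme 4.34nM --out trace.csv
exec/cyclofit fit-trace trace.csv
exec/cyclofit simulate-titration --preset csa --out csa.csv
exec/cyclofit fit-ki csa.csv
exec/cyclofit scan-helix protein.fasta --window 18 --roi 35:70
exec/cyclofit reproduce
exec/cyclofit show-config
```

Concentration flags take molar strings with SI prefixes (`4.34nM`,
`11.16uM`); bare numbers are rejected so units are always explicit.
`reproduce` runs the full pipeline on generated fixtures and prints a table
of computed versus reference constants with relative errors.

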