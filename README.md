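# idrbind

Quantitative NMR-titration analysis of how long intrinsically disordered
regions (IDRs) bind folded partner domains — the situation typified by
endocytic adaptor proteins, whose disordered tails carry short linear
motifs (DLL/DLF, DPF, FxDxF) and occasionally much larger composite
binding elements, and engage partners such as the clathrin heavy-chain
terminal domain and the AP2 α/β2 appendage domains.

The package is aimed at NMR spectroscopists and structural biologists who
have per-residue titration observables (chemical shifts, peak
intensities, ¹⁵N R₁ρ rates, CPMG dispersions, ITC thermograms) and want
reproducible, residue-resolved binding parameters, together with seeded
synthetic-data generators that make every analysis step testable against
ground truth.

## What it computes

**Chemical shift perturbations.** For each residue,

    CSP = sqrt((Δδ¹H · 6.5)² + (Δδ¹⁵N)²)

(the proton difference scaled by 6.5 and combined in quadrature with the
nitrogen difference), plus intensity ratios I/I₀ in which
exchange-broadened ("disappeared") peaks are kept as zero-ratio entries.

**Residue-wise K_D from fast-exchange R₁ρ.** Under weak 1:1 binding in
fast exchange the observed rate is the population-weighted average

    R₁ρ = [B_tot]/(K_D + [A_tot]) · (R₁ρᴮ − R₁ρᴬ) + R₁ρᴬ,

linear in added partner. A weighted linear fit of R₁ρ against [B_tot]
gives per-residue K_D = (R₁ρᴮ − intercept)/slope − [A_tot], with
Monte-Carlo percentile intervals. Rates come from two-parameter
exponential fits of magnetization decays with Monte-Carlo errors.

**Global two-state CPMG exchange fitting.** R₂eff(ν_CPMG) profiles for
many residues at one or two static fields are fit jointly with shared
exchange rate k_ex and bound population p_B, per-residue |Δω| (ppm) and
per-residue-per-field R₂⁰. The fit kernel is an exact closed-form
solution of the two-site CPMG cycle propagator (the Carver–Richards
expression retaining both eigenmode amplitudes), validated to < 0.1 s⁻¹
against independent numerical Bloch–McConnell propagation. From the
fitted p_B and the sample composition, 1:1 mass balance gives

    K_D = [A_free][B_free]/[AB],  k_off = (1 − p_B)·k_ex,
    k_on = p_B·k_ex/[B_free].

**Conformational propensities.** Secondary chemical shifts
(observed − random coil, bundled reference table) and windowed
secondary-structure propensities normalized so that fully formed helix
scores +1 and fully formed strand −1.

**ITC.** Exact 1:1 isotherms with displaced-volume dilution bookkeeping,
fit for (n, K_D, ΔH, offset) by Levenberg–Marquardt.

**Motifs and interaction windows.** Overlap-aware scanning for
D-L-[LF], D-P-F and F-x-D-x-F; extraction of 21-residue windows centered
on the hydrophobic residue with the highest titration-induced rate
increase; ranking and position-frequency matrices for logos.

## Worked example

Simulate a paper-scale CPMG experiment (22 dispersing residues, 600 and
850 MHz, 14 frequencies between 31.25 and 1000 Hz at t_relax = 32 ms,
0.5 s⁻¹ noise) and refit it:

```r
library(idrbind)
set.seed(1)
dw_map <- setNames(runif(22, 1, 4), 430 + seq_len(22))  # |dw| in ppm
g <- gen_dispersion(dw_map, k_ex = 662, p_b = 0.089,
                    fields = c(600, 850), noise_sd = 0.5, seed = 20)
fit <- global_fit(g$data, a_total = 100, b_total = 10)
print(fit)
#> global two-state exchange fit (22 residues, 616 points)
#>   k_ex = 663.4 +- 4.1 s-1
#>   p_b  = 8.892% +- 0.029% (bound population)
#>   chi2 = 563.63 (reduced 1.029)
#>   derived: KD = 11.4 uM, k_on = 53.2 uM-1 s-1, k_off = 604 s-1
```

The generator's truth (k_ex = 662 s⁻¹, p_B = 8.9%) is recovered within
noise, and the derived thermodynamics follow from the fitted population
and the 100 µM / 10 µM sample composition.

Residue-wise K_D from a rate titration (0/50/100/150% partner at 100 µM
observed protein, 2% rate noise, truth K_D = 177 µM):

```r
design <- titration_design(100, data.frame(
  label = c("0%", "50%", "100%", "150%"),
  b     = c("0%", "50%", "100%", "150%")))
sq    <- gen_sequence(8, seed = 1)$sequence
rates <- gen_titration_rates(sq, setNames(177, 4), design,
                             r_free = 3, r_bound = 30,
                             noise_sd = 0.02, seed = 2)
fit_site_kd(rates$rates, design, r_bound = 30, residue = 4,
            n_mc = 200, seed = 3)
#> residue 4: KD = 174.5 uM [166.4, 184.2] (ok)
```

A 1:1 ITC isotherm (30 µM cell, 19 × 2 µL injections of 300 µM titrant,
1% heat noise, truth K_D = 5.1 µM, ΔH = −10 kcal/mol):

```r
itc <- gen_itc(n = 1, kd = 5.1, dh = -10, noise_sd = 0.01, seed = 4)
fit_itc(itc$data)
#> 1:1 ITC fit: n = 0.990 +- 0.014, KD = 5.12 +- 0.51 uM, dH = -10 +- 0.34 kcal/mol
#>   offset = -0.00347 ucal/injection, Wiseman c = 5.8
```

An end-to-end configuration-driven run (simulate → fit → report) is shown
in `inst/extdata/example_config.yaml`:

```r
cfg <- run_config(system.file("extdata", "example_config.yaml",
                              package = "idrbind"))
dir <- tempfile()
run_simulate(cfg, dir)
run_fit(cfg, "cpmg", dir); run_fit(cfg, "relaxation", dir)
run_fit(cfg, "itc", dir);  run_fit(cfg, "motifs", dir)
run_report(file.path(dir, "results"))
```

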