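---
title: "Models and methods: NMR titration analysis of IDR binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: NMR titration analysis of IDR binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrbind)
```

# Scope

`idrbind` analyses NMR titrations of an isotopically labeled,
intrinsically disordered protein (the "observed" species A) with a folded,
unlabeled partner (B). Because a disordered chain binds through many small
sites, the analysis is residue-resolved throughout: chemical shift
perturbations, intensity ratios, R₁ρ relaxation rates and CPMG relaxation
dispersion are all indexed by residue number of the full-length protein,
with each construct carrying an explicit `first_residue_number` offset so
segments and full-length data align without implicit shifts.

# The 1:1 binding model

All thermodynamic reasoning reduces to the bimolecular equilibrium
A + B ⇌ AB with dissociation constant $K_D = [A][B]/[AB]$ (µM throughout).
The complex concentration solves a quadratic in the totals; we evaluate
the root in the multiply-conjugate form

$$[AB] = \frac{2\,a_{tot} b_{tot}}{(a_{tot}+b_{tot}+K_D) +
\sqrt{(a_{tot}+b_{tot}+K_D)^2 - 4 a_{tot} b_{tot}}}$$

which avoids catastrophic cancellation when $K_D \ll$ the concentrations
(`bound_fraction_exact()`). The inverse map, from a bound population
$p_B$ to $K_D$, and the kinetic decomposition
$k_{off} = (1-p_B)k_{ex}$, $k_{on} = p_B k_{ex}/[B]_{free}$ are algebraic
and mutually consistent by construction: $k_{off}/k_{on}$ reproduces the
mass-balance $K_D$ exactly, and the test suite asserts the round trip to
$10^{-9}$ relative.

# Chemical shift perturbations

The combined amide CSP is computed as
$\mathrm{CSP} = \sqrt{(6.5\,\Delta\delta_{^1H})^2 + \Delta\delta_{^{15}N}^2}$.
Note the weighting: the **proton** difference is scaled *up* by 6.5 rather
than the common alternative of dividing the nitrogen difference by ~6.5.
The two conventions differ only by a global factor of 6.5, so per-residue
patterns, rankings and any threshold expressed in the same convention are
unchanged; we keep this form because it is the one used with the data this
package is designed around. Peaks that vanish during a titration are kept
in intensity-ratio profiles as `ratio = 0` with a `disappeared` flag, so
exchange broadening appears as signal rather than as missing data; CSPs,
by contrast, are simply not defined for unmatched residues and are
omitted. Default peak-matching tolerances are 0.05 ppm (¹H) and 0.5 ppm
(¹⁵N), configurable; ambiguous nearest-neighbour matches (two candidates
inside the tolerance ellipse, in either direction) are excluded rather
than guessed.

# Residue-wise K_D from fast-exchange R₁ρ

For weak binding in fast exchange the observed rotating-frame rate is the
population-weighted average of free and bound values. With
$p_B \approx b_{tot}/(K_D + a_{tot})$ this gives the linear relation

$$R_{1\rho}(b_{tot}) = \frac{b_{tot}}{K_D + a_{tot}}
\left(R_{1\rho}^B - R_{1\rho}^A\right) + R_{1\rho}^A$$

(`predict_r1rho()`). Per residue we fit a weighted linear regression of
rate against added partner and invert:
$K_D = (R_{1\rho}^B - \mathrm{intercept})/\mathrm{slope} - a_{tot}$. The
bound-state rate $R_{1\rho}^B$ is measured once on the partner and treated
as constant across the titration. Fits with non-positive slope or with an
intercept at or above $R_{1\rho}^B$ are flagged invalid and report no
$K_D$. Because the transform is nonlinear, uncertainties are asymmetric
Monte-Carlo percentile intervals (2.5/97.5%) over rate resampling
(default 500 draws; the seed is a required argument).

Rates themselves come from unweighted two-parameter least-squares fits of
$I(t) = I_0 e^{-Rt}$ over at least three delays (the generators use seven
delays spanning 10–230 ms), with rate errors from Monte-Carlo resampling
of the stated intensity errors. $R_{1\rho}$ is used as fitted, without
$R_1$/tilt-angle correction — appropriate for a strong spin lock
(1.5 kHz) and small $R_1$ changes across the titration, which is the
regime this analysis targets.

## Validity of the linear approximation

The linear form neglects partner depletion: its bound fraction
$b_{tot}/(K_D + a_{tot})$ exceeds the exact quadratic result by a relative
error of approximately $(b_{tot} - [AB])/(K_D + a_{tot})$. On the domain
$b_{tot} \le 0.05\,(K_D + a_{tot})$ this stays below 5%; at
$b_{tot} = 0.1\,(K_D + a_{tot})$ it reaches ≈5% when $K_D = a_{tot}$ and
≈9% when $K_D \gg a_{tot}$, and the test suite documents this boundary.
The divergence grows as binding tightens (smaller $K_D$ at fixed
$b_{tot}$) up to the saturation regime, where both forms reconverge. The
synthetic generator can produce rates from either the linear (`eq2`) or
the exact model, so this bias is directly measurable: fitting
exact-model data for a tight site ($K_D \ll a_{tot}$) with the linear
analysis gives visibly biased $K_D$, which is the expected behaviour, not
an error.

# Two-state CPMG relaxation dispersion

Effective transverse rates are
$R_2^{eff} = -\ln(I/I_0)/T_{relax}$ from constant-time intensities
(points with $I \le 0$ are dropped and flagged). The forward model for
two-site exchange under an even pulse train of ideal, instantaneous 180°
pulses is implemented twice, deliberately:

* `simulate_bm()` — numerical Bloch–McConnell propagation of the complex
  two-state magnetization through $n = \mathrm{round}(\nu T)$ cycles of
  $\tau$–180°–$2\tau$–180°–$\tau$, with pulses as complex conjugation and
  detection of the magnitude of the summed magnetization. The 2×2 matrix
  exponentials use the spectral form, whose eigenvalue exponentials never
  overflow because relaxation eigenvalues have non-positive real parts.
* `simulate_cr()` — the closed form. One cycle is the linear map
  $Q = P(\tau)\,\overline{P(2\tau)}\,P(\tau)$ (the two antilinear pulse
  conjugations compose into an elementwise conjugate of the middle
  propagator), and $Q^n$ follows from the analytic eigendecomposition of
  the 2×2 cycle matrix. Retaining only the dominant eigenvalue of $Q$
  recovers the textbook Carver–Richards `acosh` expression; we keep both
  eigenmodes and their amplitudes. This matters: the dominant-eigenvalue
  truncation deviates from finite-time propagation by several s⁻¹ in slow
  exchange at $p_B \sim 0.2$, while the full spectral form agrees with
  `simulate_bm()` to numerical precision across all regimes. The
  acceptance grid (k_ex 100–3000 s⁻¹, p_B 0.01–0.2, |Δω| 0.5–4 ppm, 600
  and 850 MHz, 14 frequencies) verifies agreement to < 0.1 s⁻¹, and the
  low-frequency limit is checked against the analytic fast-exchange
  result $R_{ex} = p_A p_B \Delta\omega^2 / k_{ex}$.

Conventions: |Δω| is fit in ppm (field-independent) and converted to
rad/s per field with the ¹⁵N/¹H gyromagnetic ratio magnitude 0.101329;
its sign is fixed non-negative because CPMG alone cannot determine it.
Frequency grids always satisfy the integer-cycle rule
$n = \mathrm{round}(\nu T)\ \ge 1$ — at $T = 32$ ms the 14-point default
grid runs 31.25–1000 Hz (a nominal 31.35 Hz point rounds to the same
single cycle). Point errors are floored at 0.5 s⁻¹ before fitting.

## The global fit

`global_fit()` minimizes the error-weighted sum of squares over all
residues and fields jointly, sharing $(k_{ex}, p_B)$, with per-residue
|Δω| and per-residue-per-field $R_2^0$. Optimization is
Levenberg–Marquardt (`minpack.lm`) with box bounds
($k_{ex} \in [1, 10^5]$ s⁻¹, $p_B \in [10^{-4}, 0.499]$,
|Δω| ∈ [0, 20] ppm), started from every point of the grid
$k_{ex} \in \{100, 300, 600, 1000, 2000\} \times
p_B \in \{0.02, 0.05, 0.1, 0.2\}$; each start runs a capped first pass
and the best chi-square (ties broken toward smaller $k_{ex}$) is polished
to convergence. Initial |Δω| per residue comes from its dispersion
amplitude via the fast-exchange relation; initial $R_2^0$ is the group
minimum. Only residues whose dispersion amplitude
$\Delta R_2 = R_2^{eff}(\nu_{low}) - R_2^{eff}(\nu_{high})$ exceeds three
times the pooled (rms) point error enter the fit by default.
Uncertainties come from the covariance at the optimum (central-difference
Jacobian), scaled by the reduced chi-square when it exceeds one; optional
Monte-Carlo resampling is available. A single residue at a single field
is fit but flagged, since $(k_{ex}, p_B, \Delta\omega)$ are then strongly
degenerate. Concentrations enter only after the fit, converting $p_B$
to $K_D$, $k_{on}$, $k_{off}$; the fit itself is concentration-agnostic,
and whether to constrain $p_B$ by known concentrations is left to the
user (we fit it freely).

# Secondary chemical shifts and propensities

SCS = observed − random coil, so positive Cα/CO and negative Cβ
deviations indicate helix. The bundled random-coil table holds average
literature values (see `inst/extdata/PROVENANCE.md`); users with
neighbour- or condition-corrected references can supply their own.
The propensity score combines Cα and Cβ (CO optional, default off since
its dispersion is smaller) over a sliding window (default 5 residues,
odd): atoms enter with sign +1 (Cα, CO) and −1 (Cβ), and the window sum
is normalized by the corresponding sum of fully-formed helix references
when positive, or strand references when negative. A window exactly
matching the helix references scores +1, strand scores −1, and the score
is linear in the population in between; residues whose window holds no
carbon data are reported missing. Glycine contributes no Cβ and proline
no amide — both are handled purely by data availability.

# ITC

The forward model applies exact 1:1 mass balance to the running cell
composition under the perfect-mixing displaced-volume convention (each
injection of volume $v$ dilutes cell contents by $1 - v/V_0$ and delivers
syringe material at $v/V_0$); stoichiometry $n$ scales the cell-side site
concentration, and the heat of injection $i$ is
$\Delta H\,V_0\,([AB]_i - [AB]_{i-1}(1 - v_i/V_0))$ plus a constant
per-injection offset (µcal, with ΔH in kcal/mol). Fitting is
Levenberg–Marquardt over $(n, K_D, \Delta H, \mathrm{offset})$ with at
least eight usable injections; the first injection is excluded by default
(standard practice for the diffusion-corrupted initial injection). A
Wiseman parameter $c = n\,[\mathrm{cell}]/K_D$ outside [1, 1000] triggers
a warning because the isotherm shape then constrains $K_D$ poorly.
Cell volume (200 µL) and injection count (19 × 2 µL) are generator
conventions chosen to match a typical low-volume instrument.

# Motifs and interaction windows

Motif scanning reports every match, including overlapping ones, of
D-L-[LF], D-P-F and F-x-D-x-F (a relaxed D-[LI]-[LF] variant is available
behind a flag for degenerate DIF-type sites). Interaction windows are
derived from titration-induced rate increases: contiguous runs of
residues exceeding `min_prominence` (default 2 s⁻¹ above baseline — the
threshold is a package convention, configurable) form regions, and each
region is represented by a 21-residue window centered on the hydrophobic
residue with the highest rate. The hydrophobic set {L, F, I, V, M, W, Y}
deliberately excludes alanine: in this analysis small residues act as
flanking preferences rather than anchors. Windows at chain termini are
gap-padded with `-`. Ranking is by central rate, descending, ties by
residue number; the position-frequency matrix counts letters per column
excluding gaps, ready for any logo renderer.

# Synthetic data and what passing tests mean

Every generator takes an explicit seed and records its ground truth, and
identical (configuration, seed) pairs reproduce identical bytes. Default
noise levels are 2% relative on rates, 0.5 s⁻¹ absolute on $R_2^{eff}$,
1% of the largest heat on ITC, and 0.02 ppm on carbon shifts (amide ¹H at
a tenth of that) — values chosen to mimic well-set-up experiments.
Background sequences draw from a disorder-promoting composition
(enriched G/S/A/P/D/E); planted motifs are inserted verbatim and chance
background hits are audited into the truth file.

The generators emulate the *statistical* structure of the experiments:
independent Gaussian noise, complete residue coverage, no peak overlap,
no assignment errors, a single global two-state process, and
field-independent baselines per residue. Real data violate several of
these (overlapping peaks, correlated baseline distortions, multi-site
exchange, missing assignments), so recovery tests demonstrate the
estimators' correctness and precision under the stated model — not
robustness to every experimental artefact. Problem sizes used in the
shipped tests and acceptance script (22 residues × 2 fields × 14
frequencies for CPMG; 10–20 seeds for recovery medians; 25–50 seeds for
the scalar fits) were chosen as the smallest sets that make the medians
stable; the full multi-start grid is retained in every fit.

# Known limitations

* CPMG pulses are ideal and instantaneous: no finite pulse width,
  off-resonance or TROSY/anti-TROSY differential relaxation effects.
* Two-state exchange only; three-state or competing equilibria must be
  modelled elsewhere.
* The R₁ρ treatment assumes on-resonance spin lock and negligible $R_1$
  contribution; off-resonance R₁ρ dispersion is out of scope.
* ITC assumes a constant baseline offset; no drift model, and no
  competitive or multi-site isotherms.
* NMR-STAR support is read-only and restricted to the atom-chemical-shift
  loop; deposited entries in construct-local numbering need the explicit
  `number_offset`.
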