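---
title: "Mapping a TPR-peptide interaction: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a TPR-peptide interaction: models, defaults and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampmap)
```

clampmap analyses the data types that characterise a protein–peptide
interaction in solution: HSQC titration peak lists, heteronuclear NOE and
PRE intensity tables, integrated ITC thermograms, and PDB coordinates.
This vignette is the package's own account of the underlying models, why
the defaults are what they are, and what the accompanying tests do and do
not demonstrate.

## Chemical shift perturbation

For an amide observed free and bound, the combined perturbation is
$\Delta\delta_{av} = \sqrt{\Delta\delta_H^2 + (w_N\,\Delta\delta_N)^2}$.
The nitrogen weight $w_N$ compensates the ~5-fold larger dispersion of
the ^15^N dimension; 1/5 is the most widely used convention and is the
default, with 0.14 and 0.10 accepted alternatives via the `weight_N`
argument. The perturbation cutoff for interface mapping defaults to
0.10 ppm and is applied as a strict inequality: a residue at exactly the
cutoff is not called perturbed. Both choices are deliberate conventions,
not fitted quantities, and both are configurable.

Peak tracking across titration points is by assignment label only.
Residues that vanish at a point (exchange broadening) are recorded as
gaps — the package never interpolates a missing peak, because a peak lost
to broadening carries information (intermediate exchange, large
interface) that an interpolated position would erase. A weighted shift
step larger than `jump_threshold` (default 0.15 ppm) between consecutive
points raises a warning about possible mis-assignment but never triggers
automatic reassignment.

## The 1:1 fast-exchange binding model

Under fast exchange the observed shift is the population average of the
free and bound states, so per residue
$\Delta\delta_{obs} = \Delta\delta_{max}\, f_b(P, L, K_d)$ with the exact
mass-balance bound fraction
$f_b = \bigl((P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}\bigr)/2P$.
The discriminant is analytically positive; the implementation clamps it
at zero against floating-point cancellation and clips the result to
$[0, \min(1, L/P)]$.

`fit_binding()` fits in $\log_{10} K_d$ over $[10^{-3}, 10^{5}]$ μM.
For a fixed $K_d$ each residue's $\Delta\delta_{max}$ has a closed-form
linear least-squares solution (non-negativity enforced), so the profiled
objective is one-dimensional; it is scanned on a log-spaced grid and the
best starts are refined with Brent's method. This is scale-free, immune
to the local minima that plague joint non-linear starts, and fast enough
to be re-run inside every bootstrap replicate. A fit whose optimum sits
at a box bound is reported with `converged = FALSE` rather than as a
number. All-zero CSP input raises an explicit "no binding detectable"
error — a spurious K~d~ from flat data is worse than no answer.

The default is a single shared K~d~ across residues (a global fit):
residues reporting on one binding event should agree, and pooling them is
what makes weak signals identifiable. Per-residue mode is retained as a
diagnostic; systematic disagreement between per-residue K~d~ values is
itself evidence that the 1:1 model is wrong for part of the interface.

### Uncertainty and the limits of the isotherm

`bootstrap_uncertainty()` resamples residues with replacement (global
mode) or residuals (per-residue mode), deterministically for a fixed
seed. Case resampling alone, however, understates uncertainty when the
titration design itself is uninformative: every replicate sees the same
concentration grid, so if the grid only samples the saturated plateau or
only the linear foot of the isotherm, resampled fits can cluster tightly
around a meaningless optimum. The report therefore also carries a
profile-likelihood (F-test) interval for K~d~, and the fit is labelled
*poorly determined* when either the bootstrap 90 % interval or the
profile interval spans more than one order of magnitude.

Two failure regimes deserve naming. When the protein concentration is
far above K~d~, the isotherm is a sharp stoichiometric break; the
curvature that encodes K~d~ shrinks as $\sqrt{K_d/P}$, and whether a fit
is meaningful depends on how that compares with the shift noise — at
0.004 ppm noise a titration at $P/K_d \approx 100$ with points bracketing
the break still determines K~d~ to within a factor of about two, which is
why the package measures determinacy from the data rather than declaring
a concentration regime unfittable a priori. Conversely, a titration that
*defies saturation* — peaks still moving after many equivalents because
the affinity is far weaker than the sampled ligand range — pins only the
product $\Delta\delta_{max}/K_d$; there the profile interval collapses
onto the parameter bound and the poorly-determined flag fires robustly.
The tests exercise exactly that case.

## Heteronuclear NOE and PRE profiles

The hetNOE observable is the plain intensity ratio I~sat~/I~ref~; it is
scale-invariant by construction. Classes are "highly flexible" below 0
(negative NOE requires sub-nanosecond motion), "rigid" at or above 0.65,
and "partially ordered" between; both boundaries are arguments. Error
propagation uses supplied spectral noise estimates only — when none are
given, no error column is invented.

The PRE observable is I~para~/I~dia~ per residue. The default proximal
cutoff of 0.7 is an explicit convention (experimental reports usually say
only "significant broadening"); a second mode flags residues below the
profile mean minus one standard deviation instead. Residues visible in
the diamagnetic but absent from the paramagnetic spectrum are assigned
ratio 0 and flagged, with a message; negative paramagnetic intensities
are clamped to 0 and logged. For structure checks the nitroxide is
represented by the label-site side-chain terminal heavy atom (falling
back to CB, then CA), since the label extends from the mutated cysteine
side chain, and proximal flags are compared against a 20 Å radius — the
conventional reach of nitroxide broadening at these correlation times.

## One-site ITC

The forward model follows the perfusion (displaced-volume) convention of
low-volume titration calorimeters: injection $i$ of volume $dv$ dilutes
the cell contents by $(1 - dv/V_0)$, bound complex follows the one-site
quadratic with stoichiometry $n$, the cumulative heat is
$Q_i = n\,\Delta H\,V_0\,[PL]_i$, and the measured heat is
$q_i = Q_i - Q_{i-1} + \frac{dv_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2} + q_{dil}$,
the middle term crediting the complex carried out with the displaced
volume at the mean of the pre- and post-injection concentrations. That
correction is exact to first order in $dv/V_0$; the tests allow the
cumulative heat a post-saturation drift of order $(dv/V_0)^2$ per
injection, which for 2 μL injections into a 200 μL cell is about
10^-3^ μcal. A physical consequence of perfusion worth knowing: the
cumulative heat converges to $n\,\Delta H\,P_0 V_0$ *minus* the heat of
protein displaced from the cell before it bound (~2.5 % under a
20 × 2 μL protocol), and the heat-conservation test verifies this against
an independent stoichiometric-limit bookkeeping oracle rather than
pretending the displaced heat does not exist.

`fit_one_site()` fits $(\log_{10} K_b, \Delta H, q_{dil})$ by
Levenberg–Marquardt with $n$ fixed at 1 — the standard assumption for a
single-site complex — from five log-spaced K~b~ starts; the first
injection is discarded by default (syringe-tip diffusion during
equilibration), and ΔS, ΔG and K~d~ are derived afterwards from
$\Delta G = -RT\ln K_b = \Delta H - T\Delta S$ with
$R = 1.9872\times10^{-3}$ kcal mol^-1^ K^-1^ and $T = 298$ K unless the
protocol says otherwise. Units match calorimetric practice throughout:
μcal for heats, kcal/mol for ΔH and ΔG, cal mol^-1^ K^-1^ for ΔS, μM for
K~d~. Dilution heats are modelled as a constant per-injection offset;
blank-titration subtraction can be applied upstream by subtracting the
blank heats from the thermogram before fitting.

## Accessibility and docking restraints

Solvent accessibility is computed by the Shrake–Rupley algorithm with a
1.4 Å probe and 960 sphere points per atom. The point set is a
golden-section spiral made antipodally symmetric, which both improves the
quadrature and guarantees exactly equal areas for mirror-image atom
arrangements; doubling the point count changes a 20-residue structure's
total area by well under 0.5 %. Relative accessibility divides by the
Tien et al. (2013) theoretical maximum-ASA values (any other table can be
passed in); termini can exceed 100 % and are reported as-is with a
message, never clipped.

Active residues for docking are those that are both perturbed
(Δδ_av > 0.10 ppm) and accessible (relative SASA > 45 %); passive
residues are the remaining accessible residues with any heavy atom within
6.5 Å of an active residue — the standard "solvent-exposed neighbours"
rule, with 6.5 Å the protocol's conventional radius for "juxtaposed".
Whether the 45 % cutoff should apply to all-atom or side-chain-only
accessibility differs between accessibility programs; this implementation
uses whole-residue all-atom accessibility and exposes the threshold, so
either convention can be reproduced. Restraints are emitted as CNS-syntax
ambiguous distance restraints, one `assign` block per active residue
against the partner's active + passive union, with the conventional
2.0 Å (−2.0/+0.0) bounds, and the writer round-trips through its own
parser. An empty active set is an error pointing at the thresholds, not
an empty file.

## The synthetic-data module

The generators produce data with the statistical structure the analysis
assumes — and only that structure. The titration generator moves each
shifting residue along a fixed direction in the (H, N) plane by the
mass-balance bound fraction, which is exactly the straight-line
fast-exchange trajectory; per-residue directions are drawn once from the
seed. Noise is Gaussian on each axis (σ on ^1^H, σ/w~N~ on ^15^N so both
axes contribute equally after weighting). The PRE generator uses a
reduced parametrisation — Γ~2~ = Γ~2,ref~ (r~ref~/r)^6^ and
ratio = R~2~/(R~2~+Γ~2~)·e^(−Γ₂t)^ with defaults R~2~ = 15 s^-1^,
Γ~2,ref~ = 50 s^-1^ at r~ref~ = 12 Å, t = 10 ms — rather than full
Solomon–Bloembergen constants, because the analysis consumes only ratios
and a distance cutoff, so only the monotone r^-6^ shape matters; these
defaults put the 0.7-ratio contour near 17 Å, inside the 20 Å
interpretation radius. Toy structures are ideal alanine backbones
(Engh–Huber bond geometry, helix φ/ψ = −57/−47, extended −120/120) built
by internal-coordinate chain extension.

What the generators do *not* emulate: peak overlap and mis-assignment,
intermediate-exchange line broadening, correlated baseline drifts in
calorimetry, conformational averaging of the spin label, or any
nonspecific secondary binding. Passing tests therefore demonstrate that
the estimators are correct and well-calibrated *for data obeying their
own models*, not that real spectra will be as kind.

## Problem sizes and study conditions

The simulation studies use conditions matching the experimental system
the package was designed around: CSP recovery runs 100 replicates of a
12-point titration (ratios 0–8) of a 10 μM labelled protein with six
shifting residues (Δδ_max 0.10–0.30 ppm), K~d~ = 3.27 μM and 0.004 ppm
shift noise; ITC recovery runs 50 replicates of a 20 × 2 μL, 1 mM-into-
50 μM, 200 μL-cell titration at K~d~ = 16.1 μM, ΔH = −3.37 kcal/mol with
0.05 μcal heat noise (Wiseman c ≈ 3, squarely in the fittable range).
These sizes give medians stable to a few percent while keeping the whole
suite comfortably fast on a single CPU.

## Known limitations

* Only 1:1 binding: no cooperative, 2:1 or competitive models, and no
  slow/intermediate-exchange lineshape analysis.
* PRE is interpreted qualitatively (proximal / not proximal); no
  Γ~2~-to-distance inversion for refinement.
* ITC fitting consumes integrated heats; raw power traces and baseline
  integration are out of scope, as is ΔC~p~ analysis.
* The AIR writer emits restraints; it does not run docking.
* Residue-numbering offsets between constructs and structures are never
  guessed — they must be declared, and the readers will happily produce
  misaligned profiles if given a wrong offset.
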