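# clampmap

Biophysical interaction mapping for protein–peptide complexes studied by
solution NMR and isothermal titration calorimetry (ITC). The package was
built around a common experimental situation in structural biology: a
tetratricopeptide-repeat (TPR) domain grips the C-terminal peptide of a
partner protein through a "carboxylate clamp", and the interface is mapped
by HSQC titrations, backbone dynamics, paramagnetic labelling and
calorimetry, then turned into ambiguous interaction restraints (AIRs) for
data-driven docking. Every stage of that workflow is implemented here as a
testable, scriptable pipeline for R users who have assigned peak lists and
integrated thermograms rather than raw spectra.

## What it computes

**Chemical shift perturbation (CSP).** For each backbone amide tracked
across a titration, the combined perturbation between free and bound
states is

  Δδ_av = sqrt( Δδ_H² + (w_N · Δδ_N)² ),  w_N = 1/5 by default,

and residues with Δδ_av strictly above a cutoff (0.10 ppm by default) are
called perturbed.

**1:1 fast-exchange K_d.** Under fast exchange the observed shift is the
population-weighted average of free and bound states, so
Δδ_obs = Δδ_max · f_b with the bound fraction from the exact 1:1 mass
balance

  f_b = ( (P + L + K_d) − sqrt((P + L + K_d)² − 4PL) ) / (2P).

`fit_binding()` profiles the per-residue Δδ_max out analytically and
minimises over log10 K_d, sharing one K_d across residues by default;
`bootstrap_uncertainty()` adds residue-resampling errors and a
profile-likelihood interval, and flags fits whose interval spans more than
an order of magnitude as poorly determined.

**Backbone dynamics.** Steady-state ¹H–¹⁵N heteronuclear NOE ratios
I_sat/I_ref per residue, classified into highly flexible (NOE < 0),
partially ordered, and rigid (NOE ≥ 0.65).

**PRE proximity mapping.** Paramagnetic/diamagnetic intensity ratios
I_para/I_dia per residue (MTSL vs dMTSL label), with residues below a
broadening threshold flagged as proximal to the nitroxide and checked
against a structure (≈20 Å interpretation radius).

**One-site ITC.** A perfusion-cell forward model for integrated injection
heats, Levenberg–Marquardt fitting of (K_b, ΔH, dilution offset) with
n = 1, and the thermodynamic identities ΔG = −RT ln K_b = ΔH − TΔS
(R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹) for interconverting K_d, ΔH and ΔS.

**Docking restraints.** Shrake–Rupley solvent-accessible surface area,
relative accessibility against a published maximum-ASA table, active
residues = perturbed ∩ accessible (>45 %), passive residues = accessible
neighbours, written as CNS-syntax ambiguous distance restraints.

**Synthetic data.** Seeded generators for fast-exchange titrations,
hetNOE and PRE intensity tables (driven by an r⁻⁶ broadening model on a
toy structure), one-site thermograms and ideal helix/extended PDB
coordinates, so the full pipeline runs and is tested without any
experimental download.

## Worked example

```r
library(clampmap)

## a fast-exchange titration of a 10 uM labelled protein, four shifting
## C-terminal residues, generated at K_d = 3.27 uM with 0.004 ppm noise
dmax <- setNames(c(0.12, 0.18, 0.22, 0.30), 404:407)
ser <- gen_titration_dataset(K_d_true = 3.27, delta_max_map = dmax,
                             P_tot = 10, ratios = c(0, 0.2, 0.5, 1, 2, 5),
                             noise_csp = 0.004, seed = 42)
tr   <- match_titration_peaks(ser)
prof <- build_csp_profile(tr, observation_ratio = 5)
head(as.data.frame(prof), 4)
#>   residue_number    delta_H     delta_N  delta_av
#> 1            404 -0.1182034  0.04559698 0.1185546
#> 2            405 -0.1299308 -0.61718142 0.1792164
#> 3            406  0.2050568 -0.14268578 0.2070330
#> 4            407  0.2639819  0.50118333 0.2823718

classify_perturbed(prof, threshold = 0.10)
#> [1] 404 405 406 407

fit <- fit_binding(tr)
fit
#> 1:1 fast-exchange fit (global): K_d = 3.358 uM, 8 residues, converged
round(bootstrap_uncertainty(tr, fit, n_boot = 100, seed = 1)$interval, 2)
#> [1] 2.83 3.48
```

The fitted K_d of 3.36 μM recovers the generating 3.27 μM within the
bootstrap 90 % interval; the four shifting residues — and none of the
negative controls — pass the 0.10 ppm cutoff. The same loop closes for
calorimetry:

```r
prot <- itc_protocol(cell_conc = 50, syringe_conc = 1000,
                     cell_volume = 200, injection_volumes = rep(2, 20))
tg <- gen_itc_thermogram(derive_thermo(K_d = 16.1, dH = -3.37, T = 298),
                         prot, noise_q = 0.05, seed = 7)
fit_one_site(tg)
#> one-site ITC fit:
#> K_d = 14.78 uM  dG = -6.586 kcal/mol  dH = -3.350 kcal/mol  dS = 10.860 cal/(mol K)  n = 1  T = 298 K
```

## Documentation

The methods vignette (`vignettes/interaction-mapping.Rmd`) describes the
models, their assumptions, the defaults and the known limitations; every
exported function carries full help.
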