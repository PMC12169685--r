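---
title: "Modelling thiol reactivity of covalent reactive groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thiol reactivity of covalent reactive groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crgreact)
```

## The scientific problem

Covalent inhibitors carry an electrophilic covalent reactive group
(CRG) — typically an α,β-unsaturated amide such as an acrylamide or an
α-methylene-γ-lactam — that bonds to a nucleophilic cysteine of the
target protein. Tuning the intrinsic electrophilicity of the CRG is a
central design problem: too reactive and the compound is promiscuous,
too inert and it never labels the target. Glutathione (GSH), a thiol
tripeptide, is the standard surrogate nucleophile for measuring that
intrinsic reactivity, and N-heteroaryl substitution of the lactam
scaffold turns out to modulate it over a wide range.

`crgreact` implements the complete analysis chain for this kind of
study:

1. **Kinetics** — pseudo-first-order rate constants from NMR
   reaction-monitoring series, half-lives, and Eyring activation free
   energies.
2. **Descriptors** — a registered vocabulary of electronic/steric
   descriptors, a Hammett-type substituent constant for heteroaryl
   groups (σ_Het), and Henderson–Hasselbalch protonation handling.
3. **Modelling** — univariate linear free-energy-relationship (LFER)
   screening, a single-parameter electron-affinity (EA) model,
   protonation-weighted predictions, test-set validation by mean
   unsigned error (MUE), and a generic multivariate option with
   leave-one-out Q².
4. **Papain** — enzyme progress-curve analysis (initial rates,
   residual activity E/E₀) and correlation of inactivation with thiol
   reactivity.
5. **Synthetic data** — seeded generators emulating each experimental
   design, so every stage is testable with known ground truth.

## Kinetic model

With GSH in 10-fold excess, electrophile decay is pseudo-first-order:

$$\ln [\mathrm{CRG}]_t = -k\,t + \ln [\mathrm{CRG}]_0 .$$

`fit_pseudo_first_order()` performs ordinary least squares of the log
fraction remaining on time; the rate constant is minus the slope.
Derived quantities are the half-life $t_{1/2} = \ln 2 / k$ and the
Eyring activation free energy (unit transmission coefficient)

$$\Delta G^{\ddagger} = R\,T \ln\!\frac{k_B T}{h\,k},$$

evaluated by default at $T = 310.15$ K, the assay temperature.
Constants are fixed SI/CODATA values ($k_B = 1.380649\times10^{-23}$
J/K, $h = 6.62607015\times10^{-34}$ J·s, $R = 1.987204\times10^{-3}$
kcal mol⁻¹ K⁻¹). A 22-minute half-life corresponds to

```{r}
rate_to_dg(log(2) / (22 * 60))
```

kcal/mol. The two conversions are exact inverses (round-trip relative
error below $10^{-10}$ across the experimental k range), which the test
suite asserts.

### Conventions and degenerate inputs

* **Time unit.** All internal times are seconds; CSV input declares its
  unit (minutes by default, matching how reaction monitoring is usually
  reported).
* **Normalization.** The fraction remaining is the integral at time *t*
  divided by the integral of the first observation. Non-positive
  integrals cannot be log-transformed; they are dropped with a warning
  before fitting.
* **Window.** All points of the monitored window (~9 h, 46 spectra at
  10-minute spacing) are fitted by default (`max_conversion = 1`);
  a smaller `max_conversion` restricts the fit to the early, low-
  conversion phase.
* **Non-decaying series.** A fitted slope ≥ 0 yields a flagged result
  (`decaying = FALSE`) with undefined half-life and barrier rather than
  an error, so batch fits survive inert compounds.
* **Replicates.** Runs are performed in replicate on different days.
  The per-compound summary half-life is the arithmetic mean of the
  per-replicate half-lives; this matches the convention of reporting a
  "mean half-life". The alternative — $\ln 2$ over the mean rate
  constant — is available via `t_half_method = "from_mean_k"` (the two
  differ because the mean of reciprocals is not the reciprocal of the
  mean). The summary barrier is always computed from the mean rate
  constant. Both conventions are exposed because reported mean
  half-lives do not in general determine which was used.
* **log k.** `log_k_gsh` is log base 10 of k in s⁻¹, the usual
  chemistry convention for LFER plots.

## The heteroaryl substituent constant

Hammett constants are not tabulated for most heteroaryl groups.
`sigma_het()` defines one from the ionization of the corresponding
carboxylic acids:

$$\sigma_{\mathrm{Het}} = \mathrm{p}K_a(\mathrm{Ph}) -
\mathrm{p}K_a(\mathrm{Het}),$$

with benzoic acid as reference (ρ = 1 implicitly, as in the classical
definition; no additional scaling is applied). A heteroaryl acid more
acidic than benzoic acid gives σ_Het > 0 (electron-withdrawing); less
acidic gives σ_Het < 0 (electron-donating). The default reference is
the experimental aqueous benzoic-acid pKa 4.20; when σ_Het values are
produced from computed pKa values, the reference should come from the
same computational protocol so systematic errors cancel.

## Protonation-state weighting

Compounds with a basic sp² ring nitrogen exist at assay pH as a mixture
of neutral and protonated species that react at different rates. The
protonated fraction follows Henderson–Hasselbalch,
$f = 1/(1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a})$, and
`weighted_prediction()` combines the two species' predicted barriers:

* `dg_space` (default): $f\,\Delta G^{\ddagger}_{H^+} + (1-f)\,
  \Delta G^{\ddagger}_{0}$ — a weighted average of predicted free
  energies, which is how such weighted predictions are usually quoted;
* `rate_space`: the f-weighted mean of the two Eyring *rates*,
  converted back to a free energy. This is the physically motivated
  convention for parallel reacting species; by convexity of the
  exponential it never exceeds the dg-space value.

Both are available because a reported "weighted average of predicted
ΔG‡" is ambiguous between the two; the default follows the plainer
reading, and the choice is a config switch so either can be reproduced.

## The single-parameter EA model and its validation

`screen_descriptors()` fits one univariate OLS per registered
descriptor against the chosen response (experimental barrier, computed
barrier, or log k) and ranks by R² (coefficient of determination —
identical to squared Pearson r in simple regression), with alphabetical
tie-breaks for reproducibility. Outlier handling is explicit: compounds
leave a fit only through the `exclude` argument, and the packaged
training table carries an `outlier` annotation (compound 1f, run in
100% DMSO-d₆ for solubility) rather than any automatic rejection.

The predictive model is the best-fit line of the experimental barrier
against the computed electron affinity of the CRG — electron affinity
tracks the stability of the developing negative charge in the
thiolate-addition transition state, so a single descriptor suffices.
`validate()` scores a test table by the unweighted mean of absolute
prediction errors (MUE, kcal/mol) and the R² of predicted versus
observed. `fit_multivariate()` provides the generic multi-descriptor
OLS with leave-one-out Q² (reported unclamped; negative Q² means the
model predicts worse than the mean).

A related constant: thiolate-referenced computed barriers sit below
experimental ones because GSH is almost fully protonated at pH 7.4;
`gsh_deprotonation_penalty()` (3.1 kcal/mol) shifts them onto the
experimental scale.

## Papain assay analysis

Enzyme activity is read as a chromogenic-substrate progress curve
(background-corrected absorbance A400 − A790, one reading per minute
for an hour). `initial_rate()` takes the OLS slope over the first 15
minutes (configurable); `papain_activity()` averages triplicate wells
and normalizes by the untreated control to give residual activity
E/E₀; `correlate_inactivation()` regresses log₁₀(E/E₀) on either
log₁₀ k_GSH or the predicted barrier. Log base 10 is used on both axes.
Compounds with E/E₀ ≤ 0 are dropped with a warning (their log is
undefined). No mechanistic enzyme kinetics (K_M, k_inact/K_I) are
modelled — only linear initial rates.

## What the synthetic generators emulate

All generators take a mandatory seed, restore the caller's RNG state,
and return their ground truth as attributes.

* `gen_decay()` — exponential decay sampled every 600 s for 46 points
  (the NMR design) with **multiplicative log-normal** noise on the
  integrals (sd 0.02 by default). Integrals are positive with roughly
  constant relative error, which the log-normal captures; the true
  noise process of NMR integration is not published, so this is a
  modelling choice. Default rate constants span the observed half-life
  range (22–6188 min) so both fast and slow regimes are exercised.
* `gen_descriptor_table()` — EA uniform on [0, 1.1] eV (the span of
  the study's computed LUMO/EA scale), barrier = slope·EA + intercept +
  Gaussian noise with defaults slope −3.8 (kcal/mol)/eV, intercept 25
  kcal/mol, residual sd 0.3 kcal/mol — a realistic residual scale for a
  good single-descriptor LFER. Optional protonation columns drive the
  weighted-prediction path.
* `gen_progress_curves()` — linear early phase at planted rates
  (control 0.01 absorbance/min), optional saturation after 20 min,
  additive Gaussian absorbance noise (sd 0.001).

What passing tests on these data do **not** show: real NMR integrals
have baseline and phasing artefacts, temperature drift, and occasional
overlapping peaks; real descriptor–barrier relationships are only
approximately linear and their residuals are not exactly Gaussian; real
progress curves have lag phases and instrument drift. The generators
validate the *estimators*, not those experimental complications.

## Problem sizes and numerical choices

The property-style checks use 200 seeded simulations at the
experimental design (46-point decays; 8-compound descriptor tables),
which gives a binomial standard error of about 0.015 on a 95% CI
coverage estimate and tight Monte-Carlo error on the half-normal MUE
prediction $\sigma\sqrt{2/\pi}$. OLS fits use `stats::lm` throughout;
the test suite cross-checks slopes, standard errors and R² against
closed-form textbook formulas computed independently. Rank-deficient
multivariate designs are rejected by a QR rank check before fitting.

## Data availability and known limitations

The packaged training table (`crg_training_set()`) contains the eight
N-heteroaryl lactams 1a–1h with the values available in machine-
readable published text: mean GSH half-lives, and the CDCl₃ ¹³C shift
of the exocyclic methylene carbon (Cβ) and ¹H shift of the upfield
exocyclic alkene proton (Hβ1) from the compound characterization data.
These reproduce the reported NMR-shift/reactivity correlations closely
(R² ≈ 0.83 for Hβ1 over all eight compounds; ≈ 0.99 for Cβ once the
DMSO-d₆ outlier 1f is excluded). The all-eight Cβ correlation computed
from whole-minute half-lives comes out at 0.87 against a reported 0.88
— rounding of the half-lives to whole minutes is the likely cause.

Computed descriptor values — electron affinities, LUMO energies,
σ_Het values, DFT barriers, conjugate-acid pKa values — and the
test-set (2a–2g) kinetic data are published only in figures and
supplementary tables that are not available as text, so those columns
are `NA` in the fixture and the corresponding published checks (EA
model R² ≈ 0.93, σ_Het R² ≈ 0.81, test-set MUE ≈ 0.4 kcal/mol, and the
acrylamide test-set MUE ≈ 0.3 kcal/mol) cannot be recomputed from
shipped data. The machinery itself is fully exercised on synthetic
tables with known truth; a user holding the missing values can paste
them into the fixture columns and run exactly those checks through
`screen_descriptors()`, `fit_univariate()` and `validate()`.

Quantum-chemistry computation of descriptors (DFT transition states,
EA/LUMO/NICS/NPA/pKa) is out of scope by design: descriptors are
inputs here.

## End-to-end example

```{r, eval = FALSE}
spec <- sim_spec(seed = 1)
series <- gen_decay(spec)                  # synthetic NMR monitoring
summarise_kinetics(series)                 # k, t1/2, dG per compound

tab <- gen_descriptor_table(spec)          # synthetic descriptor table
model <- fit_univariate(tab, "EA_eV")      # the single-parameter model
validate(model, gen_descriptor_table(sim_spec(seed = 2)))
```

The umbrella driver `run_full_analysis()` chains kinetics → screen →
train → validate → papain from CSV inputs, writes CSV/JSON artifacts
plus a provenance record (config, input checksums), and is exposed on
the command line via the thin wrapper in `inst/cli/crg.R`.
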