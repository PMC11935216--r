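---
title: "Monitoring gut-barrier integrity by equivalent-circuit impedance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring gut-barrier integrity by equivalent-circuit impedance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its model

Three-dimensional bioelectronic culture devices grow a stratified human gut
model - a fibroblast-derived lamina-propria layer inside a conducting-polymer
scaffold, with an intestinal epithelial monolayer on its apical surface - and
use the scaffold itself as the working electrode of a two-electrode
electrochemical cell. Sweeping a small AC excitation from 100 kHz down to
100 mHz at 10 points per decade yields a complex impedance spectrum whose
shape tracks the state of the tissue in-line, without labels or endpoints.
During a host-microbe intervention (heat-inactivated postbiotic consortia or
live bacterial strains added apically), spectra are recorded at a
pre-inoculation baseline and at 30 min, 2, 4, 8, 12 and 24 h.

Raw impedance is an aggregate of every electrochemical process in the cell,
so the biological contribution has to be deconvolved. The package models the
cell as

$$Z(\omega) = \left(R_{CE} \,\|\, Z_Q\right) + R_{electrolyte} +
  \left(R_b \,\|\, Z_C\right),$$

where $Z_Q = (Q (j\omega)^{\alpha})^{-1}$ is a constant phase element
lumping the counter-electrode and working-electrode/scaffold interfacial
processes, $R_{electrolyte}$ the series solution resistance, and the barrier
element $R_b \,\|\, C_b$ (with $Z_C = (j\omega C)^{-1}$) represents the
epithelium: $R_b$ the tight-junction-regulated paracellular pathway, $C_b$
the transcellular (membrane) pathway. $R_b$ is the figure of merit for
barrier integrity - closely related to, though not identical with,
conventional TEER. A blank (host-tissue-free) device is encoded as
$R_b = C_b = 0$; parallel composition is done in admittance space so that
this encoding is exact.

Two read-outs are produced per device:

* the **normalised 500 Hz cross-section** $|Z(500\,\mathrm{Hz}, t)| /
  |Z(500\,\mathrm{Hz}, 0)|$, a fit-free qualitative metric from the
  mid-frequency band shaped by the paracellular resistance (500 Hz is not on
  the measurement grid; the value is interpolated linearly in
  $\log|Z|$-$\log f$); and
* the **fitted $R_b(t)$** with its fold-change $R_b(t)/R_b(0)$ per device
  and, at the endpoint, relative to the control-arm mean.

## Fitting: multistart complex non-linear least squares

Circuit parameters are estimated by CNLS: the stacked residual
$[w_i(\mathrm{Re}\,\hat Z_i - \mathrm{Re}\,Z_i),\,
   w_i(\mathrm{Im}\,\hat Z_i - \mathrm{Im}\,Z_i)]$
is minimised with modulus weighting $w_i = 1/|Z_i|$ by default, because
$|Z|$ spans about three decades over the sweep and unweighted residuals
would let the low-frequency points dominate. Unit weighting is available.

$R_{electrolyte}$ is not free: it is fixed to the real part of the
highest-frequency impedance measurement, where both parallel branches have
negligible real contribution. The rule is applied literally to the measured
value, noise included; a configuration flag allows co-fitting instead.

The cost surface is multimodal, so the fit is a multistart global search:
`n_starts` (default 32) initial points are drawn log-uniformly within the
bounds (the CPE exponent uniformly), each start is refined by bounded
Levenberg-Marquardt least squares with an analytic Jacobian, and the lowest
final cost wins, ties broken by lowest start index. Optimisation runs in
log10 space for the magnitude parameters - enforcing positivity and
conditioning a search across many decades - with $\alpha$ in natural space.
The start stream is seeded and nested (the first $k$ starts are the same for
any configuration sharing a seed), which makes fits reproducible and the
best cost non-increasing in `n_starts`. Internally the search is two-phase:
a 50-iteration exploration from every start followed by a full-tolerance
(relative cost change $10^{-12}$) polish of the four most promising basins;
on cohort-like spectra roughly a third of random starts land in the global
basin, so 32 starts make a missed global minimum vanishingly rare
($\sim 10^{-5}$).

Bounds are wide - resistances $[10^{-2}, 10^9]\,\Omega$, $Q$
$[10^{-12}, 10^{-1}]$, $\alpha \in [0.3, 1]$ - with one deliberate
exception: $C_b \le 10^{-4}$ F. An epithelial monolayer over tens of
mm$^2$ sits near $1\,\mu$F/cm$^2$, so $10^{-4}$ F is still orders of
magnitude above any physical barrier capacitance, but the cap removes a
genuine degeneracy: with $C_b$ free to approach $Q_{CE}$, a noisy fit can
swap the roles of the two branches and report the electrode interface as the
"barrier".

**Degenerate (blank) devices.** With no barrier present the barrier element
is unidentifiable and the optimiser parks it in one of three shapes:
$R_b$ pinned at its lower bound, a sliver of resistance (< 2% of the DC
resistance $R_{CE} + R_{el} + R_b$) absorbing the small bias the fixing rule
introduces, or a shunt whose corner frequency $1/(2\pi R_b C_b)$ falls below
the measured band. All three raise the `no_barrier` flag; fitted barriers in
tissue-bearing devices sit at tens of percent of the DC resistance with
their corner well inside the sweep, far from the flag conditions.

A property worth knowing about the fixing rule: the barrier branch retains a
real part $\approx 1/(\omega_{max}^2 R_b C_b^2)$ at 100 kHz, so the fixed
$R_{electrolyte}$ is biased high by that amount and the bias is
redistributed - mostly into the weakly identified $R_{CE}$ - when the rest
of the circuit is fitted. With the default device values this is
$\sim 0.01\,\Omega$ and parameter recovery on noiseless data is well inside
0.1%; on devices with much smaller $R_b C_b$ products the same rule costs
measurably more accuracy. Co-fitting $R_{electrolyte}$ recovers noiseless
parameters to machine precision.

## The synthetic cohort

The generator exists so the whole pipeline - file formats, fitting, metrics
and statistics - is testable end to end at exactly the study's structure:
arms of $N = 2$ biological $\times$ $n = 3$ technical devices, seven
timepoints, the default sweep. What it emulates, and what it does not,
bounds what green tests mean for real data.

Baseline device parameters are drawn around central values
($R_{CE} = 2\,\mathrm{k}\Omega$, $Q_{CE} = 2\times 10^{-3}$,
$\alpha = 0.9$, $R_{el} = 120\,\Omega$, $R_b = 900\,\Omega$,
$C_b = 0.5\,\mu$F) with multiplicative log-normal jitter of CV 0.10 per
parameter, which keeps every parameter positive; $\alpha$ is jittered the
same way and clamped into $[0.3, 1]$ since a CPE exponent cannot exceed the
ideal-capacitor limit. Two of the central values deserve comment. $C_b$
balances two constraints: small enough that $|Z(500\,\mathrm{Hz})|$
increases monotonically with $R_b$ over the whole programmed fraction range
(verified for 200 jittered devices), so the cross-section is a faithful
proxy of the paracellular resistance, and large enough that the fixing-rule
bias above stays negligible. $Q_{CE}$ reflects electrodes whose
capacitances are maximised by design: blank-device spectra are then a flat
ohmic line from mid to high frequency (coefficient of variation
$\approx 1\%$ over 10 Hz-10 kHz at the default noise), with the
counter-electrode capacitance dominating only the lowest decades.

Interventions are programmed $R_b(t)/R_b(0)$ fraction tables at the
protocol anchors, piecewise-linearly interpolated in between: a constant
control; a fast, deep postbiotic drop plateauing at 0.40
(pro-inflammatory); a slower decline to the same plateau
(anti-inflammatory); a shallow consortium response plateauing at 0.78
(SIHUMI); a commensal live strain dipping to 0.85 and recovering to 0.90
(E. coli TOP10); and a progressive live-pathogen decline to 0.45
(E. coli LF82). These tables are qualitative emulations of the dynamics
such experiments report - every test in the package compares fitted values
against the *programmed* tables, never against published experimental
percentages, which derive from deposited instrument data and are not
reproducible from summary figures. An anaerobe preset is shipped non-default
and flagged with a caveat, mirroring the practice of excluding an arm whose
co-culture viability failed. Noise is multiplicative complex Gaussian,
independent per frequency (`sigma` default 0.01): the simplest model with
constant relative error across the magnitude range. Real instrument noise
is frequency-correlated and heteroscedastic, real devices drift between
timepoints, and real arms share biological-replicate effects - none of
which the generator reproduces, so passing tests certify the analysis
chain, not instrument realism.

All randomness flows from one master seed through deterministically derived
child seeds (device jitter, per-timepoint noise), so a cohort is
reproducible byte-for-byte down to its CSV exports.

## Statistics

Endpoint comparisons follow the conventional chain for this design:
Levene's homogeneity test (classic mean-centred form; the Brown-Forsythe
median variant is an option) applied as a reported gate at $p > 0.01$ - the
pipeline does not switch tests automatically on failure, it surfaces the
gate outcome - then one-way ANOVA across arms and Tukey HSD post-hoc
contrasts with significance coded at $p < 0.05$, $0.01$, $0.001$,
$10^{-4}$. Unbalanced arms (devices drop out pairwise when a fit fails) use
the Tukey-Kramer denominator. Observations are per-device endpoint values;
biological and technical replicates are pooled, as the reported per-arm
device counts imply. The implementation wraps the standard R machinery
(`aov`, `TukeyHSD`, `car::leveneTest`); the test suite checks it against
hand-coded decompositions, a 100k-permutation oracle and a 5000-run null
calibration of the type-I error.

## Worked example

```{r example}
library(barrierEIS)

# one pro-inflammatory device, 1% noise
tc <- simulate_timecourse(intervention_presets()$pro_inflammatory,
                          noise = noise_model(0.01), seed = 42)

# fit-free metric
normalized_crosssection_series(tc)

# fitted barrier resistance and fold-change
fc <- rb_foldchange(rb_series(tc, fit_config(seed = 1)))
fc$value  # ~ programmed (1, .70, .60, .52, .45, .42, .40)
```

The analysis drivers under `analysis/` run the full study: `01_simulate.R`
(6-arm cohort to `results/dataset/`), `02_fit.R` (252 circuit fits to
`results/fits.csv`), `03_report.R` (metrics, endpoint summary and the
comparison report) and `04_figures.R` (Bode and trajectory figures).

## Numerical choices and limitations

* Sweep grids are log10-spaced from $f_{max}$ down to $f_{min}$ with both
  endpoints included (61 points for the default protocol), so the
  highest-frequency point the fixing rule needs always exists.
* Phases are reported in degrees; impedances are stored with signed
  imaginary part (negative = capacitive) in memory and on disk.
* Spectra CSVs carry full 17-digit floats and `#` metadata headers; a
  write-read round trip is exact. Dataset manifests (JSON) validate file
  existence, (device, timepoint) uniqueness and per-device baselines on
  read.
* Problem sizes in the test suite (cohort of 36-42 devices, 50-replicate
  robustness checks, 20 endpoint-only seeded replications of the group
  inference, 5000-run null calibration) were chosen as the smallest sizes
  at which the checked statistics are stable.
* Out of scope: Warburg/diffusion elements and transmission-line scaffold
  models, Kramers-Kronig validity testing, Bayesian uncertainty on
  parameters, area-normalised TEER in $\Omega\cdot$cm$^2$ (a user-supplied
  culture area can scale $R_b$, but no instrument cross-calibration is
  attempted), and any mechanistic model of bacterial growth or metabolite
  kinetics.
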