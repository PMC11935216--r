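# barrierEIS

Equivalent-circuit analysis of electrochemical impedance spectroscopy (EIS)
recordings from 3D bioelectronic culture devices that monitor the integrity
of an engineered human gut barrier in-line — for instance while the tissue
is exposed to postbiotic preparations or live bacteria over a 24-hour
host–microbe intervention. The intended users are groups running
organ-on-chip or bioelectronic barrier models who need to turn raw
impedance sweeps into a quantitative, statistically tested barrier metric.

## The model

A two-electrode cell containing the tissue-bearing conducting-polymer
scaffold is modelled as

```
Z(ω) = (R_CE // Z_Q) + R_electrolyte + (R_b // C_b)
Z_Q  = (Q (jω)^α)^-1        Z_C = (jωC)^-1        ω = 2πf
```

where the CPE branch lumps the electrode interfaces, `R_electrolyte` is the
series solution resistance, and the barrier element models the paracellular
(`R_b`, resistive) and transcellular (`C_b`, capacitive) ionic pathways of
the epithelium. `R_b` is the figure of merit for barrier integrity.

The package provides:

* the forward circuit model, Bode quantities, and the impedance-magnitude
  cross-section at 500 Hz (log–log interpolated), normalised per device to
  its pre-inoculation baseline;
* complex non-linear least-squares fitting (stacked Re/Im residuals,
  modulus weighting) with seeded multistart global optimisation, analytic
  Jacobians, and the series resistance fixed to Re(Z) at the highest
  measured frequency;
* time-course metrics: `R_b(t)`, fold-changes versus baseline and versus
  the control arm;
* the between-group inference chain — Levene's homogeneity gate, one-way
  ANOVA, Tukey HSD with significance stars;
* CSV spectrum I/O (rectangular and polar dialects) with JSON dataset
  manifests; and
* a fully seeded synthetic-data generator emulating the measurement
  protocol (100 kHz–100 mHz at 10 points/decade; baseline + 30 min, 2, 4,
  8, 12, 24 h; N biological × n technical replicated devices; programmed
  barrier-resistance trajectories per intervention arm).

## Worked example

```r
library(barrierEIS)

# one device following the pro-inflammatory postbiotic preset, 1% noise
tc <- simulate_timecourse(intervention_presets()$pro_inflammatory,
                          noise = noise_model(0.01), seed = 42)

# fit-free metric: 500 Hz cross-section normalised to baseline
normalized_crosssection_series(tc)$value
#> 1.0000 0.9265 0.8824 0.8375 0.7989 0.7671 0.7440

# circuit fits at every timepoint -> R_b fold-change vs baseline
fc <- rb_foldchange(rb_series(tc, fit_config(seed = 1)))
fc$value
#> 1.0000 0.6993 0.5979 0.5192 0.4497 0.4178 0.4012
```

The fold-changes recover this device's programmed trajectory
(1, .70, .60, .52, .45, .42, .40) to a few parts per thousand at 1% noise;
the cross-section declines monotonically with it. A single fit prints as:

```r
fit_timecourse(tc, fit_config(seed = 1))$fits[["0"]]
#> CNLS fit: cost = 1.225e-02 (32/32 starts converged)
#> Equivalent-circuit parameters (R_CE//Q_CE)-R_el-(R_b//C_b):
#>   R_CE  = 2056.41 Ohm   Q_CE = 0.00222951 S.s^a   alpha = 0.8342
#>   R_el  = 115.42 Ohm   R_b  = 1110.64 Ohm     C_b   = 5.00672e-07 F
```

The full study lives in `analysis/`: `01_simulate.R` writes a 6-arm cohort
(control, pro-/anti-inflammatory postbiotics, full SIHUMI postbiotic, live
E. coli TOP10 and LF82; 2 biological × 3 technical devices) under
`results/dataset/`; `02_fit.R` fits all 252 spectra; `03_report.R` produces
the metric tables, the 24 h endpoint summary and the ANOVA + Tukey
comparison report; `04_figures.R` draws Bode and trajectory figures. With
the shipped seeds, every intervention arm differs from control at
p < 1e-4 while the two arms programmed to the same 0.40 plateau are the
only non-significant pair.

See `vignettes/barrier-impedance-analysis.Rmd` for the model, the
multistart CNLS design, what the generator does and does not emulate, and
known limitations.

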