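# limnodigest

Quantitative analyses of wood digestion by the marine woodborer *Limnoria*
(the gribble), packaged as tested, reusable R functions plus a numbered
analysis workflow. The gribble digests lignocellulose with a sterile gut —
no microbial symbionts — which makes the quantitative evidence for *how*
wood is consumed unusually interdisciplinary. This package implements the
four analysis stages behind that evidence, for researchers who want to run
the same computations on their own feeding, proteomics, relaxometry or
thermal-shift data, or to test analysis code against synthetic data with
known ground truth:

- **Mass balance & composition** — percent of ingested mass lost during gut
  passage, `loss = 100·(I − F)/I` with `I = initial − remaining`; acetyl
  bromide-soluble lignin `%ABSL = (A/(ε·l))·(V·100/m)·d` (ε = 18.21
  L g⁻¹ cm⁻¹); three-fraction percentages; fecal composition normalized by
  `(100 − loss)/100`; HPAEC sugar quantification against linear
  calibrations; wood-vs-feces reductions with propagated errors.
- **emPAI proteomics** — in silico tryptic digestion, observable-peptide
  counting in a mass window, `emPAI = 10^(observed/observable) − 1`, molar
  percentages, the expect ≤ 0.05 and ≥ 2 peptide identification filters,
  replicate normalization, GH-family shares and the hemocyanin
  fluid-vs-tissue contrast.
- **CPMG relaxometry** — regularized non-negative inverse Laplace
  transform `min_{f≥0} ‖Kf − s‖² + λ‖f‖²` with `K_ij = exp(−t_i/T2_j)`;
  log-Gaussian pore-population deconvolution with areas `A = √(2π)·a·c` and
  propagated errors; the fast-diffusion pore map `1/T2 = ρ(S/V) = 2ρ/r`;
  ssNMR region normalization and difference spectra.
- **Thermal shift** — five-parameter sigmoid melt-curve fits
  `y = L + (U−L)/(1+e^{−k(T−m)})^d` with the melting temperature reported
  as the half-transition midpoint, and condition-to-condition Tm shifts.

A synthetic-data generator (`willow_scenario()`, `pine_scenario()`,
`t2_truth_preset()`, `digestome_preset()`, `hemocyanin_melt_preset()`)
emulates the study design so every stage is verifiable by parameter
recovery; see the methods vignette
(`vignettes/wood-digestion-analytics.Rmd`) for the models, noise
assumptions and design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on synthetic
data with known truths (`01` generates, `02`–`05` analyze; outputs land
under `results/`):

```sh
Rscript analysis/01_simulate_datasets.R
Rscript analysis/02_mass_balance.R
```

```
willow: 22.0% +/- 3.8% of ingested mass lost (n = 10)
  fraction reductions: lignin -2.5%, hemicellulose -0.6%, cellulose 51.5%
pine: 23.4% +/- 3.7% of ingested mass lost (n = 10)
  fraction reductions: lignin -2.7%, hemicellulose 19.4%, cellulose 41.7%
```

Willow loses ~22% of ingested mass, carried by the cellulosic fraction
(half of it consumed); pine additionally loses ~20% of its hemicellulose.
The relaxometry stage inverts the CPMG decays and compares pore
populations:

```sh
Rscript analysis/03_relaxometry.R
```

```
control: SNR 199, lambda 0.216; populations at T2 = 0.00091/0.01/0.11 s, areas 0.24/0.38/0.38
treated: SNR 375, lambda 0.0906; populations at T2 = 0.00093/0.01/0.11 s, areas 0.35/0.41/0.24
```

— after hemocyanin pretreatment the two lower-T2 (smaller-pore)
populations gain relative area, the signature of opened-up cell-wall
structure. The proteome stage reports

```
GH7+GH9 share of GH molar abundance in gut fluid, per replicate: 76, 75.5, 77.2%
hemocyanin mol%: gut fluid 29.6 +/- 1.4 vs gut tissue 7.2 +/- 1.0
```

and the thermal stage fits melting temperatures per condition (native
70.0 °C; seawater 5.0 °C below buffer; chelator 51.9 °C, below 55 °C).

Or in R, one command generates, analyzes and checks everything:

```r
library(limnodigest)
res <- run_demo(run_config(out_dir = tempfile(), seed = 1))
res$ok          # TRUE: every recovered quantity within its tolerance
res$report      # stage, quantity, recovered, truth, tolerance
```

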