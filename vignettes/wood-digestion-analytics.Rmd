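---
title: "Quantitative analytics of wood digestion in Limnoria: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analytics of wood digestion in Limnoria: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnodigest)
```

# The problem

The gribble *Limnoria quadripunctata* is a marine crustacean that eats wood
with a sterile digestive system: no resident gut microbes help it break down
lignocellulose. Understanding how it nevertheless extracts energy from wood
involves four very different quantitative measurements, and this package
implements the analysis for each of them, end to end:

1. **Mass balance and composition** — how much of the ingested wood is
   consumed during gut passage, and which biomass fraction (lignin,
   hemicellulose, cellulose) carries the loss.
2. **Digestive-proteome quantification** — which proteins dominate the gut
   fluids, quantified label-free by emPAI molar percentages.
3. **CPMG relaxometry** — how the pore structure of the wood cell wall
   changes after treatment, via inverse-Laplace T2 distributions
   deconvolved into log-Gaussian pore populations.
4. **Thermal shift assays** — how the stability of hemocyanin (the
   candidate lignin-disrupting protein) changes with solvent conditions,
   via five-parameter sigmoid melt-curve fits.

Real instrument data for these assays are not redistributable at package
scale, so the package ships a first-class synthetic-data generator whose
presets encode the study design. Every analysis stage is then validated by
*parameter recovery*: generate data whose truth is known, run the stage,
and check that the truth comes back within the tolerance the noise allows.

# Mass balance and compositional fractionation

Each feeding batch gives three masses: the initial dried stick, the
remaining stick, and the fecal pellets collected over the feeding period.
With ingested mass $I = m_\text{initial} - m_\text{remaining}$ and fecal
mass $F$, the percent of ingested material consumed is

$$\text{loss} = 100\,\frac{I - F}{I}.$$

`mass_loss_percent()` implements exactly this; negative values (possible
under measurement noise) are flagged, never clipped. The summary across
batches is the mean of per-batch ratios, matching how replicate feeding
sticks are treated as independent units.

Composition rests on three operational fractions measured from separate
aliquots: acetyl bromide-soluble lignin (ABSL), TFA-hydrolysable
hemicellulose, and H2SO4-hydrolysable cellulose. The ABSL assay is a pure
formula (`absl_percent()`),

$$\%\,\text{ABSL} = \frac{A_{280}}{\varepsilon\, l}\cdot
  \frac{V\cdot 100}{m}\cdot d,$$

with the poplar extinction coefficient $\varepsilon = 18.21$
L g$^{-1}$ cm$^{-1}$ as default, volume in mL and biomass in mg. Fraction
masses become percentages of their summed total
(`fraction_percentages()`); fecal percentages are then rescaled by
$(100 - \text{loss})/100$ (`normalize_feces_to_mass_loss()`), so that with
a 22% mass loss the fecal fractions total 78 and wood and feces can be
compared on the same ingested-mass basis. Monosaccharides are quantified
against linear HPAEC calibrations with free intercepts
(`hpaec_calibration()`, `quantify_sugars()`); the regression form is a
package choice, since comparison-to-standards admits several. Per-quantity
reductions between wood and normalized feces are ratios of group means with
first-order (delta-method) error propagation (`digestion_delta()`).

**Design choices.** The loss denominator is ingested mass (not initial
stick mass): only what the animal ate can be digested. Fecal normalization
uses one pooled loss constant rather than per-batch losses; both views are
available by passing a different `mass_loss`. All nine calibration sugars,
including glucuronic acid, are carried through the pipeline.

# emPAI proteome quantification

The exponentially modified protein abundance index converts peptide
coverage into a molar scale:

$$\text{emPAI} = 10^{\,N_\text{observed}/N_\text{observable}} - 1,
\qquad \text{mol\%}_i = 100\,\frac{\text{emPAI}_i}{\sum_j \text{emPAI}_j}.$$

$N_\text{observable}$ counts fully tryptic peptides (cleavage after K/R
except before proline, zero missed cleavages — the canonical emPAI
convention, even though the search that produces the evidence allows two)
whose monoisotopic mass falls in the instrument window. The default window,
[748.0, 7495.0] Da, is derived from a scan range of m/z 375–1500 at
charges 2–5 ($m = z\cdot m/z - z\,m_{H^+}$); it is a documented, adjustable
parameter, not a claim about any particular search engine's internal
definition. Cysteine is counted carbamidomethylated (+57.02146 Da) to match
the fixed modification of the search settings.

Identification filtering reproduces the two-stage rule: peptide matches
with expect score above 0.05 are removed first, then proteins lacking two
distinct peptides — in at least one sample under the default
`scope = "any sample"` (the rule used for organ comparisons), or per sample
on request. Filtering is idempotent. Replicates are normalized on the
expectation of equal total protein across organs: each replicate's
cross-organ total is scaled to the mean of the totals
(`normalize_replicates()`); any global rescaling of a replicate therefore
cancels in the molar percentages. Family summaries renormalize within the
glycosyl-hydrolase subset and report the hemocyanin fluid-vs-tissue
contrast as replicate mean ± SD.

**Generator model.** `gen_proteome_evidence()` works at the level the
quantification consumes (peptide matches with expect scores), not raw
spectra. Detection is *emPAI-consistent by construction*: a protein with
relative molar abundance $a_i$ has expected peptide coverage
$r_i = \log_{10}(1 + C a_i)$, the inverse of the emPAI transform, with the
dynamic-range constant $C = 20$ chosen so coverage stays below one for all
preset abundances. Counting noise on $r_i$ shrinks as
$1/\sqrt{\text{depth}}$, so molar percentages converge to the preset truth
as sampling depth grows — the property the recovery tests rely on. A naive
alternative (sampling peptide-spectrum matches and marking peptides seen)
saturates at high depth: every observable peptide is eventually seen, all
emPAI values collapse toward $10^1-1$, and no estimator could recover
abundances; that model would make depth-convergence impossible, which is
why it was rejected. About 10% of emitted matches carry expect scores
above 0.05, and a keratin-like contaminant contributes exactly one peptide
per sample, so both filters are genuinely exercised on every run.

# CPMG relaxometry and pore populations

A CPMG experiment on solvent-saturated wood measures a multiexponential
echo decay

$$s(t_n) = \int f(T_2)\, e^{-t_n/T_2}\, dT_2, \qquad t_n = n\,\Delta t_E,$$

whose inversion to the T2 distribution $f$ is the classic ill-posed inverse
Laplace transform. `ilt_nnls()` discretizes the kernel
$K_{ij} = e^{-t_i/T_{2,j}}$ on a log-spaced grid and solves

$$\min_{f \ge 0}\; \lVert Kf - s\rVert^2 + \lambda \lVert f \rVert^2$$

as plain non-negative least squares on the augmented system
$[K;\ \sqrt{\lambda} I]$ (Lawson–Hanson). The distribution is returned
normalized to unit trapezoidal area over $\log_{10} T_2$.

Deconvolution fits a sum of Gaussians on the $x = \log_{10} T_2$ axis,

$$f(x) = \sum_k a_k e^{-(x-b_k)^2/2c_k^2},$$

each component being one pore population with area
$A_k = \sqrt{2\pi}\,a_k c_k$ and propagated error
$\sigma_{A_k} = \sqrt{2\pi}\sqrt{(c_k\sigma_{a_k})^2 + (a_k\sigma_{c_k})^2}$.
Base-10 logarithms are used because the relevant pore scales are
decade-based (nm to µm). The component count can be fixed (three, for the
wood cell-wall system) or selected by BIC over 1..k_max; both modes exist
because a published three-component description may have been either fixed
a priori or selected. In the fast-diffusion regime pore size follows
$1/T_2 = \rho\,(S/V) = 2\rho/r$, so $r = 2\rho T_2$; the surface relaxivity
$\rho$ is material-specific and deliberately has **no default** — it only
sets the absolute scale of the pore axis. Samples are compared population
by population after matching components by ascending center, with area
errors combined in quadrature.

**Numerical choices.** (i) Long echo trains are subsampled log-uniformly to
at most 2,048 points before inversion; the decay's information is
logarithmic in time, so this preserves content while keeping the NNLS
desk-scale. (ii) The default inversion grid has 64 points over
$[10^{-5}, 10]$ s (~11 per decade), commensurate with the achievable
resolution of the inversion; finer grids add only correlated ringing, which
measurably destabilizes BIC component selection. (iii) With
`lambda = "auto"` the damping is chosen by a relative discrepancy rule: the
largest $\lambda$ whose data residual exceeds the $\lambda \to 0$ residual
by at most 0.5%. The textbook absolute target ($\sigma\sqrt{m}$) is
brittle here because the residual is nearly flat in $\lambda$ over many
decades, so small errors in the tail-estimated noise SD swing the selected
$\lambda$ wildly; anchoring to the measured noise floor is robust.
(iv) Gaussian fits are seeded from prominence-ranked local maxima (ties
broken toward lower T2), padded with quantile positions when fewer peaks
than components exist, and optimized by bounded Levenberg–Marquardt;
parameter SDs come from $\hat\sigma^2 (J^\top J)^{-1}$ at the solution,
with singular directions (collapsed components) reported as zero SD.
(v) An all-zero decay returns a flagged zero distribution rather than an
error, and SNR estimates above $10^5$ are reported as the noiseless
sentinel because they are indistinguishable from detrending residue.

The SNR of a decay is defined as maximum signal amplitude over noise SD —
the definition is stated explicitly because SNR values (199 control, 367
treated) are otherwise not reproducible — and estimated from the last 5%
of echoes after quadratic detrending.

The solid-state NMR utilities (`normalize_spectrum_to_region()`,
`difference_spectrum()`) implement the normalize-then-subtract construction
used to compare treated and control lignin spectra on a common scale:
intensities are scaled to unit integral over a reference region (the
aliphatic 10–60 ppm or O-aliphatic 60–110 ppm carbons), making the
difference spectrum scale-invariant.

# Thermal shift

Melt curves are fitted with the five-parameter logistic

$$y(T) = L + \frac{U - L}{\left(1 + e^{-k(T - m)}\right)^d},$$

and the melting temperature is reported as the **half-transition midpoint**,
the temperature where the fitted curve crosses $(L+U)/2$:

$$T_m = m - \frac{\ln\!\left(2^{1/d} - 1\right)}{k}.$$

This midpoint definition makes $T_m$ robust to the exact parameterization
of the sigmoid (for $d = 1$, $T_m = m$ exactly) — important because
"five-parameter sigmoid" tools differ in their formulas. The fit starts
from three deterministic initializations (d = 1, 0.5, 2; asymptotes from
the data extrema; midpoint at the steepest smoothed slope) and keeps the
best residual; descending curves are handled by sign detection ($k < 0$).
$T_m$ standard deviations come from the fit covariance via the delta
method, and condition-to-condition shifts combine them in quadrature.
Constant curves are an error; a fitted $T_m$ outside the measured range is
flagged as extrapolated.

# What the synthetic generator does and does not emulate

The presets encode the study conditions: a willow scenario whose 22%
ingested-mass loss is carried entirely by consuming half of the cellulosic
fraction (composition 26/30/44% lignin/hemicellulose/cellulose); a Scots
pine scenario with 40% cellulose and 20% hemicellulose reduction, the
hemicellulose loss carried by mannose and glucose with little xylose loss
(composition 28/27/45%); CPMG truths of three log-Gaussian pore populations
a decade apart (1, 10, 100 ms; relative areas 0.25/0.35/0.40) at SNR 199,
with the treated sample at SNR 367 and weight shifted into the two
lower-T2 populations; a digestome in which GH7+GH9 hold well over half of
GH molar abundance in fluids, hemocyanin is fluid-enriched, and ferritin is
a 0.5 mol% trace; and melt presets at midpoints 70 °C (native/buffer),
65 °C (seawater) and 52 °C (chelator) with noise SD 2% of the fluorescence
range on a 25–95 °C grid. Mass measurements carry multiplicative
log-normal noise (masses are positive) with CV 0.05 by default; the
ingested fraction varies biologically with CV 0.2 around 30% of a 120 mg
stick, values chosen once as realistic for month-long feeding of
10-animal batches.

What passing recovery tests **do** show: the estimators are unbiased and
correctly propagate uncertainty under the stated noise models, the filters
behave per their definitions, and the pipelines are internally consistent
(conservation, normalization, idempotence). What they **cannot** show: the
generators do not emulate baseline drift or temperature instability in
CPMG acquisitions, chromatographic co-elution or integration error in
HPAEC, peptide-level detectability biases beyond the emPAI model itself
(ionization efficiency, modifications), or post-transition quench
artifacts in thermofluor curves (a truncation flag exists for the latter).
Conclusions about real instruments still require real calibration.

# Problem sizes and runtime

The test suite and the demonstration (`run_demo()`, or the numbered
scripts under `analysis/`) use reduced-but-faithful sizes chosen to keep a
full run on one core comfortable: 4,096-echo CPMG decays for unit tests
with the full 50,000-echo instrument preset exercised where acquisition
settings themselves matter (the model-selection study runs 20 full-preset
seeds), sampling depth 10^4 for the proteome evidence, 141-point melt
curves, and 10-batch feeding experiments with 10 wood / 8 fecal samples —
the design sizes of the emulated experiments.

# Known limitations

- The regularization functional of the original instrument-vendor ILT code
  is not public; the Tikhonov-on-amplitudes form here is a standard choice,
  and fixed-$\lambda$ inversion is available for sensitivity analysis.
- emPAI is a coarse quantification; the generator and estimator share its
  model, so recovery tests validate the pipeline, not emPAI's biological
  accuracy.
- Pore sizes are relative unless $\rho$ is calibrated for the material.
- The five-parameter logistic is one of several "five-parameter sigmoid"
  conventions; only the midpoint $T_m$ is comparable across conventions,
  which is exactly why it is the reported quantity.
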