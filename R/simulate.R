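# Synthetic-data generators. Each generator is a pure function of
# (inputs, seed): the RNG is seeded locally and restored, so identical calls
# give identical outputs and nothing leaks into the caller's RNG stream.

#' Simulate a CPMG echo-train decay from log-Gaussian T2 populations
#'
#' Forward model of transverse relaxation: the T2 distribution implied by the
#' log-Gaussian components is discretized on a fine log-spaced grid,
#' normalized to unit area, and the multiexponential signal
#' \eqn{s(t_n) = \sum_j w_j e^{-t_n / T_{2,j}}} is evaluated at the echo times
#' \eqn{t_n = n \cdot \Delta t_E}, n = 1..N (the first echo is at one echo
#' spacing, not at zero; the noiseless extrapolate \eqn{s(0) = \sum_j w_j = 1}
#' is returned as `s0`). Zero-mean Gaussian noise with SD = max(s)/SNR is
#' added unless the acquisition is noiseless.
#'
#' @param components list of [log_gaussian_component()] truths.
#' @param acq an [acquisition_params()] object.
#' @param grid_points number of internal discretization points.
#' @param grid_range T2 range (seconds) of the internal grid.
#' @return An object of class `cpmg_decay`: list with `time` (s), `signal`,
#'   `noise_sd`, `s0`, `echo_time`, `snr` and the generating `components`.
#' @export
#' @examples
#' dec <- gen_cpmg_decay(t2_truth_preset(),
#'                       acquisition_params(n_echoes = 1024, snr = 199, seed = 1))
gen_cpmg_decay <- function(components, acq = acquisition_params(),
                           grid_points = 512,
                           grid_range = c(1e-5, 10)) {
  if (!inherits(acq, "acquisition_params"))
    stop_param("'acq' must be an acquisition_params object")
  if (inherits(components, "log_gaussian_component")) components <- list(components)
  for (cm in components)
    if (!inherits(cm, "log_gaussian_component") || cm$c <= 0)
      stop_param("all components must be log_gaussian_component with width > 0")
  x <- seq(log10(grid_range[1]), log10(grid_range[2]), length.out = grid_points)
  dens <- rowSums(vapply(components,
                         function(cm) cm$a * exp(-(x - cm$b)^2 / (2 * cm$c^2)),
                         numeric(length(x))))
  w <- trapezoid_weights(x) * dens
  w <- w / sum(w)                          # unit-area discretized distribution
  t <- seq_len(acq$n_echoes) * acq$echo_time
  signal <- as.vector(exp(-outer(t, 10^x, "/")) %*% w)
  noise_sd <- if (acq$noiseless) 0 else max(signal) / acq$snr
  if (noise_sd > 0)
    signal <- signal + with_seed(acq$seed, stats::rnorm(length(signal), 0, noise_sd))
  structure(list(time = t, signal = signal, noise_sd = noise_sd, s0 = sum(w),
                 echo_time = acq$echo_time, snr = acq$snr,
                 components = components),
            class = "cpmg_decay")
}

#' Estimate the signal-to-noise ratio of a CPMG decay
#'
#' SNR is defined as maximum signal amplitude divided by the noise standard
#' deviation. The noise SD is estimated from the tail of the decay (by
#' default the last 5% of echoes, where the signal has fully relaxed for any
#' T2 well below the acquisition length), after removing a linear trend.
#'
#' @param decay a `cpmg_decay` or any list with `time` and `signal`.
#' @param tail_frac fraction of trailing echoes used for the noise estimate.
#' @return An object of class `snr_estimate`: list with `snr` (Inf when
#'   noiseless), `noise_sd`, and logical flags `noiseless` and `degenerate`.
#' @export
estimate_snr <- function(decay, tail_frac = 0.05) {
  s <- decay$signal
  if (length(s) < 100) stop_param("decay must have at least 100 points")
  if (all(s == 0))
    return(structure(list(snr = NA_real_, noise_sd = NA_real_,
                          noiseless = FALSE, degenerate = TRUE),
                     class = "snr_estimate"))
  n <- length(s)
  idx <- seq.int(from = n - max(20L, ceiling(tail_frac * n)) + 1L, to = n)
  tail_t <- decay$time[idx]; tail_s <- s[idx]
  # quadratic detrend: removes residual relaxation curvature in short
  # acquisitions whose tail has not fully decayed
  res <- stats::residuals(stats::lm(tail_s ~ tail_t + I(tail_t^2)))
  sd_hat <- stats::sd(res)
  peak <- max(s)
  # estimates above SNR 1e5 are indistinguishable from detrending residue
  if (sd_hat <= 1e-5 * peak)
    return(structure(list(snr = Inf, noise_sd = 0, noiseless = TRUE,
                          degenerate = FALSE), class = "snr_estimate"))
  structure(list(snr = peak / sd_hat, noise_sd = sd_hat, noiseless = FALSE,
                 degenerate = FALSE), class = "snr_estimate")
}

#' Simulate a wood feeding experiment with paired biomass composition
#'
#' Generates (i) a per-batch mass-balance table: initial stick mass, remaining
#' stick mass and collected fecal-pellet mass, with the expected fecal mass
#' equal to ingested mass times (1 - mass-loss fraction); and (ii) paired
#' compositional measurements (fraction masses per analytical aliquot, plus
#' per-sugar amounts) for wood and fecal-pellet samples. Measured masses
#' carry multiplicative log-normal noise with the scenario's CV.
#'
#' @param scenario a [digestion_scenario()].
#' @param n_batches number of feeding batches (>= 1).
#' @param seed integer seed.
#' @param n_wood,n_feces numbers of compositional samples.
#' @param initial_mg mean initial stick mass (mg).
#' @param ingested_frac mean fraction of the stick ingested over the feeding
#'   period (biological variability CV 0.2 regardless of measurement CV).
#' @param aliquot_mg analytical aliquot mass (mg) for composition assays.
#' @return List with data.frames `feeding` (batch, initial_mg, remaining_mg,
#'   feces_mg), `wood_fractions` / `feces_fractions` (sample, lignin_mg,
#'   hemicellulose_mg, cellulose_mg, aliquot_mg), tidy `wood_sugars` /
#'   `feces_sugars` (sample, fraction, sugar, amount_mg), and the `scenario`.
#' @export
gen_feeding_experiment <- function(scenario, n_batches = 10, seed = NULL,
                                   n_wood = 10, n_feces = 8,
                                   initial_mg = 120, ingested_frac = 0.3,
                                   aliquot_mg = 3.5) {
  if (!inherits(scenario, "digestion_scenario"))
    stop_param("'scenario' must be a digestion_scenario")
  if (n_batches < 1) stop_param("'n_batches' must be >= 1")
  cv <- scenario$cv
  with_seed(seed, {
    initial <- initial_mg * lognormal_noise(n_batches, cv)
    ingested <- initial * ingested_frac * lognormal_noise(n_batches, 0.2)
    remaining <- initial - ingested
    feces <- ingested * (1 - scenario$mass_loss) * lognormal_noise(n_batches, cv)
    feeding <- data.frame(batch = seq_len(n_batches), initial_mg = initial,
                          remaining_mg = remaining, feces_mg = feces)

    make_samples <- function(n, comp, shares, prefix) {
      fr <- data.frame(sample = paste0(prefix, seq_len(n)))
      fr$lignin_mg <- aliquot_mg * comp[["lignin"]] * lognormal_noise(n, cv)
      fr$hemicellulose_mg <- aliquot_mg * comp[["hemicellulose"]] * lognormal_noise(n, cv)
      fr$cellulose_mg <- aliquot_mg * comp[["cellulose"]] * lognormal_noise(n, cv)
      fr$aliquot_mg <- aliquot_mg
      sug <- do.call(rbind, lapply(seq_len(n), function(i) {
        do.call(rbind, lapply(c("hemicellulose", "cellulose"), function(frn) {
          sh <- shares[[frn]]
          data.frame(sample = fr$sample[i], fraction = frn,
                     sugar = names(sh),
                     amount_mg = fr[[paste0(frn, "_mg")]][i] * as.numeric(sh) *
                       lognormal_noise(length(sh), cv))
        }))
      }))
      rownames(sug) <- NULL
      list(fractions = fr, sugars = sug)
    }

    # fecal sugar shares: survival-weighted wood shares, renormalized
    feces_shares <- lapply(c(hemicellulose = "hemicellulose",
                             cellulose = "cellulose"), function(frn) {
      surv <- scenario$sugar_shares[[frn]] *
        (1 - scenario$sugar_consumption[[frn]][names(scenario$sugar_shares[[frn]])])
      surv / sum(surv)
    })
    wood <- make_samples(n_wood, scenario$composition, scenario$sugar_shares, "W")
    fec <- make_samples(n_feces, scenario$feces_composition, feces_shares, "F")

    list(feeding = feeding,
         wood_fractions = wood$fractions, wood_sugars = wood$sugars,
         feces_fractions = fec$fractions, feces_sugars = fec$sugars,
         scenario = scenario)
  })
}

#' Simulate peptide-level identification evidence for a proteome preset
#'
#' Emulates the processed evidence a database search produces, at the level
#' the quantification consumes: one row per peptide match with an expect
#' score, for each compartment and replicate. Detection follows an
#' emPAI-consistent coverage model: the expected fraction of a protein's
#' observable tryptic peptides that is detected is
#' \eqn{r_i = \log_{10}(1 + C a_i)} where \eqn{a_i} is the preset relative
#' molar abundance and `empai_scale` (C) sets the dynamic range; counting
#' noise on the coverage ratio shrinks as `1/sqrt(depth)`. A configurable
#' fraction of emitted matches carries expect scores above 0.05 (and must be
#' removed by the identification filter), and a keratin-like contaminant
#' contributes exactly one peptide per sample so that the minimum-two-peptides
#' rule is exercised.
#'
#' @param preset a [proteome_preset()].
#' @param depth sampling depth (overrides the preset default).
#' @param n_replicates replicate count (overrides the preset default).
#' @param seed integer seed (default: the preset seed).
#' @param expect_fail_frac fraction of emitted matches with expect > 0.05.
#' @param empai_scale dynamic-range constant C (default 20); must satisfy
#'   C * max(abundance) < 9 so coverage stays below 1.
#' @param mass_window observable-peptide mass window (Da), passed to
#'   [observable_peptides()].
#' @return List with `evidence` (data.frame: protein_id, peptide, expect,
#'   sample, compartment, replicate), `fasta` (named character vector of
#'   protein sequences incl. the contaminant), and the `preset`.
#' @export
gen_proteome_evidence <- function(preset, depth = preset$depth,
                                  n_replicates = preset$n_replicates,
                                  seed = preset$seed,
                                  expect_fail_frac = 0.10,
                                  empai_scale = 20,
                                  mass_window = default_mass_window()) {
  if (!inherits(preset, "proteome_preset"))
    stop_param("'preset' must be a proteome_preset")
  if (nrow(preset$proteins) == 0) stop_param("empty protein list")
  if (expect_fail_frac < 0 || expect_fail_frac >= 1)
    stop_param("'expect_fail_frac' must lie in [0, 1)")
  ids <- as.character(preset$proteins$protein_id)
  contaminant <- with_seed(child_seed(seed, 303L),
                           stats::setNames(random_protein_sequence(400), "CONT_KRT1"))
  fasta <- c(preset$sequences, contaminant)
  obs_peps <- lapply(fasta, function(sq)
    observable_peptide_set(sq, mass_window = mass_window))
  max_a <- max(vapply(preset$compartments,
                      function(cp) max(preset$proteins[[cp]]), 0))
  if (empai_scale * max_a >= 9)
    stop_param("'empai_scale' too large: coverage ratio would saturate")

  rows <- list()
  with_seed(seed, {
    for (cp in preset$compartments) {
      for (rep_i in seq_len(n_replicates)) {
        sample_id <- sprintf("%s_rep%d", cp, rep_i)
        for (k in seq_along(ids)) {
          id <- ids[k]
          a <- preset$proteins[[cp]][k]
          peps <- obs_peps[[id]]
          n_obs <- length(peps)
          if (n_obs == 0 || a <= 0) next
          r <- log10(1 + empai_scale * a) + stats::rnorm(1) / sqrt(depth)
          r <- min(max(r, 0), 1)
          target <- r * n_obs
          n_hit <- floor(target) + stats::rbinom(1, 1, target - floor(target))
          if (n_hit == 0) next
          hit <- sample(peps, n_hit)
          good <- data.frame(protein_id = id, peptide = hit,
                             expect = stats::runif(n_hit, 1e-4, 0.049),
                             sample = sample_id, compartment = cp,
                             replicate = rep_i)
          n_fail <- round(n_hit * expect_fail_frac / (1 - expect_fail_frac))
          bad <- NULL
          pool <- setdiff(peps, hit)
          if (n_fail > 0 && length(pool) > 0) {
            n_fail <- min(n_fail, length(pool))
            bad <- data.frame(protein_id = id,
                              peptide = sample(pool, n_fail),
                              expect = stats::runif(n_fail, 0.051, 0.5),
                              sample = sample_id, compartment = cp,
                              replicate = rep_i)
          }
          rows[[length(rows) + 1L]] <- rbind(good, bad)
        }
        # single-peptide contaminant: must be removed by the 2-peptide rule
        cpep <- obs_peps[["CONT_KRT1"]]
        if (length(cpep) > 0)
          rows[[length(rows) + 1L]] <-
            data.frame(protein_id = "CONT_KRT1", peptide = sample(cpep, 1),
                       expect = stats::runif(1, 1e-4, 0.049),
                       sample = sample_id, compartment = cp,
                       replicate = rep_i)
      }
    }
  })
  evidence <- do.call(rbind, rows)
  rownames(evidence) <- NULL
  list(evidence = evidence, fasta = fasta, preset = preset)
}

#' Simulate a thermal-shift melt curve
#'
#' Evaluates the five-parameter logistic (see [fit_5pl()]) on the preset's
#' temperature grid and adds Gaussian noise.
#'
#' @param preset a [melt_preset()].
#' @return An object of class `melt_curve`: list with `temperature` (deg C),
#'   `fluorescence` (a.u.), the generating `preset`, and
#'   `midpoint_outside_grid` flag.
#' @export
gen_melt_curve <- function(preset) {
  if (!inherits(preset, "melt_preset")) stop_param("'preset' must be a melt_preset")
  if (preset$midpoint_outside_grid)
    warning("melt midpoint lies outside the temperature grid; ",
            "fit may be unidentifiable")
  y <- fivepl(preset$temperatures, lower = preset$lower, upper = preset$upper,
              midpoint = preset$midpoint, slope = preset$slope,
              asymmetry = preset$asymmetry)
  if (preset$noise_sd > 0)
    y <- y + with_seed(preset$seed,
                       stats::rnorm(length(y), 0, preset$noise_sd))
  structure(list(temperature = preset$temperatures, fluorescence = y,
                 preset = preset,
                 midpoint_outside_grid = preset$midpoint_outside_grid),
            class = "melt_curve")
}
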