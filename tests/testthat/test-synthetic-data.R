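# Generators: forward models, noise contracts, determinism.

test_that("CPMG generator honours the instrument acquisition preset", {
  acq <- acquisition_params()
  expect_equal(acq$n_echoes, 50000L)
  expect_equal(acq$echo_time, 70e-6)
  dec <- gen_cpmg_decay(t2_truth_preset(), acquisition_params(snr = Inf),
                        grid_points = 128)
  expect_length(dec$signal, 50000L)
  expect_equal(diff(dec$time)[1], 70e-6)
  expect_equal(dec$time[1], 70e-6)           # first echo at one echo spacing
})

test_that("noiseless decays start below the zero-time extrapolate and decay", {
  comp <- log_gaussian_component(a = 1, b = -2, c = 0.2)
  dec <- gen_cpmg_decay(comp, test_acq(snr = Inf))
  expect_equal(dec$s0, 1)
  expect_lte(dec$signal[1], 1)
  expect_true(all(diff(dec$signal) <= 0))
  expect_true(all(dec$signal >= 0))
})

test_that("generators are pure functions of their seed", {
  d1 <- gen_cpmg_decay(t2_truth_preset(), test_acq(seed = 42))
  d2 <- gen_cpmg_decay(t2_truth_preset(), test_acq(seed = 42))
  expect_identical(d1$signal, d2$signal)
  d3 <- gen_cpmg_decay(t2_truth_preset(), test_acq(seed = 43))
  expect_false(identical(d1$signal, d3$signal))

  e1 <- gen_proteome_evidence(digestome_preset(seed = 5))
  e2 <- gen_proteome_evidence(digestome_preset(seed = 5))
  expect_identical(e1$evidence, e2$evidence)
  expect_identical(e1$fasta, e2$fasta)

  m1 <- gen_melt_curve(hemocyanin_melt_preset("native", seed = 9))
  m2 <- gen_melt_curve(hemocyanin_melt_preset("native", seed = 9))
  expect_identical(m1$fluorescence, m2$fluorescence)

  rng_before <- .Random.seed
  invisible(gen_cpmg_decay(t2_truth_preset(), test_acq(seed = 1)))
  expect_identical(rng_before, .Random.seed)  # no RNG state leaks
})

test_that("invalid acquisition or component parameters are rejected", {
  expect_error(acquisition_params(n_echoes = 1), "n_echoes")
  expect_error(acquisition_params(echo_time = 0), "echo_time")
  expect_error(acquisition_params(snr = -1), "snr")
  expect_error(log_gaussian_component(a = 1, b = 0, c = 0), "width")
})

test_that("SNR estimation recovers the generating preset within 15%", {
  snrs <- vapply(1:20, function(s) {
    d <- gen_cpmg_decay(t2_truth_preset(), test_acq(snr = 199, seed = s))
    estimate_snr(d)$snr
  }, 0)
  expect_true(all(abs(snrs / 199 - 1) < 0.15))
})

test_that("doubling the noise halves the SNR estimate", {
  r <- vapply(1:10, function(s) {
    a <- estimate_snr(gen_cpmg_decay(t2_truth_preset(),
                                     test_acq(snr = 199, seed = s)))$snr
    b <- estimate_snr(gen_cpmg_decay(t2_truth_preset(),
                                     test_acq(snr = 99.5, seed = s)))$snr
    b / a
  }, 0)
  expect_true(all(abs(r - 0.5) < 0.5 * 0.15))
})

test_that("noiseless and all-zero decays are flagged, not numbers", {
  d <- gen_cpmg_decay(t2_truth_preset(), test_acq(snr = Inf))
  est <- estimate_snr(d)
  expect_true(est$noiseless)
  est0 <- estimate_snr(list(time = seq_len(200) * 1e-4, signal = rep(0, 200)))
  expect_true(est0$degenerate)
  expect_error(estimate_snr(list(time = 1:10, signal = rnorm(10))), "100")
})

test_that("digestion scenarios enforce a consistent mass budget", {
  w <- willow_scenario()
  expect_equal(sum(w$composition), 1)
  expect_equal(w$mass_loss, 0.22)             # 0.44 cellulose * 0.50 consumed
  expect_equal(unname(w$fraction_consumption["cellulose"]), 0.5)
  p <- pine_scenario()
  expect_equal(unname(p$fraction_consumption["cellulose"]), 0.40)
  expect_equal(unname(p$fraction_consumption["hemicellulose"]), 0.20)
  expect_equal(p$mass_loss,
               sum(p$composition * p$fraction_consumption))
  expect_error(digestion_scenario("bad",
    composition = c(lignin = 0.5, hemicellulose = 0.4, cellulose = 0.4),
    sugar_shares = w$sugar_shares, sugar_consumption = w$sugar_consumption),
    "sum to 1")
})

test_that("noiseless feeding experiments round-trip the scenario exactly", {
  ex <- gen_feeding_experiment(willow_scenario(cv = 0), n_batches = 5, seed = 1)
  loss <- mass_loss_percent(ex$feeding$initial_mg, ex$feeding$remaining_mg,
                            ex$feeding$feces_mg)
  expect_equal(unname(loss), rep(22, 5))
  # conservation: initial = remaining + ingested; feces <= ingested
  ing <- ex$feeding$initial_mg - ex$feeding$remaining_mg
  expect_true(all(ing > 0))
  expect_true(all(ex$feeding$feces_mg <= ing))
})

test_that("a zero-consumption scenario conserves mass end to end", {
  sc <- digestion_scenario("inert",
    composition = c(lignin = 0.3, hemicellulose = 0.3, cellulose = 0.4),
    sugar_shares = willow_scenario()$sugar_shares,
    sugar_consumption = list(
      hemicellulose = willow_scenario()$sugar_consumption$hemicellulose * 0,
      cellulose = willow_scenario()$sugar_consumption$cellulose * 0),
    cv = 0)
  expect_equal(sc$mass_loss, 0)
  ex <- gen_feeding_experiment(sc, n_batches = 3, seed = 2)
  ing <- ex$feeding$initial_mg - ex$feeding$remaining_mg
  expect_equal(ex$feeding$feces_mg, ing)
})

test_that("proteome preset abundances are validated and recovered at depth", {
  pre <- digestome_preset()
  for (cp in pre$compartments)
    expect_equal(sum(pre$proteins[[cp]]), 1)
  # convergence: at depth 1e5 estimated mol% within 2 points of preset truth
  ev <- gen_proteome_evidence(digestome_preset(depth = 1e5, seed = 11))
  filt <- filter_identifications(ev$evidence)
  mol <- molar_percentages(empai_quantify(filt$matches, ev$fasta))
  gf <- mol[mol$compartment == "gut_fluid" & mol$replicate == 1, ]
  truth <- 100 * pre$proteins$gut_fluid[match(gf$protein_id,
                                              pre$proteins$protein_id)]
  expect_true(all(abs(gf$mol_percent - truth)[truth > 1] < 2))
})

test_that("single-protein preset yields 100 mol%", {
  p <- data.frame(protein_id = "only", family = "other", gut_fluid = 1)
  pre <- proteome_preset(p, compartments = "gut_fluid", seed = 3)
  ev <- gen_proteome_evidence(pre, n_replicates = 1, empai_scale = 5)
  filt <- filter_identifications(ev$evidence)
  mol <- molar_percentages(empai_quantify(filt$matches, ev$fasta))
  expect_equal(unique(mol$mol_percent), 100)
})

test_that("evidence generation exercises both identification filters", {
  ev <- gen_proteome_evidence(digestome_preset(seed = 4))
  expect_true(any(ev$evidence$expect > 0.05))
  expect_true("CONT_KRT1" %in% ev$evidence$protein_id)
  filt <- filter_identifications(ev$evidence)
  expect_false("CONT_KRT1" %in% filt$matches$protein_id)
  expect_true(all(filt$matches$expect <= 0.05))
})

test_that("melt presets encode the hemocyanin stability conditions", {
  expect_equal(hemocyanin_melt_preset("native")$midpoint, 70)
  expect_equal(hemocyanin_melt_preset("seawater")$midpoint,
               hemocyanin_melt_preset("buffer")$midpoint - 5)
  expect_lt(hemocyanin_melt_preset("chelator")$midpoint, 55)
  pre <- melt_preset(midpoint = 70, noise_sd = 0)
  curve <- gen_melt_curve(pre)
  # symmetric sigmoid: value at the midpoint is halfway between asymptotes
  y_mid <- approx(curve$temperature, curve$fluorescence, xout = 70)$y
  expect_equal(y_mid, (pre$lower + pre$upper) / 2, tolerance = 1e-9)
})

test_that("a midpoint outside the grid is flagged", {
  pre <- melt_preset(midpoint = 120)
  expect_true(pre$midpoint_outside_grid)
  expect_warning(gen_melt_curve(pre), "outside")
})
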