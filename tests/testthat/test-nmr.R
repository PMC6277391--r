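# Inverse Laplace transform, log-Gaussian deconvolution, pore mapping.

test_that("kernel matches hand-computed exponentials", {
  expect_equal(build_kernel(1, 1)[1, 1], exp(-1))
  expect_equal(build_kernel(1e-9, 1)[1, 1], 1, tolerance = 1e-8)
  t <- c(0.5, 1, 2); g <- c(1, 4)
  K <- build_kernel(t, g)
  expect_equal(K, outer(t, g, function(ti, gj) exp(-ti / gj)),
               tolerance = 1e-12)
  expect_equal(dim(K), c(3L, 2L))
  expect_error(build_kernel(c(1, 0.5), g), "increasing")
  expect_error(build_kernel(c(-1, 1), g), "positive")
})

test_that("noiseless single-exponential decay inverts onto its T2", {
  comp <- log_gaussian_component(a = 1, b = -1, c = 0.02)   # T2 = 0.1 s
  dec <- gen_cpmg_decay(comp, test_acq(snr = Inf))
  dist <- ilt_nnls(dec)
  inside <- dist$t2 >= 0.05 & dist$t2 <= 0.2
  expect_gte(sum(dist$mass[inside]) / sum(dist$mass), 0.95)
})

test_that("T2 distributions integrate to one over log10(T2)", {
  dec <- gen_cpmg_decay(t2_truth_preset(), test_acq(seed = 2))
  dist <- ilt_nnls(dec)
  area <- pracma::trapz(dist$log10_t2, dist$amplitude)
  expect_equal(area, 1, tolerance = 1e-9)
  expect_true(all(dist$amplitude >= 0))
})

test_that("zero decays give a flagged zero distribution", {
  dist <- ilt_nnls(list(time = (1:200) * 1e-4, signal = rep(0, 200)))
  expect_true(dist$degenerate)
  expect_true(all(dist$amplitude == 0))
})

test_that("the inversion never fits worse than the zero solution", {
  for (s in 1:5) {
    dec <- gen_cpmg_decay(t2_truth_preset(), test_acq(seed = s))
    dist <- ilt_nnls(dec)
    idx <- limnodigest:::subsample_log(length(dec$signal), 2048)
    expect_lte(dist$resnorm, sqrt(sum(dec$signal[idx]^2)))
  }
})

test_that("deconvolution recovers exactly log-Gaussian distributions", {
  truth <- t2_truth_preset()
  dist <- dist_from_components(truth)
  fit <- fit_log_gaussians(dist, n_components = "auto", k_max = 5)
  expect_equal(fit$k, 3)
  centers <- vapply(fit$components, `[[`, 0, "b")
  expect_equal(centers, c(-3, -2, -1), tolerance = 0.05)
  # model contains the truth: residual is a vanishing share of the signal
  expect_lt(sqrt(fit$rss), 1e-6 * sum(dist$amplitude))
})

test_that("BIC selects one component for a single-Gaussian distribution", {
  dist <- dist_from_components(list(log_gaussian_component(1, -2, 0.3)))
  fit <- fit_log_gaussians(dist, n_components = "auto", k_max = 4)
  expect_equal(fit$k, 1)
})

test_that("two equal pore populations are recovered at half weight each", {
  truth <- t2_truth_preset(areas = c(0.5, 0.5), centers = c(-3, -1),
                           widths = c(0.15, 0.15))
  errs <- vapply(1:5, function(s) {
    dec <- gen_cpmg_decay(truth, acquisition_params(n_echoes = 8192, snr = 400,
                                                    seed = s))
    fit <- fit_log_gaussians(ilt_nnls(dec), n_components = 2)
    max(abs(relative_areas(fit)$rel_area - 0.5))
  }, 0)
  expect_true(all(errs < 0.05))
})

test_that("relative pore-population areas are recovered across noise seeds", {
  truth <- t2_truth_preset()
  ta <- relative_areas(truth)$rel_area
  hits <- vapply(1:50, function(s) {
    dec <- gen_cpmg_decay(truth, test_acq(snr = 199, seed = s))
    fit <- fit_log_gaussians(ilt_nnls(dec), n_components = 3)
    max(abs(relative_areas(fit)$rel_area - ta)) <= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("component areas follow the closed form with propagated error", {
  expect_equal(component_area(log_gaussian_component(1, 0, 1)),
               c(A = sqrt(2 * pi), sd_A = 0))
  expect_equal(unname(component_area(log_gaussian_component(0, 0, 1))["A"]), 0)
  got <- component_area(log_gaussian_component(a = 2, b = 0, c = 0.5,
                                               sd_a = 0.1, sd_c = 0.05))
  expect_equal(unname(got["A"]), sqrt(2 * pi), tolerance = 1e-6)
  expect_equal(unname(got["sd_A"]), sqrt(2 * pi) * sqrt(0.0025 + 0.01),
               tolerance = 1e-6)
})

test_that("pore map is the linear fast-diffusion relation", {
  expect_equal(pore_size(1, rho = 1), 2)
  expect_equal(pore_size(2 * 0.37, 5), 2 * pore_size(0.37, 5))
  r <- pore_size(c(1e-4, 1), rho = 1000)       # nm/s, spans the DMAc range
  expect_equal(r[2] / r[1], 1e4)               # four orders of magnitude
  expect_equal(t2_from_pore_size(pore_size(0.123, 7), 7), 0.123)
  expect_equal(surface_to_volume(2), 1)
  expect_error(pore_size(-1, 1), "positive")
  expect_error(pore_size(1, 0), "positive")
})

test_that("pore population comparison matches by center and combines errors", {
  truth <- t2_truth_preset()
  dist <- dist_from_components(truth)
  fit <- fit_log_gaussians(dist, 3)
  same <- compare_pore_populations(fit, fit)
  expect_equal(same$delta, rep(0, 3))
  # quadrature on toy area errors
  ra <- data.frame(component = 1, center = -2, rel_area = 0.6,
                   sd_rel_area = 0.3)
  rb <- data.frame(component = 1, center = -2, rel_area = 0.4,
                   sd_rel_area = 0.4)
  expect_equal(compare_pore_populations(ra, rb)$sd_delta, 0.5)
  # a constructed pair with the lower-two populations increased
  truth_b <- t2_truth_preset(areas = c(0.35, 0.45, 0.20))
  fit_b <- fit_log_gaussians(dist_from_components(truth_b), 3)
  delta <- compare_pore_populations(fit_b, fit)
  expect_true(all(delta$delta[1:2] > 0))
  expect_lt(delta$delta[3], 0)
  fit1 <- fit_log_gaussians(dist_from_components(truth[1]), 1)
  expect_error(compare_pore_populations(fit, fit1), "fixed component count")
})

test_that("spectrum normalization is idempotent and scale-invariant", {
  ppm <- seq(0, 200, by = 0.5)
  y <- dnorm(ppm, 56, 4) + 0.5 * dnorm(ppm, 150, 8)
  sp <- nmr_spectrum(ppm, y)
  n1 <- normalize_spectrum_to_region(sp, c(10, 60))
  n2 <- normalize_spectrum_to_region(n1, c(10, 60))
  expect_equal(n1$intensity, n2$intensity)
  n7 <- normalize_spectrum_to_region(nmr_spectrum(ppm, 7 * y), c(10, 60))
  expect_equal(n1$intensity, n7$intensity)
  # boxcar of height 2 over a width-1 region integrates to 2 -> height 1
  box <- nmr_spectrum(seq(0, 2, by = 0.01),
                      ifelse(seq(0, 2, by = 0.01) >= 0.5 &
                               seq(0, 2, by = 0.01) <= 1.5, 2, 0))
  nb <- normalize_spectrum_to_region(box, c(0.5, 1.5))
  expect_equal(max(nb$intensity), 1, tolerance = 1e-9)
  expect_error(normalize_spectrum_to_region(nmr_spectrum(ppm, 0 * y),
                                            c(10, 60)), "zero integral")
})

test_that("difference spectra are pointwise and linear", {
  ppm <- c(1, 2, 3)
  a <- nmr_spectrum(ppm, c(1, 2, 3))
  b <- nmr_spectrum(ppm, c(1, 1, 1))
  expect_equal(difference_spectrum(a, b)$intensity, c(0, 1, 2))
  expect_equal(difference_spectrum(a, a)$intensity, c(0, 0, 0))
  d1 <- difference_spectrum(difference_spectrum(a, b), b)
  expect_equal(d1$intensity, a$intensity - 2 * b$intensity)
  b2 <- nmr_spectrum(c(1, 2, 4), c(1, 1, 1))
  expect_error(difference_spectrum(a, b2), "interpolate")
  expect_equal(difference_spectrum(a, b2, interpolate = TRUE)$intensity,
               c(0, 1, 2))
})
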