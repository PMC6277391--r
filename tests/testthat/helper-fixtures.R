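# Shared fixtures, built in code at test time.

# Small, fast CPMG acquisition used throughout the unit tests (the full
# 50,000-echo instrument preset is exercised where acquisition itself is
# under test).
test_acq <- function(snr = 199, seed = 1, n_echoes = 4096) {
  acquisition_params(n_echoes = n_echoes, snr = snr, seed = seed)
}

# A t2_distribution built exactly from log-Gaussian components (no
# inversion involved), for deconvolution oracles.
dist_from_components <- function(components, n = 64, range = c(1e-5, 10)) {
  grid <- default_t2_grid(n, range)
  x <- log10(grid)
  dens <- rowSums(vapply(components,
                         function(cm) cm$a * exp(-(x - cm$b)^2 / (2 * cm$c^2)),
                         numeric(length(x))))
  w <- limnodigest:::trapezoid_weights(x)
  t2_distribution(grid, dens * w)
}

# Tiny evidence table for filter tests.
toy_evidence <- function() {
  data.frame(
    protein_id = c("P1", "P1", "P1", "P2", "P3", "P3"),
    peptide    = c("AAAK", "CCCK", "DDDK", "EEEK", "FFFK", "FFFK"),
    expect     = c(0.001, 0.02, 0.06, 0.01, 0.03, 0.04),
    sample     = c("s1", "s1", "s1", "s1", "s1", "s2"),
    compartment = "gut_fluid",
    replicate  = c(1L, 1L, 1L, 1L, 1L, 2L))
}
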