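# Constructors for the parameter objects that describe an experiment, plus
# the named presets mirroring the study's scenarios. Presets are plain
# constructors: everything downstream is an ordinary function of them.

#' CPMG acquisition parameters
#'
#' Describes a CPMG echo-train acquisition: number of echoes, echo spacing and
#' signal-to-noise ratio. SNR is defined as the maximum (noiseless) signal
#' amplitude divided by the noise standard deviation; `snr = Inf` gives a
#' noiseless acquisition.
#'
#' The default mirrors the benchtop acquisition used for DMAc-saturated wood:
#' 50,000 echoes at 70 microsecond spacing.
#'
#' @param n_echoes integer >= 2, number of echoes.
#' @param echo_time echo spacing in seconds (> 0).
#' @param snr positive SNR (max amplitude / noise SD), or `Inf` for noiseless.
#' @param seed integer seed for the noise stream (may be `NULL`).
#' @return An object of class `acquisition_params`.
#' @export
#' @examples
#' acquisition_params()                      # full instrument preset
#' acquisition_params(n_echoes = 4096, snr = 199)
acquisition_params <- function(n_echoes = 50000L, echo_time = 70e-6,
                               snr = Inf, seed = NULL) {
  if (!is.numeric(n_echoes) || length(n_echoes) != 1 || n_echoes < 2)
    stop_param("'n_echoes' must be a single integer >= 2")
  if (!is.numeric(echo_time) || length(echo_time) != 1 || echo_time <= 0)
    stop_param("'echo_time' must be a single positive number (seconds)")
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0)
    stop_param("'snr' must be a single positive number (use Inf for noiseless)")
  structure(list(n_echoes = as.integer(n_echoes), echo_time = echo_time,
                 snr = snr, noiseless = !is.finite(snr), seed = seed),
            class = "acquisition_params")
}

#' Log-Gaussian component of a T2 distribution
#'
#' One pore population on the log10(T2) axis: a Gaussian of amplitude `a`,
#' center `b` (log10 seconds) and width `c`, optionally carrying standard
#' deviations of `a` and `c` from a fit. The component's (unnormalized) area
#' is `sqrt(2*pi) * a * c`.
#'
#' @param a amplitude (>= 0).
#' @param b center on the log10(T2 / s) axis.
#' @param c width (> 0) on the log10 axis.
#' @param sd_a,sd_b,sd_c parameter standard deviations (>= 0; default 0).
#' @return An object of class `log_gaussian_component`.
#' @export
log_gaussian_component <- function(a, b, c, sd_a = 0, sd_b = 0, sd_c = 0) {
  if (a < 0) stop_param("amplitude 'a' must be >= 0")
  if (c <= 0) stop_param("width 'c' must be > 0")
  if (sd_a < 0 || sd_b < 0 || sd_c < 0)
    stop_param("parameter standard deviations must be >= 0")
  structure(list(a = a, b = b, c = c, sd_a = sd_a, sd_b = sd_b, sd_c = sd_c),
            class = "log_gaussian_component")
}

#' Three-population T2 truth used for relaxometry recovery studies
#'
#' The synthetic ground truth for CPMG simulations: three log-Gaussian pore
#' populations centred one decade apart (1, 10 and 100 ms), the structure
#' reported for DMAc-saturated wood cell walls. Relative areas 0.25/0.35/0.40.
#'
#' @param areas relative areas of the three populations (sum 1).
#' @param centers component centers, log10(T2 / s).
#' @param widths component widths on the log10 axis.
#' @return List of three [log_gaussian_component()] objects.
#' @export
t2_truth_preset <- function(areas = c(0.25, 0.35, 0.40),
                            centers = c(-3, -2, -1),
                            widths = c(0.25, 0.25, 0.25)) {
  stopifnot(length(areas) == length(centers), length(centers) == length(widths))
  areas <- areas / sum(areas)
  Map(function(A, b, c) log_gaussian_component(a = A / (sqrt(2 * pi) * c), b = b, c = c),
      areas, centers, widths)
}

#' Wood digestion scenario
#'
#' Describes a feeding experiment: the initial composition of the wood in the
#' three operational fractions (ABSL lignin, TFA-soluble hemicellulose,
#' H2SO4-soluble cellulose), the per-sugar make-up of the two polysaccharide
#' fractions, and the fraction of each sugar consumed during gut passage.
#' Per-fraction consumption and the overall mass-loss fraction are *derived*
#' (composition-weighted sums), so the mass budget is consistent by
#' construction and cannot be specified inconsistently.
#'
#' @param species label, e.g. `"willow"`.
#' @param composition named numeric `c(lignin=, hemicellulose=, cellulose=)`
#'   summing to 1.
#' @param sugar_shares named list with elements `hemicellulose` and
#'   `cellulose`, each a named numeric vector over the nine HPAEC sugars
#'   summing to 1.
#' @param sugar_consumption same shape as `sugar_shares`: fraction of each
#'   sugar consumed, all in \[0, 1\]. Lignin is assumed refractory.
#' @param lignin_consumption fraction of the lignin fraction consumed
#'   (default 0).
#' @param cv replicate noise coefficient of variation (>= 0) applied
#'   multiplicatively to measured masses.
#' @return An object of class `digestion_scenario` with derived fields
#'   `fraction_consumption` and `mass_loss` (fractions).
#' @export
digestion_scenario <- function(species, composition, sugar_shares,
                               sugar_consumption, lignin_consumption = 0,
                               cv = 0.05) {
  comp <- composition[c("lignin", "hemicellulose", "cellulose")]
  if (anyNA(comp)) stop_param("'composition' needs lignin, hemicellulose, cellulose")
  if (abs(sum(comp) - 1) > 1e-9) stop_param("composition fractions must sum to 1")
  if (any(comp < 0)) stop_param("composition fractions must be non-negative")
  if (cv < 0) stop_param("'cv' must be >= 0")
  if (lignin_consumption < 0 || lignin_consumption > 1)
    stop_param("'lignin_consumption' must lie in [0, 1]")
  for (fr in c("hemicellulose", "cellulose")) {
    sh <- sugar_shares[[fr]]; cons <- sugar_consumption[[fr]]
    if (is.null(sh) || abs(sum(sh) - 1) > 1e-9)
      stop_param("sugar shares for ", fr, " must sum to 1")
    if (is.null(cons) || any(cons < 0) || any(cons > 1))
      stop_param("sugar consumption for ", fr, " must lie in [0, 1]")
    if (!setequal(names(sh), names(cons)))
      stop_param("sugar shares and consumption must name the same sugars (", fr, ")")
  }
  frac_cons <- c(
    lignin = lignin_consumption,
    hemicellulose = sum(sugar_shares$hemicellulose *
                          sugar_consumption$hemicellulose[names(sugar_shares$hemicellulose)]),
    cellulose = sum(sugar_shares$cellulose *
                      sugar_consumption$cellulose[names(sugar_shares$cellulose)])
  )
  mass_loss <- sum(comp * frac_cons)
  feces_comp <- comp * (1 - frac_cons)
  if (any(feces_comp < -1e-12))
    stop_param("inconsistent mass budget: negative fecal composition")
  structure(list(species = species, composition = comp,
                 sugar_shares = sugar_shares,
                 sugar_consumption = sugar_consumption,
                 fraction_consumption = frac_cons,
                 mass_loss = mass_loss,
                 feces_composition = feces_comp / sum(feces_comp),
                 cv = cv),
            class = "digestion_scenario")
}

#' The nine HPAEC monosaccharides
#' @return Character vector of sugar abbreviations.
#' @export
hpaec_sugars <- function() {
  c("Fuc", "Ara", "Rha", "Gal", "Glu", "Xyl", "Man", "GalA", "GlcA")
}

sugar_vec <- function(...) {
  v <- c(...)
  full <- stats::setNames(numeric(length(hpaec_sugars())), hpaec_sugars())
  full[names(v)] <- v
  full
}

#' Willow feeding scenario
#'
#' Hardwood scenario: digestion consumes half of the cellulosic fraction and
#' essentially none of the hemicellulose or lignin, giving an overall mass
#' loss of exactly 22% of ingested material.
#'
#' @param cv measurement noise CV (default 0.05).
#' @return A [digestion_scenario()].
#' @export
willow_scenario <- function(cv = 0.05) {
  shares <- list(
    hemicellulose = sugar_vec(Xyl = 0.55, Glu = 0.11, Gal = 0.08, Ara = 0.06,
                              Man = 0.05, Rha = 0.04, GalA = 0.09, Fuc = 0.01,
                              GlcA = 0.01),
    cellulose = sugar_vec(Glu = 0.92, Xyl = 0.05, Man = 0.02, Gal = 0.01)
  )
  cons <- list(
    hemicellulose = sugar_vec(),                       # untouched
    cellulose = sugar_vec(Glu = 0.5, Xyl = 0.5, Man = 0.5, Gal = 0.5)
  )
  digestion_scenario("willow",
                     composition = c(lignin = 0.26, hemicellulose = 0.30,
                                     cellulose = 0.44),
                     sugar_shares = shares, sugar_consumption = cons, cv = cv)
}

#' Scots pine feeding scenario
#'
#' Softwood scenario: the cellulosic fraction is reduced by ~40% and the
#' galactoglucomannan-rich hemicellulose by ~20%, with the hemicellulose loss
#' carried mainly by mannose and glucose and little xylose loss.
#'
#' @param cv measurement noise CV (default 0.05).
#' @return A [digestion_scenario()].
#' @export
pine_scenario <- function(cv = 0.05) {
  shares <- list(
    hemicellulose = sugar_vec(Man = 0.45, Xyl = 0.20, Glu = 0.15, Gal = 0.08,
                              Ara = 0.07, GalA = 0.03, Rha = 0.01,
                              Fuc = 0.005, GlcA = 0.005),
    cellulose = sugar_vec(Glu = 0.95, Xyl = 0.03, Man = 0.02)
  )
  # mannose consumption set so the hemicellulose fraction loss is exactly 20%
  man_cons <- (0.20 - sum(shares$hemicellulose[c("Glu", "Xyl", "Gal", "Ara", "GalA")] *
                            c(0.30, 0.02, 0.05, 0.02, 0.02))) /
    shares$hemicellulose[["Man"]]
  cons <- list(
    hemicellulose = sugar_vec(Man = man_cons, Glu = 0.30, Gal = 0.05,
                              Xyl = 0.02, Ara = 0.02, GalA = 0.02),
    cellulose = sugar_vec(Glu = 0.40, Xyl = 0.40, Man = 0.40)
  )
  digestion_scenario("pine",
                     composition = c(lignin = 0.28, hemicellulose = 0.27,
                                     cellulose = 0.45),
                     sugar_shares = shares, sugar_consumption = cons, cv = cv)
}

#' Proteome preset
#'
#' Defines a synthetic digestive proteome: protein identifiers, family
#' annotation (a CAZy GH family number, `"hemocyanin"`, `"ferritin"` or
#' `"other"`), and per-compartment relative molar abundances that each sum
#' to 1. Protein sequences are generated reproducibly from `seed` with a
#' realistic K/R content so tryptic peptide counts are plausible.
#'
#' @param proteins data.frame with columns `protein_id`, `family`, and one
#'   abundance column per compartment.
#' @param compartments names of the abundance columns.
#' @param seq_lengths named integer vector of protein lengths (residues);
#'   defaults to lengths drawn reproducibly in 350..700.
#' @param depth default per-replicate sampling depth (expected peptide-spectrum
#'   observations driving counting noise).
#' @param n_replicates default replicate count.
#' @param seed integer seed for sequence generation.
#' @return An object of class `proteome_preset` (includes `$sequences`).
#' @export
proteome_preset <- function(proteins,
                            compartments = c("gut_fluid", "gut_tissue",
                                             "hepatopancreas"),
                            seq_lengths = NULL, depth = 1e4,
                            n_replicates = 3, seed = 1L) {
  stopifnot(is.data.frame(proteins), nrow(proteins) >= 1)
  if (!all(c("protein_id", "family") %in% names(proteins)))
    stop_param("'proteins' needs columns protein_id and family")
  if (!all(compartments %in% names(proteins)))
    stop_param("missing abundance columns: ",
               paste(setdiff(compartments, names(proteins)), collapse = ", "))
  for (cp in compartments) {
    ab <- proteins[[cp]]
    if (any(ab < 0)) stop_param("abundances must be >= 0 (", cp, ")")
    if (abs(sum(ab) - 1) > 1e-9)
      stop_param("abundances in compartment '", cp, "' must sum to 1")
  }
  ids <- as.character(proteins$protein_id)
  if (anyDuplicated(ids)) stop_param("duplicate protein ids")
  if (is.null(seq_lengths)) {
    seq_lengths <- with_seed(child_seed(seed, 101L),
                             stats::setNames(sample(350:700, length(ids),
                                                    replace = TRUE), ids))
  }
  sequences <- with_seed(child_seed(seed, 202L),
                         stats::setNames(vapply(ids, function(id)
                           random_protein_sequence(seq_lengths[[id]]), ""), ids))
  structure(list(proteins = proteins, compartments = compartments,
                 sequences = sequences, depth = depth,
                 n_replicates = n_replicates, seed = seed),
            class = "proteome_preset")
}

# Random protein sequence with amino-acid frequencies loosely matching
# vertebrate/invertebrate proteomes; ~11% K+R gives tryptic peptides of
# typical length.
random_protein_sequence <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  freq <- c(8.3, 5.5, 4.0, 5.5, 1.4, 3.9, 6.7, 7.1, 2.3, 6.0,
            9.7, 5.8, 2.4, 3.9, 4.7, 6.6, 5.3, 1.1, 2.9, 6.9)
  paste(sample(aa, n, replace = TRUE, prob = freq), collapse = "")
}

#' Default digestome preset
#'
#' The study-structure preset: hemocyanins abundant in gut fluids, GH7 and
#' GH9 cellulases dominating the glycosyl-hydrolase complement (well over
#' half of GH molar abundance in fluids), minor GH5/GH30/GH35/GH16, trace
#' ferritin (0.5 mol% in fluids), and abundant structural "other" proteins in
#' tissue.
#'
#' @param depth per-replicate sampling depth (default 1e4).
#' @param n_replicates replicate count (default 3).
#' @param seed sequence/sampling seed.
#' @return A [proteome_preset()].
#' @export
digestome_preset <- function(depth = 1e4, n_replicates = 3, seed = 1L) {
  p <- data.frame(
    protein_id = c("Hc1", "Hc2", "Hc3", "Hc4",
                   "GH7A", "GH7B", "GH9A", "GH9B",
                   "GH5A", "GH5B", "GH30A", "GH35A", "GH16A",
                   "Fer1",
                   "Act1", "Tub1", "Myo1", "Hsp70", "Cut1"),
    family = c(rep("hemocyanin", 4),
               "GH7", "GH7", "GH9", "GH9",
               "GH5", "GH5", "GH30", "GH35", "GH16",
               "ferritin",
               rep("other", 5)),
    gut_fluid = c(0.12, 0.09, 0.05, 0.04,
                  0.130, 0.080, 0.080, 0.050,
                  0.040, 0.025, 0.022, 0.012, 0.008,
                  0.005,
                  0.080, 0.060, 0.050, 0.040, 0.018),
    gut_tissue = c(0.03, 0.02, 0.015, 0.01,
                   0.030, 0.020, 0.020, 0.015,
                   0.010, 0.008, 0.006, 0.004, 0.002,
                   0.010,
                   0.250, 0.200, 0.180, 0.120, 0.050),
    hepatopancreas = c(0.10, 0.08, 0.05, 0.04,
                       0.110, 0.070, 0.070, 0.045,
                       0.035, 0.020, 0.015, 0.010, 0.005,
                       0.010,
                       0.120, 0.090, 0.080, 0.070, 0.080)
  )
  for (cp in c("gut_fluid", "gut_tissue", "hepatopancreas"))
    p[[cp]] <- p[[cp]] / sum(p[[cp]])
  proteome_preset(p, depth = depth, n_replicates = n_replicates, seed = seed)
}

#' Melt-curve preset
#'
#' Parameters of a five-parameter logistic melt curve plus acquisition grid
#' and noise. The transition midpoint temperature (the Tm of a symmetric
#' curve) is `midpoint`.
#'
#' @param midpoint transition midpoint, degrees C.
#' @param lower,upper fluorescence asymptotes (a.u.), `upper > lower`.
#' @param slope logistic rate per degree C (sign sets direction).
#' @param asymmetry asymmetry exponent d (> 0; 1 = symmetric).
#' @param temperatures strictly increasing grid within \[25, 95\] degrees C.
#' @param noise_sd additive Gaussian noise SD (a.u.); the default is 2% of
#'   the fluorescence range.
#' @param seed noise seed.
#' @return An object of class `melt_preset`.
#' @export
melt_preset <- function(midpoint = 70, lower = 100, upper = 1000, slope = 0.7,
                        asymmetry = 1, temperatures = seq(25, 95, by = 0.5),
                        noise_sd = 0.02 * (upper - lower), seed = NULL) {
  if (upper <= lower) stop_param("'upper' must exceed 'lower'")
  if (asymmetry <= 0) stop_param("'asymmetry' must be > 0")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop_param("'temperatures' must be strictly increasing")
  if (min(temperatures) < 25 - 1e-9 || max(temperatures) > 95 + 1e-9)
    stop_param("'temperatures' must lie within [25, 95] degrees C")
  if (noise_sd < 0) stop_param("'noise_sd' must be >= 0")
  warn <- midpoint < min(temperatures) || midpoint > max(temperatures)
  structure(list(midpoint = midpoint, lower = lower, upper = upper,
                 slope = slope, asymmetry = asymmetry,
                 temperatures = temperatures, noise_sd = noise_sd,
                 seed = seed, midpoint_outside_grid = warn),
            class = "melt_preset")
}

#' Named melt presets for the hemocyanin stability conditions
#'
#' Midpoints: `"native"`/`"buffer"` 70 degrees C, `"seawater"` 65 (5 degrees
#' below buffer), `"chelator"` 52 (destabilised below 55).
#'
#' @param condition one of `"native"`, `"buffer"`, `"seawater"`, `"chelator"`.
#' @param seed noise seed.
#' @return A [melt_preset()].
#' @export
hemocyanin_melt_preset <- function(condition = c("native", "buffer",
                                                 "seawater", "chelator"),
                                   seed = NULL) {
  condition <- match.arg(condition)
  tm <- switch(condition, native = 70, buffer = 70, seawater = 65,
               chelator = 52)
  melt_preset(midpoint = tm, seed = seed)
}
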