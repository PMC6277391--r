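# Mass-balance and biomass-fraction arithmetic: gut-passage mass loss,
# acetyl bromide-soluble lignin, three-fraction percentages, normalization of
# fecal composition to digestion mass loss, HPAEC sugar calibration, and
# wood-vs-feces digestion deltas.

#' Percent of ingested mass lost during gut passage
#'
#' The ingested mass is the initial stick mass minus what remains; the mass
#' loss is the ingested mass minus the fecal-pellet mass recovered from it,
#' expressed as a percentage of the ingested mass. A negative value (more
#' feces than ingested wood, possible under measurement noise) is returned
#' as-is with attribute `negative_loss = TRUE`, never clipped.
#'
#' @param initial_mg,remaining_mg,feces_mg masses in mg (vectorized).
#' @return Percent mass loss (vector), attribute `negative_loss` flagging
#'   any negative entries.
#' @export
#' @examples
#' mass_loss_percent(100, 50, 39)   # 22
mass_loss_percent <- function(initial_mg, remaining_mg, feces_mg) {
  if (any(initial_mg < 0) || any(remaining_mg < 0) || any(feces_mg < 0))
    stop_param("masses must be non-negative")
  if (any(remaining_mg > initial_mg))
    stop_param("'remaining_mg' cannot exceed 'initial_mg'")
  ingested <- initial_mg - remaining_mg
  if (any(ingested <= 0)) stop_param("nothing was eaten: ingested mass <= 0")
  loss <- 100 * (ingested - feces_mg) / ingested
  if (any(loss < 0)) attr(loss, "negative_loss") <- TRUE
  loss
}

#' Acetyl bromide-soluble lignin percentage
#'
#' `%ABSL = (absorbance / (coefficient * path)) *
#'          ((total_volume * 100) / biomass_weight) * dilution`,
#' with volume in mL and biomass weight in mg. The default extinction
#' coefficient is the poplar value 18.21 L g^-1 cm^-1.
#'
#' @param absorbance absorbance at 280 nm of the diluted aliquot.
#' @param coefficient extinction coefficient, L g^-1 cm^-1 (default 18.21).
#' @param path_cm cuvette path length, cm (default 1).
#' @param total_volume_ml extraction volume, mL (default 5).
#' @param biomass_weight_mg biomass aliquot weight, mg.
#' @param dilution dilution factor of the measured aliquot (default 10).
#' @return Percent lignin.
#' @export
absl_percent <- function(absorbance, coefficient = 18.21, path_cm = 1,
                         total_volume_ml = 5, biomass_weight_mg,
                         dilution = 10) {
  if (any(absorbance < 0)) stop_param("'absorbance' must be >= 0")
  if (coefficient <= 0 || path_cm <= 0)
    stop_param("'coefficient' and 'path_cm' must be positive")
  if (any(biomass_weight_mg <= 0)) stop_param("'biomass_weight_mg' must be positive")
  if (total_volume_ml <= 0 || dilution <= 0)
    stop_param("'total_volume_ml' and 'dilution' must be positive")
  (absorbance / (coefficient * path_cm)) *
    ((total_volume_ml * 100) / biomass_weight_mg) * dilution
}

#' Percentages of the three biomass fractions
#'
#' Each fraction mass divided by the summed total, times 100.
#'
#' @param lignin_mg,hemicellulose_mg,cellulose_mg fraction masses
#'   (vectorized over samples).
#' @return data.frame with columns `lignin`, `hemicellulose`, `cellulose`
#'   (percent; rows sum to 100).
#' @export
fraction_percentages <- function(lignin_mg, hemicellulose_mg, cellulose_mg) {
  total <- lignin_mg + hemicellulose_mg + cellulose_mg
  if (any(total <= 0)) stop_param("total fraction mass must be positive")
  data.frame(lignin = 100 * lignin_mg / total,
             hemicellulose = 100 * hemicellulose_mg / total,
             cellulose = 100 * cellulose_mg / total)
}

#' Normalize fecal fraction percentages to digestion mass loss
#'
#' Rescales fecal composition percentages (summing to 100) by
#' `(100 - loss)/100`, so that the fecal total represents the mass remaining
#' after digestion: with a 22% mass loss the fecal fractions sum to 78.
#'
#' @param percentages numeric vector or data.frame of percentages summing to
#'   100 per sample.
#' @param mass_loss_percent mass loss in \[0, 100\].
#' @return Scaled percentages (same shape); each sample sums to
#'   `100 - mass_loss_percent`.
#' @export
#' @examples
#' normalize_feces_to_mass_loss(c(30, 30, 40), 22)   # sums to 78
normalize_feces_to_mass_loss <- function(percentages, mass_loss_percent) {
  if (mass_loss_percent < 0 || mass_loss_percent > 100)
    stop_param("'mass_loss_percent' must lie in [0, 100]")
  sums <- if (is.data.frame(percentages)) rowSums(percentages) else sum(percentages)
  if (any(abs(sums - 100) > 1e-6))
    stop_param("'percentages' must sum to 100 before normalization")
  percentages * (100 - mass_loss_percent) / 100
}

#' Linear HPAEC calibration from standard injections
#'
#' Ordinary least-squares line (free intercept) of peak area on amount for
#' each analyte.
#'
#' @param standards data.frame with columns `sugar`, `amount`, `area`; at
#'   least two standard levels per analyte.
#' @return Object of class `hpaec_calibration`: data.frame `sugar`, `slope`,
#'   `intercept`.
#' @export
hpaec_calibration <- function(standards) {
  stopifnot(all(c("sugar", "amount", "area") %in% names(standards)))
  out <- do.call(rbind, lapply(split(standards, standards$sugar), function(d) {
    if (nrow(d) < 2)
      stop_param("analyte ", d$sugar[1], " has fewer than 2 standard levels")
    fit <- stats::lm(area ~ amount, data = d)
    slope <- unname(stats::coef(fit)[2])
    if (slope <= 0) stop_param("non-positive calibration slope for ", d$sugar[1])
    data.frame(sugar = d$sugar[1], slope = slope,
               intercept = unname(stats::coef(fit)[1]))
  }))
  rownames(out) <- NULL
  structure(out, class = c("hpaec_calibration", "data.frame"))
}

#' Quantify sugars from integrated peak areas
#'
#' Back-calculates each analyte amount from the calibration line,
#' `amount = (area - intercept) / slope`, converts it to an amount per mg of
#' biomass using the resuspension volume, and floors negative
#' back-calculations at 0 (flagged, not silent).
#'
#' @param peak_areas data.frame with columns `sugar`, `area` (one row per
#'   analyte peak).
#' @param cal an [hpaec_calibration()].
#' @param volume_ml resuspension volume in mL.
#' @param biomass_mg biomass aliquot weight in mg.
#' @return data.frame `sugar`, `amount_per_mg` (units of the calibration
#'   amounts per mg), `floored` (logical).
#' @export
quantify_sugars <- function(peak_areas, cal, volume_ml, biomass_mg) {
  stopifnot(all(c("sugar", "area") %in% names(peak_areas)))
  if (volume_ml <= 0 || biomass_mg <= 0)
    stop_param("'volume_ml' and 'biomass_mg' must be positive")
  missing <- setdiff(unique(peak_areas$sugar), cal$sugar)
  if (length(missing))
    stop_param("no calibration for analyte(s): ", paste(missing, collapse = ", "))
  idx <- match(peak_areas$sugar, cal$sugar)
  raw <- (peak_areas$area - cal$intercept[idx]) / cal$slope[idx]
  floored <- raw < 0
  raw[floored] <- 0
  data.frame(sugar = peak_areas$sugar,
             amount_per_mg = raw * volume_ml / biomass_mg,
             floored = floored)
}

#' Per-quantity percent reduction between wood and normalized feces
#'
#' For each shared quantity (fraction percentage, or sugar amount per mg),
#' `reduction% = 100 * (mean_wood - mean_feces) / mean_wood`, where the fecal
#' values must already be normalized to the digestion mass loss. The group
#' standard deviations are propagated to the reduction by the first-order
#' (delta-method) formula for a ratio of independent means.
#'
#' @param wood,feces_normalized data.frames of per-sample values with
#'   matching numeric columns (rows = samples).
#' @return data.frame: `quantity`, `mean_wood`, `sd_wood`, `mean_feces`,
#'   `sd_feces`, `reduction_percent`, `sd_reduction`, `n_wood`, `n_feces`,
#'   `undefined` (TRUE where the wood mean is zero).
#' @export
digestion_delta <- function(wood, feces_normalized) {
  cols <- intersect(names(wood)[vapply(wood, is.numeric, TRUE)],
                    names(feces_normalized)[vapply(feces_normalized, is.numeric, TRUE)])
  if (length(cols) == 0) stop_param("no shared numeric quantities to compare")
  if (nrow(wood) == 0 || nrow(feces_normalized) == 0)
    stop_param("both sample sets must be non-empty")
  out <- do.call(rbind, lapply(cols, function(cn) {
    w <- wood[[cn]]; f <- feces_normalized[[cn]]
    mw <- mean(w); mf <- mean(f)
    sw <- stats::sd(w); sf <- stats::sd(f)
    if (abs(mw) < .Machine$double.eps) {
      return(data.frame(quantity = cn, mean_wood = mw, sd_wood = sw,
                        mean_feces = mf, sd_feces = sf,
                        reduction_percent = NA_real_, sd_reduction = NA_real_,
                        n_wood = length(w), n_feces = length(f),
                        undefined = TRUE))
    }
    red <- 100 * (mw - mf) / mw
    sd_red <- 100 / mw * sqrt(sf^2 + (mf / mw)^2 * sw^2)
    data.frame(quantity = cn, mean_wood = mw, sd_wood = sw,
               mean_feces = mf, sd_feces = sf,
               reduction_percent = red, sd_reduction = sd_red,
               n_wood = length(w), n_feces = length(f), undefined = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction percentages and normalized sugar amounts of generated samples
#'
#' Convenience wrappers turning the tables produced by
#' [gen_feeding_experiment()] into the per-sample quantities compared by
#' [digestion_delta()].
#'
#' @param fractions fraction-mass table (`sample`, `lignin_mg`,
#'   `hemicellulose_mg`, `cellulose_mg`).
#' @param mass_loss percent mass loss used to normalize fecal percentages;
#'   `NULL` (wood) leaves values unscaled.
#' @return data.frame of per-sample fraction percentages (normalized when
#'   `mass_loss` is given).
#' @export
sample_fraction_table <- function(fractions, mass_loss = NULL) {
  pc <- fraction_percentages(fractions$lignin_mg, fractions$hemicellulose_mg,
                             fractions$cellulose_mg)
  if (!is.null(mass_loss)) pc <- normalize_feces_to_mass_loss(pc, mass_loss)
  cbind(sample = fractions$sample, pc)
}

#' @rdname sample_fraction_table
#' @param sugars tidy sugar table (`sample`, `fraction`, `sugar`,
#'   `amount_mg`) from [gen_feeding_experiment()].
#' @param aliquot_mg aliquot mass used to express amounts per mg biomass.
#' @return For `sample_sugar_table`: wide data.frame of per-sample sugar
#'   amounts per mg (columns `<fraction>.<sugar>`), fecal values scaled by
#'   `(100 - mass_loss)/100` when `mass_loss` is given.
#' @export
sample_sugar_table <- function(sugars, aliquot_mg, mass_loss = NULL) {
  sugars$amount_per_mg <- sugars$amount_mg / aliquot_mg
  if (!is.null(mass_loss))
    sugars$amount_per_mg <- sugars$amount_per_mg * (100 - mass_loss) / 100
  key <- paste(sugars$fraction, sugars$sugar, sep = ".")
  samples <- unique(sugars$sample)
  cols <- unique(key)
  m <- matrix(NA_real_, length(samples), length(cols),
              dimnames = list(NULL, cols))
  m[cbind(match(sugars$sample, samples), match(key, cols))] <-
    sugars$amount_per_mg
  data.frame(sample = samples, m, check.names = FALSE)
}
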