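# Thermofluor melt-curve fitting: five-parameter logistic with the melting
# temperature reported as the half-transition midpoint.

#' Five-parameter logistic
#'
#' \deqn{y(T) = L + \frac{U - L}{\left(1 + e^{-k (T - m)}\right)^d}}
#' Ascending for `slope > 0`; descending curves use `slope < 0`. With
#' `asymmetry = 1` the curve is symmetric and its midpoint is `m`.
#'
#' @param temperature temperatures, degrees C.
#' @param lower,upper asymptotes L and U.
#' @param midpoint location parameter m, degrees C.
#' @param slope rate k per degree C.
#' @param asymmetry asymmetry exponent d (> 0).
#' @return Fluorescence values.
#' @export
fivepl <- function(temperature, lower, upper, midpoint, slope, asymmetry = 1) {
  lower + (upper - lower) / (1 + exp(-slope * (temperature - midpoint)))^asymmetry
}

# Exact half-transition temperature of the five-parameter logistic:
# y = (L+U)/2  <=>  (1 + e^{-k(T-m)})^d = 2  <=>  T = m - log(2^{1/d} - 1)/k.
fivepl_tm <- function(midpoint, slope, asymmetry) {
  midpoint - log(2^(1 / asymmetry) - 1) / slope
}

#' Fit a melt curve with the five-parameter sigmoid
#'
#' Nonlinear least-squares fit of the five-parameter logistic to a
#' fluorescence melt curve, started from three deterministic initializations
#' (asymmetry 1, 0.5 and 2; asymptotes from the data extrema; midpoint at the
#' steepest observed slope) with the best residual retained. The melting
#' temperature is the temperature at which the fitted curve crosses the
#' half-transition (L+U)/2; its standard deviation comes from the fit
#' covariance by the delta method. Descending curves are handled by sign
#' detection (negative slope).
#'
#' @param curve a `melt_curve` (or list with `temperature`, `fluorescence`).
#' @return Object of class `melt_fit`: list with `lower`, `upper`,
#'   `midpoint`, `slope`, `asymmetry`, `tm`, `sd_tm`, `rmse`, `coef_sd`,
#'   `extrapolated` (Tm outside the data range), and the fit object.
#' @export
fit_5pl <- function(curve) {
  temp <- curve$temperature; y <- curve$fluorescence
  if (length(temp) < 10) stop_param("melt curve needs at least 10 points")
  if (stats::sd(y) < .Machine$double.eps * max(abs(y), 1))
    stop_param("constant fluorescence: nothing to fit")
  ysm <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  dy <- diff(as.numeric(ysm)) / diff(temp)
  i_max <- which.max(abs(dy))
  m0 <- mean(temp[i_max + 0:1])
  ascending <- dy[i_max] > 0
  k0 <- (if (ascending) 1 else -1) * 4 / (diff(range(temp)) / 8)
  df <- data.frame(temp = temp, y = y)
  range_y <- diff(range(y))
  starts <- lapply(c(1, 0.5, 2), function(d0)
    list(L = min(y), U = max(y), m = m0, k = k0, d = d0))
  best <- NULL
  diagnostics <- list()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ L + (U - L) / (1 + exp(-k * (temp - m)))^d,
        data = df, start = st,
        lower = c(L = min(y) - range_y, U = min(y) - range_y,
                  m = min(temp) - 20, k = -20, d = 0.05),
        upper = c(L = max(y) + range_y, U = max(y) + range_y,
                  m = max(temp) + 20, k = 20, d = 20),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) e)
    if (inherits(fit, "error")) { diagnostics <- c(diagnostics, list(fit)); next }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop_param("five-parameter fit failed from all starts: ",
               paste(vapply(diagnostics, conditionMessage, ""), collapse = "; "))
  fit <- best$fit
  cf <- stats::coef(fit)
  L <- cf[["L"]]; U <- cf[["U"]]; m <- cf[["m"]]; k <- cf[["k"]]; d <- cf[["d"]]
  if (U < L) {         # canonical orientation: U is the upper asymptote
    tmp <- L; L <- U; U <- tmp
  }
  tm <- fivepl_tm(m, k, d)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 5), names(cf)))
  # delta method on (m, k, d)
  g <- c(m = 1,
         k = log(2^(1 / d) - 1) / k^2,
         d = -(2^(1 / d) * log(2) / d^2) / ((2^(1 / d) - 1) * k))
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  sd_tm <- if (is.null(V)) NA_real_ else {
    v <- V[c("m", "k", "d"), c("m", "k", "d")]
    sqrt(drop(t(g) %*% v %*% g))
  }
  structure(list(lower = L, upper = U, midpoint = m, slope = k,
                 asymmetry = d, tm = tm, sd_tm = sd_tm,
                 rmse = sqrt(best$rss / length(y)),
                 coef_sd = se,
                 extrapolated = tm < min(temp) || tm > max(temp),
                 fit = fit),
            class = "melt_fit")
}

#' Melting-temperature shift between two conditions
#'
#' Fits both curves (unless already fitted) and returns Tm(A) - Tm(B) with
#' the standard deviation combined in quadrature.
#'
#' @param curve_a,curve_b `melt_curve` or `melt_fit` objects.
#' @return List with `delta_tm`, `sd`, and the two fits.
#' @export
tm_shift <- function(curve_a, curve_b) {
  fa <- if (inherits(curve_a, "melt_fit")) curve_a else fit_5pl(curve_a)
  fb <- if (inherits(curve_b, "melt_fit")) curve_b else fit_5pl(curve_b)
  list(delta_tm = fa$tm - fb$tm,
       sd = sqrt(fa$sd_tm^2 + fb$sd_tm^2),
       fit_a = fa, fit_b = fb)
}
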