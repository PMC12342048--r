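#' Single-exponential substrate-depletion progress model
#'
#' Fraction of substrate cleaved after time `t` by enzyme at concentration
#' `E` acting under [S] << Km conditions: `P = 1 - exp(-E * t * k)` where `k`
#' is the catalytic efficiency kcat/Km.
#'
#' @param E Enzyme concentration (molar).
#' @param t Time (seconds).
#' @param k Catalytic efficiency kcat/Km (M-1 s-1).
#' @return Fraction cleaved, in \[0, 1\].
#' @export
#' @examples
#' progress_fraction(1e-9, 1200, 2.4e5)
progress_fraction <- function(E, t, k) {
  if (any(E < 0) || any(t < 0) || any(k < 0))
    abort("E, t and k must be non-negative")
  1 - exp(-E * t * k)
}

#' Fit kcat/Km from substrate-depletion progress curves
#'
#' Ordinary nonlinear least squares of the single-parameter model
#' `P = 1 - exp(-E * t * k)` pooled over replicates (Levenberg-Marquardt).
#'
#' @param curves Tibble with columns `enzyme_conc` (molar), `time_s`,
#'   `fraction` (and optionally `replicate`). Raw fractions slightly outside
#'   \[0, 1\] (within ±0.05) are accepted; the model domain is \[0, 1\].
#' @return Object of class `progress_fit` with `estimate` (kcat/Km, M-1 s-1),
#'   `se`, the `nls` fit and the data.
#' @export
fit_progress_kcat_km <- function(curves) {
  need <- c("enzyme_conc", "time_s", "fraction")
  if (!all(need %in% names(curves)))
    abort(paste0("`curves` needs columns: ", paste(need, collapse = ", ")))
  if (nrow(curves) < 3) abort("need >= 3 points to fit")
  if (any(curves$fraction < -0.05 | curves$fraction > 1.05))
    abort("fractions outside [-0.05, 1.05]; check units")
  nz <- curves$fraction > 0.01 & curves$time_s > 0
  if (!any(nz))
    abort("no measurable conversion: kcat/Km is not identifiable")
  # log-linear starting value from points with usable conversion
  p <- pmin(curves$fraction[nz], 0.999)
  k0 <- median(-log(1 - p) / (curves$enzyme_conc[nz] * curves$time_s[nz]))
  fit <- minpack.lm::nlsLM(
    fraction ~ 1 - exp(-enzyme_conc * time_s * k),
    data = curves, start = list(k = k0), lower = 0,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(estimate = unname(coef(fit)["k"]),
                 se = sqrt(vcov(fit)[1, 1]),
                 fit = fit, data = as_tibble(curves),
                 model = "P = 1 - exp(-E t kcat/Km)"),
            class = "progress_fit")
}

#' Morrison tight-binding inhibition equation
#'
#' Fractional velocity under tight-binding (quadratic) inhibition:
#' `vi/v0 = 1 - (Et + I + Ki - sqrt((Et + I + Ki)^2 - 4 Et I)) / (2 Et)`.
#' The discriminant is clamped at zero against floating-point negatives. Used
#' when inhibitor and enzyme concentrations are comparable, where the
#' classical isotherm `1 / (1 + I/Ki)` (the Et -> 0 limit) breaks down.
#'
#' @param Et Total active enzyme concentration (molar, > 0).
#' @param I Inhibitor concentration(s) (molar, >= 0).
#' @param Ki Apparent inhibition constant (molar, >= 0).
#' @return vi/v0 in \[0, 1\].
#' @export
#' @examples
#' morrison_velocity(0.2e-9, 0.2e-9, 0.045e-9)  # 0.375
morrison_velocity <- function(Et, I, Ki) {
  if (any(Et <= 0)) abort("Et must be > 0 (use the classical limit for Et = 0)")
  if (any(I < 0) || any(Ki < 0)) abort("I and Ki must be >= 0")
  s <- Et + I + Ki
  disc <- pmax(s^2 - 4 * Et * I, 0)
  v <- 1 - (s - sqrt(disc)) / (2 * Et)
  pmin(pmax(v, 0), 1)
}

#' Fit Ki(app) with the Morrison equation
#'
#' Single-parameter ordinary nonlinear least squares of [morrison_velocity()]
#' in Ki at fixed, known `Et`. With `fit_v0 = TRUE` a multiplicative scale is
#' floated as a nuisance parameter for series supplied as raw velocities
#' rather than pre-normalized vi/v0 ratios.
#'
#' @param series Tibble with `inhibitor_conc` (molar) and `vi_over_v0`.
#' @param Et Total active enzyme concentration (molar). If missing, taken
#'   from `attr(series, "Et")` or a constant `Et` column.
#' @param fit_v0 Float a v0 scale factor (default `FALSE`).
#' @return Object of class `morrison_fit` with `estimate` (Ki, molar), `se`,
#'   the fit and the data.
#' @export
fit_morrison_ki <- function(series, Et = NULL, fit_v0 = FALSE) {
  need <- c("inhibitor_conc", "vi_over_v0")
  if (!all(need %in% names(series)))
    abort(paste0("`series` needs columns: ", paste(need, collapse = ", ")))
  Et <- Et %||% attr(series, "Et") %||%
    (if ("Et" %in% names(series)) unique(series$Et)[1] else NULL)
  if (is.null(Et)) abort("supply `Et` (total active enzyme concentration)")
  if (length(unique(series$inhibitor_conc)) < 4 ||
      !any(series$inhibitor_conc == 0))
    abort("need >= 4 inhibitor concentrations including 0")
  if (all(series$vi_over_v0 > 0.95))
    abort("no measurable inhibition: Ki is not identifiable")
  if (any(series$vi_over_v0 < -0.05 | series$vi_over_v0 > 1.1))
    abort("vi/v0 outside [0, 1.05] beyond tolerance; check normalization")
  # I at half-inhibition estimates Ki + Et/2 for a tight binder
  ord <- arrange(series, .data$inhibitor_conc)
  i50 <- approx(ord$vi_over_v0, ord$inhibitor_conc, xout = 0.5,
                ties = mean)$y
  ki0 <- max(if (is.na(i50)) max(series$inhibitor_conc) / 4 else i50 - Et / 2,
             Et * 1e-3)
  dat <- mutate(series, Et = Et)
  fit <- if (fit_v0) {
    minpack.lm::nlsLM(
      vi_over_v0 ~ v0 * morrison_velocity(Et, inhibitor_conc, Ki),
      data = dat, start = list(Ki = ki0, v0 = 1),
      lower = c(0, 0.5), upper = c(Inf, 2),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  } else {
    minpack.lm::nlsLM(
      vi_over_v0 ~ morrison_velocity(Et, inhibitor_conc, Ki),
      data = dat, start = list(Ki = ki0), lower = 0,
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  structure(list(estimate = unname(coef(fit)["Ki"]),
                 se = sqrt(vcov(fit)["Ki", "Ki"]),
                 Et = Et, fit = fit, data = as_tibble(series),
                 model = "Morrison tight-binding"),
            class = "morrison_fit")
}

#' Interpolate analyte concentrations from a standard curve
#'
#' Linear interpolation of signals on a monotone standard curve. Signals
#' outside the standard range are flagged and return `NA` unless
#' `extrapolate = TRUE`.
#'
#' @param curve Tibble with `concentration` (ascending) and `signal`
#'   (monotone).
#' @param signals Numeric signals to convert.
#' @param extrapolate Allow linear extrapolation outside the standards
#'   (default `FALSE`).
#' @return Tibble `signal`, `concentration`, `out_of_range`.
#' @export
interpolate_standard_curve <- function(curve, signals, extrapolate = FALSE) {
  need <- c("concentration", "signal")
  if (!all(need %in% names(curve)))
    abort("`curve` needs columns `concentration` and `signal`")
  if (nrow(curve) < 2) abort("standard curve needs >= 2 points")
  if (is.unsorted(curve$concentration, strictly = TRUE))
    abort("standard concentrations must be strictly ascending")
  dsig <- diff(curve$signal)
  if (!(all(dsig > 0) || all(dsig < 0)))
    abort("standard curve signals are not monotone")
  rng <- range(curve$signal)
  oor <- signals < rng[1] | signals > rng[2]
  conc <- approx(curve$signal, curve$concentration, xout = signals,
                 rule = if (extrapolate) 2 else 1, ties = mean)$y
  if (extrapolate && any(oor)) {
    # rule = 2 clamps; do true linear extension from the terminal segments
    lo <- which(signals < rng[1]); hi <- which(signals > rng[2])
    slope_lo <- diff(curve$concentration[1:2]) / diff(curve$signal[1:2])
    nlast <- nrow(curve)
    slope_hi <- diff(curve$concentration[(nlast - 1):nlast]) /
      diff(curve$signal[(nlast - 1):nlast])
    conc[lo] <- curve$concentration[1] + (signals[lo] - curve$signal[1]) * slope_lo
    conc[hi] <- curve$concentration[nlast] +
      (signals[hi] - curve$signal[nlast]) * slope_hi
  }
  tibble(signal = signals, concentration = conc, out_of_range = oor)
}

#' @export
print.progress_fit <- function(x, ...) {
  cat(sprintf("<progress_fit> kcat/Km = %.4g M-1 s-1 (se %.3g), n = %d\n",
              x$estimate, x$se, nrow(x$data)))
  invisible(x)
}

#' @export
print.morrison_fit <- function(x, ...) {
  cat(sprintf("<morrison_fit> Ki(app) = %.4g M (se %.3g), Et = %.3g M, n = %d\n",
              x$estimate, x$se, x$Et, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_progress_kcat_km
#' @param x A `progress_fit` object.
#' @param ... Unused.
#' @export
tidy.progress_fit <- function(x, ...) {
  tibble(term = "kcat_km", estimate = x$estimate, std.error = x$se)
}

#' @rdname fit_morrison_ki
#' @param x A `morrison_fit` object.
#' @param ... Unused.
#' @export
tidy.morrison_fit <- function(x, ...) {
  est <- coef(x$fit)
  tibble(term = names(est), estimate = unname(est),
         std.error = sqrt(diag(vcov(x$fit))))
}

glance_nls <- function(x) {
  s <- summary(x$fit)
  tibble(sigma = s$sigma, df.residual = s$df[2], nobs = nrow(x$data),
         converged = x$fit$convInfo$isConv %||% TRUE)
}

#' @rdname fit_progress_kcat_km
#' @export
glance.progress_fit <- function(x, ...) glance_nls(x)

#' @rdname fit_morrison_ki
#' @export
glance.morrison_fit <- function(x, ...) glance_nls(x)

#' @rdname fit_progress_kcat_km
#' @param object A `progress_fit` object.
#' @export
autoplot.progress_fit <- function(object, ...) {
  grid <- tibble(
    time_s = seq(0, max(object$data$time_s), length.out = 200),
    enzyme_conc = object$data$enzyme_conc[1])
  grid$fraction <- progress_fraction(grid$enzyme_conc, grid$time_s, object$estimate)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_s, .data$fraction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "fraction cleaved",
                  subtitle = sprintf("kcat/Km = %.3g M⁻¹s⁻¹",
                                     object$estimate)) +
    ggplot2::theme_minimal()
}

#' @rdname fit_morrison_ki
#' @param object A `morrison_fit` object.
#' @export
autoplot.morrison_fit <- function(object, ...) {
  grid <- tibble(inhibitor_conc = seq(0, max(object$data$inhibitor_conc),
                                      length.out = 300))
  grid$vi_over_v0 <- morrison_velocity(object$Et, grid$inhibitor_conc,
                                       object$estimate)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$inhibitor_conc, .data$vi_over_v0)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "[inhibitor] (M)", y = "vi / v0",
                  subtitle = sprintf("Ki(app) = %.3g M", object$estimate)) +
    ggplot2::theme_minimal()
}
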