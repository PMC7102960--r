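# Two-state melting-curve analysis: linear folded/unfolded baselines,
# fraction-folded transformation and Tm at the 50%-folded crossing.

# centered running mean with shrinking windows at the edges
.running_mean <- function(x, k = 5L) {
  n <- length(x)
  h <- k %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, 0)
}

# global two-state van't Hoff fit with linear baselines; returns refined
# baseline coefficients (and the nuisance Tm/dH), or NULL when the
# optimisation fails or wanders outside the data range
.refine_baselines_global <- function(to, so, tm0, bf0, bu0) {
  R <- 0.0019872             # kcal mol^-1 K^-1
  model <- function(p) {
    tk <- to + 273.15
    th <- 1 / (1 + exp((-exp(p[2L]) / R) * (1 / tk - 1 / (p[1L] + 273.15))))
    th * (p[3L] + p[4L] * to) + (1 - th) * (p[5L] + p[6L] * to)
  }
  obj <- function(p) {
    r <- so - model(p)
    sum(r * r)
  }
  p0 <- c(tm0, log(45), bf0, bu0)
  fit <- tryCatch(
    stats::optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par))) return(NULL)
  p <- fit$par
  if (p[1L] < min(to) || p[1L] > max(to)) return(NULL)
  resid <- so - model(p)
  sst <- sum((so - mean(so))^2)
  list(bf = p[3:4], bu = p[5:6], tm = p[1L], dH = -exp(p[2L]),
       noise = stats::sd(resid),
       r2 = if (sst > 0) 1 - sum(resid^2) / sst else NA_real_)
}

#' Fit a two-state melting model to a melting curve
#'
#' Fits linear folded and unfolded baselines to the lowest and highest
#' `baseline_fraction` of the temperature span, converts the signal to a
#' fraction-folded curve
#' `theta(T) = (s_U(T) - s(T)) / (s_U(T) - s_F(T))` (clamped to `[0, 1]`),
#' and takes the melting temperature as the temperature at which
#' `theta = 0.5`, by linear interpolation between the bracketing points.
#' After the initial end-fraction baseline fit, the baselines are refined
#' by a global two-state van't Hoff least-squares fit (melting temperature,
#' enthalpy and both lines free), which removes the bias that the
#' transition tails impose on end-fraction line fits when the transition is
#' broad; Tm is still read off the empirical theta = 0.5 crossing.  When theta crosses 0.5 more than once the crossing
#' nearest the steepest part of the transition is used (with a warning).
#'
#' @param curve A data frame with numeric columns `temperature` (degrees
#'   Celsius, strictly monotone) and `signal` (e.g. molar ellipticity, any
#'   units), as produced by [simulate_melting_curve()] or
#'   [read_melting_csv()].  A `branch` attribute/column
#'   (`"heating"`/`"cooling"`) is carried through if present.
#' @param baseline_fraction Fraction of the temperature span used for each
#'   baseline fit, in `(0, 0.4]` (default 0.15).
#' @return An object of class `tm_fit` with components `tm`,
#'   `tm_uncertainty` (degrees Celsius), `folded_baseline` and
#'   `unfolded_baseline` (intercept/slope), `theta` (fraction folded per
#'   point), `branch`, `data`.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`.
#' @examples
#' cv <- simulate_melting_curve(tm = 40.8, dH = -45, noise_sd = 0.005,
#'                              seed = 1)
#' fit <- fit_two_state(cv)
#' coef(fit)["tm"]
#' @export
fit_two_state <- function(curve, baseline_fraction = 0.15) {
  stopifnot(is.data.frame(curve),
            all(c("temperature", "signal") %in% names(curve)))
  tt <- curve$temperature; ss <- curve$signal
  if (length(tt) < 10L) stop("melting curve needs at least 10 points")
  if (any(!is.finite(tt)) || any(!is.finite(ss))) {
    stop("non-finite values in melting curve")
  }
  dtt <- diff(tt)
  if (!(all(dtt > 0) || all(dtt < 0))) {
    stop("temperatures must be strictly monotone within a branch")
  }
  if (baseline_fraction <= 0 || baseline_fraction > 0.4) {
    stop("`baseline_fraction` must be in (0, 0.4]")
  }
  branch <- if (!is.null(curve$branch)) as.character(curve$branch[1L]) else {
    if (all(dtt > 0)) "heating" else "cooling"
  }
  span <- max(tt) - min(tt)
  o <- order(tt)
  to <- tt[o]; so <- ss[o]
  n <- length(to)
  # shared: given baseline lines, transform to fraction folded and locate
  # the theta = 0.5 crossing(s)
  crossing_from <- function(bf, bu, noise) {
    s_f <- bf[1L] + bf[2L] * to
    s_u <- bu[1L] + bu[2L] * to
    denom <- s_u - s_f
    if (all(abs(denom) < max(1e-8, 1e-6 * stats::sd(so)))) {
      stop("no transition in range: folded and unfolded baselines coincide")
    }
    theta_raw <- (s_u - so) / denom
    # short running mean suppresses point noise around the crossing (the
    # crossing location is unchanged for a transition antisymmetric in Tm)
    th <- .running_mean(theta_raw, 5L)
    d <- th - 0.5
    cross <- which(d[-1L] * d[-n] < 0 | d[-n] == 0)
    if (!length(cross)) {
      stop("no transition in range: theta never crosses 0.5")
    }
    tm_at <- vapply(cross, function(i) {
      if (d[i] == 0) return(to[i])
      to[i] + (0.5 - th[i]) * (to[i + 1L] - to[i]) / (th[i + 1L] - th[i])
    }, 0)
    pick <- 1L
    if (length(tm_at) > 1L) {
      slope <- abs(diff(th) / diff(to))
      steepest <- to[which.max(slope)] + diff(to)[which.max(slope)] / 2
      pick <- which.min(abs(tm_at - steepest))
    }
    list(bf = bf, bu = bu, theta_raw = theta_raw, th = th, denom = denom,
         tm = tm_at[pick], n_cross = length(tm_at), noise = noise)
  }
  # initial baselines from the extreme temperature fractions; also yields
  # the "no transition" error for degenerate input
  lo <- to <= min(to) + baseline_fraction * span
  hi <- to >= max(to) - baseline_fraction * span
  if (sum(lo) < 2L || sum(hi) < 2L) stop("too few baseline points")
  fit_f <- stats::lm(so[lo] ~ to[lo])
  fit_u <- stats::lm(so[hi] ~ to[hi])
  noise0 <- stats::sd(c(stats::residuals(fit_f), stats::residuals(fit_u)))
  res <- crossing_from(unname(stats::coef(fit_f)),
                       unname(stats::coef(fit_u)), noise0)
  # refine the baselines with a global two-state van't Hoff least-squares
  # fit (Tm, dH and both lines free); end-fraction line fits are biased by
  # the transition tails when the transition is broad.  Tm is still read
  # off the empirical theta = 0.5 crossing afterwards.
  refined <- .refine_baselines_global(to, so, res$tm, res$bf, res$bu)
  if (!is.null(refined)) {
    res <- tryCatch(crossing_from(refined$bf, refined$bu, refined$noise),
                    error = function(e) res)
  }
  if (res$n_cross > 1L) {
    warning(sprintf(paste0("theta crosses 0.5 %d times; using the crossing ",
                           "nearest the steepest slope (%.1f degC)"),
                    res$n_cross, res$tm))
  }
  tm <- res$tm
  bf <- res$bf; bu <- res$bu
  theta_o <- pmin(1, pmax(0, res$theta_raw))
  theta <- theta_o[order(o)]   # back to input point order
  # uncertainty: baseline residual noise propagated through the local slope
  amp <- mean(abs(res$denom))
  i0 <- which.min(abs(to - tm))
  i1 <- max(1L, i0 - 1L); i2 <- min(n, i0 + 1L)
  local_slope <- abs((res$th[i2] - res$th[i1]) / (to[i2] - to[i1]))
  tm_unc <- if (is.finite(local_slope) && local_slope > 0 && amp > 0) {
    (res$noise / amp) / local_slope
  } else {
    NA_real_
  }
  # a failed global two-state fit, or one explaining less than half the
  # variance, marks the curve as unreliable
  poor_fit <- is.null(refined) ||
    (is.finite(refined$r2) && refined$r2 < 0.5)
  if (!is.finite(tm_unc) || res$noise > 0.25 * amp || poor_fit) {
    warning("low signal-to-noise ratio; the Tm estimate is unreliable")
    tm_unc <- Inf
  }
  out <- list(tm = unname(tm), tm_uncertainty = unname(tm_unc),
              folded_baseline = c(intercept = bf[1L], slope = bf[2L]),
              unfolded_baseline = c(intercept = bu[1L], slope = bu[2L]),
              theta = theta, branch = branch,
              baseline_fraction = baseline_fraction,
              data = data.frame(temperature = tt, signal = ss))
  class(out) <- "tm_fit"
  out
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("Two-state melting fit (%s branch)\n", x$branch))
  cat(sprintf("  Tm = %.1f degC (theta = 0.5 crossing; +/- %.2f degC)\n",
              x$tm, x$tm_uncertainty))
  invisible(x)
}

#' @export
#' @method summary tm_fit
summary.tm_fit <- function(object, ...) {
  cat(sprintf("Two-state melting fit (%s branch, %d points)\n",
              object$branch, nrow(object$data)))
  cat(sprintf("  folded baseline:   %.4g %+.4g * T\n",
              object$folded_baseline[1L], object$folded_baseline[2L]))
  cat(sprintf("  unfolded baseline: %.4g %+.4g * T\n",
              object$unfolded_baseline[1L], object$unfolded_baseline[2L]))
  cat(sprintf("  baseline fraction: %.2f of the temperature span per end\n",
              object$baseline_fraction))
  cat(sprintf("  Tm = %.2f degC, uncertainty %.2f degC\n", object$tm,
              object$tm_uncertainty))
  invisible(object)
}

#' @export
#' @method coef tm_fit
coef.tm_fit <- function(object, ...) {
  c(tm = object$tm,
    folded.intercept = unname(object$folded_baseline[1L]),
    folded.slope = unname(object$folded_baseline[2L]),
    unfolded.intercept = unname(object$unfolded_baseline[1L]),
    unfolded.slope = unname(object$unfolded_baseline[2L]))
}

#' Predict the fraction folded at new temperatures
#'
#' Linear interpolation of the fitted fraction-folded curve.
#'
#' @param object A `tm_fit`.
#' @param temperature Temperatures (degrees Celsius) at which to evaluate.
#' @param ... Unused.
#' @return Numeric vector of fraction folded values.
#' @export
#' @method predict tm_fit
predict.tm_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) return(object$theta)
  stats::approx(object$data$temperature, object$theta, xout = temperature,
                rule = 2L)$y
}

#' @export
#' @method plot tm_fit
plot.tm_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  tt <- x$data$temperature
  graphics::plot(tt, x$data$signal, xlab = "temperature (degC)",
                 ylab = "signal", pch = 20, cex = 0.6, ...)
  graphics::abline(x$folded_baseline[1L], x$folded_baseline[2L],
                   col = "steelblue", lty = 2)
  graphics::abline(x$unfolded_baseline[1L], x$unfolded_baseline[2L],
                   col = "firebrick", lty = 2)
  graphics::plot(tt, x$theta, xlab = "temperature (degC)",
                 ylab = "fraction folded", pch = 20, cex = 0.6,
                 ylim = c(0, 1))
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$tm, lty = 3)
  graphics::mtext(sprintf("Tm = %.1f degC", x$tm), side = 3, line = 0.2,
                  cex = 0.8)
  invisible(x)
}

#' Consensus Tm from heating and cooling branches
#'
#' The reported melting temperature is the mean of the unfolding (heating)
#' and refolding (cooling) estimates and its uncertainty their mean
#' deviation: `((tm_h + tm_c) / 2, |tm_h - tm_c| / 2)`.
#'
#' @param heating,cooling `tm_fit` objects or numeric Tm values.
#' @return Named numeric vector `c(tm = , dev = )`.
#' @examples
#' tm_consensus(41.3, 40.3)  # 40.8 +/- 0.5
#' @export
tm_consensus <- function(heating, cooling) {
  th <- if (inherits(heating, "tm_fit")) heating$tm else as.numeric(heating)
  tc <- if (inherits(cooling, "tm_fit")) cooling$tm else as.numeric(cooling)
  stopifnot(is.finite(th), is.finite(tc))
  c(tm = (th + tc) / 2, dev = abs(th - tc) / 2)
}

#' Melting-temperature difference between a variant and a reference
#'
#' @param tm_variant,tm_reference Tm values in degrees Celsius (numeric or
#'   `tm_fit`).
#' @return Signed difference `tm_variant - tm_reference`.
#' @examples
#' delta_tm(66.2, 40.8)  # +25.4
#' @export
delta_tm <- function(tm_variant, tm_reference) {
  tv <- if (inherits(tm_variant, "tm_fit")) tm_variant$tm else {
    as.numeric(tm_variant)
  }
  tr <- if (inherits(tm_reference, "tm_fit")) tm_reference$tm else {
    as.numeric(tm_reference)
  }
  stopifnot(is.finite(tv), is.finite(tr))
  tv - tr
}

#' Read a melting curve from CSV
#'
#' Expects columns `temperature_C` (or `temperature`) and `signal`, with an
#' optional `branch` column (`"heating"`/`"cooling"`).
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `temperature`, `signal` and optionally
#'   `branch`.
#' @export
read_melting_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("temperature_C", "temperature"), names(df))[1L]
  if (is.na(tcol) || !"signal" %in% names(df)) {
    stop("CSV must have columns temperature_C (or temperature) and signal")
  }
  out <- data.frame(temperature = as.numeric(df[[tcol]]),
                    signal = as.numeric(df$signal))
  if ("branch" %in% names(df)) out$branch <- df$branch
  out
}
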