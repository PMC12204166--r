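#' Fit an exponential recoil to a post-ablation retraction curve
#'
#' Retraction of an epithelium after laser ablation follows Kelvin-Voigt
#' dynamics, so length decays exponentially to the rest length:
#' \deqn{L(t) = L_{rest} + l_{stretch}\, e^{-t/\tau}.}
#' The fit returns the rest length, the recoverable stretch, the
#' characteristic time tau, and the derived initial recoil velocity
#' \code{stretch/tau} — the three standard ablation proxies for
#' tension/viscosity (initial recoil), viscosity/stiffness (tau) and
#' tension/stiffness (total recoil).
#'
#' Nonlinear least squares by Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}), initialized from the curve itself: rest =
#' last observed length, stretch = first minus last, tau = time to reach
#' 63\% of the total drop; tau is bounded in (0, 10x the observation
#' window].
#'
#' @param curve a data frame with columns \code{t_min} (time since ablation,
#'   min; a \code{t_s} column in seconds is accepted and converted) and
#'   \code{length_um}. Displacement series can be fitted the same way (the
#'   rest level is then an offset).
#' @param noise_floor total drop (um) below which the curve is declared
#'   flat ("no recoil") instead of fitted; default 1e-3 um.
#' @return An object of class \code{"recoil_fit"}: a list with
#'   \code{rest_length}, \code{stretch_length}, \code{tau_fit},
#'   \code{initial_recoil}, \code{rss}, \code{r_squared}, \code{n},
#'   \code{converged}, \code{no_recoil}, \code{monotone}.
#' @export
fit_exponential_recoil <- function(curve, noise_floor = 1e-3) {
  curve <- as.data.frame(curve)
  if (!"t_min" %in% names(curve) && "t_s" %in% names(curve))
    curve$t_min <- curve$t_s / 60
  if (!all(c("t_min", "length_um") %in% names(curve)))
    stop("curve needs columns t_min (or t_s) and length_um")
  t <- curve$t_min
  y <- curve$length_um
  if (length(t) < 5L) stop("need at least 5 samples to fit a recoil")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (abs(t[1]) > 1e-9) stop("retraction times must start at 0")

  # rough monotone-trend check on a smoothed copy
  k <- min(5L, length(y))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys <- ys[!is.na(ys)]
  monotone <- length(ys) < 2L || (utils::tail(ys, 1) - ys[1]) <= 0

  # initialize from short head/tail averages so single noisy samples
  # cannot push the starting values outside the parameter bounds
  rest0 <- mean(utils::tail(y, 3))
  ls0 <- mean(utils::head(y, 3)) - rest0
  if (ls0 <= noise_floor) {
    return(structure(
      list(rest_length = mean(y), stretch_length = 0, tau_fit = NA_real_,
           initial_recoil = 0, rss = sum((y - mean(y))^2), r_squared = 0,
           n = length(y), converged = TRUE, no_recoil = TRUE,
           monotone = monotone),
      class = "recoil_fit"))
  }
  window <- diff(range(t))
  drop63 <- y[1] - 0.632 * ls0
  tau0 <- t[which(y <= drop63)[1]]
  if (is.na(tau0) || tau0 <= 0) tau0 <- window / 5
  tau_starts <- unique(pmin(pmax(c(tau0, window / 5, window / 20, window),
                                 1e-3), 10 * window))
  fit <- NULL
  last_err <- NULL
  for (tau_try in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        length_um ~ rest + ls * exp(-t_min / tau),
        data = data.frame(t_min = t, length_um = y),
        start = list(rest = max(rest0, 0), ls = max(ls0, noise_floor),
                     tau = tau_try),
        lower = c(rest = 0, ls = 0, tau = 1e-6),
        upper = c(rest = Inf, ls = Inf, tau = 10 * window),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
    last_err <- fit
  }
  if (inherits(fit, "error"))
    stop("exponential recoil fit did not converge: ",
         conditionMessage(last_err),
         " (n = ", length(y), ", total drop = ", signif(ls0, 4), " um)")
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(rest_length = unname(cf["rest"]),
         stretch_length = unname(cf["ls"]),
         tau_fit = unname(cf["tau"]),
         initial_recoil = unname(cf["ls"] / cf["tau"]),
         rss = rss, r_squared = 1 - rss / tss, n = length(y),
         converged = TRUE, no_recoil = FALSE, monotone = monotone),
    class = "recoil_fit")
}

#' @export
print.recoil_fit <- function(x, ...) {
  if (x$no_recoil) {
    cat("Recoil fit: flat curve (no recoil); rest =",
        signif(x$rest_length, 5), "um\n")
  } else {
    cat(sprintf(
      "Recoil fit (n = %d): rest %.4g um + stretch %.4g um * exp(-t/%.4g min)\n",
      x$n, x$rest_length, x$stretch_length, x$tau_fit))
    cat(sprintf("  initial recoil %.4g um/min, R^2 = %.4f\n",
                x$initial_recoil, x$r_squared))
  }
  invisible(x)
}

#' Discriminate material class from recoil ratio versus cell length
#'
#' Regresses the per-cell recoil ratio (recoil length over pre-ablation
#' length) on pre-ablation length. The sign of the dependence separates the
#' three material classes: increasing for an elastic Kelvin-Voigt cell
#' (fixed rest length, growing stretch), decreasing for a Maxwell-like cell
#' (saturated stretch, growing viscous flow), constant for the ratchet
#' model (every added unit carries the same stretch fraction).
#'
#' Classification uses the two-sided t test on the OLS slope: significantly
#' positive at \code{alpha} gives \code{"elastic-increasing"},
#' significantly negative \code{"maxwell-decreasing"}, otherwise
#' \code{"plastic-constant"}.
#'
#' Records with negative recoil (cell longer after relaxation than before
#' ablation) are flagged as wound-response candidates and excluded from the
#' regression, as is any record with a TRUE \code{exclude} column.
#'
#' @param records data frame with columns \code{length_before_um} and
#'   either \code{ratio} or \code{length_after_um}; optional logical
#'   \code{exclude}.
#' @param alpha significance level for the slope test (default 0.05).
#' @return An object of class \code{"discrimination_result"}: slope
#'   (1/um), \code{slope_se}, \code{p_value}, \code{classification},
#'   \code{n}, \code{n_excluded}, \code{mean_ratio}, \code{alpha}.
#' @export
recoil_ratio_regression <- function(records, alpha = 0.05) {
  records <- as.data.frame(records)
  if (!"length_before_um" %in% names(records))
    stop("records need a length_before_um column")
  if (!"ratio" %in% names(records)) {
    if (!"length_after_um" %in% names(records))
      stop("records need either a ratio or a length_after_um column")
    records$ratio <- (records$length_before_um - records$length_after_um) /
      records$length_before_um
  }
  drop <- records$ratio < 0
  if ("exclude" %in% names(records))
    drop <- drop | (records$exclude %in% TRUE)
  n_excluded <- sum(drop)
  if (n_excluded > 0)
    message(n_excluded,
            " record(s) excluded (negative recoil / wound-response flag)")
  records <- records[!drop, , drop = FALSE]
  if (nrow(records) < 6L)
    stop("need at least 6 usable records for the discrimination regression")
  lr <- range(records$length_before_um)
  if (lr[2] / lr[1] < 1.5)
    stop(sprintf(
      "degenerate length range %.3g-%.3g um (< 1.5-fold): slope not identifiable",
      lr[1], lr[2]))
  fit <- stats::lm(ratio ~ length_before_um, data = records)
  sm <- summary(fit)$coefficients
  slope <- sm["length_before_um", "Estimate"]
  se <- sm["length_before_um", "Std. Error"]
  p <- sm["length_before_um", "Pr(>|t|)"]
  classification <- if (p < alpha && slope > 0) "elastic-increasing"
    else if (p < alpha && slope < 0) "maxwell-decreasing"
    else "plastic-constant"
  structure(
    list(slope = slope, slope_se = se, p_value = p,
         classification = classification, n = nrow(records),
         n_excluded = n_excluded, mean_ratio = mean(records$ratio),
         alpha = alpha),
    class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "Recoil-ratio discrimination (n = %d, %d excluded): %s\n",
    x$n, x$n_excluded, x$classification))
  cat(sprintf("  slope %.4g +/- %.4g per um (p = %.3g, alpha = %g); mean ratio %.3f\n",
              x$slope, x$slope_se, x$p_value, x$alpha, x$mean_ratio))
  invisible(x)
}

#' Per-embryo elongation speed by linear regression
#'
#' Ordinary least-squares slope of length on time within a time window, one
#' regression per embryo — the standard way to summarize steady tissue
#' elongation.
#'
#' @param data data frame with columns \code{time_min}, \code{length_um}
#'   and optionally \code{embryo_id} (a single embryo is assumed when
#'   absent).
#' @param window numeric length-2 vector of times (min) delimiting the
#'   regression window (inclusive); default: full range.
#' @return A tibble with one row per embryo: \code{embryo_id},
#'   \code{speed_um_per_min}, \code{se}, \code{adj_r_squared}, \code{n}.
#' @export
elongation_speed <- function(data, window = NULL) {
  data <- as.data.frame(data)
  if (!all(c("time_min", "length_um") %in% names(data)))
    stop("data needs columns time_min and length_um")
  if (!"embryo_id" %in% names(data)) data$embryo_id <- "embryo_1"
  if (is.null(window)) window <- range(data$time_min)
  if (length(window) != 2L || window[1] >= window[2])
    stop("'window' must be c(t_lo, t_hi) with t_lo < t_hi")
  sub <- data[data$time_min >= window[1] & data$time_min <= window[2], ]
  if (nrow(sub) == 0L)
    stop("window [", window[1], ", ", window[2], "] contains no data")
  per_embryo <- lapply(split(sub, sub$embryo_id), function(d) {
    if (nrow(d) < 4L)
      stop("embryo ", d$embryo_id[1], ": need >= 4 points in the window")
    fit <- stats::lm(length_um ~ time_min, data = d)
    sm <- suppressWarnings(summary(fit))  # noiseless input: perfect fit
    tibble::tibble(
      embryo_id = d$embryo_id[1],
      speed_um_per_min = unname(stats::coef(fit)["time_min"]),
      se = sm$coefficients["time_min", "Std. Error"],
      adj_r_squared = sm$adj.r.squared,
      n = nrow(d))
  })
  do.call(rbind, per_embryo)
}

# 5PL curve value: y = lower + (upper - lower) / (1 + 10^(b*(xmid - x)))^s
logistic5 <- function(x, lower, upper, xmid, b, s) {
  lower + (upper - lower) / (1 + 10^(b * (xmid - x)))^s
}

# analytic derivative of the 5PL
logistic5_deriv <- function(x, lower, upper, xmid, b, s) {
  u <- 10^(b * (xmid - x))
  (upper - lower) * s * b * log(10) * u / (1 + u)^(s + 1)
}

#' Five-parameter logistic fit and maximum closure speed
#'
#' Fits the generalized (asymmetric) five-parameter logistic
#' \deqn{y = lower + \frac{upper - lower}{(1 + 10^{b (x_{mid} - x)})^s}}
#' to a monotone closure series and reports the maximum absolute rate of
#' change, the standard summary for, e.g., the fastest short-axis closure
#' speed of the amnioserosa. The maximum slope has the closed form
#' \deqn{|dy/dx|_{max} = (upper - lower)\,|b|\,\ln 10\,/\,(1 + 1/s)^{s+1}}
#' attained at \eqn{x = x_{mid} + \log_{10}(s)/b}; at \eqn{s = 1} this
#' reduces to the symmetric 4PL with inflection at \eqn{x_{mid}}.
#'
#' @param curve data frame with columns \code{x} and \code{y} (e.g. time in
#'   min and short-axis length in um).
#' @return An object of class \code{"logistic5_fit"}: \code{lower},
#'   \code{upper}, \code{xmid}, \code{b} (slope factor, 1/x-unit), \code{s}
#'   (asymmetry exponent), \code{max_speed} (|y-units| per x-unit),
#'   \code{x_at_max}, \code{rss}, \code{n}, \code{s_at_bound}.
#' @export
fit_logistic5_max_speed <- function(curve) {
  curve <- as.data.frame(curve)
  if (!all(c("x", "y") %in% names(curve)))
    stop("curve needs columns x and y")
  x <- curve$x; y <- curve$y
  if (length(x) < 8L) stop("need at least 8 points for a 5PL fit")
  if (stats::sd(y) == 0)
    stop("degenerate (constant) series: 5PL not identifiable")

  lower0 <- min(y); upper0 <- max(y)
  increasing <- stats::cor(x, y) >= 0
  xmid0 <- stats::approx(y, x, xout = (lower0 + upper0) / 2, ties = mean)$y
  if (is.na(xmid0)) xmid0 <- stats::median(x)
  b0 <- (if (increasing) 1 else -1) * 4 / (diff(range(x)) * log(10))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ logistic5(x, lower, upper, xmid, b, s),
      data = data.frame(x = x, y = y),
      start = list(lower = lower0, upper = upper0, xmid = xmid0,
                   b = b0, s = 1),
      lower = c(lower = -Inf, upper = -Inf, xmid = -Inf, b = -Inf,
                s = 1e-3),
      upper = c(lower = Inf, upper = Inf, xmid = Inf, b = Inf, s = 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("5PL fit did not converge: ", conditionMessage(fit))
  cf <- as.list(stats::coef(fit))
  if (cf$upper <= cf$lower)
    stop("5PL fit degenerate: upper asymptote <= lower asymptote")
  s_at_bound <- cf$s <= 2e-3 || cf$s >= 0.99e3
  if (s_at_bound)
    warning("asymmetry exponent pinned at its bound (s = ",
            signif(cf$s, 3), "); treat the asymmetry as unidentified")
  max_speed <- (cf$upper - cf$lower) * abs(cf$b) * log(10) /
    (1 + 1 / cf$s)^(cf$s + 1)
  x_at_max <- cf$xmid + log10(cf$s) / cf$b
  structure(
    list(lower = cf$lower, upper = cf$upper, xmid = cf$xmid, b = cf$b,
         s = cf$s, max_speed = max_speed, x_at_max = x_at_max,
         rss = sum(stats::resid(fit)^2), n = length(x),
         s_at_bound = s_at_bound),
    class = "logistic5_fit")
}

#' @export
print.logistic5_fit <- function(x, ...) {
  cat(sprintf(
    "5PL fit (n = %d): asymptotes [%.4g, %.4g], xmid %.4g, b %.4g, s %.4g\n",
    x$n, x$lower, x$upper, x$xmid, x$b, x$s))
  cat(sprintf("  max |dy/dx| = %.4g at x = %.4g\n", x$max_speed, x$x_at_max))
  invisible(x)
}
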