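#' Centre a peak series about zero
#'
#' Subtracts the sample mean so the autoregressive model is fit to the data
#' pattern rather than its level; the mean is stored so the original scale
#' can be reconstructed exactly.
#'
#' @param x numeric vector or peak series of length >= 3.
#' @return centred numeric vector with attribute `"mean"`.
#' @export
demean <- function(x) {
  y <- peak_values(x)
  if (length(y) < 3) stop("series must have length >= 3")
  m <- base::mean(y)
  structure(y - m, mean = m)
}

#' Characteristic roots of an AR(2) model
#'
#' Solves the characteristic equation \eqn{m^2 - \phi_1 m - \phi_2 = 0},
#' giving \eqn{m_{1,2} = (\phi_1 \pm \sqrt{\phi_1^2 + 4\phi_2})/2}.  The
#' process is stationary iff both moduli are below one; a negative
#' discriminant yields a complex-conjugate pair (pseudo-periodic
#' fluctuation).
#'
#' @param phi1,phi2 scalar AR coefficients.
#' @return list with `roots` (complex length-2 vector, largest modulus
#'   first) and `moduli`.
#' @examples
#' characteristic_roots(1.5, -0.56)$roots  # 0.8 and 0.7
#' @export
characteristic_roots <- function(phi1, phi2) {
  disc <- phi1^2 + 4 * phi2
  m <- (phi1 + c(1, -1) * sqrt(as.complex(disc))) / 2
  m <- m[order(-Mod(m))]
  list(roots = m, moduli = Mod(m))
}

#' Fit an autoregressive model to a gait peak series
#'
#' The central model fit: a second-order (by default) autoregressive model
#' \deqn{y_t = \delta + \phi_1 y_{t-1} + \phi_2 y_{t-2} + \epsilon_t}
#' fit to a vertical-GRF peak time series by conditional least squares — the
#' series is centred about its mean (so \eqn{\delta = 0} by construction)
#' and \eqn{y_t} is regressed on its `order` lags without intercept.
#' \eqn{\delta} is reported as \eqn{\bar y (1 - \sum_i \phi_i)} for
#' completeness.  The innovation variance is RSS / (n_effective - order).
#' For `order = 2` the characteristic roots, stationarity-triangle
#' membership and centroid distance (the gait-stability statistic) are
#' attached.
#'
#' A Yule-Walker fit (solving the Toeplitz system of biased
#' autocorrelations) is available via `method = "yw"`; coefficient standard
#' errors come from the usual least-squares covariance.
#'
#' @param x numeric vector or a [build_peak_series()] object (length >=
#'   order + 10).
#' @param order model order p (default 2).
#' @param method `"cls"` (conditional least squares, default) or `"yw"`
#'   (Yule-Walker).
#' @return an object of class `"gait_ar"`; see Details.  Methods:
#'   [coef()], [fitted()], [residuals()], [predict.gait_ar()],
#'   [simulate.gait_ar()], [summary.gait_ar()], [plot.gait_ar()].
#' @details The returned list carries `coefficients` (phi1..phip), `mean`,
#'   `delta`, `sigma2`, `se`, `residuals` and `fitted` (length n - p, on the
#'   original scale for `fitted`), `roots` and `moduli`, `stationary`,
#'   `distance` (centroid distance, order 2 only), `n`, `n_effective`,
#'   `series`, `limb`, `condition`.
#' @examples
#' y <- simulate_ar2_series(0.5, 0.2, 2000, noise_sd = 1, seed = 1)
#' fit <- gait_ar(y)
#' coef(fit)
#' @export
gait_ar <- function(x, order = 2L, method = c("cls", "yw")) {
  method <- match.arg(method)
  y <- peak_values(x)
  n <- length(y)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (n < order + 10L)
    stop("series too short: need at least order + 10 = ", order + 10L,
         " values, got ", n)
  yc <- demean(y)
  m <- attr(yc, "mean")
  if (sum(yc^2) == 0) stop("constant series: AR fit is undefined")

  X <- sapply(seq_len(order), function(k) yc[(order + 1 - k):(n - k)])
  if (order == 1L) X <- matrix(X, ncol = 1L)
  yy <- yc[(order + 1):n]
  n_eff <- length(yy)

  if (method == "cls") {
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-14) stop("singular design: cannot fit AR model")
    phi <- drop(solve(XtX, crossprod(X, yy)))
  } else {
    r <- correlogram(y, max_lag = order)$acf  # r[1] = 1
    R <- stats::toeplitz(r[seq_len(order)])
    phi <- drop(solve(R, r[2:(order + 1)]))
  }
  names(phi) <- paste0("phi", seq_len(order))

  fit_c <- drop(X %*% phi)
  res <- yy - fit_c
  rss <- sum(res^2)
  sigma2 <- rss / (n_eff - order)
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)
  names(se) <- names(phi)

  if (order == 2L) {
    rt <- characteristic_roots(phi[1], phi[2])
  } else {
    # roots of m^p - phi1 m^{p-1} - ... - phip
    rr <- polyroot(c(-rev(unname(phi)), 1))
    rt <- list(roots = rr[order(-Mod(rr))], moduli = sort(Mod(rr), decreasing = TRUE))
  }

  out <- list(
    coefficients = phi,
    order = order,
    mean = m,
    delta = m * (1 - sum(phi)),
    sigma2 = sigma2,
    se = se,
    residuals = res,
    fitted = fit_c + m,
    roots = rt$roots,
    moduli = rt$moduli,
    stationary = max(rt$moduli) < 1,
    distance = if (order == 2L) centroid_distance(phi[[1]], phi[[2]]) else NA_real_,
    n = n,
    n_effective = n_eff,
    method = method,
    series = y,
    limb = if (inherits(x, "peak_series")) x$limb else NA_character_,
    condition = if (inherits(x, "peak_series")) x$condition else NA_character_,
    call = match.call()
  )
  class(out) <- "gait_ar"
  out
}

#' @export
print.gait_ar <- function(x, digits = 4, ...) {
  cat("AR(", x$order, ") gait model (", x$method, " fit, n = ", x$n,
      ")\n", sep = "")
  print(round(x$coefficients, digits))
  cat("innovation variance:", signif(x$sigma2, digits),
      " series mean:", signif(x$mean, digits), "\n")
  if (x$order == 2L)
    cat(if (x$stationary) "stationary" else "NOT stationary",
        "; distance from triangle centroid (0, -1/3):",
        signif(x$distance, digits), "\n")
  invisible(x)
}

#' @export
coef.gait_ar <- function(object, ...) object$coefficients

#' @export
residuals.gait_ar <- function(object, ...) object$residuals

#' @export
fitted.gait_ar <- function(object, ...) object$fitted

#' Summary of a fitted gait AR model
#'
#' Adds coefficient standard errors, characteristic roots and moduli,
#' triangle membership/distance and the Anderson-Darling residual normality
#' check to the basic fit printout.
#'
#' @param object a [gait_ar()] fit.
#' @param ... unused.
#' @export
summary.gait_ar <- function(object, ...) {
  ad <- ad_normality(object$residuals)
  out <- list(fit = object, ad = ad,
              coef_table = cbind(estimate = object$coefficients,
                                 se = object$se))
  class(out) <- "summary.gait_ar"
  out
}

#' @export
print.summary.gait_ar <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficients:\n")
  print(round(x$coef_table, digits))
  cat("\nCharacteristic roots (moduli):",
      paste(sprintf("%.4f%+.4fi (%.4f)", Re(x$fit$roots), Im(x$fit$roots),
                    x$fit$moduli), collapse = ", "), "\n")
  cat("Anderson-Darling residual normality: A2* =",
      signif(x$ad$adjusted, digits),
      if (x$ad$reject) "(normality rejected at alpha = 0.05)"
      else "(normality not rejected at alpha = 0.05)", "\n")
  invisible(x)
}

#' Forecast from a fitted gait AR model
#'
#' With `n.ahead = 0` (default) returns the in-sample one-step fitted
#' values; otherwise iterates the fitted recursion forward from the end of
#' the series, with innovations set to zero (the conditional mean
#' forecast).
#'
#' @param object a [gait_ar()] fit.
#' @param n.ahead number of steps to forecast.
#' @param ... unused.
#' @return fitted values or a numeric forecast vector of length `n.ahead`.
#' @export
predict.gait_ar <- function(object, n.ahead = 0, ...) {
  if (n.ahead == 0) return(object$fitted)
  p <- object$order
  phi <- object$coefficients
  yc <- object$series - object$mean
  buf <- c(tail(yc, p), numeric(n.ahead))
  for (h in seq_len(n.ahead))
    buf[p + h] <- sum(phi * buf[(p + h - 1):(h)])
  buf[(p + 1):(p + n.ahead)] + object$mean
}

#' Simulate new series from a fitted gait AR model
#'
#' Draws fresh realisations of the fitted process (coefficients, mean and
#' innovation variance taken from the fit) using the same stationary-start,
#' burn-in scheme as [simulate_ar2_series()].
#'
#' @param object a [gait_ar()] fit (order 2).
#' @param nsim number of series to simulate.
#' @param seed integer seed.
#' @param n length of each simulated series (default: length of the
#'   original).
#' @param ... unused.
#' @return a numeric vector (`nsim = 1`) or a matrix with `nsim` columns.
#' @export
simulate.gait_ar <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (object$order != 2L)
    stop("simulate() is implemented for order-2 fits")
  if (is.null(n)) n <- object$n
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  sims <- sapply(seq_len(nsim), function(i) {
    simulate_ar2_series(object$coefficients[[1]], object$coefficients[[2]],
                        n = n, noise_sd = sqrt(object$sigma2),
                        mean = object$mean, seed = derive_seed(seed, i))
  })
  if (nsim == 1) drop(sims) else sims
}

#' Plot a fitted gait AR model
#'
#' Two panels: the peak series with the one-step model reconstruction
#' overlaid, and the coefficient point on the stationarity triangle with
#' the centroid marked.
#'
#' @param x a [gait_ar()] fit.
#' @param ... passed to the series plot.
#' @export
plot.gait_ar <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  idx <- seq_along(x$series)
  plot(idx, x$series, type = "l", xlab = "peak index",
       ylab = "peak magnitude (BW)", main = "peak series vs AR fit", ...)
  lines(idx[-seq_len(x$order)], x$fitted, col = "red")
  v <- triangle_vertices()
  plot(NA, xlim = c(-2.2, 2.2), ylim = c(-1.2, 1.2),
       xlab = expression(phi[1]), ylab = expression(phi[2]),
       main = "stationarity triangle")
  polygon(v[, 1], v[, 2])
  ctr <- triangle_centroid()
  points(ctr[1], ctr[2], pch = 3, cex = 1.5)
  if (x$order == 2L)
    points(x$coefficients[1], x$coefficients[2], pch = 19, col = "red")
  invisible(x)
}
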