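#' Autocorrelation and partial autocorrelation of a peak series
#'
#' Box-Jenkins model identification tools.  The ACF uses the biased
#' estimator \eqn{r_k = \sum_{t=k+1}^n (y_t-\bar y)(y_{t-k}-\bar y) /
#' \sum_t (y_t-\bar y)^2} (divide-by-n convention), which guarantees a valid
#' correlation sequence; the PACF is obtained from it by the
#' Durbin-Levinson recursion.  For an AR(p) process the PACF cuts off after
#' lag p, which is how the model order is identified (see
#' [select_order()]).
#'
#' @param x numeric vector or [build_peak_series()] object.
#' @param max_lag largest lag (default `min(20, n - 1)`); must be `< n`.
#' @return an object of class `"correlogram"`: a list with `lag` (0..L),
#'   `acf` (length L+1, `acf[1]` is lag 0 = 1), `pacf` (lags 1..L),
#'   `n`, and `bound` = 1.96/sqrt(n), the approximate white-noise 95%
#'   cutoff.
#' @examples
#' y <- simulate_ar2_series(0.5, 0.2, 500, seed = 1)
#' cg <- correlogram(y)
#' cg$pacf[1:3]
#' @export
correlogram <- function(x, max_lag = NULL) {
  y <- peak_values(x)
  n <- length(y)
  if (is.null(max_lag)) max_lag <- min(20L, n - 1L)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  if (max_lag < 1L) stop("max_lag must be >= 1")
  yc <- y - base::mean(y)
  denom <- sum(yc^2)
  if (denom == 0) stop("constant series: autocorrelation is undefined")
  r <- vapply(0:max_lag, function(k) {
    sum(yc[(k + 1):n] * yc[1:(n - k)]) / denom
  }, numeric(1))
  structure(list(lag = 0:max_lag, acf = r,
                 pacf = durbin_levinson(r)$pacf,
                 n = n, bound = 1.96 / sqrt(n)),
            class = "correlogram")
}

# Durbin-Levinson recursion on a correlation sequence r[1]=rho0=1,
# r[2]=rho1, ... Returns the pacf (phi_kk) and the final AR coefficient
# vector at each order.
durbin_levinson <- function(r) {
  L <- length(r) - 1L
  pacf <- numeric(L)
  phi_prev <- numeric(0)
  for (k in seq_len(L)) {
    if (k == 1L) {
      a <- r[2]
      phi <- a
    } else {
      num <- r[k + 1] - sum(phi_prev * r[k:2])
      den <- 1 - sum(phi_prev * r[2:k])
      a <- num / den
      phi <- c(phi_prev - a * rev(phi_prev), a)
    }
    pacf[k] <- a
    phi_prev <- phi
  }
  list(pacf = pacf, phi = phi_prev)
}

#' @export
print.correlogram <- function(x, ...) {
  cat("Correlogram (n =", x$n, ", 95% white-noise bound +/-",
      signif(x$bound, 3), ")\n")
  df <- data.frame(lag = x$lag[-1], acf = signif(x$acf[-1], 3),
                   pacf = signif(x$pacf, 3))
  print(head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("... (", nrow(df) - 10, " more lags)\n", sep = "")
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$lag[-1], x$acf[-1], type = "h", xlab = "lag", ylab = "ACF",
       ylim = c(-1, 1), ...)
  abline(h = c(-1, 1) * x$bound, lty = 2, col = "blue")
  abline(h = 0)
  plot(x$lag[-1], x$pacf, type = "h", xlab = "lag", ylab = "PACF",
       ylim = c(-1, 1), ...)
  abline(h = c(-1, 1) * x$bound, lty = 2, col = "blue")
  abline(h = 0)
  invisible(x)
}

#' Recommend an AR order from the PACF cutoff
#'
#' Implements the identification rule used for gait peak series: the
#' recommended order is the largest lag `k <= max_order` whose partial
#' autocorrelation exceeds the 1.96/sqrt(n) white-noise bound.  Order 0 is
#' returned for white noise.  The returned record keeps the ACF/PACF and
#' bound so the choice is auditable.
#'
#' @inheritParams correlogram
#' @param max_order largest order considered; must be below `n/4`.
#' @return a list with `order`, `pacf`, `acf`, `bound`, `n`.
#' @export
select_order <- function(x, max_order = 10L) {
  y <- peak_values(x)
  n <- length(y)
  if (max_order >= n / 4) stop("max_order must be below n/4")
  cg <- correlogram(y, max_lag = max_order)
  exceed <- which(abs(cg$pacf) > cg$bound)
  list(order = if (length(exceed)) max(exceed) else 0L,
       pacf = cg$pacf, acf = cg$acf, bound = cg$bound, n = n)
}

# Accept numeric vectors or peak_series objects everywhere a series is
# expected.
peak_values <- function(x) {
  if (inherits(x, "peak_series")) return(x$value)
  if (!is.numeric(x)) stop("expected a numeric series or a peak_series")
  as.numeric(x)
}
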