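#' Simulate a stationary AR(2) series with a prescribed mean
#'
#' Generates \eqn{y_t = \delta + \phi_1 y_{t-1} + \phi_2 y_{t-2} +
#' \epsilon_t} with Gaussian innovations, where the intercept
#' \eqn{\delta = \mu (1 - \phi_1 - \phi_2)} is chosen so the process mean is
#' `mean`.  A burn-in (default 500 samples, never below 200) is discarded so
#' the returned stretch is effectively drawn from the stationary
#' distribution.  Coefficients outside the stationarity triangle are
#' rejected.
#'
#' @param phi1,phi2 AR coefficients; must lie strictly inside the
#'   stationarity triangle (see [is_stationary()]).
#' @param n length of the returned series (>= 3).
#' @param noise_sd innovation standard deviation (>= 0).
#' @param mean stationary process mean.
#' @param seed integer seed; identical arguments give identical output.
#' @param burn_in burn-in length to discard (minimum 200 enforced).
#' @return numeric vector of length `n`.
#' @examples
#' y <- simulate_ar2_series(0.5, 0.2, n = 1000, noise_sd = 1, seed = 1)
#' @export
simulate_ar2_series <- function(phi1, phi2, n, noise_sd = 1, mean = 0,
                                seed = NULL, burn_in = 500) {
  stopifnot(is.numeric(phi1), is.numeric(phi2), length(phi1) == 1L,
            length(phi2) == 1L)
  if (!isTRUE(as.logical(is_stationary(phi1, phi2))))
    stop("(phi1, phi2) = (", phi1, ", ", phi2,
         ") violates AR(2) stationarity: the point is not strictly inside ",
         "the triangle with vertices (-2,-1), (2,-1), (0,1)")
  if (n < 3) stop("n must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  burn_in <- max(200L, as.integer(burn_in))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  ntot <- n + burn_in
  eps <- rnorm(ntot, 0, noise_sd)
  delta <- mean * (1 - phi1 - phi2)
  y <- numeric(ntot)
  # start at the process mean; burn-in washes out the initial condition
  y[1] <- mean + eps[1]
  y[2] <- delta + phi1 * y[1] + phi2 * mean + eps[2]
  for (t in 3:ntot)
    y[t] <- delta + phi1 * y[t - 1] + phi2 * y[t - 2] + eps[t]
  y[(burn_in + 1):ntot]
}
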