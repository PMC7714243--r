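# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# AR(2) stationarity by brute force: both characteristic roots of
# m^2 - phi1 m - phi2 inside the unit circle (polyroot, not the triangle
# inequalities).
oracle_max_root_modulus <- function(phi1, phi2) {
  max(Mod(polyroot(c(-phi2, -phi1, 1))))
}

# Strict stationarity: a unit root (boundary) is NOT stationary; the small
# tolerance keeps grid points that sit exactly on a triangle edge from being
# misclassified by root-finding round-off.
oracle_is_stationary <- function(phi1, phi2) {
  oracle_max_root_modulus(phi1, phi2) < 1 - 1e-9
}

# One-way ANOVA F by spreadsheet-style sums of squares.
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); N <- length(all)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Brute-force scan for interior local maxima/minima of a sampled curve.
oracle_local_maxima <- function(y) {
  idx <- 2:(length(y) - 1)
  idx[y[idx] > y[idx - 1] & y[idx] >= y[idx + 1]]
}
oracle_local_minima <- function(y) {
  idx <- 2:(length(y) - 1)
  idx[y[idx] < y[idx - 1] & y[idx] <= y[idx + 1]]
}

# Direct-summation lag-k sample autocorrelation (biased, divide by n).
oracle_acf <- function(y, k) {
  n <- length(y); yc <- y - mean(y)
  sum(yc[(k + 1):n] * yc[1:(n - k)]) / sum(yc^2)
}

# Quiet-standing style constant-force recording builder.
make_recording <- function(force_left, fs = 1200, body_weight = 700,
                           force_right = NULL, units = "N") {
  force <- list(left = force_left)
  if (!is.null(force_right)) force$right <- force_right
  structure(list(time = (seq_along(force_left) - 1) / fs, force = force,
                 sampling_rate = fs, body_weight = body_weight,
                 units = units, metadata = list()),
            class = "grf_recording")
}
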