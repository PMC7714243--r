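#' Anderson-Darling normality check for model residuals
#'
#' Composite-normality Anderson-Darling test (mean and variance estimated
#' from the sample).  The raw statistic
#' \deqn{A^2 = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)\,[\ln F(z_{(i)}) +
#'   \ln(1 - F(z_{(n+1-i)}))]}
#' is computed on the standardized order statistics and adjusted for sample
#' size as \eqn{A^{2*} = A^2 (1 + 4/n - 25/n^2)}; normality is rejected at
#' \eqn{\alpha = 0.05} when \eqn{A^{2*}} exceeds the critical value 0.752.
#' Histogram bin counts of the residuals are returned for the usual visual
#' check that residuals are centred on zero.
#'
#' @param x numeric vector of residuals (length >= 8, non-constant).
#' @param alpha significance level; only 0.05 is supported (critical value
#'   0.752).
#' @return list of class `"ad_normality"` with `statistic` (raw A2),
#'   `adjusted`, `critical`, `reject` (logical), `n`, and `histogram`
#'   (counts and breaks).
#' @examples
#' set.seed(1)
#' ad_normality(rnorm(200))$reject
#' @export
ad_normality <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 residuals")
  s <- sd(x)
  if (s == 0) stop("residuals have zero variance")
  if (!isTRUE(all.equal(alpha, 0.05)))
    stop("only alpha = 0.05 (critical value 0.752) is supported")
  z <- sort((x - base::mean(x)) / s)
  p <- pnorm(z)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  A2 <- -n - base::mean((2 * seq_len(n) - 1) * (log(p) + log(1 - rev(p))))
  adj <- A2 * (1 + 4 / n - 25 / n^2)
  h <- hist(x, plot = FALSE)
  structure(list(statistic = A2, adjusted = adj, critical = 0.752,
                 reject = adj > 0.752, n = n,
                 histogram = list(counts = h$counts, breaks = h$breaks)),
            class = "ad_normality")
}

#' @export
print.ad_normality <- function(x, ...) {
  cat("Anderson-Darling composite normality test\n")
  cat("  A2 =", signif(x$statistic, 4), " adjusted A2* =",
      signif(x$adjusted, 4), " (critical 0.752 at alpha = 0.05)\n")
  cat("  normality", if (x$reject) "REJECTED" else "not rejected", "\n")
  invisible(x)
}
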