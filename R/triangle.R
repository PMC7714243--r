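#' The AR(2) stationarity triangle
#'
#' An AR(2) process \eqn{y_t = \delta + \phi_1 y_{t-1} + \phi_2 y_{t-2} +
#' \epsilon_t} is stationary exactly when the coefficient point
#' \eqn{(\phi_1, \phi_2)} lies strictly inside the triangle with vertices
#' (-2, -1), (2, -1) and (0, 1), equivalently when both characteristic roots
#' have modulus below one.  `triangle_vertices()` returns the vertices,
#' `triangle_centroid()` the centroid (0, -1/3) — the arithmetic mean of the
#' vertices — from which gait-stability distances are measured.
#'
#' @return `triangle_vertices()`: a 3 x 2 numeric matrix with columns
#'   `phi1`, `phi2`. `triangle_centroid()`: a named numeric vector
#'   `c(phi1 = 0, phi2 = -1/3)`.
#' @examples
#' triangle_centroid()
#' colMeans(triangle_vertices())
#' @export
triangle_vertices <- function() {
  matrix(c(-2, 2, 0, -1, -1, 1), ncol = 2,
         dimnames = list(NULL, c("phi1", "phi2")))
}

#' @rdname triangle_vertices
#' @export
triangle_centroid <- function() {
  c(phi1 = 0, phi2 = -1 / 3)
}

#' Stationarity test for AR(2) coefficients
#'
#' Tests strict membership of \eqn{(\phi_1, \phi_2)} in the stationarity
#' triangle: \eqn{\phi_1 + \phi_2 < 1}, \eqn{\phi_2 - \phi_1 < 1} and
#' \eqn{|\phi_2| < 1}.  Points within `tol` of an edge are flagged as
#' boundary cases and reported as not stationary (a unit root is not a
#' stationary process).
#'
#' @param phi1,phi2 numeric vectors of AR coefficients (recycled).
#' @param tol boundary tolerance (default 1e-9).
#' @return a logical vector, with attribute `"boundary"` marking points
#'   within `tol` of an edge.
#' @examples
#' is_stationary(0, 0)       # interior
#' is_stationary(1.2, -0.1)  # phi1 + phi2 > 1: explosive
#' @export
is_stationary <- function(phi1, phi2, tol = 1e-9) {
  n <- max(length(phi1), length(phi2))
  phi1 <- rep_len(phi1, n)
  phi2 <- rep_len(phi2, n)
  e1 <- 1 - (phi1 + phi2)   # > 0 inside
  e2 <- 1 - (phi2 - phi1)   # > 0 inside
  e3 <- 1 - abs(phi2)       # > 0 inside
  boundary <- pmin(abs(e1), abs(e2), abs(e3)) < tol
  inside <- e1 > tol & e2 > tol & e3 > tol
  structure(inside, boundary = boundary)
}

#' Distance of AR(2) coefficients from the triangle centroid
#'
#' The gait-stability statistic: Euclidean distance of the coefficient point
#' \eqn{(\phi_1, \phi_2)} from the stationarity-triangle centroid (0, -1/3).
#' Larger distances place the fitted model nearer the triangle edge, i.e. a
#' less stable gait pattern.  Defined for points outside the triangle too.
#'
#' @inheritParams is_stationary
#' @return numeric vector of distances (>= 0).
#' @examples
#' centroid_distance(0, -1/3)  # 0 at the centroid
#' centroid_distance(1, -1/3)  # 1
#' @export
centroid_distance <- function(phi1, phi2) {
  sqrt(phi1^2 + (phi2 + 1 / 3)^2)
}

#' Assemble labelled triangle points from fitted coefficients
#'
#' Builds the per-series analysis table used for plotting and for the group
#' comparison: each row carries the AR coefficients, the strict stationarity
#' flag (with boundary annotation) and the centroid distance.
#'
#' @param phi1,phi2 numeric vectors of coefficients.
#' @param participant,limb,condition optional label vectors (recycled).
#' @return a data.frame of class `"triangle_points"` with columns
#'   `participant`, `limb`, `condition`, `phi1`, `phi2`, `inside`,
#'   `boundary`, `distance`.
#' @seealso [render_triangle()]
#' @export
triangle_points <- function(phi1, phi2, participant = NA, limb = NA,
                            condition = NA) {
  n <- max(length(phi1), length(phi2))
  ins <- is_stationary(phi1, phi2)
  out <- data.frame(
    participant = rep_len(participant, n),
    limb = rep_len(limb, n),
    condition = rep_len(condition, n),
    phi1 = rep_len(phi1, n),
    phi2 = rep_len(phi2, n),
    inside = as.logical(ins),
    boundary = attr(ins, "boundary"),
    distance = centroid_distance(rep_len(phi1, n), rep_len(phi2, n)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("triangle_points", "data.frame")
  out
}

#' Plot the stationarity triangle with fitted coefficient points
#'
#' Draws the triangle edges, marks the centroid (0, -1/3) with a cross, and
#' overlays the supplied points with one glyph/colour per condition plus a
#' legend.  Written to `out_path` as SVG or PNG (chosen by file extension).
#'
#' @param points a `triangle_points` data.frame (non-empty).
#' @param out_path output file ending in `.svg` or `.png`.
#' @param zoom optional `c(xlim_lo, xlim_hi, ylim_lo, ylim_hi)` window; by
#'   default the full triangle (plus margin) is shown.
#' @param width,height device size in inches.
#' @return `out_path`, invisibly.
#' @export
render_triangle <- function(points, out_path, zoom = NULL,
                            width = 6, height = 5) {
  if (!inherits(points, "data.frame") || nrow(points) == 0L)
    stop("'points' must be a non-empty triangle_points data.frame")
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "svg") {
    svg(out_path, width = width, height = height)
  } else if (ext == "png") {
    png(out_path, width = width, height = height, units = "in", res = 150)
  } else stop("out_path must end in .svg or .png")
  on.exit(dev.off(), add = TRUE)

  v <- triangle_vertices()
  cond <- factor(ifelse(is.na(points$condition), "series", points$condition))
  pal <- c("#C2185B", "#1565C0", "#2E7D32", "#E65100", "#6A1B9A",
           "#00838F", "#555555")
  cols <- pal[((as.integer(cond) - 1L) %% length(pal)) + 1L]
  pchs <- c(4, 1, 2, 15, 17, 19, 8)[((as.integer(cond) - 1L) %% 7L) + 1L]
  if (is.null(zoom)) {
    xlim <- c(-2.2, 2.2); ylim <- c(-1.2, 1.2)
  } else {
    xlim <- zoom[1:2]; ylim <- zoom[3:4]
  }
  plot(NA, xlim = xlim, ylim = ylim, xlab = expression(phi[1]),
       ylab = expression(phi[2]), main = "AR(2) stationarity triangle")
  polygon(v[, 1], v[, 2], border = "black", lwd = 1.5)
  ctr <- triangle_centroid()
  points(ctr[1], ctr[2], pch = 3, cex = 1.6, lwd = 2)
  points(points$phi1, points$phi2, col = cols, pch = pchs, cex = 1.1)
  legend("topright", legend = levels(cond), bty = "n",
         col = pal[((seq_along(levels(cond)) - 1L) %% length(pal)) + 1L],
         pch = c(4, 1, 2, 15, 17, 19, 8)[((seq_along(levels(cond)) - 1L) %% 7L) + 1L])
  invisible(out_path)
}
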