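# Silverman's rule-of-thumb bandwidth per dimension (as in stats::bw.nrd0),
# with a positive fallback when the spread collapses.
silverman_bw <- function(x) {
  h <- tryCatch(stats::bw.nrd0(x), error = function(e) NA_real_)
  if (!is.finite(h) || h <= 0) {
    s <- stats::sd(x)
    h <- if (is.finite(s) && s > 0) 0.9 * s * length(x)^(-1 / 5) else NA_real_
  }
  h
}

is_collapsed <- function(x) {
  s <- stats::sd(x)
  !is.finite(s) || s <= 1e-10 * max(1, abs(mean(x)))
}

# Continuous product-Gaussian kernel density of points (x, y) with
# bandwidths h = c(hx, hy), evaluated at (px, py).
kde2_eval <- function(x, y, h, px, py) {
  vapply(seq_along(px), function(i)
    mean(stats::dnorm((px[i] - x) / h[1]) * stats::dnorm((py[i] - y) / h[2])),
    numeric(1)) / (h[1] * h[2])
}

kde1_eval <- function(x, h, px) {
  vapply(px, function(p) mean(stats::dnorm((p - x) / h)), numeric(1)) / h
}

#' Two-dimensional kernel density estimate of a bootstrap cloud
#'
#' Estimates the joint density of a two-column cloud with a smooth
#' product-Gaussian kernel (per-dimension bandwidth by Silverman's rule
#' unless given), evaluates it over a regular grid covering the cloud extent
#' padded by `pad` bandwidths, and converts bin densities to bin masses
#' normalized to total mass one.
#'
#' If one column has (numerically) zero spread -- a collapsed cloud, e.g.
#' when the hyper-flexible interpolant serves as help model and its cost is
#' identically zero -- the estimate degrades to a one-dimensional density on
#' the varying column, with a warning of class `bootgof_collapsed_cloud`.
#' Zero spread in both columns is an error.
#'
#' @param cloud a `boot_cloud` with exactly two columns, or a two-column
#'   numeric matrix.
#' @param grid_n number of grid points per dimension (default 128).
#' @param bw optional length-2 bandwidths overriding Silverman's rule.
#' @param pad grid padding in bandwidths beyond the cloud extent.
#' @return An object of class `density_grid`: list with bin-center
#'   coordinates `gx`, `gy`, per-bin `density` and probability `mass`
#'   (summing to 1), `bw`, the cloud points, and `collapsed`
#'   (0 = none, 1 or 2 = that column is constant).
#' @examples
#' z <- matrix(rnorm(400), ncol = 2)
#' g <- kde2d_cloud(z, grid_n = 32)
#' sum(g$mass)  # 1
#' @export
kde2d_cloud <- function(cloud, grid_n = 128L, bw = NULL, pad = 3) {
  X <- if (inherits(cloud, "boot_cloud")) cloud$stats else as.matrix(cloud)
  if (ncol(X) != 2L) stop("kde2d_cloud needs a two-column cloud")
  x <- X[, 1]; y <- X[, 2]
  cx <- is_collapsed(x); cy <- is_collapsed(y)
  if (cx && cy)
    stop("cloud has zero spread in both columns: no density to estimate")
  collapsed <- if (cx) 1L else if (cy) 2L else 0L
  if (collapsed) {
    warning(structure(
      class = c("bootgof_collapsed_cloud", "warning", "condition"),
      list(message = paste0("cloud column ", collapsed,
        " is constant; degrading to a 1D density on the other column"),
        call = sys.call(-1))))
    v <- if (cx) y else x
    h <- if (is.null(bw)) silverman_bw(v) else bw[if (cx) 2 else 1]
    g <- seq(min(v) - pad * h, max(v) + pad * h, length.out = grid_n)
    dens <- kde1_eval(v, h, g)
    mass <- dens * (g[2] - g[1])
    mass <- mass / sum(mass)
    return(structure(list(gx = if (cx) unique(x) else g,
                          gy = if (cx) g else unique(y),
                          density = dens, mass = mass,
                          bw = h, x = x, y = y, collapsed = collapsed),
                     class = "density_grid"))
  }
  h <- if (is.null(bw)) c(silverman_bw(x), silverman_bw(y)) else rep_len(bw, 2)
  gx <- seq(min(x) - pad * h[1], max(x) + pad * h[1], length.out = grid_n)
  gy <- seq(min(y) - pad * h[2], max(y) + pad * h[2], length.out = grid_n)
  B <- length(x)
  Kx <- stats::dnorm(outer(gx, x, "-") / h[1])   # grid_n x B
  Ky <- stats::dnorm(outer(gy, y, "-") / h[2])
  dens <- (Kx %*% t(Ky)) / (B * h[1] * h[2])
  mass <- dens * (gx[2] - gx[1]) * (gy[2] - gy[1])
  mass <- mass / sum(mass)
  structure(list(gx = gx, gy = gy, density = dens, mass = mass, bw = h,
                 x = x, y = y, collapsed = 0L),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  if (x$collapsed) {
    cat("<density_grid> collapsed cloud (column ", x$collapsed,
        " constant): 1D density, ", length(x$mass), " bins\n", sep = "")
  } else {
    cat("<density_grid> ", length(x$gx), " x ", length(x$gy),
        " grid, bandwidths (", format(signif(x$bw[1], 4)), ", ",
        format(signif(x$bw[2], 4)), ")\n", sep = "")
  }
  invisible(x)
}

#' Two-dimensional highest-density-region p-value
#'
#' The density at the observed statistic pair, `rho(Z)`, is evaluated with
#' the continuous kernel sum (not grid interpolation); the p-value is the
#' total probability mass of grid bins whose density is strictly below
#' `rho(Z)` -- the mass outside the equidensity contour through the observed
#' point. Like a two-tailed test, this rejects in every low-density
#' direction, including "surprisingly good" fits.
#'
#' For a collapsed (effectively one-dimensional) cloud the same construction
#' is applied to the 1D density on the varying column.
#'
#' @param grid a [kde2d_cloud()] result.
#' @param observed length-2 numeric: the observed statistic pair.
#' @return p-value in `[0, 1]`.
#' @export
p_value_2d <- function(grid, observed) {
  stopifnot(inherits(grid, "density_grid"), all(is.finite(observed)))
  if (grid$collapsed) {
    v <- if (grid$collapsed == 1L) grid$y else grid$x
    obs <- observed[if (grid$collapsed == 1L) 2L else 1L]
    rho_z <- kde1_eval(v, grid$bw, obs)
  } else {
    rho_z <- kde2_eval(grid$x, grid$y, grid$bw, observed[1], observed[2])
  }
  sum(grid$mass[grid$density < rho_z])
}

#' Geometry diagnostic of a two-column cloud
#'
#' Reports the column correlation, the principal-axis angle (degrees,
#' relative to the first column's axis after standardizing by column sd is
#' NOT applied -- the angle is in the raw statistic plane), and collapse
#' flags. A cloud lying parallel to an axis (correlation near 0, or one
#' column constant) gains nothing from a joint 2D analysis; a tilted cloud
#' is the configuration where the 2D and two-model tests add power.
#'
#' @param cloud a `boot_cloud` or two-column matrix.
#' @return list of class `cloud_geometry` with `correlation`, `angle_deg`,
#'   `collapsed` (logical per column), `advice`.
#' @export
cloud_geometry <- function(cloud) {
  X <- if (inherits(cloud, "boot_cloud")) cloud$stats else as.matrix(cloud)
  if (ncol(X) != 2L) stop("cloud_geometry needs a two-column cloud")
  collapsed <- c(is_collapsed(X[, 1]), is_collapsed(X[, 2]))
  if (any(collapsed)) {
    cor_xy <- NA_real_
    angle <- if (collapsed[1]) 90 else 0
  } else {
    cor_xy <- stats::cor(X[, 1], X[, 2])
    ev <- eigen(stats::cov(X), symmetric = TRUE)$vectors[, 1]
    angle <- atan2(ev[2], ev[1]) * 180 / pi
    if (angle > 90) angle <- angle - 180
    if (angle <= -90) angle <- angle + 180
  }
  advice <- if (any(collapsed))
    "cloud collapsed to a line: all information is in one dimension; a 2D/help-model analysis cannot add power"
  else if (is.finite(cor_xy) && abs(cor_xy) < 0.1)
    "cloud lies parallel to the axes: little benefit expected from a joint 2D analysis"
  else
    "cloud is tilted away from the axes: a joint 2D (or LHR) analysis can add power"
  structure(list(correlation = cor_xy, angle_deg = angle,
                 collapsed = collapsed, advice = advice),
            class = "cloud_geometry")
}

#' @export
print.cloud_geometry <- function(x, ...) {
  cat("<cloud_geometry> correlation = ", format(signif(x$correlation, 4)),
      ", principal angle = ", format(signif(x$angle_deg, 4)), " deg",
      if (any(x$collapsed)) paste0(", collapsed column(s): ",
                                   paste(which(x$collapsed), collapse = ", "))
      else "", "\n  ", x$advice, "\n", sep = "")
  invisible(x)
}

#' Plot a cloud with its density contours and the observed point
#'
#' @param x a [kde2d_cloud()] grid; @param observed optional length-2
#'   observed statistic pair drawn as a filled square; @param ... passed to
#'   [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.density_grid <- function(x, observed = NULL, ...) {
  if (x$collapsed) {
    v <- if (x$collapsed == 1L) x$y else x$x
    g <- if (x$collapsed == 1L) x$gy else x$gx
    graphics::plot(g, x$density, type = "l",
                   xlab = "statistic", ylab = "density", ...)
    graphics::rug(v)
  } else {
    graphics::plot(x$x, x$y, pch = 1, col = "darkgreen",
                   xlab = "statistic 1", ylab = "statistic 2", ...)
    graphics::contour(x$gx, x$gy, x$density, add = TRUE, col = "grey40")
    if (!is.null(observed))
      graphics::points(observed[1], observed[2], pch = 15, col = "red",
                       cex = 1.4)
  }
  invisible(x)
}
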