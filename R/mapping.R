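## Thin-plate spline radial basis U(r) = r^2 log r (0 at r = 0).
tps_basis <- function(r) ifelse(r > 0, r^2 * log(r), 0)

## Cell-centred grid coordinates over an extent.
grid_centers <- function(n, extent) {
  w <- diff(extent)
  extent[1] + (2 * seq_len(n) - 1) / (2 * n) * w
}

#' Thin-plate-spline surface through electrode values
#'
#' Fits the classic thin-plate spline f(x, y) = a0 + a1 x + a2 y +
#' sum_i w_i U(||p - p_i||), U(r) = r^2 log r, through the supplied points
#' (exact interpolation at the default `lambda = 0`) and evaluates it on a
#' cell-centred regular grid over the map extent. The spline reproduces
#' affine fields exactly and passes through every data point.
#'
#' @param x,y Point coordinates (mm); typically the 7 electrode centers.
#' @param values Value at each point (e.g. per-electrode learnability).
#' @param grid_n Grid resolution per axis (default 7 x 7).
#' @param extent `c(min, max)` of both axes in mm (default the 2 mm map).
#' @param lambda Smoothing parameter (0 = exact interpolation).
#' @return A `learnability_map`: list with `grid` (matrix, rows = y
#'   descending from rostral to caudal, columns = x left to right), `gx`,
#'   `gy` (cell-centre coordinates), and the fitted coefficients.
#' @export
tps_surface <- function(x, y, values, grid_n = 7, extent = c(-1, 1),
                        lambda = 0) {
  n <- length(x)
  stopifnot(length(y) == n, length(values) == n, n >= 3)
  pts <- cbind(x, y)
  if (anyDuplicated(pts)) stop("duplicate points")
  if (qr(cbind(1, pts))$rank < 3) stop("collinear point configuration")

  D <- as.matrix(stats::dist(pts))
  K <- tps_basis(D) + diag(lambda, n)
  P <- cbind(1, pts)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(values, 0, 0, 0)
  coef <- solve(A, rhs)
  w <- coef[seq_len(n)]
  a <- coef[n + 1:3]

  gx <- grid_centers(grid_n, extent)
  gy <- rev(grid_centers(grid_n, extent))  # rostral (y+) on top
  grid <- matrix(0, grid_n, grid_n, dimnames = list(y = sprintf("%.3f", gy),
                                                    x = sprintf("%.3f", gx)))
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      r <- sqrt((gx[j] - x)^2 + (gy[i] - y)^2)
      grid[i, j] <- a[1] + a[2] * gx[j] + a[3] * gy[i] + sum(w * tps_basis(r))
    }
  }
  structure(list(grid = grid, gx = gx, gy = gy,
                 weights = w, affine = a, points = pts, values = values),
            class = "learnability_map")
}

#' Evaluate a fitted thin-plate spline at arbitrary points
#'
#' @param map A `learnability_map` from [tps_surface()].
#' @param x,y Coordinates (mm).
#' @return Numeric vector of surface values.
#' @export
tps_predict <- function(map, x, y) {
  vapply(seq_along(x), function(k) {
    r <- sqrt((x[k] - map$points[, 1])^2 + (y[k] - map$points[, 2])^2)
    map$affine[1] + map$affine[2] * x[k] + map$affine[3] * y[k] +
      sum(map$weights * tps_basis(r))
  }, 0)
}

#' Align per-animal surfaces and stack them into cohort maps
#'
#' Each animal's electrode coordinates are translated by its measured
#' array shift (um, converted to mm) before interpolation, so that
#' surfaces are expressed in a common brainstem frame; electrodes pushed
#' off the map extent are clipped to the border with a warning. The
#' aligned surfaces are then z-stacked: the cohort mean map is the
#' per-cell mean of the per-animal mean surfaces, the cross-animal SEM map
#' is their per-cell SD / sqrt(n), and when per-animal SEM values are
#' supplied their aligned surfaces are averaged the same way.
#'
#' @param per_animal A list; each element a list with `points` (data frame
#'   `x`, `y`, `value` and optionally `sem`) and `shift`
#'   (`c(lateral_um, rostrocaudal_um)`).
#' @param grid_n,extent,lambda Passed to [tps_surface()].
#' @return A list: `mean` (cohort mean map), `sem_across` (cross-animal
#'   SEM map), `mean_sem` (average of per-animal SEM surfaces, or `NULL`),
#'   `n_animals`.
#' @export
align_and_stack <- function(per_animal, grid_n = 7, extent = c(-1, 1),
                            lambda = 0) {
  stopifnot(length(per_animal) >= 1)
  fit_one <- function(an, col) {
    x <- an$points$x + an$shift[1] / 1000
    y <- an$points$y + an$shift[2] / 1000
    if (any(x < extent[1] | x > extent[2] | y < extent[1] | y > extent[2])) {
      warning("shift moves electrode(s) off the map extent; clipping")
      x <- pmin(pmax(x, extent[1]), extent[2])
      y <- pmin(pmax(y, extent[1]), extent[2])
    }
    tps_surface(x, y, an$points[[col]], grid_n, extent, lambda)$grid
  }
  means <- lapply(per_animal, fit_one, col = "value")
  n <- length(means)
  stack <- simplify2array(means)
  mean_map <- apply(stack, 1:2, mean)
  sem_map <- if (n > 1) apply(stack, 1:2, stats::sd) / sqrt(n) else
    mean_map * 0
  mean_sem <- NULL
  if (all(vapply(per_animal, function(a) "sem" %in% names(a$points), TRUE))) {
    sems <- lapply(per_animal, fit_one, col = "sem")
    mean_sem <- apply(simplify2array(sems), 1:2, mean)
  }
  list(mean = mean_map, sem_across = sem_map, mean_sem = mean_sem,
       n_animals = n)
}
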