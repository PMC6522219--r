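#' Point pattern in a polygonal region
#'
#' @param points two-column matrix/data.frame of (x, y) in µm; all
#'   points must lie inside the region (even-odd rule, edges inside).
#' @param region a [polygon_region()].
#' @return object of class `point_pattern` with `points`, `region`,
#'   `n` and `lambda` (points/µm²).
#' @export
point_pattern <- function(points, region) {
  pts <- as.matrix(points)
  if (length(pts) == 0L) pts <- matrix(numeric(0), ncol = 2L)
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  if (nrow(pts) && !all(in_region(pts[, 1L], pts[, 2L], region)))
    stop("all points must lie inside the region", call. = FALSE)
  A <- region_area(region)
  structure(list(points = pts, region = region, n = nrow(pts),
                 lambda = nrow(pts) / A, area = A),
            class = "point_pattern")
}

#' Edge-corrected neighbourhood density N(r)
#'
#' `N(r) = (1/Np) sum_i sum_{j != i} f(i, j, r)` with
#' `f = 2 pi d(i,j) / C_in` when `d(i,j) <= r` and 0 otherwise, where
#' `C_in` is the arclength of the circle of radius `d(i,j)` centred on
#' point `i` that lies inside the region — the isotropic edge
#' correction that reweights pairs whose circles are cut by the region
#' boundary. Pairs with `C_in = 0` are excluded with a warning.
#'
#' @param pattern a [point_pattern()].
#' @param r radii (µm, > 0, increasing); vectorized.
#' @return N(r) values on `r`.
#' @export
edge_corrected_density <- function(pattern, r) {
  stopifnot(inherits(pattern, "point_pattern"), all(r > 0),
            !is.unsorted(r))
  res <- .ripley_nr_cpp(pattern$points[, 1L], pattern$points[, 2L],
                        pattern$region[, 1L], pattern$region[, 2L],
                        as.double(r))
  if (res$excluded > 0L)
    warning(res$excluded, " pairs with zero in-region arclength excluded",
            call. = FALSE)
  res$N
}

#' Edge-corrected Ripley curve L(r) - r
#'
#' `K(r) = N(r) / lambda` and `L(r) - r = sqrt(K(r) / pi) - r`. Under
#' complete spatial randomness the curve stays at 0 for all radii;
#' positive values indicate clustering at that scale, negative values
#' regularity.
#'
#' @param pattern a [point_pattern()].
#' @param radii positive increasing radius grid (µm).
#' @return object of class `ripley_curve`: data.frame with `r`, `N`,
#'   `K`, `L_minus_r`.
#' @export
ripley_l_curve <- function(pattern, radii) {
  N <- edge_corrected_density(pattern, radii)
  K <- N / pattern$lambda
  out <- data.frame(r = radii, N = N, K = K,
                    L_minus_r = sqrt(K / pi) - radii)
  class(out) <- c("ripley_curve", "data.frame")
  out
}

#' CSR envelope for the Ripley curve
#'
#' Simulates complete spatial randomness with the observed point count
#' in the same region and returns pointwise quantiles of `L(r) - r`,
#' the reference band against which clustering is judged.
#'
#' @param region a [polygon_region()].
#' @param n_points points per simulated pattern.
#' @param radii radius grid (µm).
#' @param n_sims number of simulations (>= 20).
#' @param probs quantiles of the band (default 2.5% and 97.5%).
#' @param seed integer seed.
#' @return data.frame with `r`, `lo`, `hi`, `mean`.
#' @export
csr_envelope <- function(region, n_points, radii, n_sims = 100L,
                         probs = c(0.025, 0.975), seed = NULL) {
  stopifnot(n_sims >= 20L)
  curves <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      p <- point_pattern(runif_in_region(n_points, region), region)
      ripley_l_curve(p, radii)$L_minus_r
    }, numeric(length(radii)))
  })
  data.frame(r = radii,
             lo = apply(curves, 1L, stats::quantile, probs[1L]),
             hi = apply(curves, 1L, stats::quantile, probs[2L]),
             mean = rowMeans(curves))
}

#' Subsampled Ripley curves
#'
#' Repeatedly subsamples the detections uniformly without replacement
#' (all of them when the pattern is smaller than `n_points`), computes
#' the Ripley curve per draw, and returns the pointwise mean and SD —
#' the uncertainty convention for localization-microscopy patterns
#' whose detection counts vary enormously between cells.
#'
#' @param pattern a [point_pattern()].
#' @param radii radius grid (µm).
#' @param n_points detections per draw (default 25000).
#' @param n_draws number of draws (default 100).
#' @param seed integer seed.
#' @return list with `mean`, `sd` (per radius), `radii`, `n_draws`.
#' @export
subsample_detections <- function(pattern, radii, n_points = 25000L,
                                 n_draws = 100L, seed = NULL) {
  curves <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      k <- min(n_points, pattern$n)
      pick <- sample.int(pattern$n, k)
      p <- point_pattern(pattern$points[pick, , drop = FALSE],
                         pattern$region)
      ripley_l_curve(p, radii)$L_minus_r
    }, numeric(length(radii)))
  })
  list(radii = radii, mean = rowMeans(curves),
       sd = apply(curves, 1L, stats::sd), n_draws = n_draws)
}

#' @export
plot.ripley_curve <- function(x, ...) {
  graphics::plot(x$r, x$L_minus_r, type = "l", xlab = "r (um)",
                 ylab = "L(r) - r", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
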