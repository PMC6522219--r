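#' Polygonal region
#'
#' Construct a validated closed simple polygon used for nuclei,
#' compartments and nucleoli. Coordinates are in micrometres, origin at
#' the image top-left with y increasing downward. Containment uses the
#' even-odd rule; points exactly on an edge count as inside. This
#' tie-break is applied consistently by every containment test in the
#' package.
#'
#' @param vertices two-column numeric matrix (or data.frame) of x, y
#'   vertex coordinates in µm, in order, not repeating the first vertex.
#' @return an object of class `polygon_region`: the vertex matrix with
#'   columns `x`, `y`.
#' @examples
#' sq <- polygon_region(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' region_area(sq)
#' @export
polygon_region <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L)
    stop("a polygon needs >= 3 (x, y) vertices", call. = FALSE)
  storage.mode(v) <- "double"
  if (anyNA(v) || any(!is.finite(v)))
    stop("polygon vertices must be finite", call. = FALSE)
  # drop a repeated closing vertex if present
  n <- nrow(v)
  if (n > 3L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  colnames(v) <- c("x", "y")
  if (.polygon_self_intersects_cpp(v[, 1L], v[, 2L]))
    stop("polygon is self-intersecting", call. = FALSE)
  if (.polygon_area_cpp(v[, 1L], v[, 2L]) <= 0)
    stop("polygon has zero area", call. = FALSE)
  structure(v, class = c("polygon_region", "matrix", "array"))
}

#' Area of a polygonal region
#' @param region a [polygon_region()].
#' @return area in µm².
#' @export
region_area <- function(region) {
  .polygon_area_cpp(region[, 1L], region[, 2L])
}

#' Point-in-region test
#'
#' Even-odd rule; points exactly on an edge are inside.
#'
#' @param x,y numeric vectors of point coordinates (µm).
#' @param region a [polygon_region()].
#' @return logical vector.
#' @export
in_region <- function(x, y, region) {
  .pip_cpp(as.double(x), as.double(y), region[, 1L], region[, 2L])
}

#' Do two polygons overlap?
#'
#' True if the polygons share any point (vertex containment or edge
#' crossing, touching counts as overlap).
#'
#' @param a,b [polygon_region()] objects.
#' @return logical scalar.
#' @export
regions_overlap <- function(a, b) {
  .polygons_overlap_cpp(a[, 1L], a[, 2L], b[, 1L], b[, 2L])
}

#' Translate a polygon
#' @param region a [polygon_region()].
#' @param dx,dy translation in µm.
#' @return translated `polygon_region`.
#' @export
translate_region <- function(region, dx, dy) {
  v <- unclass(region)
  v[, 1L] <- v[, 1L] + dx
  v[, 2L] <- v[, 2L] + dy
  polygon_region(v)
}

#' Centroid of a polygon's vertices
#' @param region a [polygon_region()].
#' @return length-2 numeric (x, y).
#' @keywords internal
region_centroid <- function(region) {
  c(mean(region[, 1L]), mean(region[, 2L]))
}

#' Fraction of a circle's arc inside a region
#'
#' The isotropic edge-correction primitive: the fraction of the circle
#' of radius `r` centred at (`cx`, `cy`) whose circumference lies inside
#' the region, computed by exact circle-edge intersection with midpoint
#' classification of each arc.
#'
#' @param cx,cy circle centre (µm).
#' @param r radius (µm).
#' @param region a [polygon_region()].
#' @return fraction in \[0, 1\]; `C_in = 2*pi*r*` this value.
#' @export
arc_fraction_inside <- function(cx, cy, r, region) {
  .arc_fraction_cpp(cx, cy, r, region[, 1L], region[, 2L])
}

# Run expr with a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a parent seed and a stream label.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271 + sum(utf8ToInt(stream)) * 7919) %% 2147483629L
}

# Uniform random points inside a polygon by bounding-box rejection.
runif_in_region <- function(n, region) {
  xr <- range(region[, 1L]); yr <- range(region[, 2L])
  out <- matrix(numeric(0), ncol = 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- stats::runif(m, xr[1L], xr[2L])
    py <- stats::runif(m, yr[1L], yr[2L])
    keep <- in_region(px, py, region)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

# Regular n-gon approximating a disc; convenience for tests and demos.
#' Regular polygon approximating a disc
#' @param cx,cy centre (µm).
#' @param r radius (µm).
#' @param n number of vertices.
#' @return a [polygon_region()].
#' @export
disc_region <- function(cx = 0, cy = 0, r = 1, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  polygon_region(cbind(cx + r * cos(th), cy + r * sin(th)))
}
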