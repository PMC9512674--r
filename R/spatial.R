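# Gaussian-process covariance over family residence coordinates.

#' Exponentiated quadratic kernel between two coordinates
#'
#' `sigma_p_sq * exp(-||x - y||^2 / (2 * length_scale^2))` with Euclidean
#' distance on (latitude, longitude) degree pairs. A haversine great-circle
#' distance (kilometres) is available via `haversine = TRUE`; the default is
#' the raw Euclidean form, in which case `length_scale` is in degrees.
#'
#' @param x,y numeric length-2 vectors `c(latitude, longitude)` in degrees.
#' @param sigma_p_sq marginal variance (> 0).
#' @param length_scale kernel length scale (> 0).
#' @param haversine use great-circle distance in kilometres instead of
#'   Euclidean degrees.
#' @return the covariance value.
#' @examples
#' expQuadKernel(c(0, 0), c(0, 1), sigma_p_sq = 1, length_scale = 1)
#' @export
expQuadKernel <- function(x, y, sigma_p_sq, length_scale,
                          haversine = FALSE) {
  .checkCoord(x); .checkCoord(y)
  .checkKernelParams(sigma_p_sq, length_scale)
  d2 <- if (haversine) .haversineKm(x, y)^2 else sum((x - y)^2)
  sigma_p_sq * exp(-d2 / (2 * length_scale^2))
}

.checkCoord <- function(x) {
  if (length(x) != 2L || !is.numeric(x) || any(!is.finite(x)))
    stop("coordinate must be a finite numeric pair (latitude, longitude)")
  if (abs(x[1]) > 90) stop("latitude must lie in [-90, 90]")
  if (abs(x[2]) > 180) stop("longitude must lie in [-180, 180]")
  invisible(x)
}

.checkKernelParams <- function(sigma_p_sq, length_scale) {
  if (!is.numeric(sigma_p_sq) || sigma_p_sq <= 0)
    stop("sigma_p_sq must be > 0")
  if (!is.numeric(length_scale) || length_scale <= 0)
    stop("length_scale must be > 0")
  invisible(NULL)
}

.haversineKm <- function(x, y) {
  r <- 6371
  toRad <- pi / 180
  dlat <- (y[1] - x[1]) * toRad
  dlon <- (y[2] - x[2]) * toRad
  a <- sin(dlat / 2)^2 +
    cos(x[1] * toRad) * cos(y[1] * toRad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Squared Euclidean distance matrix on (lat, lon) rows.
.sqDistMatrix <- function(coords) {
  as.matrix(dist(coords))^2
}

#' Gaussian-process covariance matrix over coordinates
#'
#' Builds the exponentiated-quadratic covariance over a set of coordinates,
#' with a small diagonal jitter (default `1e-6 * sigma_p_sq`) to keep the
#' matrix numerically positive definite when locations coincide.
#' Individuals sharing a coordinate receive identical rows/columns up to
#' the jitter, which is the model's contract: one spatial random effect per
#' location.
#'
#' @param coords data.frame or matrix with columns latitude, longitude
#'   (degrees), one row per individual (or per unique location); row names
#'   (or a `location_id` column) become labels.
#' @param sigma_p_sq,length_scale kernel parameters, see [expQuadKernel()].
#' @param jitter diagonal inflation; `NULL` means `1e-6 * sigma_p_sq`.
#' @param haversine see [expQuadKernel()].
#' @return a [RelationshipMatrix-class] of kind `"geographic"`.
#' @export
buildGeoCovariance <- function(coords, sigma_p_sq, length_scale,
                               jitter = NULL, haversine = FALSE) {
  .checkKernelParams(sigma_p_sq, length_scale)
  if (is.null(jitter)) jitter <- 1e-6 * sigma_p_sq
  labels <- NULL
  if (is.data.frame(coords)) {
    if ("location_id" %in% names(coords))
      labels <- as.character(coords$location_id)
    coords <- as.matrix(coords[, c("latitude", "longitude")])
  }
  if (is.null(labels))
    labels <- rownames(coords)
  if (is.null(labels))
    labels <- as.character(seq_len(nrow(coords)))
  apply(coords, 1, .checkCoord)
  if (haversine) {
    n <- nrow(coords)
    D2 <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      D2[i, j] <- .haversineKm(coords[i, ], coords[j, ])^2
  } else {
    D2 <- .sqDistMatrix(coords)
  }
  K <- sigma_p_sq * exp(-D2 / (2 * length_scale^2)) +
    diag(jitter, nrow(coords))
  .newRelMatrix(K, labels, "geographic")
}
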