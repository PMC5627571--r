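## Ordinary kriging of point-wise diversity measures onto a regular
## lon/lat grid, with an exponential variogram fitted by weighted least
## squares. Distances are Euclidean in degrees for small extents and
## great-circle (km) above 5 degrees.

pairDistances <- function(lon, lat, distType) {
  if (distType == "greatcircle") {
    geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
  } else {
    as.matrix(dist(cbind(lon, lat)))
  }
}

crossDistances <- function(lon1, lat1, lon2, lat2, distType) {
  if (distType == "greatcircle") {
    geosphere::distm(cbind(lon1, lat1), cbind(lon2, lat2),
                     fun = geosphere::distHaversine) / 1000
  } else {
    d2 <- outer(lon1, lon2, function(a, b) (a - b)^2) +
      outer(lat1, lat2, function(a, b) (a - b)^2)
    sqrt(d2)
  }
}

chooseDistType <- function(lon, lat) {
  if (max(diff(range(lon)), diff(range(lat))) > 5) "greatcircle"
  else "euclidean"
}

#' Fit an exponential variogram by weighted least squares
#'
#' Builds the empirical semivariogram (semivariance
#' \eqn{\gamma(h) = \frac{1}{2}E[(Z(x)-Z(x+h))^2]} binned by separation
#' distance) and fits `nugget + sill * (1 - exp(-h/range))` by least
#' squares weighted by the number of point pairs per bin.
#'
#' @param points data.frame with columns `lon`, `lat`, `value` (>= 10
#'   points with non-degenerate spread).
#' @param nBins number of distance bins.
#' @param distType `"euclidean"` (degrees), `"greatcircle"` (km) or
#'   `"auto"` (great-circle above 5 degree extents).
#' @return a [VariogramModel-class].
#' @export
fitVariogram <- function(points, nBins = 13, distType = c("auto",
                         "euclidean", "greatcircle")) {
  distType <- match.arg(distType)
  stopifnot(all(c("lon", "lat", "value") %in% names(points)))
  points <- points[complete.cases(points[, c("lon", "lat", "value")]), ]
  n <- nrow(points)
  if (n < 10) stop("at least 10 points are required to fit a variogram")
  if (distType == "auto") distType <- chooseDistType(points$lon, points$lat)
  D <- pairDistances(points$lon, points$lat, distType)
  if (max(D) == 0) stop("all points are co-located")
  v <- points$value
  if (var(v) == 0) {
    warning("all values identical; returning a pure-nugget (flat) model")
    return(new("VariogramModel", model = "exponential", nugget = 0,
               sill = 0, range = max(D) / 3, distType = distType))
  }
  iu <- which(upper.tri(D))
  h <- D[iu]
  g <- 0.5 * (outer(v, v, "-")[iu])^2
  maxD <- max(h) / 2
  use <- h <= maxD & h > 0
  brk <- seq(0, maxD, length.out = nBins + 1)
  bin <- cut(h[use], brk, include.lowest = TRUE)
  gHat <- tapply(g[use], bin, mean)
  hMid <- tapply(h[use], bin, mean)
  nPair <- as.numeric(table(bin))
  ok <- !is.na(gHat) & nPair > 0
  gHat <- gHat[ok]; hMid <- hMid[ok]; nPair <- nPair[ok]
  if (length(gHat) < 3) stop("too few informative distance bins")
  obj <- function(par) {
    gm <- par[1] + par[2] * (1 - exp(-hMid / par[3]))
    sum(nPair * (gHat - gm)^2)
  }
  # multi-start: the WLS surface has flat ridges (large range + large sill
  # mimics a linear variogram), so try several range scales and keep the
  # best fit
  # sill bounded near the sample variance and range bounded by the domain
  # half-diameter: keeps the fit off the degenerate "almost linear" ridge
  # (huge sill + huge range) that a single realization can suggest
  best <- NULL
  for (r0 in maxD * c(0.05, 1 / 3, 1)) {
    init <- c(max(min(gHat), 1e-10), max(var(v), 1e-10), r0)
    fit <- optim(init, obj, method = "L-BFGS-B",
                 lower = c(0, 1e-12, maxD * 1e-3),
                 upper = c(max(gHat) * 2, 3 * var(v), 2 * maxD))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  new("VariogramModel", model = "exponential", nugget = best$par[1],
      sill = best$par[2], range = best$par[3], distType = distType)
}

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf(
    "VariogramModel (%s): nugget %.4g, sill %.4g, range %.4g (%s distances)\n",
    object@model, object@nugget, object@sill, object@range, object@distType))
})

variogramCov <- function(model, D) {
  # covariance implied by the exponential variogram; nugget only at h = 0
  C <- model@sill * exp(-D / model@range)
  C[D == 0] <- model@sill + model@nugget
  C
}

#' Ordinary kriging onto a regular grid
#'
#' Best linear unbiased prediction under the fitted variogram, with
#' weights constrained to sum to 1. Duplicate point locations are
#' averaged first. With zero nugget the surface interpolates the data
#' exactly at point locations.
#'
#' @param points data.frame with `lon`, `lat`, `value`.
#' @param model a [VariogramModel-class] (e.g. from [fitVariogram()]).
#' @param lon,lat grid cell-center coordinates (lat decreasing).
#' @param mask optional logical matrix (`length(lat)` x `length(lon)`);
#'   cells with `FALSE` are left `NA`.
#' @return a [DiversitySurface-class].
#' @export
krige <- function(points, model, lon, lat, mask = NULL) {
  stopifnot(is(model, "VariogramModel"))
  points <- points[complete.cases(points[, c("lon", "lat", "value")]), ]
  key <- paste(points$lon, points$lat)
  if (anyDuplicated(key)) {
    message("krige: averaging values at ", sum(duplicated(key)),
            " duplicated locations")
    points <- aggregate(value ~ lon + lat, data = points, FUN = mean)
  }
  n <- nrow(points)
  if (n < 2) stop("at least 2 distinct points are required")
  if (max(lon) < max(points$lon) || min(lon) > min(points$lon) ||
      max(lat) < max(points$lat) || min(lat) > min(points$lat))
    warning("grid does not cover the point extent; extrapolating")
  D <- pairDistances(points$lon, points$lat, model@distType)
  K <- rbind(cbind(variogramCov(model, D), 1), c(rep(1, n), 0))
  if (is.null(mask)) mask <- matrix(TRUE, length(lat), length(lon))
  cells <- which(mask)
  cr <- (cells - 1L) %% length(lat) + 1L
  cc <- (cells - 1L) %/% length(lat) + 1L
  D0 <- crossDistances(points$lon, points$lat, lon[cc], lat[cr],
                       model@distType)
  C0 <- rbind(variogramCov(model, D0), 1)
  C0[seq_len(n), ][D0 == 0] <- model@sill + model@nugget
  lambda <- solve(K, C0)
  pred <- drop(crossprod(lambda[seq_len(n), , drop = FALSE], points$value))
  vals <- matrix(NA_real_, length(lat), length(lon))
  vals[cells] <- pred
  new("DiversitySurface", lon = lon, lat = lat, values = vals, mask = mask)
}

#' @rdname DiversitySurface-class
#' @param x a `DiversitySurface`.
#' @aliases surfaceValues
#' @export
setMethod("surfaceValues", "DiversitySurface", function(x) x@values)

setMethod("show", "DiversitySurface", function(object) {
  cat("DiversitySurface:", length(object@lat), "x", length(object@lon),
      "grid;", sum(object@mask), "cells with values\n")
  v <- object@values[object@mask]
  if (length(v))
    cat(sprintf("  value range [%.4g, %.4g]\n", min(v), max(v)))
})

#' Pearson correlation between two diversity surfaces
#'
#' Computed over jointly unmasked cells; the surfaces must share grid and
#' mask geometry. Fewer than 3 common cells yields `NA` with a warning.
#'
#' @param a,b [DiversitySurface-class] objects on identical grids.
#' @return Pearson correlation coefficient.
#' @export
surfaceCorrelation <- function(a, b) {
  stopifnot(is(a, "DiversitySurface"), is(b, "DiversitySurface"))
  if (!isTRUE(all.equal(a@lon, b@lon)) || !isTRUE(all.equal(a@lat, b@lat)))
    stop("surfaces are on different grids")
  common <- a@mask & b@mask & !is.na(a@values) & !is.na(b@values)
  if (sum(common) < 3) {
    warning("fewer than 3 common cells; correlation undefined")
    return(NA_real_)
  }
  cor(a@values[common], b@values[common])
}
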