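## ABC inference of the geographic origin of a range expansion from the
## spatial distribution of singletons: spatial k-means groups, a
## singleton-histogram summary statistic, a prior-predictive reference
## table of range-expansion simulations, and rejection / regression /
## neural-network posterior estimation with 2D kernel density estimates.

#' Spatial k-means grouping of sample coordinates
#'
#' Lloyd's algorithm seeded with k-means++ centers, best of `nRestarts`
#' restarts by within-cluster sum of squares. Deterministic under a fixed
#' RNG state.
#'
#' @param coords data.frame or matrix with columns `lon`, `lat` (row names
#'   used as ids when present).
#' @param k number of groups (`k <=` number of distinct coordinates).
#' @param nRestarts restarts.
#' @return factor of group labels (`g1..gk`), named by id; the minimum
#'   group size is reported via `message()`.
#' @export
spatialKmeans <- function(coords, k, nRestarts = 10) {
  xy <- as.matrix(as.data.frame(coords)[, c("lon", "lat")])
  nDistinct <- nrow(unique(xy))
  if (k > nDistinct)
    stop("k (", k, ") exceeds the number of distinct coordinates (",
         nDistinct, ")")
  if (k == nrow(xy)) {
    g <- factor(paste0("g", seq_len(nrow(xy))),
                levels = paste0("g", seq_len(nrow(xy))))
    names(g) <- rownames(coords)
    return(g)
  }
  kmeansppCenters <- function() {
    centers <- xy[sample.int(nrow(xy), 1), , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- apply(centers, 1, function(ce)
        (xy[, 1] - ce[1])^2 + (xy[, 2] - ce[2])^2)
      mind2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
      if (sum(mind2) == 0) {
        centers <- rbind(centers, xy[sample.int(nrow(xy), 1), ])
      } else {
        centers <- rbind(centers,
                         xy[sample.int(nrow(xy), 1, prob = mind2), ])
      }
    }
    centers
  }
  best <- NULL
  for (r in seq_len(nRestarts)) {
    km <- tryCatch(
      kmeans(xy, centers = kmeansppCenters(), iter.max = 100,
             algorithm = "Lloyd"),
      warning = function(w) suppressWarnings(
        kmeans(xy, centers = kmeansppCenters(), iter.max = 200,
               algorithm = "Lloyd")))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  g <- factor(paste0("g", best$cluster), levels = paste0("g", seq_len(k)))
  names(g) <- rownames(coords)
  message("spatialKmeans: minimum group size ", min(table(g)))
  g
}

#' Smallest k keeping all groups above a size floor
#'
#' Searches downward from `kMax` for the largest k whose smallest group
#' still holds at least `minSize` members.
#'
#' @param coords coordinates as in [spatialKmeans()].
#' @param minSize group-size floor.
#' @param kMax largest k to consider.
#' @return the selected k.
#' @export
chooseGroupCount <- function(coords, minSize = 6, kMax = 20) {
  for (k in seq(kMax, 1)) {
    g <- suppressMessages(spatialKmeans(coords, k))
    if (min(table(g)) >= minSize) return(k)
  }
  1L
}

#' Singleton-histogram summary statistic
#'
#' Per group, the mean number of singletons over member chromosomes
#' divided by the total number of singletons in the sample.
#'
#' @param profile a [SingletonProfile-class] with at least one singleton.
#' @param groups group assignment covering every chromosome.
#' @return named numeric vector, one entry per group.
#' @export
singletonHistogram <- function(profile, groups) {
  stopifnot(is(profile, "SingletonProfile"))
  if (singletonTotal(profile) == 0)
    stop("no singletons: summary statistic undefined")
  cnt <- singletonCounts(profile)
  g <- asGroupAssignment(groups, names(cnt))
  vapply(levels(g), function(lev) {
    mean(cnt[g == lev]) / singletonTotal(profile)
  }, numeric(1))
}

#' Inject missing calls to match an observed missingness level
#'
#' Entries are set to missing independently at the target rate, globally
#' or per chromosome.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param rate scalar rate in `[0, 1)`, or one rate per chromosome.
#' @return the masked `HaplotypeMatrix`.
#' @export
maskMissing <- function(x, rate) {
  stopifnot(is(x, "HaplotypeMatrix"))
  if (any(rate < 0) || any(rate >= 1))
    stop("missingness rates must lie in [0, 1)")
  a <- alleles(x)
  if (length(rate) == 1L) rate <- rep(rate, ncol(a))
  if (length(rate) != ncol(a))
    stop("one rate per chromosome (or a scalar) is required")
  for (j in seq_len(ncol(a))) {
    if (rate[j] > 0)
      a[runif(nrow(a)) < rate[j], j] <- NA_integer_
  }
  out <- x
  SummarizedExperiment::assay(out, "alleles") <- a
  out
}

#' Prior specification for the origin of expansion
#'
#' @param grid habitat [DemeGrid-class] constraining the origin to
#'   habitable cells.
#' @param lonRange,latRange origin support (degrees); defaults to the
#'   Sahel box, lon -16..40 and lat 5..30.
#' @param taperFraction fraction of each coordinate range over which the
#'   prior density is linearly down-weighted toward the edges.
#' @param nuisance named list of `c(min, max)` ranges for `migrationRate`,
#'   `growthRate`, `duration`, `ancestralSize`, `lag` (all uniform).
#' @return a [PriorSpec-class].
#' @export
priorSpec <- function(grid, lonRange = c(-16, 40), latRange = c(5, 30),
                      taperFraction = 0.2,
                      nuisance = list(
                        migrationRate = c(0.01, 0.2),
                        growthRate = c(0.05, 0.5),
                        duration = c(500, 3000),
                        ancestralSize = c(50, 1000),
                        lag = c(50, 500))) {
  new("PriorSpec", lonRange = lonRange, latRange = latRange,
      taperFraction = taperFraction, grid = grid, nuisance = nuisance)
}

taperWeight <- function(x, range, frac) {
  if (frac <= 0) return(rep(1, length(x)))
  edge <- frac * diff(range)
  d <- pmin(x - range[1], range[2] - x)
  pmin(1, pmax(0, d / edge))
}

#' Draw parameters from the origin prior
#'
#' Origins are drawn by rejection sampling: uniform on the lon/lat box,
#' thinned by the triangular edge taper, and constrained to habitable
#' cells of the prior's grid. Nuisance parameters are uniform on their
#' ranges.
#'
#' @param spec a [PriorSpec-class].
#' @param n number of draws.
#' @return data.frame with columns `lon`, `lat`, `migrationRate`,
#'   `growthRate`, `duration`, `ancestralSize`, `lag`.
#' @export
samplePrior <- function(spec, n = 1L) {
  grid <- spec@grid
  cap <- capacity(grid)
  habAny <- FALSE
  lon <- numeric(0); lat <- numeric(0)
  guard <- 0L
  while (length(lon) < n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("prior support appears empty (no habitable cell)")
    m <- 4L * n
    cl <- runif(m, spec@lonRange[1], spec@lonRange[2])
    ca <- runif(m, spec@latRange[1], spec@latRange[2])
    w <- taperWeight(cl, spec@lonRange, spec@taperFraction) *
         taperWeight(ca, spec@latRange, spec@taperFraction)
    keep <- runif(m) < w
    cl <- cl[keep]; ca <- ca[keep]
    if (length(cl)) {
      hab <- vapply(seq_along(cl), function(i) {
        rc <- nearestCell(grid, cl[i], ca[i])
        cap[rc["row"], rc["col"]] > 0
      }, logical(1))
      lon <- c(lon, cl[hab]); lat <- c(lat, ca[hab])
      if (any(hab)) habAny <- TRUE
    }
  }
  nu <- spec@nuisance
  data.frame(
    lon = lon[seq_len(n)], lat = lat[seq_len(n)],
    migrationRate = runif(n, nu$migrationRate[1], nu$migrationRate[2]),
    growthRate = runif(n, nu$growthRate[1], nu$growthRate[2]),
    duration = round(runif(n, nu$duration[1], nu$duration[2])),
    ancestralSize = round(runif(n, nu$ancestralSize[1], nu$ancestralSize[2])),
    lag = round(runif(n, nu$lag[1], nu$lag[2])))
}

# Snap fixed sampling sites to occupied demes of a finished expansion;
# NULL when some site has no occupied cell within the search radius.
snapSites <- function(history, siteLon, siteLat, chromsPerSite,
                      searchRadius = 6L, minOccupancy = 1) {
  grid <- history@grid
  nr <- nrow(capacity(grid))
  finalN <- history@densities[, ncol(history@densities)]
  occ <- which(finalN >= minOccupancy)
  if (!length(occ)) return(NULL)
  occR <- (occ - 1L) %% nr + 1L; occC <- (occ - 1L) %/% nr + 1L
  occLon <- grid@lon[occC]; occLat <- grid@lat[occR]
  cellW <- mean(diff(grid@lon))
  dRow <- integer(length(siteLon)); dCol <- integer(length(siteLon))
  for (i in seq_along(siteLon)) {
    d2 <- (occLon - siteLon[i])^2 + (occLat - siteLat[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > searchRadius * cellW) return(NULL)
    dRow[i] <- occR[j]; dCol[i] <- occC[j]
  }
  k <- chromsPerSite
  new("SpatialSample",
      demeRow = rep(dRow, each = k), demeCol = rep(dCol, each = k),
      lon = rep(siteLon, each = k), lat = rep(siteLat, each = k),
      siteId = rep(seq_along(siteLon), each = k), mode = "individual")
}

#' Build an ABC reference table of range-expansion simulations
#'
#' For each row: draw parameters from the prior, run the forward
#' demography on the prior's grid, sample the fixed sites, trace the
#' backward coalescent, optionally inject missingness, and record the
#' singleton-histogram statistic. Rows whose origin cannot support the
#' sampling design (a site with no occupied deme nearby) or that yield no
#' singleton are skipped with a log entry; per-row seeds make the table
#' reproducible and resumable.
#'
#' @param nSims target number of rows.
#' @param spec a [PriorSpec-class].
#' @param sites data.frame with `lon`, `lat` of the fixed sampling sites.
#' @param groups group assignment over sites (e.g. from [spatialKmeans()]
#'   on the site coordinates).
#' @param nLoci loci per simulation.
#' @param chromsPerSite chromosomes sampled per site.
#' @param mutationRate per-locus per-generation mutation rate.
#' @param missingRate missingness injected into each simulated matrix.
#' @param seed root seed; row i uses `seed + i`.
#' @param verbose print progress every 50 rows.
#' @return a [ReferenceTable-class].
#' @export
buildReferenceTable <- function(nSims, spec, sites, groups, nLoci = 150L,
                                chromsPerSite = 1L, mutationRate = 5e-4,
                                missingRate = 0, seed = 1L,
                                verbose = FALSE) {
  stopifnot(nrow(sites) >= 1, nSims >= 1)
  siteGroups <- asGroupAssignment(groups, rownames(sites))
  chromGroups <- rep(as.character(siteGroups), each = chromsPerSite)
  params <- vector("list", nSims)
  stats <- vector("list", nSims)
  seeds <- integer(nSims)
  got <- 0L
  trySeed <- 0L
  nSkip <- 0L
  while (got < nSims) {
    trySeed <- trySeed + 1L
    if (trySeed > 20L * nSims) stop("too many failed simulations")
    rowSeed <- as.integer(seed) + trySeed
    set.seed(rowSeed)
    draw <- samplePrior(spec, 1L)
    scen <- expansionScenario(
      originLon = draw$lon, originLat = draw$lat,
      migrationRate = draw$migrationRate, growthRate = draw$growthRate,
      duration = draw$duration, ancestralSize = draw$ancestralSize,
      lag = draw$lag, mutationRate = mutationRate, nLoci = nLoci)
    h <- runForwardDemography(spec@grid, scen)
    sam <- snapSites(h, sites$lon, sites$lat, chromsPerSite)
    if (is.null(sam)) { nSkip <- nSkip + 1L; next }
    hm <- sampleBackwardCoalescent(h, sam, nLoci = nLoci)
    if (missingRate > 0 && nLoci(hm) > 0) hm <- maskMissing(hm, missingRate)
    prof <- suppressMessages(countSingletons(hm))
    if (singletonTotal(prof) == 0) { nSkip <- nSkip + 1L; next }
    stat <- singletonHistogram(
      prof, setNames(chromGroups, chromosomeIds(hm)))
    got <- got + 1L
    params[[got]] <- draw
    stats[[got]] <- stat
    seeds[got] <- rowSeed
    if (verbose && got %% 50L == 0L)
      message("buildReferenceTable: ", got, "/", nSims)
  }
  if (nSkip > 0)
    message("buildReferenceTable: skipped ", nSkip, " simulations")
  new("ReferenceTable",
      params = do.call(rbind, params),
      stats = do.call(rbind, stats),
      seeds = seeds[seq_len(got)],
      metadata = list(rootSeed = seed, nLoci = nLoci,
                      chromsPerSite = chromsPerSite,
                      mutationRate = mutationRate,
                      missingRate = missingRate,
                      groups = siteGroups, sites = sites))
}

setMethod("show", "ReferenceTable", function(object) {
  cat("ReferenceTable:", nrow(object@params), "simulations,",
      ncol(object@stats), "summary statistics\n")
})

#' Write / read a reference table as CSV + JSON sidecar
#'
#' @param table a [ReferenceTable-class].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `writeReferenceTable` returns `path` invisibly;
#'   `readReferenceTable` returns the [ReferenceTable-class].
#' @export
writeReferenceTable <- function(table, path) {
  df <- cbind(seed = table@seeds, table@params,
              setNames(as.data.frame(table@stats),
                       paste0("stat_", colnames(table@stats))))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  meta <- table@metadata
  meta$groups <- as.character(meta$groups)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeReferenceTable
#' @export
readReferenceTable <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  statCols <- grep("^stat_", names(df))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stats <- as.matrix(df[, statCols, drop = FALSE])
  colnames(stats) <- sub("^stat_", "", colnames(stats))
  new("ReferenceTable",
      params = df[, setdiff(seq_along(df), c(1L, statCols)), drop = FALSE],
      stats = stats, seeds = as.integer(df$seed), metadata = as.list(meta))
}

weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# Weighted 2D Gaussian product-kernel density on a regular grid.
weightedKde2d <- function(x, y, w, lonGrid, latGrid) {
  w <- w / sum(w)
  nEff <- 1 / sum(w^2)
  bw <- function(v) {
    s <- sqrt(sum(w * (v - sum(w * v))^2))
    h <- 1.06 * max(s, 1e-6) * nEff^(-1 / 5)
    max(h, 1e-6)
  }
  hx <- bw(x); hy <- bw(y)
  kx <- outer(lonGrid, x, function(g, xi) dnorm((g - xi) / hx)) / hx
  ky <- outer(latGrid, y, function(g, yi) dnorm((g - yi) / hy)) / hy
  ky %*% (t(kx) * w)               # latGrid x lonGrid
}

#' ABC posterior for the origin of expansion
#'
#' Summary statistics are standardized by their table-wide median absolute
#' deviation; the accepted set is the `tolerance` fraction of rows closest
#' to the observed statistic in Euclidean distance. Methods:
#' `"rejection"` keeps accepted draws unweighted; `"loclinear"` applies
#' the Beaumont local-linear regression adjustment with Epanechnikov
#' kernel weights; `"neuralnet"` adjusts through an ensemble of
#' single-hidden-layer feed-forward regressions (default 250 members,
#' averaged). The joint lon/lat posterior is summarized by a weighted 2D
#' kernel density estimate on a regular grid (default 100 x 100 over the
#' prior box), its mode, and equal-tailed credible intervals.
#'
#' @param observed named numeric vector (the observed singleton
#'   histogram).
#' @param table a [ReferenceTable-class].
#' @param tolerance accepted fraction of rows (default 0.05).
#' @param method `"loclinear"` (default), `"rejection"` or `"neuralnet"`.
#' @param spec optional [PriorSpec-class]; when given, adjusted samples
#'   are clamped to the prior box and the density is zeroed on
#'   uninhabitable cells.
#' @param gridN KDE grid points per coordinate.
#' @param nNets ensemble size for `method = "neuralnet"`.
#' @param hiddenUnits hidden-layer size for `method = "neuralnet"`.
#' @param ciLevel credible-interval level.
#' @return a [PosteriorEstimate-class].
#' @export
abcEstimate <- function(observed, table, tolerance = 0.05,
                        method = c("loclinear", "rejection", "neuralnet"),
                        spec = NULL, gridN = 100L, nNets = 250L,
                        hiddenUnits = 4L, ciLevel = 0.95) {
  method <- match.arg(method)
  stopifnot(tolerance > 0, tolerance <= 1)
  X <- table@stats
  if (length(observed) != ncol(X))
    stop("observed statistic dimension does not match the table")
  scl <- apply(X, 2, mad)
  scl[scl == 0] <- apply(X, 2, sd)[scl == 0]
  scl[scl == 0 | is.na(scl)] <- 1
  Z <- sweep(X, 2, scl, "/")
  zObs <- observed / scl
  d <- sqrt(rowSums(sweep(Z, 2, zObs, "-")^2))
  nAcc <- ceiling(tolerance * nrow(X))
  if (nAcc < 20)
    stop("tolerance accepts only ", nAcc,
         " rows (< 20); increase the tolerance or enlarge the table")
  ord <- order(d)[seq_len(nAcc)]
  delta <- max(d[ord])
  if (delta == 0) delta <- 1e-12
  w <- 1 - (d[ord] / delta)^2            # Epanechnikov
  w[w <= 0] <- min(w[w > 0], 1e-6)
  par <- as.matrix(table@params[ord, c("lon", "lat")])
  if (method == "rejection") {
    adj <- par
    w <- rep(1, nAcc)
  } else if (method == "loclinear") {
    Zc <- sweep(Z[ord, , drop = FALSE], 2, zObs, "-")
    Xr <- cbind(1, Zc)
    adj <- par
    for (j in 1:2) {
      fit <- lm.wfit(Xr, par[, j], w)
      bet <- fit$coefficients[-1]
      bet[is.na(bet)] <- 0
      adj[, j] <- par[, j] - Zc %*% bet
    }
  } else {
    Za <- Z[ord, , drop = FALSE]
    adj <- par
    for (j in 1:2) {
      predObs <- numeric(nNets)
      predSelf <- matrix(0, nAcc, nNets)
      for (b in seq_len(nNets)) {
        fit <- nnet::nnet(Za, par[, j], weights = w, size = hiddenUnits,
                          linout = TRUE, trace = FALSE, maxit = 300,
                          decay = 0.01)
        predObs[b] <- predict(fit, matrix(zObs, nrow = 1))
        predSelf[, b] <- predict(fit, Za)
      }
      adj[, j] <- mean(predObs) + (par[, j] - rowMeans(predSelf))
    }
  }
  if (!is.null(spec)) {
    adj[, 1] <- pmin(pmax(adj[, 1], spec@lonRange[1]), spec@lonRange[2])
    adj[, 2] <- pmin(pmax(adj[, 2], spec@latRange[1]), spec@latRange[2])
  }
  lonR <- if (!is.null(spec)) spec@lonRange else range(table@params$lon)
  latR <- if (!is.null(spec)) spec@latRange else range(table@params$lat)
  lonGrid <- seq(lonR[1], lonR[2], length.out = gridN)
  latGrid <- seq(latR[1], latR[2], length.out = gridN)
  dens <- weightedKde2d(adj[, 1], adj[, 2], w, lonGrid, latGrid)  # lat x lon
  if (!is.null(spec)) {
    cap <- capacity(spec@grid)
    for (i in seq_along(latGrid)) {
      for (j in seq_along(lonGrid)) {
        rc <- nearestCell(spec@grid, lonGrid[j], latGrid[i])
        if (cap[rc["row"], rc["col"]] <= 0) dens[i, j] <- 0
      }
    }
  }
  if (sum(dens) > 0) dens <- dens / (sum(dens) *
    mean(diff(lonGrid)) * mean(diff(latGrid)))
  mo <- which(dens == max(dens), arr.ind = TRUE)[1, ]
  alpha <- (1 - ciLevel) / 2
  wN <- w / sum(w)
  ci <- list(
    lon = weightedQuantile(adj[, 1], wN, c(alpha, 1 - alpha)),
    lat = weightedQuantile(adj[, 2], wN, c(alpha, 1 - alpha)))
  samples <- data.frame(lon = adj[, 1], lat = adj[, 2],
                        lonRaw = par[, 1], latRaw = par[, 2],
                        distance = d[ord])
  new("PosteriorEstimate", samples = samples, weights = wN,
      lonGrid = lonGrid, latGrid = latGrid, density = dens,
      mode = c(lon = lonGrid[mo["col"]], lat = latGrid[mo["row"]]),
      ci = ci, method = method, tolerance = tolerance)
}

setMethod("show", "PosteriorEstimate", function(object) {
  cat("PosteriorEstimate (", object@method, ", tolerance ",
      object@tolerance, ")\n", sep = "")
  pm <- posteriorMean(object)
  cat(sprintf("  posterior mean: lon %.2f, lat %.2f; mode: lon %.2f, lat %.2f\n",
              pm["lon"], pm["lat"], object@mode["lon"], object@mode["lat"]))
  cat(sprintf("  CI lon [%.2f, %.2f], lat [%.2f, %.2f]\n",
              object@ci$lon[1], object@ci$lon[2],
              object@ci$lat[1], object@ci$lat[2]))
})

#' Weighted posterior mean of the origin coordinates
#'
#' @param x a [PosteriorEstimate-class].
#' @return named vector `c(lon, lat)`.
#' @export
posteriorMean <- function(x) {
  stopifnot(is(x, "PosteriorEstimate"))
  c(lon = sum(x@weights * x@samples$lon),
    lat = sum(x@weights * x@samples$lat))
}

#' Validate origin recovery by cross-validation over the reference table
#'
#' Each test takes one reference-table row as the pseudo-observed data set
#' (its parameters were drawn from the prior and its statistic simulated
#' from them), estimates the origin with the remaining rows, and records
#' the posterior mean. Reported are the squared Pearson correlations
#' between estimated and true coordinates.
#'
#' @param table a [ReferenceTable-class].
#' @param nTest number of held-out tests (>= 10).
#' @param tolerance,method,spec passed to [abcEstimate()].
#' @param seed RNG seed for the choice of held-out rows.
#' @param ... further arguments for [abcEstimate()] (e.g. `nNets`).
#' @return list with `r2` (named vector, lon/lat) and `estimates` (one row
#'   per test: true and estimated coordinates).
#' @export
validateOriginRecovery <- function(table, nTest = 20L, tolerance = 0.1,
                                   method = "loclinear", spec = NULL,
                                   seed = 1L, ...) {
  stopifnot(nTest >= 10, nTest < nrow(table@params))
  set.seed(seed)
  testRows <- sample.int(nrow(table@params), nTest)
  est <- matrix(NA_real_, nTest, 2)
  for (i in seq_len(nTest)) {
    r <- testRows[i]
    sub <- new("ReferenceTable",
               params = table@params[-r, , drop = FALSE],
               stats = table@stats[-r, , drop = FALSE],
               seeds = table@seeds[-r], metadata = table@metadata)
    pe <- abcEstimate(table@stats[r, ], sub, tolerance = tolerance,
                      method = method, spec = spec, gridN = 20L, ...)
    est[i, ] <- posteriorMean(pe)
  }
  truth <- table@params[testRows, c("lon", "lat")]
  r2 <- c(lon = cor(est[, 1], truth$lon)^2,
          lat = cor(est[, 2], truth$lat)^2)
  list(r2 = r2,
       estimates = data.frame(trueLon = truth$lon, trueLat = truth$lat,
                              estLon = est[, 1], estLat = est[, 2]))
}
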