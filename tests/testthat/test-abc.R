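test_that("spatial k-means recovers well-separated clouds", {
  set.seed(31)
  centers <- cbind(lon = c(0, 10, 20), lat = c(0, 10, 0))
  coords <- data.frame(
    lon = rep(centers[, 1], each = 20) + rnorm(60, 0, 0.3),
    lat = rep(centers[, 2], each = 20) + rnorm(60, 0, 0.3))
  g <- suppressMessages(spatialKmeans(coords, 3))
  truth <- rep(1:3, each = 20)
  # perfect recovery up to label permutation
  expect_equal(length(unique(paste(g, truth))), 3L)

  expect_equal(nlevels(suppressMessages(spatialKmeans(coords, 1))), 1L)
  gn <- suppressMessages(spatialKmeans(coords, nrow(coords)))
  expect_equal(length(unique(gn)), nrow(coords))
  expect_error(spatialKmeans(coords[1:2, ], 5), "exceeds")
})

test_that("singleton histograms divide group means by the total", {
  prof <- new("SingletonProfile",
              counts = setNames(c(2, 4, 6, 8), paste0("c", 1:4)),
              total = 20,
              proportions = setNames(c(2, 4, 6, 8) / 20, paste0("c", 1:4)),
              nSkippedLoci = 0L)
  h <- singletonHistogram(prof, setNames(c("A", "A", "B", "B"),
                                         paste0("c", 1:4)))
  expect_equal(unname(h), c(3 / 20, 7 / 20))

  # uniform counts: all entries equal; equal group sizes sum to k/n
  profU <- new("SingletonProfile",
               counts = setNames(rep(5, 6), paste0("c", 1:6)), total = 30,
               proportions = setNames(rep(5, 6) / 30, paste0("c", 1:6)),
               nSkippedLoci = 0L)
  hU <- singletonHistogram(profU, rep(c("A", "B", "C"), each = 2))
  expect_true(all(abs(hU - hU[1]) < 1e-12))
  expect_equal(sum(hU), 3 / 6)

  # relabeling chromosomes within a group leaves the statistic unchanged
  hPerm <- singletonHistogram(prof, setNames(c("A", "A", "B", "B"),
                                             paste0("c", c(2, 1, 4, 3))))
  expect_equal(hPerm, h)

  prof0 <- new("SingletonProfile",
               counts = setNames(rep(0, 4), paste0("c", 1:4)), total = 0,
               proportions = setNames(rep(NA_real_, 4), paste0("c", 1:4)),
               nSkippedLoci = 0L)
  expect_error(singletonHistogram(prof0, rep("A", 4)), "undefined")
})

test_that("missingness masking hits the target rate", {
  set.seed(32)
  hm <- HaplotypeMatrix(matrix(rbinom(1e5, 1, 0.4), ncol = 10))
  expect_identical(alleles(maskMissing(hm, 0)), alleles(hm))
  mk <- maskMissing(hm, 0.2)
  rate <- mean(is.na(alleles(mk)))
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))
  # per-chromosome rates
  rates <- seq(0.05, 0.5, length.out = 10)
  mk2 <- maskMissing(hm, rates)
  got <- colMeans(is.na(alleles(mk2)))
  expect_true(all(abs(got - rates) < 3 * sqrt(rates * (1 - rates) / 1e4)))
  expect_error(maskMissing(hm, 1), "rates must lie")
})

test_that("prior draws respect the box, the taper and the habitat", {
  set.seed(33)
  # all-land rectangular grid, no taper: uniform draws
  g <- DemeGrid(matrix("other", 10, 10), lon = seq(0.5, 9.5, 1),
                lat = seq(9.5, 0.5, -1))
  spec <- priorSpec(g, lonRange = c(0, 10), latRange = c(0, 10),
                    taperFraction = 0)
  d <- samplePrior(spec, 4000)
  expect_true(all(d$lon >= 0 & d$lon <= 10 & d$lat >= 0 & d$lat <= 10))
  gof <- stats::chisq.test(table(cut(d$lon, seq(0, 10, 2))))
  expect_gt(gof$p.value, 0.001)
  # nuisance parameters respect their ranges
  expect_true(all(d$migrationRate >= 0.01 & d$migrationRate <= 0.2))
  expect_true(all(d$duration >= 500 & d$duration <= 3000))

  # a water column receives zero mass
  hab <- matrix("other", 10, 10); hab[, 5] <- "sea"
  g2 <- DemeGrid(hab, lon = seq(0.5, 9.5, 1), lat = seq(9.5, 0.5, -1))
  spec2 <- priorSpec(g2, lonRange = c(0, 10), latRange = c(0, 10),
                     taperFraction = 0)
  d2 <- samplePrior(spec2, 3000)
  expect_true(all(abs(d2$lon - 4.5) > 0.5))

  # taper: edge cells are down-weighted relative to the core
  spec3 <- priorSpec(g, lonRange = c(0, 10), latRange = c(0, 10),
                     taperFraction = 0.2)
  d3 <- samplePrior(spec3, 4000)
  edge <- mean(d3$lon < 1)          # outer half of the tapered band
  core <- mean(d3$lon >= 4 & d3$lon < 5)
  expect_lt(edge, core)
})

test_that("the ABC machinery concentrates around a self-matched row", {
  set.seed(34)
  tab <- toyReferenceTable(1000)
  obs <- tab@stats[17, ]
  pe <- abcEstimate(obs, tab, tolerance = 0.05, method = "rejection",
                    gridN = 25)
  # accepted draws cluster around the matched row's parameter
  expect_lt(abs(posteriorMean(pe)["lon"] - tab@params$lon[17]), 1.5)
  expect_equal(sum(pe@weights), 1)
  expect_true(all(pe@density >= 0))
})

test_that("regression adjustment reduces posterior spread on the toy model", {
  set.seed(35)
  tab <- toyReferenceTable(2000)
  obs <- c(s1 = 1.5, s2 = 1.5^2 / 5)
  rej <- abcEstimate(obs, tab, tolerance = 0.2, method = "rejection",
                     gridN = 20)
  lin <- abcEstimate(obs, tab, tolerance = 0.2, method = "loclinear",
                     gridN = 20)
  vRej <- var(rej@samples$lon)
  vLin <- sum(lin@weights * (lin@samples$lon -
                sum(lin@weights * lin@samples$lon))^2)
  expect_lte(vLin, vRej)
  # both center near the truth
  expect_lt(abs(posteriorMean(lin)["lon"] - 1.5), 0.75)
})

test_that("neural-network adjustment runs and stays near the truth", {
  set.seed(36)
  tab <- toyReferenceTable(800)
  obs <- c(s1 = -2, s2 = 4 / 5)
  pe <- abcEstimate(obs, tab, tolerance = 0.3, method = "neuralnet",
                    gridN = 15, nNets = 10, hiddenUnits = 3)
  expect_lt(abs(posteriorMean(pe)["lon"] - (-2)), 1)
})

test_that("credible intervals achieve near-nominal coverage on the toy model", {
  set.seed(37)
  tab <- toyReferenceTable(3000)
  hits <- 0; nRep <- 60
  for (i in seq_len(nRep)) {
    truth <- runif(1, -4, 4)
    obs <- c(s1 = truth + rnorm(1, 0, 0.5),
             s2 = truth^2 / 5 + rnorm(1, 0, 0.5))
    pe <- abcEstimate(obs, tab, tolerance = 0.3, method = "rejection",
                      gridN = 10, ciLevel = 0.9)
    if (truth >= pe@ci$lon[1] && truth <= pe@ci$lon[2]) hits <- hits + 1
  }
  cover <- hits / nRep
  expect_gt(cover, 0.9 - 3 * sqrt(0.9 * 0.1 / nRep))
})

test_that("small tolerances and dimension mismatches are rejected", {
  tab <- toyReferenceTable(100)
  expect_error(abcEstimate(tab@stats[1, ], tab, tolerance = 0.01),
               "increase the tolerance")
  expect_error(abcEstimate(c(1, 2, 3), tab, tolerance = 0.5),
               "dimension")
})

test_that("reference tables round-trip through CSV + JSON", {
  set.seed(38)
  tab <- toyReferenceTable(40)
  tab@metadata <- list(rootSeed = 1, nLoci = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  writeReferenceTable(tab, path)
  back <- readReferenceTable(path)
  expect_equal(back@stats, tab@stats, tolerance = 1e-6)
  expect_equal(back@params$lon, tab@params$lon, tolerance = 1e-6)
  expect_identical(back@seeds, tab@seeds)
})

test_that("reference-table construction is deterministic under a seed", {
  hab <- matrix("other", 6, 6)
  hab[1, ] <- hab[6, ] <- hab[, 1] <- hab[, 6] <- "sea"
  g <- DemeGrid(hab, lon = seq(-3, 2, 1), lat = seq(3, -2, -1))
  spec <- priorSpec(g, lonRange = c(-3, 2), latRange = c(-2, 3),
                    taperFraction = 0,
                    nuisance = list(migrationRate = c(0.1, 0.2),
                                    growthRate = c(0.3, 0.5),
                                    duration = c(40, 80),
                                    ancestralSize = c(30, 60),
                                    lag = c(10, 20)))
  sites <- data.frame(lon = c(-2, 0, 1, -1), lat = c(2, 0, -1, 1))
  rownames(sites) <- paste0("s", 1:4)
  groups <- setNames(c("a", "a", "b", "b"), rownames(sites))
  build <- function() suppressMessages(
    buildReferenceTable(2, spec, sites, groups, nLoci = 30L,
                        chromsPerSite = 2L, mutationRate = 5e-3,
                        seed = 77))
  t1 <- build(); t2 <- build()
  expect_identical(t1@stats, t2@stats)
  expect_identical(t1@params, t2@params)
  expect_identical(t1@seeds, t2@seeds)
  expect_equal(ncol(t1@stats), 2L)  # one statistic per group
})
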