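test_that("habitat maps assign the documented carrying capacities", {
  base <- demoGrid()
  hom <- makeHabitatMap("homogeneous", base)
  expect_true(all(capacity(hom)[base@habitat != "sea"] == 100))
  expect_true(all(capacity(hom)[base@habitat == "sea"] == 0))

  veg <- makeHabitatMap("vegetation", base)
  expect_true(all(capacity(veg)[base@habitat == "semi-desert"] == 60))
  expect_true(all(capacity(veg)[base@habitat == "extreme-desert"] == 30))
  expect_true(all(capacity(veg)[base@habitat == "rain-forest"] == 30))
  expect_true(all(capacity(veg)[base@habitat == "other"] == 100))

  abc <- makeHabitatMap("abc-vegetation", base)
  expect_true(all(capacity(abc)[base@habitat == "semi-desert"] == 100))
  expect_true(all(capacity(abc)[base@habitat == "extreme-desert"] == 20))
  expect_true(all(capacity(abc)[base@habitat == "rain-forest"] == 10))

  allSea <- DemeGrid(matrix("sea", 4, 4), lon = 1:4, lat = 4:1)
  expect_error(makeHabitatMap("homogeneous", allSea), "no habitable cell")
})

test_that("closed demes follow the deterministic logistic recursion", {
  hab <- matrix("sea", 5, 5); hab[3, 3] <- "other"
  g <- DemeGrid(hab, lon = 1:5, lat = 5:1)
  scen <- expansionScenario(originLon = 3, originLat = 3, migrationRate = 0,
                            growthRate = 0.1, duration = 80L,
                            ancestralSize = 1)
  h <- runForwardDemography(g, scen)
  traj <- h@densities[h@originCell, ]
  ref <- Reduce(function(N, .) N + 0.1 * N * (1 - N / 100), 1:80,
                accumulate = TRUE, init = 1)
  expect_equal(unname(traj), ref, tolerance = 1e-10)
  expect_true(all(diff(traj) >= -1e-12))

  # r = 0: no growth beyond initialization
  scen0 <- expansionScenario(originLon = 3, originLat = 3,
                             migrationRate = 0, growthRate = 0,
                             duration = 20L, ancestralSize = 7)
  h0 <- runForwardDemography(g, scen0)
  expect_true(all(h0@densities[h0@originCell, ] == 7))
})

test_that("an origin on the sea is rejected with a suggestion", {
  g <- demoGrid()
  scen <- expansionScenario(originLon = g@lon[1], originLat = g@lat[1],
                            duration = 10L)
  expect_error(runForwardDemography(g, scen), "nearest habitable")
})

test_that("forward migration conserves mass and the front advances", {
  run <- demoExpansionRun()
  h <- run$hist
  ns <- singletonMaps:::neighborStructure(run$grid)
  cap <- as.vector(capacity(run$grid))
  for (t in c(5, 60, 150)) {
    st <- singletonMaps:::forwardStep(h@densities[, t],
                                      cap, run$scen@migrationRate,
                                      run$scen@growthRate, ns)
    # migration redistributes the grown population without loss
    expect_equal(sum(st$N), sum(st$G), tolerance = 1e-9)
    expect_equal(st$N, h@densities[, t + 1], tolerance = 1e-9)
  }
  # colonization front: maximum distance of occupied cells never shrinks
  nr <- nrow(capacity(run$grid))
  oc <- h@originCell
  or <- (oc - 1) %% nr + 1; ocl <- (oc - 1) %/% nr + 1
  front <- vapply(seq(1, 251, by = 10), function(t) {
    occ <- which(h@densities[, t] >= 1)
    if (!length(occ)) return(0)
    r <- (occ - 1) %% nr + 1; cl <- (occ - 1) %/% nr + 1
    max(sqrt((r - or)^2 + (cl - ocl)^2))
  }, numeric(1))
  expect_true(all(diff(front) >= 0))
})

test_that("sampling designs have the documented shape and are seeded", {
  run <- demoExpansionRun()
  set.seed(11)
  s1 <- drawSamplingDesign(run$hist, "population", nSites = 30L,
                           chromsPerSite = 10L)
  expect_equal(length(s1@demeRow), 300L)
  expect_equal(length(unique(s1@siteId)), 30L)
  # all sampled demes occupied at sampling time
  nr <- nrow(capacity(run$grid))
  cells <- (s1@demeCol - 1L) * nr + s1@demeRow
  expect_true(all(run$hist@densities[cells, 251] >= 1))

  set.seed(12)
  a <- drawSamplingDesign(run$hist, "individual", nSites = 10L,
                          chromsPerSite = 3L)
  set.seed(12)
  b <- drawSamplingDesign(run$hist, "individual", nSites = 10L,
                          chromsPerSite = 3L)
  expect_identical(a@lon, b@lon)
  expect_identical(a@demeRow, b@demeRow)
  # zero jitter: individual sites sit at the population centers
  set.seed(13)
  c0 <- drawSamplingDesign(run$hist, "individual", nSites = 10L,
                           chromsPerSite = 2L, jitterSD = 0)
  expect_true(all(c0@lon %in% run$grid@lon))
})

test_that("single-deme backward coalescence times are geometric with mean N", {
  hab <- matrix("sea", 3, 3); hab[2, 2] <- "other"
  g <- DemeGrid(hab, lon = 1:3, lat = 3:1)
  Nsize <- 60
  scen <- expansionScenario(originLon = 2, originLat = 2, migrationRate = 0,
                            growthRate = 0, duration = 400L,
                            ancestralSize = Nsize, mutationRate = 0,
                            nLoci = 500L)
  h <- runForwardDemography(g, scen)
  sam <- new("SpatialSample", demeRow = c(2L, 2L), demeCol = c(2L, 2L),
             lon = c(2, 2), lat = c(2, 2), siteId = c(1L, 1L),
             mode = "population")
  set.seed(14)
  hm <- sampleBackwardCoalescent(h, sam, nLoci = 500L, returnTrees = TRUE)
  trees <- S4Vectors::metadata(hm)$trees
  tmrca <- vapply(trees, function(tr) max(ape::node.depth.edgelength(tr)),
                  numeric(1))
  # pair coalescence per generation at probability 1/N: mean TMRCA = N
  expect_lt(abs(mean(tmrca) - Nsize), 3 * sd(tmrca) / sqrt(length(tmrca)))
})

test_that("expansion leaves a diversity gradient away from the origin", {
  run <- demoExpansionRun()
  prof <- countSingletons(run$hm)
  p <- singletonProportions(prof)
  cd <- as.data.frame(SummarizedExperiment::colData(run$hm))
  d0 <- sqrt((cd$lon - run$scen@originLon)^2 + (cd$lat - run$scen@originLat)^2)
  siteP <- tapply(p, cd$siteId, mean)
  siteD <- tapply(d0, cd$siteId, mean)
  ct <- suppressWarnings(cor.test(siteP, siteD, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # heterozygosity shows the same gradient
  hx <- expectedHeterozygosity(run$hm, setNames(as.character(cd$siteId),
                                                chromosomeIds(run$hm)))
  ct2 <- suppressWarnings(cor.test(hx, tapply(d0, cd$siteId, mean),
                                   method = "spearman"))
  expect_lt(ct2$estimate, 0)
})

test_that("monomorphic filtering drops fixed loci and is idempotent", {
  a <- rbind(c(0, 1, 0), c(1, 1, 1), c(0, 0, 0), c(1, 0, 1))
  hm <- HaplotypeMatrix(a)
  expect_message(f <- filterMonomorphic(hm), "removed 2")
  expect_equal(nLoci(f), 2L)
  expect_silent(f2 <- filterMonomorphic(f))
  expect_equal(nLoci(f2), 2L)
  expect_message(z <- filterMonomorphic(HaplotypeMatrix(matrix(0L, 3, 4))),
                 "removed 3")
  expect_equal(nLoci(z), 0L)
})
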