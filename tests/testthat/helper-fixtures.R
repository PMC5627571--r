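# Shared fixtures, built in code and cached for the session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# brute-force singleton tally: per locus, count alleles among non-missing
# calls and credit the unique carrier (independent of countSingletons)
bruteForceSingletons <- function(a, folded = FALSE) {
  n <- ncol(a)
  counts <- numeric(n)
  for (l in seq_len(nrow(a))) {
    x <- a[l, ]
    obs <- which(!is.na(x))
    if (length(obs) < 2) next
    nDer <- sum(x[obs] == 1)
    nAnc <- length(obs) - nDer
    if (nDer == 1) {
      counts[which(!is.na(a[l, ]) & a[l, ] == 1)] <-
        counts[which(!is.na(a[l, ]) & a[l, ] == 1)] + 1
    } else if (folded && nAnc == 1) {
      counts[which(!is.na(a[l, ]) & a[l, ] == 0)] <-
        counts[which(!is.na(a[l, ]) & a[l, ] == 0)] + 1
    }
  }
  counts
}

# random 0/1/NA haplotype matrix (loci x chromosomes)
randomHaplotypeMatrix <- function(nLoci = 20, nChrom = 10, pMissing = 0.1) {
  a <- matrix(rbinom(nLoci * nChrom, 1, 0.3), nLoci, nChrom)
  a[runif(nLoci * nChrom) < pMissing] <- NA
  a
}

# small expansion run shared by expansion / surface tests
demoExpansionRun <- function() {
  cached("demoRun", {
    set.seed(2024)
    grid <- makeHabitatMap("homogeneous", demoGrid())
    scen <- expansionScenario(originLon = -14, originLat = 22,
                              duration = 250L, ancestralSize = 200,
                              mutationRate = 3e-4, nLoci = 250L)
    hist <- runForwardDemography(grid, scen)
    sam <- drawSamplingDesign(hist, "population", nSites = 25L,
                              chromsPerSite = 4L)
    hm <- sampleBackwardCoalescent(hist, sam, nLoci = 250L)
    list(grid = grid, scen = scen, hist = hist, sam = sam, hm = hm)
  })
}

# desk-scale ABC configuration: homogeneous demo grid (the vignette
# explains why the banded capacities are not used at this scale),
# 40 three-chromosome sites, 12 spatial groups, 100 loci
deskAbcConfig <- function() {
  cached("abcCfg", {
    set.seed(42)
    dg <- makeHabitatMap("homogeneous", demoGrid())
    spec <- priorSpec(dg, lonRange = c(-16, 12), latRange = c(6, 29),
                      nuisance = list(migrationRate = c(0.08, 0.25),
                                      growthRate = c(0.2, 0.6),
                                      duration = c(150, 300),
                                      ancestralSize = c(50, 300),
                                      lag = c(50, 200)))
    sp <- samplePrior(spec, 40)
    sites <- data.frame(lon = sp$lon, lat = sp$lat)
    rownames(sites) <- paste0("s", seq_len(40))
    groups <- suppressMessages(spatialKmeans(sites, 12))
    list(spec = spec, sites = sites, groups = groups)
  })
}

deskReferenceTable <- function() {
  cfg <- deskAbcConfig()
  cached("abcTable", suppressMessages(
    buildReferenceTable(300, cfg$spec, cfg$sites, cfg$groups,
                        nLoci = 100L, chromsPerSite = 3L,
                        mutationRate = 5e-3, missingRate = 0.05,
                        seed = 1000)))
}

# synthetic conic toy model for ABC sanity checks: theta ~ U(-5, 5),
# stats = (theta + noise, theta^2/5 + noise); analytically tractable
toyReferenceTable <- function(n = 2000) {
  theta <- runif(n, -5, 5)
  stats <- cbind(s1 = theta + rnorm(n, 0, 0.5),
                 s2 = theta^2 / 5 + rnorm(n, 0, 0.5))
  params <- data.frame(lon = theta, lat = theta / 2 + rnorm(n, 0, 0.1))
  new("ReferenceTable", params = params, stats = stats,
      seeds = seq_len(n), metadata = list())
}
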