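#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats var sd cor quantile rexp rpois rbinom runif rnorm rgeom
#'   dist optim kmeans setNames aggregate complete.cases weighted.mean
#'   qnorm mad median cov dnorm lm.wfit predict reorder cor.test
#' @importFrom utils read.table write.table head tail
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' HaplotypeMatrix: haploid 0/1 genotype calls with chromosome metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container for a
#' sample of `n` chromosomes typed at `L` biallelic loci. The single assay,
#' `"alleles"`, is an integer matrix with loci as rows and chromosomes as
#' columns; `0` is the ancestral (or reference) allele, `1` the derived
#' allele, and `NA` a missing call. Chromosome-level metadata (geographic
#' coordinates, deme indices, population labels) live in `colData`.
#'
#' The `polarization` slot records whether the 0/1 coding is anchored to a
#' known ancestral allele (`"ancestral-known"`, the default assumed by the
#' external-branch-length theory) or whether only minor/major status is
#' meaningful (`"folded"`).
#'
#' @slot polarization character, `"ancestral-known"` or `"folded"`.
#' @export
setClass("HaplotypeMatrix",
  contains = "SummarizedExperiment",
  slots = c(polarization = "character"),
  prototype = prototype(polarization = "ancestral-known")
)

setValidity("HaplotypeMatrix", function(object) {
  msg <- NULL
  if (!"alleles" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'alleles' is required")
  else {
    a <- SummarizedExperiment::assay(object, "alleles")
    bad <- !is.na(a) & a != 0L & a != 1L
    if (any(bad)) msg <- c(msg, "allele calls must be 0, 1 or NA")
  }
  if (ncol(object) < 2L)
    msg <- c(msg, "at least 2 chromosomes are required")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "chromosome identifiers must be unique")
  if (length(object@polarization) != 1L ||
      !object@polarization %in% c("ancestral-known", "folded"))
    msg <- c(msg, "polarization must be 'ancestral-known' or 'folded'")
  if (is.null(msg)) TRUE else msg
})

#' Per-chromosome singleton counts and proportions
#'
#' Holds the decomposition of the total singleton count xi1 into
#' per-chromosome counts xi1_i, and the normalized empirical distribution
#' of singletons p_i = xi1_i / xi1. When no singleton is present the
#' proportions are undefined (all `NA`) and `defined()` is `FALSE`.
#'
#' @slot counts named numeric vector of per-chromosome singleton counts.
#' @slot total total number of singletons in the sample.
#' @slot proportions named numeric vector summing to 1, or all-`NA`.
#' @slot nSkippedLoci number of loci excluded (fewer than 2 non-missing calls).
#' @export
setClass("SingletonProfile",
  slots = c(
    counts = "numeric",
    total = "numeric",
    proportions = "numeric",
    nSkippedLoci = "integer"
  )
)

setValidity("SingletonProfile", function(object) {
  msg <- NULL
  if (length(object@counts) != length(object@proportions))
    msg <- c(msg, "counts and proportions must have equal length")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (abs(sum(object@counts) - object@total) > 1e-9)
    msg <- c(msg, "total must equal the sum of per-chromosome counts")
  if (object@total > 0) {
    if (any(is.na(object@proportions)) ||
        abs(sum(object@proportions) - 1) > 1e-12)
      msg <- c(msg, "proportions must sum to 1 when total > 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' Group-wise summary of the empirical distribution of singletons
#'
#' @slot groupMean named per-group mean of individual singleton proportions.
#' @slot groupSD named per-group sample standard deviation.
#' @slot groupSize named group sizes.
#' @slot hexp named per-group expected heterozygosity (NA if not computed).
#' @slot ratio ratio of group means taken in user-given group order
#'   (first / second) for two groups, NA otherwise.
#' @slot defined FALSE when the profile carried no singleton.
#' @export
setClass("DiversitySummary",
  slots = c(
    groupMean = "numeric",
    groupSD = "numeric",
    groupSize = "numeric",
    hexp = "numeric",
    ratio = "numeric",
    defined = "logical"
  )
)

#' Georeferenced lattice of demes
#'
#' A rows x cols lattice over a regular lon/lat grid. Cell centers are given
#' by `lon` (west to east along columns) and `lat` (north to south along
#' rows, i.e. row 1 is the northernmost). `capacity` holds per-deme carrying
#' capacities; 0 marks uninhabitable cells (sea). `habitat` carries the
#' habitat class label used to assign capacities.
#'
#' @export
setClass("DemeGrid",
  slots = c(
    capacity = "matrix",
    habitat = "matrix",
    lon = "numeric",
    lat = "numeric"
  )
)

setValidity("DemeGrid", function(object) {
  msg <- NULL
  if (any(object@capacity < 0)) msg <- c(msg, "capacities must be >= 0")
  if (nrow(object@capacity) != length(object@lat) ||
      ncol(object@capacity) != length(object@lon))
    msg <- c(msg, "lon/lat must match the capacity matrix dimensions")
  if (!all(dim(object@capacity) == dim(object@habitat)))
    msg <- c(msg, "habitat and capacity must have identical dimensions")
  if (length(object@lon) > 1 && any(diff(object@lon) <= 0))
    msg <- c(msg, "lon must be strictly increasing")
  if (length(object@lat) > 1 && any(diff(object@lat) >= 0))
    msg <- c(msg, "lat must be strictly decreasing (row 1 = north)")
  if (is.null(msg)) TRUE else msg
})

#' Range-expansion scenario parameters
#'
#' Demographic parameters of a single-origin demic range expansion:
#' per-generation emigration fraction `migrationRate` (m), logistic growth
#' rate `growthRate` (r), expansion `duration` in generations, `ancestralSize`
#' of the source population, pre-expansion `lag` in generations, per-locus
#' per-generation `mutationRate`, and the number of independent loci `nLoci`.
#' Defaults follow the continental-scale study conditions (m = 0.07,
#' r = 0.1, 1600 generations, ancestral size 200, lag 200, mutation rate
#' 1e-5, 30000 loci).
#'
#' @export
setClass("ExpansionScenario",
  slots = c(
    originLon = "numeric",
    originLat = "numeric",
    migrationRate = "numeric",
    growthRate = "numeric",
    duration = "integer",
    ancestralSize = "numeric",
    lag = "integer",
    mutationRate = "numeric",
    nLoci = "integer"
  ),
  prototype = prototype(
    migrationRate = 0.07,
    growthRate = 0.1,
    duration = 1600L,
    ancestralSize = 200,
    lag = 200L,
    mutationRate = 1e-5,
    nLoci = 30000L
  )
)

setValidity("ExpansionScenario", function(object) {
  msg <- NULL
  if (object@migrationRate < 0 || object@migrationRate > 1)
    msg <- c(msg, "migrationRate must lie in [0, 1]")
  if (object@growthRate < 0) msg <- c(msg, "growthRate must be >= 0")
  if (object@duration < 1L) msg <- c(msg, "duration must be >= 1")
  if (object@ancestralSize <= 0) msg <- c(msg, "ancestralSize must be > 0")
  if (object@mutationRate < 0) msg <- c(msg, "mutationRate must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Recorded forward demography of a range expansion
#'
#' Deterministic per-generation deme densities (cells x generations,
#' generation 0 = initial state). Directed migrant flows are not stored:
#' the forward dynamics are deterministic, so flows are recomputed on
#' demand from consecutive density columns (see [migrantFlows()]).
#'
#' @export
setClass("OccupancyHistory",
  slots = c(
    grid = "DemeGrid",
    densities = "matrix",
    scenario = "ExpansionScenario",
    originCell = "integer"
  )
)

#' Spatially referenced sample of chromosomes
#'
#' One row per sampled chromosome: deme row/col indices on the grid, the
#' recorded geographic coordinates (cell center, or the jittered point for
#' individual sampling), and a site identifier shared by chromosomes drawn
#' at the same site.
#'
#' @export
setClass("SpatialSample",
  slots = c(
    demeRow = "integer",
    demeCol = "integer",
    lon = "numeric",
    lat = "numeric",
    siteId = "integer",
    mode = "character"
  )
)

#' Exponential variogram model
#'
#' Semivariance gamma(h) = nugget + sill * (1 - exp(-h / range)) for h > 0.
#'
#' @export
setClass("VariogramModel",
  slots = c(
    model = "character",
    nugget = "numeric",
    sill = "numeric",
    range = "numeric",
    distType = "character"
  ),
  prototype = prototype(model = "exponential", distType = "euclidean")
)

setValidity("VariogramModel", function(object) {
  msg <- NULL
  if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
  if (object@sill < 0) msg <- c(msg, "sill must be >= 0")
  if (object@range <= 0) msg <- c(msg, "range must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Interpolated diversity surface on a regular lon/lat grid
#'
#' `values` is a rows x cols matrix aligned with `lat` (north to south) and
#' `lon` (west to east); masked cells (outside the land region) are `NA`
#' with `mask == FALSE`.
#'
#' @export
setClass("DiversitySurface",
  slots = c(
    lon = "numeric",
    lat = "numeric",
    values = "matrix",
    mask = "matrix"
  )
)

#' Prior specification for the expansion-origin ABC
#'
#' Origin coordinates are drawn over a lon/lat box, down-weighted toward
#' the box edges by a triangular taper over the outer `taperFraction` of
#' each coordinate range, and constrained to habitable (capacity > 0)
#' cells of `grid`. Nuisance parameters (migration rate, growth rate,
#' duration, ancestral size, pre-expansion lag) are uniform on the ranges
#' in `nuisance`.
#'
#' @export
setClass("PriorSpec",
  slots = c(
    lonRange = "numeric",
    latRange = "numeric",
    taperFraction = "numeric",
    grid = "DemeGrid",
    nuisance = "list"
  )
)

setValidity("PriorSpec", function(object) {
  msg <- NULL
  if (diff(object@lonRange) <= 0 || diff(object@latRange) <= 0)
    msg <- c(msg, "lonRange and latRange must be increasing intervals")
  if (object@taperFraction < 0 || object@taperFraction >= 0.5)
    msg <- c(msg, "taperFraction must lie in [0, 0.5)")
  need <- c("migrationRate", "growthRate", "duration", "ancestralSize", "lag")
  if (!all(need %in% names(object@nuisance)))
    msg <- c(msg, paste("nuisance must contain ranges for:",
                        paste(need, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' ABC reference table
#'
#' Archive of prior-predictive simulations: one row per simulation with the
#' drawn parameters (`params`) and the singleton-histogram summary
#' statistic (`stats`, one column per spatial group). Row seeds and the
#' scenario configuration are kept in `metadata` so a table is reproducible
#' and resumable.
#'
#' @export
setClass("ReferenceTable",
  slots = c(
    params = "data.frame",
    stats = "matrix",
    seeds = "integer",
    metadata = "list"
  )
)

setValidity("ReferenceTable", function(object) {
  msg <- NULL
  if (nrow(object@params) != nrow(object@stats))
    msg <- c(msg, "params and stats must have the same number of rows")
  if (length(object@seeds) != nrow(object@params))
    msg <- c(msg, "one seed per row is required")
  if (anyDuplicated(object@seeds)) msg <- c(msg, "row seeds must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Posterior estimate of the expansion origin
#'
#' Accepted (and possibly regression-adjusted) parameter samples with
#' normalized weights, the joint lon/lat posterior density on a regular
#' grid, its mode, and equal-tailed credible intervals per coordinate.
#'
#' @export
setClass("PosteriorEstimate",
  slots = c(
    samples = "data.frame",
    weights = "numeric",
    lonGrid = "numeric",
    latGrid = "numeric",
    density = "matrix",
    mode = "numeric",
    ci = "list",
    method = "character",
    tolerance = "numeric"
  )
)

setValidity("PosteriorEstimate", function(object) {
  msg <- NULL
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (is.null(msg)) TRUE else msg
})
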