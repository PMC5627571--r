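## Spatially explicit demic range expansion: deterministic forward logistic
## demography with fractional migration on a von Neumann lattice, followed
## by a stochastic backward coalescent conditioned on the recorded
## densities, with infinite-sites mutation (rate per locus per generation).

#' Construct a DemeGrid
#'
#' @param habitat character matrix of habitat class labels (rows = north to
#'   south). Recognized classes: `"sea"`, `"other"`, `"semi-desert"`,
#'   `"extreme-desert"`, `"rain-forest"`.
#' @param lon,lat cell-center coordinates (lon increasing west to east,
#'   lat decreasing north to south).
#' @param capacity optional numeric matrix of carrying capacities; computed
#'   from `habitat` by [makeHabitatMap()] when omitted (all land = 100).
#' @return a [DemeGrid-class].
#' @export
DemeGrid <- function(habitat, lon, lat, capacity = NULL) {
  habitat <- as.matrix(habitat)
  if (is.null(capacity)) {
    capacity <- matrix(0, nrow(habitat), ncol(habitat))
    capacity[habitat != "sea"] <- 100
  }
  new("DemeGrid", capacity = capacity, habitat = habitat,
      lon = as.numeric(lon), lat = as.numeric(lat))
}

#' @rdname DemeGrid-class
#' @param x a `DemeGrid`.
#' @aliases capacity
#' @export
setMethod("capacity", "DemeGrid", function(x) x@capacity)

setMethod("show", "DemeGrid", function(object) {
  cat("DemeGrid:", nrow(object@capacity), "x", ncol(object@capacity),
      "demes;", sum(object@capacity > 0), "habitable\n")
  cat(sprintf("  lon [%.2f, %.2f], lat [%.2f, %.2f]\n",
              min(object@lon), max(object@lon),
              min(object@lat), max(object@lat)))
  cat("  habitat classes:",
      paste(names(table(object@habitat)), collapse = ", "), "\n")
})

#' Assign carrying capacities by habitat class
#'
#' Three capacity schemes over a land/sea + vegetation-class base grid:
#' `"homogeneous"` sets C = 100 on all land; `"vegetation"` sets C = 60 in
#' tropical semi-desert, C = 30 in tropical extreme deserts and rain
#' forests, C = 100 elsewhere on land; `"abc-vegetation"` sets C = 100 in
#' semi-desert, C = 20 in extreme desert, C = 10 in rain forest, C = 100
#' elsewhere on land.
#'
#' @param kind one of `"homogeneous"`, `"vegetation"`, `"abc-vegetation"`.
#' @param baseGrid a [DemeGrid-class] carrying the habitat classes.
#' @return a `DemeGrid` with updated capacities.
#' @export
makeHabitatMap <- function(kind = c("homogeneous", "vegetation",
                                    "abc-vegetation"), baseGrid) {
  kind <- match.arg(kind)
  hab <- baseGrid@habitat
  known <- c("sea", "other", "semi-desert", "extreme-desert", "rain-forest")
  if (!all(hab %in% known))
    stop("unknown habitat class: ",
         paste(setdiff(unique(as.vector(hab)), known), collapse = ", "))
  if (!any(hab != "sea")) stop("no habitable cell in the base grid")
  cap <- matrix(0, nrow(hab), ncol(hab))
  land <- hab != "sea"
  if (kind == "homogeneous") {
    cap[land] <- 100
  } else if (kind == "vegetation") {
    cap[land] <- 100
    cap[hab == "semi-desert"] <- 60
    cap[hab %in% c("extreme-desert", "rain-forest")] <- 30
  } else {
    cap[land] <- 100
    cap[hab == "semi-desert"] <- 100
    cap[hab == "extreme-desert"] <- 20
    cap[hab == "rain-forest"] <- 10
  }
  initialize(baseGrid, capacity = cap)
}

#' Construct an ExpansionScenario
#'
#' @param originLon,originLat geographic origin of the expansion (degrees).
#' @param migrationRate per-generation emigration fraction m.
#' @param growthRate logistic growth rate r.
#' @param duration expansion duration in generations.
#' @param ancestralSize effective size of the ancestral (source) population.
#' @param lag pre-expansion lag in generations (part of the ancestral,
#'   constant-size phase).
#' @param mutationRate per-locus per-generation mutation rate.
#' @param nLoci number of independent loci surveyed.
#' @return an [ExpansionScenario-class].
#' @export
expansionScenario <- function(originLon, originLat, migrationRate = 0.07,
                              growthRate = 0.1, duration = 1600L,
                              ancestralSize = 200, lag = 200L,
                              mutationRate = 1e-5, nLoci = 30000L) {
  new("ExpansionScenario", originLon = originLon, originLat = originLat,
      migrationRate = migrationRate, growthRate = growthRate,
      duration = as.integer(duration), ancestralSize = ancestralSize,
      lag = as.integer(lag), mutationRate = mutationRate,
      nLoci = as.integer(nLoci))
}

# Cell index helpers: cells are numbered column-major over rows x cols.
cellIndex <- function(row, col, nr) (col - 1L) * nr + row

nearestCell <- function(grid, lon, lat) {
  row <- which.min(abs(grid@lat - lat))
  col <- which.min(abs(grid@lon - lon))
  c(row = row, col = col)
}

# 4-neighborhood bookkeeping: for each cell, which von Neumann neighbors
# are habitable. Returns a list with the degree vector and, per direction,
# the (from, to) cell index pairs.
neighborStructure <- function(grid) {
  cap <- grid@capacity
  nr <- nrow(cap); nc <- ncol(cap)
  hab <- cap > 0
  dirs <- list(n = c(-1L, 0L), s = c(1L, 0L), w = c(0L, -1L), e = c(0L, 1L))
  edges <- lapply(dirs, function(d) {
    rows <- seq_len(nr); cols <- seq_len(nc)
    fromR <- rep(rows, nc); fromC <- rep(cols, each = nr)
    toR <- fromR + d[1]; toC <- fromC + d[2]
    ok <- toR >= 1L & toR <= nr & toC >= 1L & toC <= nc
    from <- cellIndex(fromR[ok], fromC[ok], nr)
    to <- cellIndex(toR[ok], toC[ok], nr)
    keep <- hab[from] & hab[to]
    cbind(from = from[keep], to = to[keep])
  })
  deg <- numeric(nr * nc)
  for (e in edges) {
    t1 <- tabulate(e[, "from"], nbins = nr * nc)
    deg <- deg + t1
  }
  list(edges = edges, degree = deg, habitable = as.vector(hab))
}

# One forward generation: logistic growth then fractional emigration split
# equally among habitable neighbors. N and the return value are vectors
# over cells; growth result is also returned (needed by the backward pass).
forwardStep <- function(N, cap, m, r, ns) {
  G <- N
  hab <- ns$habitable
  G[hab] <- N[hab] + r * N[hab] * (1 - N[hab] / cap[hab])
  G[G < 0] <- 0
  pos <- ns$degree > 0
  out <- numeric(length(G))
  out[pos] <- m * G[pos]
  Nnew <- G - out
  share <- numeric(length(G))
  share[pos] <- out[pos] / ns$degree[pos]
  for (e in ns$edges) {
    fl <- share[e[, "from"]]
    Nnew[e[, "to"]] <- Nnew[e[, "to"]] + fl
  }
  list(N = Nnew, G = G)
}

#' Run the deterministic forward demography of a range expansion
#'
#' The origin deme is initialized with the ancestral effective size; each
#' generation, every occupied deme grows logistically toward its carrying
#' capacity (`N <- N + r N (1 - N/C)`) and a fraction `m` of its
#' individuals emigrates, split equally among habitable von Neumann
#' neighbors. Densities are real-valued and recorded every generation;
#' stochasticity is confined to the backward coalescent.
#'
#' @param grid a [DemeGrid-class].
#' @param scenario an [ExpansionScenario-class]; its origin must fall on a
#'   habitable cell.
#' @return an [OccupancyHistory-class].
#' @export
runForwardDemography <- function(grid, scenario) {
  rc <- nearestCell(grid, scenario@originLon, scenario@originLat)
  nr <- nrow(grid@capacity)
  oc <- cellIndex(rc["row"], rc["col"], nr)
  if (grid@capacity[oc] <= 0) {
    hab <- which(grid@capacity > 0)
    hr <- (hab - 1L) %% nr + 1L; hc <- (hab - 1L) %/% nr + 1L
    d2 <- (grid@lat[hr] - scenario@originLat)^2 +
          (grid@lon[hc] - scenario@originLon)^2
    j <- which.min(d2)
    stop(sprintf(
      "origin (%.2f, %.2f) falls on an uninhabitable cell; nearest habitable cell is (%.2f, %.2f)",
      scenario@originLon, scenario@originLat, grid@lon[hc[j]], grid@lat[hr[j]]))
  }
  ns <- neighborStructure(grid)
  cap <- as.vector(grid@capacity)
  ncells <- length(cap)
  Tgen <- scenario@duration
  dens <- matrix(0, ncells, Tgen + 1L)
  N <- numeric(ncells)
  N[oc] <- scenario@ancestralSize
  dens[, 1L] <- N
  for (t in seq_len(Tgen)) {
    st <- forwardStep(N, cap, scenario@migrationRate, scenario@growthRate, ns)
    N <- st$N
    dens[, t + 1L] <- N
  }
  new("OccupancyHistory", grid = grid, densities = dens,
      scenario = scenario, originCell = as.integer(oc))
}

#' Directed migrant flows for one generation
#'
#' Recomputes, from the recorded densities, the directed migrant counts of
#' the forward step leading into generation `gen` (1-based over the
#' expansion): per direction, a matrix of migrants from each cell to its
#' neighbor, plus the post-growth pool and the stay counts.
#'
#' @param history an [OccupancyHistory-class].
#' @param gen generation in `1..duration`.
#' @return list with `postGrowth`, `stay`, and per-direction flow vectors
#'   (`n`, `s`, `w`, `e`) over cells (column-major).
#' @export
migrantFlows <- function(history, gen) {
  stopifnot(gen >= 1, gen <= history@scenario@duration)
  ns <- neighborStructure(history@grid)
  cap <- as.vector(capacity(history@grid))
  N <- history@densities[, gen]
  m <- history@scenario@migrationRate
  r <- history@scenario@growthRate
  G <- N
  hab <- ns$habitable
  G[hab] <- N[hab] + r * N[hab] * (1 - N[hab] / cap[hab])
  G[G < 0] <- 0
  out <- m * G
  out[ns$degree == 0] <- 0
  share <- ifelse(ns$degree > 0, out / pmax(ns$degree, 1), 0)
  flows <- lapply(ns$edges, function(e) {
    f <- numeric(length(cap))
    f[e[, "from"]] <- share[e[, "from"]]
    f
  })
  c(list(postGrowth = G, stay = G - out), flows)
}

#' Draw a spatial sampling design
#'
#' Population mode places `chromsPerSite` haploid chromosomes at each of
#' `nSites` occupied demes spread quasi-uniformly over the occupied range
#' (k-means on occupied cell coordinates, snapped to occupied cells).
#' Individual mode records one chromosome at `nSites * chromsPerSite`
#' distinct sites, each a population center jittered by independent
#' Gaussian noise (SD `jitterSD` degrees in lon and lat) and snapped to
#' the nearest occupied cell; jitters with no occupied cell within
#' `searchRadius` cells are redrawn (with attempt logging).
#'
#' @param history an [OccupancyHistory-class].
#' @param mode `"population"` or `"individual"`.
#' @param nSites number of base sites (default 30).
#' @param chromsPerSite chromosomes per base site (default 10).
#' @param jitterSD Gaussian jitter SD in degrees (individual mode).
#' @param searchRadius snap search radius in cells.
#' @param minOccupancy a deme counts as occupied above this density.
#' @return a [SpatialSample-class].
#' @export
drawSamplingDesign <- function(history, mode = c("population", "individual"),
                               nSites = 30L, chromsPerSite = 10L,
                               jitterSD = 2, searchRadius = 6L,
                               minOccupancy = 1) {
  mode <- match.arg(mode)
  grid <- history@grid
  nr <- nrow(grid@capacity)
  finalN <- history@densities[, ncol(history@densities)]
  occ <- which(finalN >= minOccupancy)
  if (length(occ) < nSites)
    stop("fewer occupied demes (", length(occ), ") than requested sites")
  occR <- (occ - 1L) %% nr + 1L; occC <- (occ - 1L) %/% nr + 1L
  occLon <- grid@lon[occC]; occLat <- grid@lat[occR]
  km <- kmeans(cbind(occLon, occLat), centers = min(nSites, length(occ)),
               iter.max = 50, nstart = 5)
  centers <- km$centers
  centerCell <- vapply(seq_len(nrow(centers)), function(i) {
    occ[which.min((occLon - centers[i, 1])^2 + (occLat - centers[i, 2])^2)]
  }, integer(1))
  centerCell <- unique(centerCell)
  while (length(centerCell) < nSites) {  # top up if snapping collided
    pool <- setdiff(occ, centerCell)
    centerCell <- c(centerCell, pool[sample.int(length(pool), 1)])
  }
  cR <- (centerCell - 1L) %% nr + 1L; cC <- (centerCell - 1L) %/% nr + 1L
  if (mode == "population") {
    k <- chromsPerSite
    new("SpatialSample",
        demeRow = rep(cR, each = k), demeCol = rep(cC, each = k),
        lon = rep(grid@lon[cC], each = k), lat = rep(grid@lat[cR], each = k),
        siteId = rep(seq_along(centerCell), each = k), mode = mode)
  } else {
    nTot <- nSites * chromsPerSite
    baseLon <- rep(grid@lon[cC], each = chromsPerSite)
    baseLat <- rep(grid@lat[cR], each = chromsPerSite)
    sLon <- numeric(nTot); sLat <- numeric(nTot)
    dRow <- integer(nTot); dCol <- integer(nTot)
    cellW <- mean(diff(grid@lon))
    attempts <- 0L
    for (i in seq_len(nTot)) {
      repeat {
        attempts <- attempts + 1L
        jl <- baseLon[i] + rnorm(1, 0, jitterSD)
        jb <- baseLat[i] + rnorm(1, 0, jitterSD)
        d2 <- (occLon - jl)^2 + (occLat - jb)^2
        j <- which.min(d2)
        if (sqrt(d2[j]) <= searchRadius * cellW) {
          sLon[i] <- jl; sLat[i] <- jb
          dRow[i] <- occR[j]; dCol[i] <- occC[j]
          break
        }
      }
    }
    if (attempts > nTot)
      message("drawSamplingDesign: ", attempts - nTot, " jitters redrawn")
    new("SpatialSample", demeRow = dRow, demeCol = dCol,
        lon = sLon, lat = sLat, siteId = seq_len(nTot), mode = mode)
  }
}

setMethod("show", "SpatialSample", function(object) {
  cat("SpatialSample:", length(object@demeRow), "chromosomes at",
      length(unique(object@siteId)), "sites (", object@mode, "mode )\n")
})

#' Backward coalescent conditioned on a recorded range expansion
#'
#' Per locus independently, sampled lineages trace backward through the
#' recorded history: each generation a lineage in deme j picks its source
#' deme with probability proportional to the forward migrant flow into j
#' (including the stayers), then lineages sharing a source deme of
#' post-growth size N coalesce pairwise with probability 1/N (multiple
#' mergers resolved sequentially). Lineages surviving to the onset of the
#' expansion coalesce in a panmictic ancestral population of the scenario's
#' ancestral size. Mutations fall on each lineage-generation with rate
#' `mutationRate`; every mutation yields one biallelic site carried by the
#' lineage's descendants (infinite sites). Sites fixed in the whole sample
#' cannot arise (mutation stops at each locus MRCA).
#'
#' @param history an [OccupancyHistory-class].
#' @param sample a [SpatialSample-class]; all sampled demes must be
#'   occupied at sampling time.
#' @param nLoci number of loci (defaults to the scenario's).
#' @param returnTrees also return per-locus genealogies (ape `phylo`,
#'   branch lengths in generations); intended for small runs.
#' @return a [HaplotypeMatrix-class] with one column per chromosome and one
#'   row per segregating site; `rowData` holds the locus index, `colData`
#'   the sample coordinates. `metadata(x)$nLociPolymorphic` counts loci
#'   with at least one site. With `returnTrees = TRUE` the genealogies are
#'   in `metadata(x)$trees`.
#' @export
sampleBackwardCoalescent <- function(history, sample, nLoci = NULL,
                                     returnTrees = FALSE) {
  scen <- history@scenario
  if (is.null(nLoci)) nLoci <- scen@nLoci
  nLoci <- as.integer(nLoci)
  grid <- history@grid
  nr <- nrow(grid@capacity)
  ncells <- length(grid@capacity)
  nChrom <- length(sample@demeRow)
  Tgen <- scen@duration
  mu <- scen@mutationRate
  sampleCells <- cellIndex(sample@demeRow, sample@demeCol, nr)
  finalN <- history@densities[, Tgen + 1L]
  if (any(finalN[sampleCells] <= 0))
    stop("sampled deme unoccupied at sampling time")
  ns <- neighborStructure(grid)
  cap <- as.vector(capacity(grid))
  m <- scen@migrationRate; r <- scen@growthRate

  # active lineage state, flattened across loci
  linCell <- rep(sampleCells, nLoci)
  linLocus <- rep(seq_len(nLoci), each = nChrom)
  linId <- rep(seq_len(nChrom), nLoci)          # representative chromosome
  desc <- rep(lapply(seq_len(nChrom), identity), nLoci)
  mutCarriers <- list(); mutLocus <- integer(0)
  trees <- NULL
  if (returnTrees) {
    trMerge <- lapply(seq_len(nLoci), function(i) NULL)  # rows: c1,c2,time
    linNode <- rep(seq_len(nChrom), nLoci)
    nextNode <- rep(nChrom + 1L, nLoci)
  }
  # per-direction reverse lookup: for flows entering cell j from its
  # neighbor in direction d, the source cell; sentinel ncells+1 (zero
  # share) marks "no habitable neighbor in that direction"
  sentinel <- ncells + 1L
  revEdges <- lapply(ns$edges, function(e) {
    src <- rep(sentinel, ncells); src[e[, "to"]] <- e[, "from"]; src
  })
  habIdx <- which(ns$habitable)
  posDeg <- which(ns$degree > 0)

  addMutations <- function(idx, dt) {
    # idx: active row indices; dt: generations of branch per lineage
    lam <- mu * dt
    nm <- rpois(length(idx), lam)
    hit <- which(nm > 0L)
    for (h in hit) {
      for (q in seq_len(nm[h])) {
        mutCarriers[[length(mutCarriers) + 1L]] <<- desc[[idx[h]]]
        mutLocus[length(mutCarriers)] <<- linLocus[idx[h]]
      }
    }
  }

  coalesceGroups <- function(gen, poolSize) {
    # pairwise merge within (locus, cell) groups; the number of merging
    # pairs per group is Binomial(k(k-1)/2, 1/N), resolved sequentially
    key <- (linCell - 1) * (nLoci + 1) + linLocus
    ord <- order(key)
    ko <- key[ord]
    runEnds <- c(which(diff(ko) != 0), length(ko))
    runStarts <- c(1L, head(runEnds, -1L) + 1L)
    sizes <- runEnds - runStarts + 1L
    pc <- 1 / pmax(1, poolSize[linCell[ord[runStarts]]])
    nMerge <- rbinom(length(sizes), sizes * (sizes - 1L) / 2, pc)
    nMerge <- pmin(nMerge, sizes - 1L)
    big <- which(nMerge > 0L)
    if (!length(big)) return(invisible(NULL))
    kill <- logical(length(linCell))
    for (b in big) {
      members <- ord[runStarts[b]:runEnds[b]]
      for (q in seq_len(nMerge[b])) {
        act <- members[!kill[members]]
        if (length(act) < 2L) break
        pick <- act[sample.int(length(act), 2L)]
        a <- pick[1]; bq <- pick[2]
        desc[[a]] <<- c(desc[[a]], desc[[bq]])
        kill[bq] <- TRUE
        if (returnTrees) {
          lc <- linLocus[a]
          trMerge[[lc]] <<- rbind(trMerge[[lc]],
                                  c(linNode[a], linNode[bq], gen))
          linNode[a] <<- nextNode[lc]
          nextNode[lc] <<- nextNode[lc] + 1L
        }
      }
    }
    if (any(kill)) {
      keep <- !kill
      linCell <<- linCell[keep]; linLocus <<- linLocus[keep]
      linId <<- linId[keep]; desc <<- desc[keep]
      if (returnTrees) linNode <<- linNode[keep]
    }
    invisible(NULL)
  }

  dropDone <- function() {
    # retire loci that reached their MRCA
    cnt <- tabulate(linLocus, nbins = nLoci)
    done <- cnt[linLocus] == 1L
    if (any(done)) {
      keep <- !done
      linCell <<- linCell[keep]; linLocus <<- linLocus[keep]
      linId <<- linId[keep]; desc <<- desc[keep]
      if (returnTrees) linNode <<- linNode[keep]
    }
  }

  for (t in seq(Tgen, 1L)) {
    if (!length(linCell)) break
    N_prev <- history@densities[, t]
    G <- N_prev
    G[habIdx] <- N_prev[habIdx] +
      r * N_prev[habIdx] * (1 - N_prev[habIdx] / cap[habIdx])
    G[G < 0] <- 0
    out <- numeric(ncells)
    out[posDeg] <- m * G[posDeg]
    stay <- G - out
    share <- c(numeric(ncells), 0)
    share[posDeg] <- out[posDeg] / ns$degree[posDeg]
    # categorical backward source per lineage: stay or one of 4 neighbors
    A <- length(linCell)
    wStay <- stay[linCell]
    wDir <- matrix(0, A, 4L)
    for (d in 1:4) wDir[, d] <- share[revEdges[[d]][linCell]]
    tot <- wStay + wDir[, 1] + wDir[, 2] + wDir[, 3] + wDir[, 4]
    if (any(tot <= 0))
      stop("lineage stranded in an empty deme at generation ", t,
           ", cell ", linCell[which(tot <= 0)[1]])
    u <- runif(length(linCell)) * tot
    newCell <- linCell
    acc <- wStay
    undecided <- u > acc
    for (d in seq_along(revEdges)) {
      pickd <- undecided & (u <= acc + wDir[, d])
      if (any(pickd)) {
        src <- revEdges[[d]][linCell[pickd]]
        newCell[pickd] <- src
      }
      acc <- acc + wDir[, d]
      undecided <- u > acc
    }
    linCell <- newCell
    # mutations for this generation (one generation of branch each)
    addMutations(seq_along(linCell), rep(1, length(linCell)))
    # coalescence in the source pools
    coalesceGroups(Tgen - t + 1L, G)
    dropDone()
  }

  # ancestral panmictic phase: geometric waiting times per locus
  if (length(linCell)) {
    Na <- max(1, scen@ancestralSize)
    for (lc in unique(linLocus)) {
      idx <- which(linLocus == lc)
      k <- length(idx)
      gen0 <- Tgen
      while (k > 1L) {
        pAny <- 1 - (1 - 1 / Na)^(k * (k - 1) / 2)
        dt <- rgeom(1, pAny) + 1L
        addMutations(idx, rep(dt, length(idx)))
        pick <- sample.int(k, 2L)
        a <- idx[pick[1]]; bq <- idx[pick[2]]
        desc[[a]] <- c(desc[[a]], desc[[bq]])
        if (returnTrees) {
          gen0 <- gen0 + dt
          trMerge[[lc]] <- rbind(trMerge[[lc]],
                                 c(linNode[a], linNode[bq], gen0))
          linNode[a] <- nextNode[lc]
          nextNode[lc] <- nextNode[lc] + 1L
        }
        idx <- idx[-pick[2]]
        k <- k - 1L
      }
    }
  }

  S <- length(mutCarriers)
  geno <- matrix(0L, S, nChrom)
  for (i in seq_len(S)) geno[i, mutCarriers[[i]]] <- 1L
  ids <- paste0("chr", seq_len(nChrom))
  hm <- HaplotypeMatrix(geno, chromosomeIds = ids,
                        coords = data.frame(lon = sample@lon,
                                            lat = sample@lat,
                                            siteId = sample@siteId,
                                            demeRow = sample@demeRow,
                                            demeCol = sample@demeCol))
  if (S > 0)
    SummarizedExperiment::rowData(hm)$locus <- mutLocus
  S4Vectors::metadata(hm)$nLociPolymorphic <- length(unique(mutLocus))
  S4Vectors::metadata(hm)$nLociSimulated <- nLoci
  if (returnTrees) {
    S4Vectors::metadata(hm)$trees <- lapply(seq_len(nLoci), function(lc) {
      mm <- trMerge[[lc]]
      if (is.null(mm) || nrow(mm) != nChrom - 1L) return(NULL)
      treeFromMerges(nChrom, mm[, 1:2, drop = FALSE], mm[, 3], ids)
    })
  }
  hm
}

#' Remove monomorphic loci
#'
#' Drops sites whose derived-allele frequency among non-missing calls is 0
#' or 1; the removal count is reported via `message()`.
#'
#' @param x a [HaplotypeMatrix-class].
#' @return the filtered `HaplotypeMatrix`.
#' @export
filterMonomorphic <- function(x) {
  stopifnot(is(x, "HaplotypeMatrix"))
  a <- alleles(x)
  d <- rowSums(a == 1L, na.rm = TRUE)
  k <- rowSums(!is.na(a))
  keep <- k > 0 & d > 0 & d < k
  nDrop <- sum(!keep)
  if (nDrop > 0) message("filterMonomorphic: removed ", nDrop, " loci")
  x[keep, ]
}
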