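## Coalescent simulators with infinite-sites mutation.
##
## Time is measured in units of 2*N1 generations throughout: while k
## lineages are active in a population of relative size x, coalescence
## occurs at rate k(k-1)/2 / x, and mutations fall on a branch of length l
## as Poisson(theta/2 * l) with theta = 2*mu*N. Under these conventions
## E[tau1] = 2 and E[xi1] = theta for a panmictic constant-size population.

# Assemble an ape phylo from merge records. times: node times (tips at 0);
# merges: (n-1) x 2 matrix of child node ids in creation order, creation c
# producing internal node n + c with time internalTimes[c]. Internal ids are
# remapped so the root (last created) becomes n + 1, as ape expects. Edge
# rows are emitted in creation order, so descendant edges always precede
# the edge above them (children-first order, usable for postorder passes).
treeFromMerges <- function(nTips, merges, internalTimes, tipLabels) {
  nInt <- nTips - 1L
  remap <- function(id) ifelse(id <= nTips, id, nTips + (nInt - (id - nTips)) + 1L)
  parents <- remap(nTips + seq_len(nInt))
  edge <- matrix(0L, 2L * nInt, 2L)
  elen <- numeric(2L * nInt)
  nodeTime <- c(rep(0, nTips), internalTimes)
  for (cix in seq_len(nInt)) {
    r <- 2L * (cix - 1L)
    for (j in 1:2) {
      ch <- merges[cix, j]
      edge[r + j, ] <- c(parents[cix], remap(ch))
      elen[r + j] <- internalTimes[cix] - nodeTime[ch]
    }
  }
  tr <- list(edge = edge, edge.length = elen, Nnode = nInt,
             tip.label = tipLabels)
  class(tr) <- "phylo"
  attr(tr, "smOrder") <- "children-first"
  tr
}

#' Simulate a neutral Kingman coalescent genealogy
#'
#' While `k` lineages remain, the waiting time to the next coalescence is
#' exponential with rate `k(k-1)/2` (time in units of 2N generations) and a
#' uniformly random pair merges. The expected total external branch length
#' is 2 and each external branch has expected length `2/n`.
#'
#' @param n sample size (>= 2).
#' @param tipLabels optional tip labels (default `t1..tn`).
#' @return a `phylo` genealogy with branch lengths in coalescent units.
#' @export
simulateNeutralGenealogy <- function(n, tipLabels = paste0("t", seq_len(n))) {
  stopifnot(n >= 2)
  n <- as.integer(n)
  active <- seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  itimes <- numeric(n - 1L)
  tau <- 0
  waits <- rexp(n - 1L) / (choose(seq(n, 2L), 2L))
  for (cix in seq_len(n - 1L)) {
    k <- n - cix + 1L
    tau <- tau + waits[cix]
    pick <- sample.int(k, 2L)
    merges[cix, ] <- active[pick]
    itimes[cix] <- tau
    active <- c(active[-pick], n + cix)
  }
  treeFromMerges(n, merges, itimes, tipLabels)
}

#' Parameters of the two-population split model
#'
#' Backward in time: two populations with no migration; population 1 has
#' present size `n1` and shrinks exponentially (looking backward) at the
#' ms-scale rate `growthRateMs` until ms-time `growthEndMs`; population 2
#' is constant at relative size `shrinkRate` (s) and joins population 1 at
#' the split time. Defaults mirror the standard configuration
#' `-t theta -I 2 50 50 -g 1 46.05 -n 2 s -eg 0.2 1 0.0 -ej t 2 1` with
#' N1 = 50,000: at 10,000 generations ago the backward size equals the
#' ancestral size 5,000.
#'
#' `splitTimeGen` and `theta` set to `NA` are redrawn uniformly on
#' `splitTimeRange` (generations) and `thetaRange` for each replicate.
#' `ancestralPhase = "ms-command"` follows the ms flags verbatim (size
#' frozen at `exp(-46.05 * 0.2)` of N1 deeper than ms-time 0.2);
#' `"hold-ancestral"` instead holds the size at `ancestralSize` deeper than
#' `expansionStartGen` generations ago.
#'
#' @param n1 present size of population 1.
#' @param shrinkRate relative size s of population 2, in (0, 1].
#' @param splitTimeGen split time in generations (NA = draw per replicate).
#' @param theta per-locus effective mutation rate (NA = draw per replicate).
#' @param sampleSizes sample sizes for populations 1 and 2.
#' @param nLoci unlinked loci per replicate.
#' @param thetaRange,splitTimeRange uniform ranges used when drawing.
#' @param growthRateMs,growthEndMs growth flags on the ms (4N) time scale.
#' @param ancestralSize,expansionStartGen ancestral size and onset of the
#'   expansion of population 1, used by the `"hold-ancestral"` phase.
#' @param ancestralPhase `"ms-command"` or `"hold-ancestral"`.
#' @param thetaScale factor applied to `theta` when dropping mutations on
#'   split-model genealogies. `theta` is the effective mutation rate in the
#'   2-mu-N convention of the theory; converting it to the ms `-t` input
#'   (4 N0 mu) on the study's time scale doubles it, hence the default 2.
#'   Set to 1 for a clock where a panmictic constant-size population gives
#'   E\[xi1\] = theta exactly.
#' @return an object of class `SplitModelParams`.
#' @export
splitModelParams <- function(n1 = 50000, shrinkRate = 0.33,
                             splitTimeGen = NA_real_, theta = NA_real_,
                             sampleSizes = c(50L, 50L), nLoci = 1000L,
                             thetaRange = c(5, 10),
                             splitTimeRange = c(1000, 10000),
                             growthRateMs = 46.05, growthEndMs = 0.2,
                             ancestralSize = 5000, expansionStartGen = 10000,
                             ancestralPhase = c("ms-command", "hold-ancestral"),
                             thetaScale = 2) {
  ancestralPhase <- match.arg(ancestralPhase)
  stopifnot(n1 > 0, shrinkRate > 0, shrinkRate <= 1, all(sampleSizes >= 1),
            thetaScale > 0)
  structure(list(
    n1 = n1, shrinkRate = shrinkRate, splitTimeGen = splitTimeGen,
    theta = theta, sampleSizes = as.integer(sampleSizes),
    nLoci = as.integer(nLoci), thetaRange = thetaRange,
    splitTimeRange = splitTimeRange, growthRateMs = growthRateMs,
    growthEndMs = growthEndMs, ancestralSize = ancestralSize,
    expansionStartGen = expansionStartGen, ancestralPhase = ancestralPhase,
    thetaScale = thetaScale
  ), class = "SplitModelParams")
}

# Resolve per-replicate draws and convert to the internal 2N1 time scale.
resolveSplitParams <- function(params) {
  t_gen <- params$splitTimeGen
  if (is.na(t_gen)) t_gen <- runif(1, params$splitTimeRange[1], params$splitTimeRange[2])
  th <- params$theta
  if (is.na(th)) th <- runif(1, params$thetaRange[1], params$thetaRange[2])
  alpha <- params$growthRateMs / 2              # per 2N1 units
  tEnd <- if (params$ancestralPhase == "ms-command") params$growthEndMs * 2
          else params$expansionStartGen / (2 * params$n1)
  xDeep <- if (params$ancestralPhase == "ms-command") exp(-alpha * tEnd)
           else params$ancestralSize / params$n1
  list(tSplit = t_gen / (2 * params$n1), theta = th, alpha = alpha,
       tEnd = tEnd, xDeep = xDeep, splitTimeGen = t_gen)
}

# Waiting time to the next coalescence in population 1 from time tau, with
# k lineages: rate c1 * exp(alpha * t) while t < tEnd (backward exponential
# shrinkage), constant c1 / xDeep afterwards. Inversion of the cumulative
# hazard; exact across the epoch boundary.
pop1WaitTime <- function(k, tau, alpha, tEnd, xDeep) {
  if (k < 2L) return(Inf)
  c1 <- k * (k - 1) / 2
  E <- rexp(1)
  if (tau >= tEnd) return(E * xDeep / c1)
  if (alpha == 0) {
    w <- E / c1
    if (tau + w <= tEnd) return(w)
    E <- E - c1 * (tEnd - tau)
    return((tEnd - tau) + E * xDeep / c1)
  }
  hazToEnd <- c1 / alpha * (exp(alpha * tEnd) - exp(alpha * tau))
  if (E <= hazToEnd) {
    return(log(exp(alpha * tau) + alpha * E / c1) / alpha - tau)
  }
  (tEnd - tau) + (E - hazToEnd) * xDeep / (c1)
}

#' Simulate a genealogy under the two-population split model
#'
#' Backward-in-time structured coalescent for [splitModelParams()]:
#' no migration before the join; population 2 at constant relative size s;
#' population 1 shrinking backward per its growth schedule; at the split
#' time every population-2 lineage moves to population 1. Tips `1..n1s`
#' belong to population 1, the remainder to population 2. Returns a `phylo`
#' whose `resolved` attribute records the per-replicate draws.
#'
#' @param params a `SplitModelParams` object.
#' @return a `phylo` with branch lengths in units of 2 N1 generations.
#' @export
simulateStructuredGenealogy <- function(params) {
  stopifnot(inherits(params, "SplitModelParams"))
  rp <- resolveSplitParams(params)
  n1s <- params$sampleSizes[1]; n2s <- params$sampleSizes[2]
  n <- n1s + n2s
  s <- params$shrinkRate
  active1 <- seq_len(n1s)
  active2 <- n1s + seq_len(n2s)
  merges <- matrix(0L, n - 1L, 2L)
  itimes <- numeric(n - 1L)
  tau <- 0
  cix <- 0L
  joined <- FALSE
  while (length(active1) + length(active2) > 1L) {
    k1 <- length(active1); k2 <- length(active2)
    w1 <- pop1WaitTime(k1, tau, rp$alpha, rp$tEnd, rp$xDeep)
    w2 <- if (k2 >= 2L) rexp(1) / (k2 * (k2 - 1) / 2 / s) else Inf
    if (!joined && min(w1, w2) > rp$tSplit - tau) {
      tau <- rp$tSplit
      active1 <- c(active1, active2)
      active2 <- integer(0)
      joined <- TRUE
      next
    }
    cix <- cix + 1L
    if (w1 <= w2) {
      tau <- tau + w1
      pick <- sample.int(k1, 2L)
      merges[cix, ] <- active1[pick]
      active1 <- c(active1[-pick], n + cix)
    } else {
      tau <- tau + w2
      pick <- sample.int(k2, 2L)
      merges[cix, ] <- active2[pick]
      active2 <- c(active2[-pick], n + cix)
    }
    itimes[cix] <- tau
    if (!joined && tau >= rp$tSplit) {
      # can only happen when the event landed exactly at the boundary
      active1 <- c(active1, active2); active2 <- integer(0); joined <- TRUE
    }
  }
  labels <- c(paste0("p1_", seq_len(n1s)), paste0("p2_", seq_len(n2s)))
  tr <- treeFromMerges(n, merges, itimes, labels)
  attr(tr, "resolved") <- rp
  tr
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each branch receives a Poisson(theta/2 x length) number of mutations;
#' every mutation creates a new biallelic site whose derived allele is
#' carried by all tips below the branch.
#'
#' @param tree a `phylo` genealogy.
#' @param theta effective mutation rate (mutations per 2/theta units of
#'   branch length); `theta = 0` yields a 0-column matrix.
#' @return 0/1 integer matrix, chromosomes (tips) x sites, with tip labels
#'   as row names.
#' @export
dropMutations <- function(tree, theta) {
  checkGenealogy(tree)
  stopifnot(theta >= 0)
  n <- length(tree$tip.label)
  E <- nrow(tree$edge)
  ord <- if (identical(attr(tree, "smOrder"), "children-first")) seq_len(E)
         else ape::postorder(tree)
  nmut <- rpois(E, theta / 2 * tree$edge.length)
  S <- sum(nmut)
  out <- matrix(0L, n, S, dimnames = list(tree$tip.label, NULL))
  descNode <- vector("list", n + tree$Nnode)
  col <- 0L
  for (i in ord) {
    ch <- tree$edge[i, 2]
    d <- if (ch <= n) ch else descNode[[ch]]
    pa <- tree$edge[i, 1]
    descNode[[pa]] <- c(descNode[[pa]], d)
    m <- nmut[i]
    if (m > 0L) {
      out[d, col + seq_len(m)] <- 1L
      col <- col + m
    }
  }
  out
}

#' Replicate the split-model singleton study
#'
#' For each replicate: simulate `nLoci` unlinked infinite-sites loci under
#' the split model, assemble the haplotype matrix, count singletons, and
#' summarize the empirical distribution of singletons by population (mean
#' proportion, standard deviation, ratio of population means). Replicates
#' with zero singletons are recorded with `NA` summaries.
#'
#' @param params a `SplitModelParams`; `NA` entries for `theta` /
#'   `splitTimeGen` are redrawn each replicate.
#' @param nReplicates number of replicates (>= 1).
#' @param seed optional integer seed.
#' @param keepTheoretical also compute the tree-based theoretical
#'   distribution p (mean external-branch ratio) per replicate; returned as
#'   the `"theoretical"` attribute (list of matrices with rows `p`,
#'   `pHat`).
#' @return data.frame with one row per replicate: `theta`, `splitTimeGen`,
#'   `pi1`, `pi2`, `ratio`, `sd1`, `sd2`, `xi1`, `polymorphicSites`.
#' @export
replicateSplitStudy <- function(params, nReplicates, seed = NULL,
                                keepTheoretical = FALSE) {
  stopifnot(nReplicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  n1s <- params$sampleSizes[1]; n2s <- params$sampleSizes[2]
  groups <- factor(rep(c("pop1", "pop2"), c(n1s, n2s)))
  res <- vector("list", nReplicates)
  theo <- if (keepTheoretical) vector("list", nReplicates) else NULL
  for (r in seq_len(nReplicates)) {
    rp <- resolveSplitParams(params)
    fixed <- params
    fixed$theta <- rp$theta
    fixed$splitTimeGen <- rp$splitTimeGen
    blocks <- vector("list", params$nLoci)
    ratioSum <- 0
    nTrees <- 0L
    for (l in seq_len(params$nLoci)) {
      tr <- simulateStructuredGenealogy(fixed)
      blocks[[l]] <- dropMutations(tr, params$thetaScale * rp$theta)
      if (keepTheoretical) {
        tauv <- externalBranchLengths(tr)
        ratioSum <- ratioSum + tauv / sum(tauv)
        nTrees <- nTrees + 1L
      }
    }
    geno <- do.call(cbind, blocks)
    hm <- HaplotypeMatrix(t(geno))
    prof <- countSingletons(hm)
    summ <- groupSummaries(prof, setNames(as.character(groups), chromosomeIds(hm)))
    m <- groupMeans(summ); sdv <- groupSDs(summ)
    res[[r]] <- data.frame(
      theta = rp$theta, splitTimeGen = rp$splitTimeGen,
      pi1 = unname(m["pop1"]), pi2 = unname(m["pop2"]),
      ratio = groupRatio(summ),
      sd1 = unname(sdv["pop1"]), sd2 = unname(sdv["pop2"]),
      xi1 = singletonTotal(prof), polymorphicSites = ncol(geno))
    if (keepTheoretical)
      theo[[r]] <- rbind(p = ratioSum / nTrees,
                         pHat = singletonProportions(prof))
  }
  out <- do.call(rbind, res)
  nUndef <- sum(out$xi1 == 0)
  if (nUndef > 0)
    message("replicateSplitStudy: ", nUndef,
            " replicates without singletons (summaries NA)")
  if (keepTheoretical) attr(out, "theoretical") <- theo
  out
}
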