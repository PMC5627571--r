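## Core estimator: the empirical distribution of singletons.
## A singleton is a derived allele (minor allele in folded mode) carried by
## exactly one chromosome among the non-missing calls at a locus.

# Align a user-supplied grouping with chromosome ids. Accepts a factor or
# vector, either named by chromosome id or positional; returns a factor with
# levels in user-given order covering every chromosome.
asGroupAssignment <- function(groups, ids) {
  if (is.factor(groups)) lev <- levels(groups) else lev <- unique(as.character(groups))
  g <- as.character(groups)
  if (!is.null(names(groups))) {
    if (!all(ids %in% names(groups)))
      stop("every chromosome must be assigned to a group")
    g <- g[match(ids, names(groups))]
  } else if (length(g) != length(ids)) {
    stop("groups must be named by chromosome id or have one entry per chromosome")
  }
  if (anyNA(g)) stop("every chromosome must be assigned to a group")
  factor(g, levels = lev[lev %in% g])
}

#' Count singletons and estimate their empirical distribution
#'
#' For each locus with at least two non-missing calls, a singleton is a
#' derived allele carried by exactly one chromosome (in folded mode, the
#' minor allele seen exactly once). The per-chromosome counts
#' \eqn{\xi_1^{(i)}} sum to the total \eqn{\xi_1}, and the empirical
#' distribution of singletons is \eqn{\hat p_i = \xi_1^{(i)}/\xi_1}.
#'
#' Loci with fewer than two non-missing calls are skipped and counted in
#' `nSkippedLoci`. In folded mode with exactly two non-missing calls, one
#' derived and one ancestral, both alleles are "seen once"; the derived
#' carrier is credited (deterministic tie-break).
#'
#' @param x a [HaplotypeMatrix-class].
#' @param folded logical; defaults to `TRUE` when `polarization(x)` is
#'   `"folded"`.
#' @return a [SingletonProfile-class].
#' @export
countSingletons <- function(x, folded = polarization(x) == "folded") {
  stopifnot(is(x, "HaplotypeMatrix"))
  a <- alleles(x)
  n <- ncol(a)
  isDer <- a == 1L
  isDer[is.na(isDer)] <- FALSE
  isAnc <- a == 0L
  isAnc[is.na(isAnc)] <- FALSE
  nonmiss <- as.integer(rowSums(isDer) + rowSums(isAnc))
  d <- as.integer(rowSums(isDer))
  usable <- nonmiss >= 2L
  counts <- numeric(n)
  derRows <- which(usable & d == 1L)
  if (length(derRows)) {
    carrier <- max.col(isDer[derRows, , drop = FALSE], ties.method = "first")
    counts <- counts + tabulate(carrier, nbins = n)
  }
  if (folded) {
    ancRows <- which(usable & (nonmiss - d) == 1L & d != 1L)
    if (length(ancRows)) {
      carrier <- max.col(isAnc[ancRows, , drop = FALSE], ties.method = "first")
      counts <- counts + tabulate(carrier, nbins = n)
    }
  }
  names(counts) <- colnames(a)
  total <- sum(counts)
  props <- if (total > 0) counts / total else rep(NA_real_, n)
  names(props) <- colnames(a)
  nSkipped <- sum(!usable)
  if (nSkipped > 0)
    message("countSingletons: skipped ", nSkipped,
            " loci with fewer than 2 non-missing calls")
  new("SingletonProfile", counts = counts, total = total,
      proportions = props, nSkippedLoci = as.integer(nSkipped))
}

#' Site frequency spectrum
#'
#' Number of polymorphic loci in each derived-allele count class
#' `1 .. n-1`, counted among non-missing calls. Monomorphic loci (derived
#' count 0 or equal to the number of non-missing calls) are excluded.
#' The first entry equals the total singleton count \eqn{\xi_1}.
#'
#' @param x a [HaplotypeMatrix-class].
#' @return named integer vector of length `nChromosomes(x) - 1`.
#' @export
siteFrequencySpectrum <- function(x) {
  stopifnot(is(x, "HaplotypeMatrix"))
  a <- alleles(x)
  n <- ncol(a)
  d <- rowSums(a == 1L, na.rm = TRUE)
  k <- rowSums(!is.na(a))
  poly <- k >= 2L & d >= 1L & d < k
  sfs <- tabulate(d[poly], nbins = n - 1L)
  names(sfs) <- seq_len(n - 1L)
  sfs
}

#' Per-group expected heterozygosity
#'
#' For each group, the mean over loci of the unbiased estimator
#' \eqn{2 \hat p (1-\hat p) \, k/(k-1)}, where `k` is the number of
#' non-missing calls in the group at the locus and \eqn{\hat p} the
#' within-group derived-allele frequency. Loci with fewer than two
#' non-missing calls in a group are skipped for that group.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param groups group assignment (factor or vector, named by chromosome id
#'   or positional), every group of size >= 2.
#' @return named numeric vector of per-group expected heterozygosities.
#' @export
expectedHeterozygosity <- function(x, groups) {
  stopifnot(is(x, "HaplotypeMatrix"))
  a <- alleles(x)
  g <- asGroupAssignment(groups, colnames(a))
  if (any(table(g) < 2L)) stop("every group must contain at least 2 chromosomes")
  vapply(levels(g), function(lev) {
    sub <- a[, g == lev, drop = FALSE]
    k <- rowSums(!is.na(sub))
    d <- rowSums(sub == 1L, na.rm = TRUE)
    ok <- k >= 2L
    if (!any(ok)) return(NA_real_)
    p <- d[ok] / k[ok]
    mean(2 * p * (1 - p) * k[ok] / (k[ok] - 1))
  }, numeric(1))
}

#' Group-wise summaries of the empirical distribution of singletons
#'
#' Per-group mean and sample standard deviation of the individual singleton
#' proportions \eqn{\hat p_i}, optionally alongside per-group expected
#' heterozygosity when the genotype matrix is supplied. For exactly two
#' groups the ratio of group means is reported in user-given group order
#' (first / second).
#'
#' @param profile a [SingletonProfile-class].
#' @param groups group assignment covering every chromosome in `profile`.
#' @param x optional [HaplotypeMatrix-class] from which per-group expected
#'   heterozygosity is computed.
#' @return a [DiversitySummary-class].
#' @export
groupSummaries <- function(profile, groups, x = NULL) {
  stopifnot(is(profile, "SingletonProfile"))
  ids <- names(singletonCounts(profile))
  g <- asGroupAssignment(groups, ids)
  sizes <- as.numeric(table(g))
  names(sizes) <- levels(g)
  if (singletonTotal(profile) == 0) {
    nas <- setNames(rep(NA_real_, nlevels(g)), levels(g))
    return(new("DiversitySummary", groupMean = nas, groupSD = nas,
               groupSize = sizes, hexp = nas, ratio = NA_real_,
               defined = FALSE))
  }
  p <- singletonProportions(profile)
  m <- vapply(levels(g), function(lev) mean(p[g == lev]), numeric(1))
  s <- vapply(levels(g), function(lev) sd(p[g == lev]), numeric(1))
  hx <- if (!is.null(x)) expectedHeterozygosity(x, g)
        else setNames(rep(NA_real_, nlevels(g)), levels(g))
  ratio <- if (nlevels(g) == 2L) unname(m[1] / m[2]) else NA_real_
  new("DiversitySummary", groupMean = m, groupSD = s, groupSize = sizes,
      hexp = hx, ratio = ratio, defined = TRUE)
}
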