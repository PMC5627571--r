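#' Construct a HaplotypeMatrix
#'
#' @param alleles matrix of 0/1/`NA` calls with loci as rows and chromosomes
#'   as columns (use `t()` or `transpose = TRUE` for chromosome-major input).
#' @param chromosomeIds optional character vector of unique chromosome
#'   identifiers; defaults to existing column names or `chr1..chrn`.
#' @param coords optional data.frame with one row per chromosome (e.g. `lon`,
#'   `lat`, `population`), stored in `colData`.
#' @param polarization `"ancestral-known"` (0 = ancestral, 1 = derived; the
#'   default assumed by the coalescent theory) or `"folded"` (only
#'   minor/major status is meaningful).
#' @param transpose set `TRUE` if `alleles` is chromosomes x loci.
#'
#' @return a [HaplotypeMatrix-class] object.
#' @examples
#' hm <- HaplotypeMatrix(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0), c(1, 1, 0)))
#' countSingletons(hm)
#' @export
HaplotypeMatrix <- function(alleles, chromosomeIds = NULL, coords = NULL,
                            polarization = c("ancestral-known", "folded"),
                            transpose = FALSE) {
  polarization <- match.arg(polarization)
  alleles <- as.matrix(alleles)
  if (transpose) alleles <- t(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(chromosomeIds)) {
    chromosomeIds <- colnames(alleles)
    if (is.null(chromosomeIds))
      chromosomeIds <- paste0("chr", seq_len(ncol(alleles)))
  }
  if (length(chromosomeIds) != ncol(alleles))
    stop("chromosomeIds must have one entry per chromosome (column)")
  colnames(alleles) <- chromosomeIds
  if (is.null(rownames(alleles)) && nrow(alleles) > 0)
    rownames(alleles) <- paste0("locus", seq_len(nrow(alleles)))
  cd <- if (is.null(coords)) S4Vectors::DataFrame(row.names = chromosomeIds)
        else S4Vectors::DataFrame(coords, row.names = chromosomeIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(alleles = alleles), colData = cd)
  new("HaplotypeMatrix", se, polarization = polarization)
}

#' @rdname HaplotypeMatrix-class
#' @param x a `HaplotypeMatrix`.
#' @aliases alleles chromosomeIds polarization nChromosomes nLoci
#' @export
setMethod("alleles", "HaplotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "alleles"))

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("chromosomeIds", "HaplotypeMatrix", function(x) colnames(x))

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("polarization", "HaplotypeMatrix", function(x) x@polarization)

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("nChromosomes", "HaplotypeMatrix", function(x) ncol(x))

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("nLoci", "HaplotypeMatrix", function(x) nrow(x))

setMethod("show", "HaplotypeMatrix", function(object) {
  a <- alleles(object)
  miss <- if (length(a)) mean(is.na(a)) else 0
  cat("HaplotypeMatrix:", ncol(object), "chromosomes x", nrow(object),
      "loci\n")
  cat("  polarization:", object@polarization,
      sprintf("| missing calls: %.2f%%\n", 100 * miss))
  if (ncol(SummarizedExperiment::colData(object)))
    cat("  colData:",
        paste(colnames(SummarizedExperiment::colData(object)),
              collapse = ", "), "\n")
})

#' @rdname SingletonProfile-class
#' @param x a `SingletonProfile`.
#' @aliases singletonCounts singletonTotal singletonProportions
#' @export
setMethod("singletonCounts", "SingletonProfile", function(x) x@counts)

#' @rdname SingletonProfile-class
#' @export
setMethod("singletonTotal", "SingletonProfile", function(x) x@total)

#' @rdname SingletonProfile-class
#' @export
setMethod("singletonProportions", "SingletonProfile",
          function(x) x@proportions)

setMethod("show", "SingletonProfile", function(object) {
  cat("SingletonProfile:", length(object@counts), "chromosomes,",
      object@total, "singletons")
  if (object@nSkippedLoci > 0)
    cat(" (", object@nSkippedLoci, " loci skipped)", sep = "")
  cat("\n")
  if (object@total > 0) {
    p <- object@proportions
    cat(sprintf("  proportions: mean %.4g, range [%.4g, %.4g]\n",
                mean(p), min(p), max(p)))
  } else {
    cat("  proportions undefined (no singleton observed)\n")
  }
})

#' @rdname DiversitySummary-class
#' @param x a `DiversitySummary`.
#' @aliases groupMeans groupSDs groupRatio
#' @export
setMethod("groupMeans", "DiversitySummary", function(x) x@groupMean)

#' @rdname DiversitySummary-class
#' @export
setMethod("groupSDs", "DiversitySummary", function(x) x@groupSD)

#' @rdname DiversitySummary-class
#' @export
setMethod("groupRatio", "DiversitySummary", function(x) x@ratio)

setMethod("show", "DiversitySummary", function(object) {
  if (!object@defined) {
    cat("DiversitySummary: undefined (no singleton observed)\n")
    return(invisible(NULL))
  }
  cat("DiversitySummary over", length(object@groupMean), "groups\n")
  df <- data.frame(group = names(object@groupMean),
                   size = object@groupSize,
                   mean = signif(object@groupMean, 4),
                   sd = signif(object@groupSD, 4))
  if (!all(is.na(object@hexp))) df$hexp <- signif(object@hexp, 4)
  print(df, row.names = FALSE)
  if (!is.na(object@ratio))
    cat(sprintf("  ratio (group 1 / group 2): %.4g\n", object@ratio))
})
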