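#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("chromosomeIds", function(x) standardGeneric("chromosomeIds"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("polarization", function(x) standardGeneric("polarization"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("nChromosomes", function(x) standardGeneric("nChromosomes"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname SingletonProfile-class
#' @export
setGeneric("singletonCounts", function(x) standardGeneric("singletonCounts"))

#' @rdname SingletonProfile-class
#' @export
setGeneric("singletonTotal", function(x) standardGeneric("singletonTotal"))

#' @rdname SingletonProfile-class
#' @export
setGeneric("singletonProportions",
           function(x) standardGeneric("singletonProportions"))

#' @rdname DiversitySummary-class
#' @export
setGeneric("groupMeans", function(x) standardGeneric("groupMeans"))

#' @rdname DiversitySummary-class
#' @export
setGeneric("groupSDs", function(x) standardGeneric("groupSDs"))

#' @rdname DiversitySummary-class
#' @export
setGeneric("groupRatio", function(x) standardGeneric("groupRatio"))

#' @rdname DemeGrid-class
#' @export
setGeneric("capacity", function(x) standardGeneric("capacity"))

#' @rdname DiversitySurface-class
#' @export
setGeneric("surfaceValues", function(x) standardGeneric("surfaceValues"))
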