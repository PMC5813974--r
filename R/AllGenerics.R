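#' @rdname PhasedGenotypes-class
#' @param x a \linkS4class{PhasedGenotypes} object.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname PhasedGenotypes-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname PhasedGenotypes-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname PhasedGenotypes-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname PhasedGenotypes-class
#' @param which 1 or 2, selecting the haplotype matrix.
#' @export
setGeneric("hapMatrix", function(x, which = 1L) standardGeneric("hapMatrix"))

#' @rdname PhasedGenotypes-class
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname ScanResult-class
#' @param x a \linkS4class{ScanResult}.
#' @export
setGeneric("results", function(x) standardGeneric("results"))

#' @rdname ScanResult-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
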