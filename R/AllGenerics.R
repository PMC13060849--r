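#' Extract the intensity matrix
#'
#' @param x an object carrying LFQ intensities.
#' @return numeric matrix, proteins x samples, \code{NA} where not detected.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Per-sample group labels
#'
#' @param x an \linkS4class{LFQExperiment}.
#' @return named character vector of group labels, one per sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Per-sample condition labels
#'
#' @param x an \linkS4class{LFQExperiment}.
#' @return named character vector of condition labels (NA when unset).
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' Detection mask of an intensity matrix
#'
#' TRUE where a protein was detected (value present) in a sample, FALSE
#' where the cell is missing. Same dimensions and dimnames as the matrix.
#'
#' @param x an \linkS4class{LFQExperiment} or numeric matrix with \code{NA}
#'   for missing values.
#' @return logical matrix.
#' @export
setGeneric("detectionMask", function(x) standardGeneric("detectionMask"))

#' Consensus protein set
#'
#' @param x a \linkS4class{ConsensusResult}.
#' @return character vector of consensus protein ids.
#' @export
setGeneric("consensusSet", function(x) standardGeneric("consensusSet"))

#' Stage-by-stage provenance of a consensus run
#'
#' @param x a \linkS4class{ConsensusResult}.
#' @return data.frame with columns group, stage, n_in, n_out.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' IC50 of a dose-response fit
#'
#' @param x a \linkS4class{DoseResponseFit}.
#' @return the midpoint parameter e on the dose scale, or \code{NA} for a
#'   non-converged fit.
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))
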