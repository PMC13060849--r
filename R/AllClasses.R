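#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' LFQExperiment: an LFQ intensity matrix with sample metadata
#'
#' Container for label-free quantitation (LFQ) protein intensities, proteins
#' in rows and samples in columns, built on
#' \linkS4class{SummarizedExperiment}. The single \code{"intensity"} assay
#' holds nonnegative linear-scale intensities; a missing (not detected)
#' protein/sample cell is \code{NA}, never 0. Column metadata carries a
#' mandatory \code{group} label per sample (e.g. \code{"PDX"},
#' \code{"cell_line"}) and an optional \code{condition} label (e.g.
#' \code{"PRC2_active"}, \code{"PRC2_inactive"}).
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{LFQExperiment}} (constructor),
#'   \code{\link{intensities}}, \code{\link{sampleGroups}},
#'   \code{\link{detectionMask}}
#' @name LFQExperiment-class
#' @exportClass LFQExperiment
setClass("LFQExperiment", contains = "SummarizedExperiment")

setValidity("LFQExperiment", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!("intensity" %in% a))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    v <- SummarizedExperiment::assay(object, "intensity")
    if (any(v[!is.na(v)] < 0))
      msg <- c(msg, "all present intensities must be >= 0")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "protein ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!("group" %in% colnames(cd)) || any(is.na(cd$group)))
    msg <- c(msg, "every sample needs a non-missing 'group' label")
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: staged record of consensus surfaceome selection
#'
#' Holds, for each sample group, the proteins surviving each selection stage
#' (detected in every sample of the group; at or above the group-wise median
#' summary intensity; present in the surface catalog), the cross-group
#' consensus (strict intersection), and a provenance table with before/after
#' counts for every stage.
#'
#' @slot groups character, the group labels analyzed.
#' @slot perGroup named list (one element per group), each a list with
#'   character vectors \code{detectedInAll}, \code{aboveMedian},
#'   \code{surface}.
#' @slot consensus character, the final cross-group consensus protein set.
#' @slot provenance data.frame with columns \code{group} (\code{"all"} for
#'   global stages), \code{stage}, \code{n_in}, \code{n_out}.
#' @name ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(groups = "character", perGroup = "list",
                 consensus = "character", provenance = "data.frame"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  if (!setequal(names(object@perGroup), object@groups))
    msg <- c(msg, "perGroup names must match groups")
  for (g in object@groups) {
    pg <- object@perGroup[[g]]
    if (!all(c("detectedInAll", "aboveMedian", "surface") %in% names(pg)))
      msg <- c(msg, sprintf("group '%s' is missing a stage set", g))
    else if (!all(object@consensus %in% pg$surface))
      msg <- c(msg, "consensus must be a subset of every per-group surface set")
  }
  if (length(msg)) msg else TRUE
})

#' BeadCalibration: fitted PE-bead fluorescence calibration
#'
#' A 4-peak (or more) bead panel with known phycoerythrin (PE) molecules per
#' bead and measured median fluorescence intensities (MFI), together with the
#' ordinary least-squares line of log10(MFI) on log10(PE) used to convert
#' sample MFIs into PE-molecule counts.
#'
#' @slot peakMFI numeric, median fluorescence intensity per bead peak.
#' @slot pePerBead numeric, lot-specific PE molecules per bead, strictly
#'   increasing.
#' @slot slope,intercept numeric, the fitted log10-log10 line.
#' @slot rSquared numeric, coefficient of determination of the fit.
#' @name BeadCalibration-class
#' @exportClass BeadCalibration
setClass("BeadCalibration",
  representation(peakMFI = "numeric", pePerBead = "numeric",
                 slope = "numeric", intercept = "numeric",
                 rSquared = "numeric"))

setValidity("BeadCalibration", function(object) {
  msg <- character()
  if (length(object@peakMFI) != length(object@pePerBead))
    msg <- c(msg, "peakMFI and pePerBead must have equal length")
  if (any(object@pePerBead <= 0) || any(diff(object@pePerBead) <= 0))
    msg <- c(msg, "pePerBead must be strictly increasing and > 0")
  if (any(object@peakMFI <= 0))
    msg <- c(msg, "peakMFI must be > 0")
  if (length(msg)) msg else TRUE
})

#' DoseResponseFit: four-parameter log-logistic dose-response fit
#'
#' Parameters follow the LL.4 convention: viability
#' \eqn{f(x) = c + (d - c) / (1 + \exp(b (\log x - \log e)))} with lower
#' asymptote \eqn{c}, upper asymptote \eqn{d}, slope \eqn{b} and midpoint
#' \eqn{e} on the dose scale, so \eqn{e} is the IC50 directly. A fit that
#' did not converge (or describes a flat response) carries
#' \code{converged = FALSE} and reports no IC50.
#'
#' @slot drug,sample character identifiers (may be empty).
#' @slot b,c,d,e numeric LL.4 parameters (NA when not converged).
#' @slot rss numeric residual sum of squares.
#' @slot converged logical.
#' @slot doseRange numeric length-2, dose range covered by the data.
#' @slot nObs integer, number of wells entering the loss.
#' @name DoseResponseFit-class
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(drug = "character", sample = "character",
                 b = "numeric", c = "numeric", d = "numeric", e = "numeric",
                 rss = "numeric", converged = "logical",
                 doseRange = "numeric", nObs = "integer"))

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (!is.finite(object@e) || object@e <= 0)
      msg <- c(msg, "converged fit requires midpoint e > 0")
  }
  if (length(msg)) msg else TRUE
})
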