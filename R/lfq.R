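#' Remove known mass-spectrometry contaminants
#'
#' Drops every protein row whose identifier appears in the contaminant list
#' (case-insensitive exact gene-symbol match; no alias resolution). In PDX
#' surfaceome data, contaminants such as HSPA5, HSPA9 and KRT1 are typically
#' high-abundance and would otherwise pass abundance filters, so this step
#' runs before normalization and selection.
#'
#' @param x an \linkS4class{LFQExperiment}.
#' @param contaminants character vector of contaminant identifiers (see
#'   \code{\link{readContaminantList}}). Empty is legal.
#' @return list with \code{experiment} (rows removed, samples untouched) and
#'   \code{removed} (character vector of the ids actually removed).
#' @export
filterContaminants <- function(x, contaminants) {
  stopifnot(is(x, "LFQExperiment"))
  bad <- .normId(rownames(x)) %in% .normId(contaminants)
  removed <- rownames(x)[bad]
  list(experiment = x[!bad, , drop = FALSE], removed = removed)
}

#' Median-normalize an LFQ intensity matrix
#'
#' Each sample's present values are scaled multiplicatively (linear scale,
#' equivalently an additive shift in log space) so that its median equals a
#' common reference. The default reference policy is the grand median of
#' the per-sample medians, which is invariant to sample ordering; a fixed
#' numeric reference may be supplied instead. Missing cells stay missing.
#' The operation is idempotent and preserves within-sample rank order.
#'
#' @param x an \linkS4class{LFQExperiment}; every sample must have at least
#'   one present value.
#' @param reference \code{"grand-median"} (default) or a single positive
#'   number.
#' @return list with \code{experiment} (normalized) and \code{report}, a
#'   data.frame of per-sample pre/post medians and scale factors with the
#'   reference median as attribute \code{"reference"}.
#' @export
medianNormalize <- function(x, reference = "grand-median") {
  stopifnot(is(x, "LFQExperiment"))
  v <- intensities(x)
  meds <- apply(v, 2L, .presentMedian)
  if (anyNA(meds))
    .stopData(sprintf("sample(s) with no present values: %s",
                      paste(colnames(v)[is.na(meds)], collapse = ", ")))
  ref <- if (identical(reference, "grand-median")) median(meds)
  else {
    if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
      .stopParam("reference", "must be 'grand-median' or a positive number")
    reference
  }
  fac <- ref / meds
  vn <- sweep(v, 2L, fac, "*")
  report <- data.frame(sample = colnames(v), median_pre = meds,
                       median_post = apply(vn, 2L, .presentMedian),
                       scale = fac, row.names = NULL)
  attr(report, "reference") <- ref
  list(experiment = .setIntensities(x, vn), report = report)
}
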