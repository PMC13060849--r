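#' Fit the bead calibration line
#'
#' Ordinary least squares of log10(median fluorescence) on log10(PE
#' molecules per bead) over the bead peaks. The fitted line converts sample
#' MFIs into PE-molecule counts per cell.
#'
#' @param peak_mfi positive median fluorescence intensities, one per peak
#'   (4 for a standard QuantiBrite-style panel).
#' @param pe_per_bead strictly increasing positive lot-specific PE counts,
#'   same length.
#' @return a \linkS4class{BeadCalibration}.
#' @examples
#' panel <- simulateBeadPanel(slope = 0.95, intercept = 0.4)
#' fitBeadCurve(panel$mfi, panel$pe_per_bead)
#' @export
fitBeadCurve <- function(peak_mfi, pe_per_bead) {
  if (length(peak_mfi) != length(pe_per_bead) || length(peak_mfi) < 2L)
    .stopParam("peak_mfi", "need >= 2 peaks matching pe_per_bead")
  if (any(peak_mfi <= 0)) .stopParam("peak_mfi", "must all be > 0")
  if (any(pe_per_bead <= 0))
    .stopParam("pe_per_bead", "must all be > 0")
  if (any(diff(pe_per_bead) <= 0))
    .stopParam("pe_per_bead", "must be strictly increasing (degenerate fit)")
  x <- log10(pe_per_bead); y <- log10(peak_mfi)
  fit <- stats::lm.fit(cbind(1, x), y)
  co <- fit$coefficients
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  new("BeadCalibration", peakMFI = as.numeric(peak_mfi),
      pePerBead = as.numeric(pe_per_bead),
      slope = unname(co[2]), intercept = unname(co[1]), rSquared = r2)
}

#' Convert median fluorescence to PE molecules per cell
#'
#' Inverts the calibration line:
#' \code{pe = 10^((log10(mfi) - intercept) / slope)}.
#'
#' @param cal a \linkS4class{BeadCalibration}.
#' @param mfi positive median fluorescence intensity (vectorized).
#' @return PE molecules per cell.
#' @export
mfiToPE <- function(cal, mfi) {
  stopifnot(is(cal, "BeadCalibration"))
  if (any(mfi <= 0)) .stopParam("mfi", "must be > 0")
  if (cal@slope == 0) .stopParam("cal", "slope must be nonzero")
  10^((log10(mfi) - cal@intercept) / cal@slope)
}

#' Antigens per cell from flow-cytometry medians
#'
#' Converts stained (and optionally isotype-control) median fluorescence
#' into PE molecules per cell via the bead calibration, subtracts the
#' isotype background on the PE-molecule scale (the physically meaningful
#' scale; switchable), and divides by the PE molecules per antibody to
#' obtain a median antigen density per cell. Negative densities after
#' subtraction are floored at 0 with a warning.
#'
#' @param cal a \linkS4class{BeadCalibration}.
#' @param flow data.frame with columns \code{sample}, \code{antigen},
#'   \code{stained_mfi}, \code{isotype_mfi}, and optionally
#'   \code{pe_per_antibody} (default 1, the 1:1 PE-conjugate convention).
#' @param subtractIsotype subtract the isotype-control PE signal
#'   (default TRUE).
#' @return data.frame: \code{sample}, \code{antigen},
#'   \code{antigens_per_cell}, \code{pe_per_antibody},
#'   \code{background_subtracted}.
#' @export
antigenDensity <- function(cal, flow, subtractIsotype = TRUE) {
  stopifnot(is(cal, "BeadCalibration"),
            all(c("sample", "antigen", "stained_mfi") %in% colnames(flow)))
  ppa <- if ("pe_per_antibody" %in% colnames(flow)) flow$pe_per_antibody
         else rep(1, nrow(flow))
  if (any(ppa <= 0)) .stopParam("pe_per_antibody", "must be > 0")
  pe <- mfiToPE(cal, flow$stained_mfi)
  if (subtractIsotype) {
    if (!("isotype_mfi" %in% colnames(flow)) || any(flow$isotype_mfi <= 0))
      .stopParam("isotype_mfi", "positive isotype MFIs required to subtract")
    pe <- pe - mfiToPE(cal, flow$isotype_mfi)
  }
  dens <- pe / ppa
  if (any(dens < 0)) {
    warning(sprintf("%d negative density value(s) floored at 0",
                    sum(dens < 0)))
    dens <- pmax(dens, 0)
  }
  data.frame(sample = flow$sample, antigen = flow$antigen,
             antigens_per_cell = dens, pe_per_antibody = ppa,
             background_subtracted = subtractIsotype,
             stringsAsFactors = FALSE)
}

setMethod("show", "BeadCalibration", function(object) {
  cat(sprintf(
    "BeadCalibration: %d peaks; log10(MFI) = %.4f + %.4f log10(PE); R^2 = %.4f\n",
    length(object@peakMFI), object@intercept, object@slope,
    object@rSquared))
})
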