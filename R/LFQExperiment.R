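#' Construct an LFQExperiment
#'
#' @param intensity numeric matrix, proteins x samples, linear-scale LFQ
#'   intensities with \code{NA} for missing (not detected) cells. Row and
#'   column names are required and must be unique.
#' @param group character vector of per-sample group labels (recycled if
#'   length 1).
#' @param condition optional character vector of per-sample condition labels.
#' @return an \linkS4class{LFQExperiment}.
#' @examples
#' m <- matrix(c(10, 20, NA, 40), 2, 2,
#'             dimnames = list(c("EGFR", "PTK7"), c("s1", "s2")))
#' lfq <- LFQExperiment(m, group = "cell_line")
#' intensities(lfq)
#' @export
LFQExperiment <- function(intensity, group, condition = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    .stopParam("intensity", "must be a numeric matrix")
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    .stopParam("intensity", "row (protein) and column (sample) names required")
  n <- ncol(intensity)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n)
    .stopParam("group", "must have one label per sample")
  cd <- S4Vectors::DataFrame(group = as.character(group),
                             row.names = colnames(intensity))
  cd$condition <- if (is.null(condition)) NA_character_ else {
    if (length(condition) == 1L) condition <- rep(condition, n)
    as.character(condition)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), colData = cd)
  new("LFQExperiment", se)
}

#' @describeIn LFQExperiment intensity matrix accessor
#' @param x an \code{LFQExperiment}
#' @export
setMethod("intensities", "LFQExperiment", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "LFQExperiment", function(x)
  setNames(SummarizedExperiment::colData(x)$group, colnames(x)))

#' @rdname sampleConditions
#' @export
setMethod("sampleConditions", "LFQExperiment", function(x)
  setNames(SummarizedExperiment::colData(x)$condition, colnames(x)))

#' @rdname detectionMask
#' @export
setMethod("detectionMask", "LFQExperiment", function(x)
  !is.na(intensities(x)))

#' @rdname detectionMask
#' @export
setMethod("detectionMask", "matrix", function(x) !is.na(x))

setMethod("show", "LFQExperiment", function(object) {
  v <- intensities(object)
  cat(sprintf("LFQExperiment: %d proteins x %d samples\n",
              nrow(v), ncol(v)))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  gr <- table(sampleGroups(object))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(gr), gr),
                         collapse = ", "), "\n")
})

# replace the intensity assay, keeping metadata
.setIntensities <- function(x, values) {
  SummarizedExperiment::assay(x, "intensity") <- values
  validObject(x)
  x
}

# subset rows by protein id keeping class
.subsetProteins <- function(x, ids) {
  x[match(ids, rownames(x)), , drop = FALSE]
}
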