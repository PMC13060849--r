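#' Proteins detected in every sample of a group
#'
#' @param x an \linkS4class{LFQExperiment}.
#' @param group one of the group labels in \code{sampleGroups(x)}.
#' @return character vector of protein ids with a present value in every
#'   sample of the group.
#' @export
detectedInAll <- function(x, group) {
  stopifnot(is(x, "LFQExperiment"))
  sel <- sampleGroups(x) == group
  if (!any(sel)) .stopParam("group", sprintf("unknown group '%s'", group))
  m <- detectionMask(x)[, sel, drop = FALSE]
  rownames(m)[rowSums(m) == ncol(m)]
}

#' Candidates at or above the group-wise median intensity
#'
#' "Top half of expression" filter: compute a per-protein summary intensity
#' across the group's samples, then retain candidates whose summary is at or
#' above the median of the candidate summaries. Ties at the median are
#' retained (only proteins strictly below the group-wise median are
#' discarded).
#'
#' @param x an \linkS4class{LFQExperiment}.
#' @param group group label.
#' @param candidates character vector of candidate protein ids (subset of
#'   \code{rownames(x)}); typically the output of
#'   \code{\link{detectedInAll}}. Empty candidates give an empty result.
#' @param mode \code{"per-protein"} (default; threshold = median of the
#'   candidates' per-protein median intensities) or \code{"pooled"}
#'   (threshold = median of all present candidate values in the group
#'   pooled together; the per-protein summary is still compared to it).
#' @return character vector of retained protein ids.
#' @export
aboveGroupMedian <- function(x, group, candidates,
                             mode = c("per-protein", "pooled")) {
  stopifnot(is(x, "LFQExperiment"))
  mode <- match.arg(mode)
  if (length(candidates) == 0L) return(character())
  if (!all(candidates %in% rownames(x)))
    .stopParam("candidates", "must all be matrix proteins")
  sel <- sampleGroups(x) == group
  if (!any(sel)) .stopParam("group", sprintf("unknown group '%s'", group))
  v <- intensities(x)[candidates, sel, drop = FALSE]
  summ <- apply(v, 1L, .presentMedian)
  thr <- if (mode == "per-protein") median(summ, na.rm = TRUE)
         else median(v[!is.na(v)])
  candidates[!is.na(summ) & summ >= thr]
}

#' Intersect protein ids with a surface-protein catalog
#'
#' Case-insensitive intersection with a Cell Surface Protein Atlas-style
#' catalog of high-confidence surface proteins.
#'
#' @param ids character vector of protein ids.
#' @param catalog character vector of catalog ids (see
#'   \code{\link{readSurfaceCatalog}}).
#' @return the ids (original spelling) found in the catalog.
#' @export
intersectSurfaceCatalog <- function(ids, catalog) {
  ids[.normId(ids) %in% .normId(catalog)]
}

#' Build the cross-group consensus surfaceome
#'
#' Runs the full selection, in order: contaminant filter, median
#' normalization, then per group detection-in-all followed by the top-half
#' abundance filter and the surface-catalog intersection, and finally the
#' strict intersection of the per-group surface sets across all groups.
#' Every stage's before/after counts are recorded in the provenance table.
#'
#' @param x an \linkS4class{LFQExperiment}.
#' @param catalog surface catalog id vector.
#' @param contaminants contaminant id vector (may be empty).
#' @param groups group labels to use (default: all groups in \code{x}).
#' @param medianMode passed to \code{\link{aboveGroupMedian}}.
#' @return a \linkS4class{ConsensusResult}.
#' @examples
#' sim <- simulateLFQ(syntheticConfig(n_proteins = 200, seed = 7))
#' res <- buildConsensus(sim$experiment, catalog = sim$truth$surface_set,
#'                       contaminants = sim$truth$contaminant_set)
#' res
#' @export
buildConsensus <- function(x, catalog, contaminants = character(),
                           groups = NULL,
                           medianMode = c("per-protein", "pooled")) {
  stopifnot(is(x, "LFQExperiment"))
  medianMode <- match.arg(medianMode)
  if (is.null(groups)) groups <- unique(sampleGroups(x))
  if (length(groups) < 1L) .stopParam("groups", "need at least one group")

  prov <- data.frame(group = character(), stage = character(),
                     n_in = integer(), n_out = integer(),
                     stringsAsFactors = FALSE)
  note <- function(group, stage, n_in, n_out)
    rbind(prov, data.frame(group = group, stage = stage,
                           n_in = n_in, n_out = n_out))

  fc <- filterContaminants(x, contaminants)
  prov <- note("all", "contaminant_filter", nrow(x), nrow(fc$experiment))
  xn <- medianNormalize(fc$experiment)$experiment
  prov <- note("all", "median_normalize", nrow(fc$experiment), nrow(xn))

  perGroup <- list()
  for (g in groups) {
    det <- detectedInAll(xn, g)
    prov <- note(g, "detected_in_all", nrow(xn), length(det))
    abv <- aboveGroupMedian(xn, g, det, mode = medianMode)
    prov <- note(g, "above_group_median", length(det), length(abv))
    surf <- intersectSurfaceCatalog(abv, catalog)
    prov <- note(g, "surface_catalog", length(abv), length(surf))
    perGroup[[g]] <- list(detectedInAll = det, aboveMedian = abv,
                          surface = surf)
  }
  cons <- Reduce(intersect, lapply(perGroup, `[[`, "surface"))
  prov <- note("all", "cross_group_intersection",
               length(unique(unlist(lapply(perGroup, `[[`, "surface")))),
               length(cons))
  new("ConsensusResult", groups = as.character(groups),
      perGroup = perGroup, consensus = sort(cons), provenance = prov)
}

#' @rdname consensusSet
#' @export
setMethod("consensusSet", "ConsensusResult", function(x) x@consensus)

#' @rdname provenance
#' @export
setMethod("provenance", "ConsensusResult", function(x) x@provenance)

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult over %d group(s): %s\n",
              length(object@groups), paste(object@groups, collapse = ", ")))
  for (g in object@groups) {
    pg <- object@perGroup[[g]]
    cat(sprintf("  %s: detected-in-all %d -> above-median %d -> surface %d\n",
                g, length(pg$detectedInAll), length(pg$aboveMedian),
                length(pg$surface)))
  }
  cat(sprintf("  consensus: %d proteins\n", length(object@consensus)))
})
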