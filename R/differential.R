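# Vectorized Welch (or pooled) two-sample t-test over protein rows of two
# log2 matrices with NA-aware counts. Returns p-values (NA when either
# condition has < 2 present values).
.rowTTest <- function(a, b, pooled = FALSE) {
  na_ <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na_ - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  ok <- na_ >= 2 & nb >= 2
  p <- rep(NA_real_, nrow(a))
  if (pooled) {
    sp2 <- ((na_ - 1) * va + (nb - 1) * vb) / (na_ + nb - 2)
    se <- sqrt(sp2 * (1 / na_ + 1 / nb))
    df <- na_ + nb - 2
  } else {
    se <- sqrt(va / na_ + vb / nb)
    df <- (va / na_ + vb / nb)^2 /
      (va^2 / (na_^2 * (na_ - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  tstat <- (mb - ma) / se
  p[ok] <- 2 * pt(abs(tstat[ok]), df[ok], lower.tail = FALSE)
  # zero-variance rows with identical means: no evidence of change
  zero <- ok & se == 0 & (mb - ma) == 0
  p[zero] <- 1
  p
}

#' PRC2-conditional differential surface abundance
#'
#' Compares two LFQ experiments (e.g. PRC2-active vs PRC2-inactive runs of
#' an isogenic line) protein by protein on the log2 scale. The log2 fold
#' change is mean log2(inactive) minus mean log2(active) over present
#' values; the test is a two-sample t-test on log2 intensities (Welch,
#' unequal variances, by default) with Benjamini-Hochberg correction across
#' all tested proteins.
#'
#' Proteins detected in only one condition get a capped fold change
#' (max finite |log2FC| + 1, signed) and the flag
#' \code{one_condition_only}; they carry no p-value but are kept in the
#' table, since presence/absence proteins are often the most interesting.
#'
#' @param active,inactive \linkS4class{LFQExperiment}s sharing (part of)
#'   a protein universe. Disjoint universes are an error.
#' @param test \code{"welch"} (default) or \code{"pooled"} variance.
#' @return data.frame with one row per protein present in either input:
#'   \code{protein}, \code{mean_log2_active}, \code{mean_log2_inactive},
#'   \code{log2fc}, \code{p_value}, \code{fdr}, \code{neg_log10_p},
#'   \code{one_condition_only}.
#' @export
differentialAbundance <- function(active, inactive,
                                  test = c("welch", "pooled")) {
  stopifnot(is(active, "LFQExperiment"), is(inactive, "LFQExperiment"))
  test <- match.arg(test)
  shared <- intersect(rownames(active), rownames(inactive))
  if (length(shared) == 0L)
    .stopData("active and inactive experiments share no proteins")
  all_ids <- union(rownames(active), rownames(inactive))

  la <- matrix(NA_real_, length(all_ids), ncol(active),
               dimnames = list(all_ids, colnames(active)))
  li <- matrix(NA_real_, length(all_ids), ncol(inactive),
               dimnames = list(all_ids, colnames(inactive)))
  la[rownames(active), ] <- log2(intensities(active))
  li[rownames(inactive), ] <- log2(intensities(inactive))

  ma <- rowMeans(la, na.rm = TRUE); mi <- rowMeans(li, na.rm = TRUE)
  ma[is.nan(ma)] <- NA; mi[is.nan(mi)] <- NA
  lfc <- mi - ma
  oneOnly <- xor(is.na(ma), is.na(mi))
  cap <- if (any(is.finite(lfc))) max(abs(lfc[is.finite(lfc)])) + 1 else 1
  lfc[oneOnly & is.na(ma)] <- cap
  lfc[oneOnly & is.na(mi)] <- -cap

  p <- .rowTTest(la, li, pooled = (test == "pooled"))
  fdr <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  fdr[tested] <- p.adjust(p[tested], method = "BH")

  data.frame(protein = all_ids, mean_log2_active = ma,
             mean_log2_inactive = mi, log2fc = lfc, p_value = p, fdr = fdr,
             neg_log10_p = -log10(p), one_condition_only = oneOnly,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Significantly more-abundant proteins (the "up" set)
#'
#' @param tab a table from \code{\link{differentialAbundance}}.
#' @param lfcMin minimum log2 fold change (default 1, i.e. 2-fold).
#' @param fdrMax maximum BH-adjusted p (default 0.05).
#' @return character vector of proteins with \code{log2fc >= lfcMin} and
#'   \code{fdr <= fdrMax} (untested proteins are excluded).
#' @export
significantUpSet <- function(tab, lfcMin = 1, fdrMax = 0.05) {
  .checkPositive(lfcMin, "lfcMin")
  .checkPositive(fdrMax, "fdrMax")
  keep <- !is.na(tab$fdr) & tab$fdr <= fdrMax & tab$log2fc >= lfcMin
  tab$protein[keep]
}

#' Intersect two up-sets across models
#'
#' The cross-model consistency step: proteins called more abundant under
#' PRC2 loss in both of two independent models.
#'
#' @param a,b character vectors of protein ids.
#' @return their intersection (case-normalized match, spelling from
#'   \code{a}).
#' @export
intersectUpSets <- function(a, b) a[.normId(a) %in% .normId(b)]

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the hit list overlaps the set more than
#' expected when drawing \code{|hits|} proteins from the universe without
#' replacement: the p-value is the upper-tail hypergeometric probability of
#' an overlap at least as large as observed. Sets are intersected with the
#' universe before testing; BH correction is applied across sets.
#'
#' @param hits character vector of hit proteins (must lie in the universe).
#' @param universe character vector, the tested background.
#' @param geneSets named list of character vectors (see
#'   \code{\link{readGMT}}).
#' @return data.frame per set: \code{set}, \code{set_size} (within
#'   universe), \code{overlap}, \code{universe_size}, \code{hits_size},
#'   \code{p_value}, \code{fdr}, \code{overlap_ids}.
#' @examples
#' sets <- list(A = c("P1", "P2", "P3"), B = c("P8", "P9"))
#' oraEnrichment(c("P1", "P2"), sprintf("P%d", 1:10), sets)
#' @export
oraEnrichment <- function(hits, universe, geneSets) {
  universe <- unique(.normId(universe))
  hits <- unique(.normId(hits))
  if (length(universe) == 0L) .stopParam("universe", "must be nonempty")
  if (length(hits) == 0L) .stopParam("hits", "must be nonempty")
  if (!all(hits %in% universe))
    .stopParam("hits", "must be a subset of the universe")
  if (is.null(names(geneSets)) || anyDuplicated(names(geneSets)))
    .stopParam("geneSets", "must be a uniquely named list")

  N <- length(universe); n <- length(hits)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(.normId(geneSets[[nm]])), universe)
    K <- length(set)
    ov <- intersect(hits, set)
    k <- length(ov)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, universe_size = N,
               hits_size = n, p_value = p,
               overlap_ids = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), c("set", "set_size", "overlap", "universe_size",
                            "hits_size", "p_value", "fdr", "overlap_ids")]
}
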