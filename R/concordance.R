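#' Match proteins to genes across an LFQ and an RNA matrix
#'
#' Inner join on case-normalized gene symbols. Per gene, the protein
#' summary is the median of present intensities across LFQ samples and the
#' RNA summary is the median TPM across RNA samples.
#'
#' @param lfq an \linkS4class{LFQExperiment}.
#' @param rna numeric matrix of TPM values (genes x samples) or a
#'   \code{SummarizedExperiment} with a TPM assay.
#' @return data.frame with columns \code{gene}, \code{intensity},
#'   \code{tpm}; attributes \code{unmatched_protein} and
#'   \code{unmatched_rna} list ids present on one side only.
#' @export
matchGenes <- function(lfq, rna) {
  stopifnot(is(lfq, "LFQExperiment"))
  if (is(rna, "SummarizedExperiment"))
    rna <- SummarizedExperiment::assay(rna, 1L)
  if (!is.matrix(rna) || is.null(rownames(rna)))
    .stopParam("rna", "must be a named genes x samples matrix")
  pid <- .normId(rownames(lfq)); gid <- .normId(rownames(rna))
  common <- intersect(pid, gid)
  if (length(common) == 0L) .stopData("no genes match between the inputs")
  ip <- match(common, pid); ir <- match(common, gid)
  out <- data.frame(
    gene = common,
    intensity = apply(intensities(lfq)[ip, , drop = FALSE], 1L,
                      .presentMedian),
    tpm = apply(rna[ir, , drop = FALSE], 1L, median),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "unmatched_protein") <- rownames(lfq)[!(pid %in% common)]
  attr(out, "unmatched_rna") <- rownames(rna)[!(gid %in% common)]
  out
}

#' Correlate RNA and surface-protein abundance
#'
#' Pearson correlation of log2(TPM + 1) against log2 intensity over matched
#' genes, optionally after removing low-abundance RNA (where high relative
#' variability erodes the correlation).
#'
#' @param pairs data.frame from \code{\link{matchGenes}} (columns
#'   \code{intensity}, \code{tpm}).
#' @param logTransform correlate on the log-log scale (default TRUE; the
#'   conventional scale for LFQ/TPM comparisons).
#' @param minTPM drop pairs with TPM below this before correlating
#'   (\code{NULL} = keep all).
#' @return list with \code{r}, \code{p} (two-sided), \code{n}.
#' @export
correlateAbundance <- function(pairs, logTransform = TRUE, minTPM = NULL) {
  keep <- !is.na(pairs$intensity) & !is.na(pairs$tpm)
  if (!is.null(minTPM)) keep <- keep & pairs$tpm >= minTPM
  x <- pairs$tpm[keep]; y <- pairs$intensity[keep]
  if (length(x) < 3L)
    .stopData("fewer than 3 matched pairs after filtering")
  if (logTransform) { x <- log2(x + 1); y <- log2(y) }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bin matched genes into surface-abundance deciles
#'
#' Genes are ranked by surface-protein intensity (ascending; decile 10 =
#' most abundant surface proteins) and split into 10 bins whose sizes
#' differ by at most 1, the larger bins sitting at the low-abundance end.
#' Ties are broken by stable lexicographic gene order for reproducibility.
#'
#' @param pairs data.frame from \code{\link{matchGenes}}; needs >= 10
#'   complete pairs.
#' @return list with \code{assignment} (the pairs table plus a
#'   \code{decile} column) and \code{summary} (per decile: \code{n},
#'   \code{median_tpm}, within-bin Pearson \code{r} of log2 TPM vs log2
#'   intensity and its \code{p}).
#' @export
decileBinning <- function(pairs) {
  keep <- !is.na(pairs$intensity) & !is.na(pairs$tpm)
  d <- pairs[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 10L) .stopData("decile binning needs >= 10 matched pairs")
  ord <- order(d$intensity, d$gene)   # ascending, stable tie-break by id
  sizes <- rep(n %/% 10L, 10L)
  r <- n %% 10L
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  dec <- integer(n)
  dec[ord] <- rep(1:10, times = sizes)
  d$decile <- dec
  summ <- do.call(rbind, lapply(1:10, function(k) {
    dk <- d[d$decile == k, , drop = FALSE]
    if (nrow(dk) >= 3L) {
      ct <- cor.test(log2(dk$tpm + 1), log2(dk$intensity))
      r_ <- unname(ct$estimate); p_ <- ct$p.value
    } else { r_ <- NA_real_; p_ <- NA_real_ }
    data.frame(decile = k, n = nrow(dk), median_tpm = median(dk$tpm),
               r = r_, p = p_)
  }))
  list(assignment = d, summary = summ)
}

#' RNA vs protein fold-change concordance
#'
#' Pearson correlation between gene-level RNA log2 fold changes (from an
#' external differential-expression tool) and protein log2 fold changes
#' from \code{\link{differentialAbundance}}, over the shared genes with
#' finite fold changes on both sides. Capped presence/absence proteins
#' (\code{one_condition_only}) are excluded.
#'
#' @param rnaFC data.frame with columns \code{gene} and \code{log2fc}.
#' @param protFC data.frame from \code{\link{differentialAbundance}}.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
foldChangeConcordance <- function(rnaFC, protFC) {
  stopifnot(all(c("gene", "log2fc") %in% colnames(rnaFC)))
  pf <- protFC[!protFC$one_condition_only & is.finite(protFC$log2fc), ]
  i <- match(.normId(rnaFC$gene), .normId(pf$protein))
  keep <- !is.na(i) & is.finite(rnaFC$log2fc)
  x <- rnaFC$log2fc[keep]; y <- pf$log2fc[i[keep]]
  if (length(x) < 3L) .stopData("fewer than 3 shared finite fold changes")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pairwise sample correlation matrix
#'
#' Pearson correlation between every pair of samples over the proteins
#' detected in both (log2 scale), the structure behind replicate-quality
#' heatmaps: technical replicates within a condition correlate markedly
#' higher than samples across conditions.
#'
#' @param x an \linkS4class{LFQExperiment} with >= 2 samples.
#' @param log correlate log2 intensities (default TRUE).
#' @return symmetric numeric matrix with unit diagonal; a pair sharing
#'   fewer than 2 detected proteins gets \code{NA}.
#' @export
sampleCorrelationMatrix <- function(x, log = TRUE) {
  stopifnot(is(x, "LFQExperiment"))
  v <- intensities(x)
  if (ncol(v) < 2L) .stopData("need >= 2 samples")
  if (log) v <- log2(v)
  n <- ncol(v)
  out <- matrix(NA_real_, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n)) {
    out[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(v[, i]) & !is.na(v[, j])
      out[i, j] <- out[j, i] <-
        if (sum(ok) >= 2L) cor(v[ok, i], v[ok, j]) else NA_real_
    }
  }
  out
}
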