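# Independent brute-force oracles, written against the plain definitions of
# each rule (loops and set operations only), deliberately sharing no code
# with the package implementation.

# random toy intensity matrix with random missingness; every sample is
# guaranteed at least one present value
randomToyMatrix <- function(nProt = sample(5:30, 1), nSamp = sample(2:6, 1),
                            nGroups = 2, missFrac = 0.2) {
  ids <- paste0("G", sample(1000:9999, nProt))
  v <- matrix(2^rnorm(nProt * nSamp, 20, 2), nProt, nSamp,
              dimnames = list(ids, paste0("s", seq_len(nSamp))))
  v[matrix(runif(nProt * nSamp) < missFrac, nProt, nSamp)] <- NA
  for (j in seq_len(nSamp))          # keep the sample usable
    if (all(is.na(v[, j]))) v[sample(nProt, 1), j] <- 2^rnorm(1, 20, 2)
  groups <- rep(paste0("grp", seq_len(nGroups)), length.out = nSamp)
  list(values = v, groups = groups)
}

# the four consensus rules, applied literally
oracleConsensus <- function(values, groups, catalog, contaminants) {
  keep <- !(toupper(rownames(values)) %in% toupper(contaminants))
  v <- values[keep, , drop = FALSE]
  meds <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) meds[j] <- median(v[!is.na(v[, j]), j])
  ref <- median(meds)
  for (j in seq_len(ncol(v))) v[, j] <- v[, j] * (ref / meds[j])
  perGroup <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    det <- character()
    for (i in seq_len(nrow(v)))
      if (!any(is.na(v[i, cols]))) det <- c(det, rownames(v)[i])
    if (length(det) == 0) { perGroup[[g]] <- character(); next }
    summ <- numeric(length(det))
    for (k in seq_along(det)) summ[k] <- median(v[det[k], cols])
    thr <- median(summ)
    abv <- det[summ >= thr]
    perGroup[[g]] <- abv[toupper(abv) %in% toupper(catalog)]
  }
  out <- perGroup[[1]]
  for (g in names(perGroup)[-1]) out <- intersect(out, perGroup[[g]])
  sort(out)
}

# exhaustive hypergeometric upper tail: enumerate every possible hit draw
# of size n from the universe and count draws overlapping the set by >= k
oracleHyperP <- function(k, setIds, universe, n) {
  draws <- utils::combn(universe, n)
  hitsAtLeast <- 0
  for (j in seq_len(ncol(draws)))
    if (sum(draws[, j] %in% setIds) >= k) hitsAtLeast <- hitsAtLeast + 1
  hitsAtLeast / ncol(draws)
}

# step-by-step antigen-density arithmetic
oracleDensity <- function(slope, intercept, stained, isotype, ppa,
                          subtract = TRUE) {
  pe <- function(mfi) 10^((log10(mfi) - intercept) / slope)
  d <- if (subtract) pe(stained) - pe(isotype) else pe(stained)
  max(d / ppa, 0)
}

# textbook Pearson correlation
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

ll4Curve <- function(x, b, c, d, e) c + (d - c) / (1 + exp(b * (log(x) - log(e))))
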