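mkPair <- function(a, i, ids = sprintf("P%02d", seq_len(nrow(a)))) {
  dimnames(a) <- list(ids, paste0("a", seq_len(ncol(a))))
  dimnames(i) <- list(ids, paste0("i", seq_len(ncol(i))))
  list(active = LFQExperiment(a, "g", "PRC2_active"),
       inactive = LFQExperiment(i, "g", "PRC2_inactive"))
}

test_that("identical matrices give zero fold change everywhere", {
  v <- matrix(2^rnorm(30, 20, 2), 10, 3)
  p <- mkPair(v, v)
  dt <- differentialAbundance(p$active, p$inactive)
  expect_equal(dt$log2fc, rep(0, 10))
  expect_false(any(dt$one_condition_only))
})

test_that("a noiseless planted 4-fold change yields log2fc exactly 2", {
  v <- matrix(1000, 5, 3)
  w <- v; w[3, ] <- 4000
  dt <- differentialAbundance(mkPair(v, w)$active, mkPair(v, w)$inactive)
  expect_equal(dt$log2fc[3], 2)
  expect_equal(dt$log2fc[-3], rep(0, 4))
})

test_that("vectorized Welch/pooled p-values match stats::t.test per row", {
  set.seed(23)
  a <- matrix(2^rnorm(60, 20, 1), 15, 4)
  i <- matrix(2^rnorm(60, 20.5, 1.5), 15, 4)
  a[sample(60, 6)] <- NA; i[sample(60, 6)] <- NA
  p <- mkPair(a, i)
  for (tst in c("welch", "pooled")) {
    dt <- differentialAbundance(p$active, p$inactive, test = tst)
    for (r in seq_len(15)) {
      xa <- log2(a[r, ]); xi <- log2(i[r, ])
      xa <- xa[!is.na(xa)]; xi <- xi[!is.na(xi)]
      if (length(xa) >= 2 && length(xi) >= 2) {
        ref <- t.test(xi, xa, var.equal = (tst == "pooled"))
        expect_equal(dt$p_value[r], ref$p.value, tolerance = 1e-12)
        expect_equal(dt$log2fc[r], unname(diff(rev(ref$estimate))),
                     tolerance = 1e-12)
      } else {
        expect_true(is.na(dt$p_value[r]))
      }
    }
  }
})

test_that("swapping condition labels negates fold changes, keeps p-values", {
  set.seed(8)
  a <- matrix(2^rnorm(40, 20, 1), 10, 4)
  i <- matrix(2^rnorm(40, 21, 1), 10, 4)
  p <- mkPair(a, i)
  d1 <- differentialAbundance(p$active, p$inactive)
  d2 <- differentialAbundance(p$inactive, p$active)
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p_value, d2$p_value)
})

test_that("one-condition-only proteins are capped and flagged, not dropped", {
  a <- matrix(c(1000, 2000, NA, NA, 500, 500), 3, 2, byrow = TRUE)
  i <- matrix(c(1000, 2000, 800, 900, NA, NA), 3, 2, byrow = TRUE)
  p <- mkPair(a, i, ids = c("BOTH", "INACTIVE_ONLY", "ACTIVE_ONLY"))
  dt <- differentialAbundance(p$active, p$inactive)
  expect_identical(dt$one_condition_only,
                   c(FALSE, TRUE, TRUE)[match(dt$protein, c(
                     "BOTH", "INACTIVE_ONLY", "ACTIVE_ONLY"))])
  cap <- max(abs(dt$log2fc[dt$protein == "BOTH"])) + 1
  expect_equal(dt$log2fc[dt$protein == "INACTIVE_ONLY"], cap)
  expect_equal(dt$log2fc[dt$protein == "ACTIVE_ONLY"], -cap)
  expect_true(all(is.na(dt$p_value[dt$one_condition_only])))
})

test_that("disjoint protein universes raise a data error", {
  a <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  i <- matrix(1, 2, 2, dimnames = list(c("C", "D"), c("x", "y")))
  expect_error(differentialAbundance(LFQExperiment(a, "g"),
                                     LFQExperiment(i, "g")),
               class = "surfkit_data_error")
})

test_that("significant up-set applies both thresholds, monotone in fdr", {
  tab <- data.frame(protein = paste0("P", 1:5),
                    log2fc = c(2, 1.5, 0.5, -2, 3),
                    fdr = c(0.01, 0.2, 0.01, 0.01, 0.04),
                    one_condition_only = FALSE)
  expect_setequal(significantUpSet(tab), c("P1", "P5"))
  # loosening fdr_max never shrinks the set
  s1 <- significantUpSet(tab, fdrMax = 0.05)
  s2 <- significantUpSet(tab, fdrMax = 0.3)
  expect_true(all(s1 %in% s2))
  zero <- data.frame(protein = "P1", log2fc = 0, fdr = 0.001)
  expect_length(significantUpSet(zero), 0)
  expect_error(significantUpSet(tab, lfcMin = -1),
               class = "surfkit_parameter_error")
})

test_that("up-set intersection is a plain intersection", {
  expect_length(intersectUpSets(c("A", "B"), c("C", "D")), 0)
  expect_setequal(intersectUpSets(c("A", "B"), c("b", "a")), c("A", "B"))
  set.seed(3)
  a <- sample(LETTERS, 10); b <- sample(LETTERS, 10)
  expect_setequal(intersectUpSets(a, b), intersect(a, b))
})

test_that("BH adjustment is monotone on sorted p-values and bounded by 1", {
  set.seed(19)
  pair <- simulatePRC2Pair(syntheticConfig(n_proteins = 200, seed = 19))
  dt <- differentialAbundance(pair$active, pair$inactive)
  ok <- !is.na(dt$p_value)
  o <- order(dt$p_value[ok])
  expect_true(all(diff(dt$fdr[ok][o]) >= -1e-12))
  expect_true(all(dt$fdr[ok] <= 1))
  expect_equal(dt$fdr[ok], p.adjust(dt$p_value[ok], "BH"))
})

test_that("ORA reproduces exact hypergeometric values", {
  # universe 10, set of 5, hits of 5, full overlap: p = 1 / C(10,5)
  u <- paste0("G", 1:10)
  sets <- list(FULL = u[1:5], NONE = u[6:10])
  res <- oraEnrichment(u[1:5], u, sets)
  expect_equal(res$p_value[res$set == "FULL"], 1 / choose(10, 5),
               tolerance = 1e-12)
  # a zero-overlap set has p = 1 (overlap 0 is certain to be reached)
  expect_equal(res$p_value[res$set == "NONE"], 1)
  expect_error(oraEnrichment(character(), u, sets),
               class = "surfkit_parameter_error")
  expect_error(oraEnrichment(c("G1", "ZZZ"), u, sets), "universe")
})

test_that("ORA matches exhaustive enumeration on small universes", {
  set.seed(71)
  for (i in 1:8) {
    N <- sample(8:15, 1)
    u <- paste0("G", seq_len(N))
    set <- sample(u, sample(2:5, 1))
    hits <- sample(u, sample(3:6, 1))
    res <- oraEnrichment(hits, u, list(S = set))
    k <- length(intersect(hits, set))
    expect_equal(res$p_value, oracleHyperP(k, set, u, length(hits)),
                 tolerance = 1e-12)
    expect_lte(res$overlap, min(length(set), length(hits)))
  }
})

test_that("a preferentially hit gene set attains the smallest ORA p", {
  set.seed(29)
  u <- paste0("G", 1:200)
  sets <- c(list(TARGET = u[1:40]),
            setNames(lapply(1:5, function(k) sample(u, 40)),
                     paste0("BG", 1:5)))
  wins <- 0
  for (s in 1:20) {
    hits <- c(sample(u[1:40], 15), sample(u[41:200], 5))
    res <- oraEnrichment(hits, u, sets)
    if (res$set[1] == "TARGET") wins <- wins + 1
  }
  expect_gte(wins, 19)
})
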