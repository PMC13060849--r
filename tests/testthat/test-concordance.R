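mkPairs <- function(intensity, tpm)
  data.frame(gene = sprintf("G%03d", seq_along(intensity)),
             intensity = intensity, tpm = tpm)

test_that("gene matching is an inner join with unmatched reporting", {
  v <- matrix(2^rnorm(12, 20, 1), 4, 3,
              dimnames = list(c("EGFR", "PTK7", "MET", "ERBB2"),
                              paste0("s", 1:3)))
  lfq <- LFQExperiment(v, "g")
  rna <- matrix(2^rnorm(9, 4, 1), 3, 3,
                dimnames = list(c("egfr", "ptk7", "NOTHERE"),
                                paste0("r", 1:3)))
  pr <- matchGenes(lfq, rna)
  expect_setequal(pr$gene, c("EGFR", "PTK7"))
  expect_setequal(attr(pr, "unmatched_protein"), c("MET", "ERBB2"))
  expect_setequal(attr(pr, "unmatched_rna"), "NOTHERE")
  rnaBad <- matrix(1, 1, 1, dimnames = list("ZZZ", "r1"))
  expect_error(matchGenes(lfq, rnaBad), class = "surfkit_data_error")
})

test_that("correlation reaches +/-1 on exact lines and matches the formula", {
  x <- 2^seq(1, 5, length.out = 10)
  up <- mkPairs(intensity = 2^(2 * log2(x + 1) + 1), tpm = x)
  expect_equal(correlateAbundance(up)$r, 1, tolerance = 1e-12)
  dn <- mkPairs(intensity = 2^(-2 * log2(x + 1) + 20), tpm = x)
  expect_equal(correlateAbundance(dn)$r, -1, tolerance = 1e-12)
  set.seed(44)
  rp <- mkPairs(intensity = 2^rnorm(20, 20, 2), tpm = 2^rnorm(20, 4, 2))
  got <- correlateAbundance(rp)
  expect_equal(got$r, oraclePearson(log2(rp$tpm + 1), log2(rp$intensity)),
               tolerance = 1e-12)
  expect_error(correlateAbundance(rp[1:2, ]),
               class = "surfkit_data_error")
})

test_that("the min-TPM filter drops the noisy low stratum and lifts r", {
  set.seed(50)
  n <- 600
  z <- rnorm(n)
  hiT <- 2^(6 + z[1:300] * 1.2)              # coupled, high abundance
  hiI <- 2^(20 + z[1:300] * 1.2 + rnorm(300, 0, 0.4))
  loT <- 2^runif(300, -2, 1)                 # uncoupled low-TPM noise
  loI <- 2^rnorm(300, 20, 1.5)
  pairs <- mkPairs(c(hiI, loI), c(hiT, loT))
  rAll <- correlateAbundance(pairs)$r
  rFlt <- correlateAbundance(pairs, minTPM = 5)$r
  expect_gt(rFlt, rAll)
})

test_that("decile binning partitions with near-equal sizes", {
  set.seed(61)
  p10 <- mkPairs(2^rnorm(10, 20, 2), 2^rnorm(10, 4, 1))
  d10 <- decileBinning(p10)
  expect_equal(d10$summary$n, rep(1, 10))
  p25 <- mkPairs(2^rnorm(25, 20, 2), 2^rnorm(25, 4, 1))
  d25 <- decileBinning(p25)
  expect_equal(d25$summary$n, c(3, 3, 3, 3, 3, 2, 2, 2, 2, 2))
  # partition: disjoint union covering all genes, sizes differ by <= 1
  for (n in c(10, 37, 104)) {
    pp <- mkPairs(2^rnorm(n, 20, 2), 2^rnorm(n, 4, 1))
    dd <- decileBinning(pp)
    expect_setequal(dd$assignment$gene, pp$gene)
    expect_lte(diff(range(dd$summary$n)), 1)
    # decile 10 holds the most abundant surface proteins
    top <- dd$assignment[dd$assignment$decile == 10, "intensity"]
    rest <- dd$assignment[dd$assignment$decile < 10, "intensity"]
    expect_gte(min(top), max(rest) - 1e-12)
  }
  expect_error(decileBinning(mkPairs(2^rnorm(5), 2^rnorm(5))),
               class = "surfkit_data_error")
})

test_that("fold-change concordance: identity, null and coupled regimes", {
  set.seed(70)
  fc <- rnorm(100, 0, 1.5)
  rnaFC <- data.frame(gene = sprintf("G%03d", 1:100), log2fc = fc)
  protFC <- data.frame(protein = sprintf("G%03d", 1:100), log2fc = fc,
                       one_condition_only = FALSE)
  expect_equal(foldChangeConcordance(rnaFC, protFC)$r, 1)
  # independent fold changes stay near zero
  prot0 <- protFC; prot0$log2fc <- rnorm(100, 0, 1.5)
  expect_lt(abs(foldChangeConcordance(rnaFC, prot0)$r), 3 / sqrt(100))
  # capped one-condition-only rows are excluded from the pairing
  protC <- protFC
  protC$one_condition_only[1:10] <- TRUE
  expect_equal(foldChangeConcordance(rnaFC, protC)$n, 90)
})

test_that("coupled fold changes give positive significant r at n = 200", {
  set.seed(81)
  hits <- 0
  for (s in 1:20) {
    latent <- rnorm(200, 0, 1)
    rnaFC <- data.frame(gene = sprintf("G%03d", 1:200),
                        log2fc = 0.5 * latent + rnorm(200, 0, sqrt(0.75)))
    protFC <- data.frame(protein = sprintf("G%03d", 1:200),
                         log2fc = 0.5 * latent + rnorm(200, 0, sqrt(0.75)),
                         one_condition_only = FALSE)
    cc <- foldChangeConcordance(rnaFC, protFC)
    if (cc$r > 0 && cc$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("sample correlation matrix is symmetric with unit diagonal", {
  set.seed(90)
  toy <- randomToyMatrix(nProt = 30, nSamp = 4)
  x <- LFQExperiment(toy$values, toy$groups)
  m <- sampleCorrelationMatrix(x)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  # a duplicated sample correlates perfectly with its twin
  vdup <- cbind(toy$values, dup = toy$values[, 1])
  colnames(vdup)[5] <- "dup"
  mdup <- sampleCorrelationMatrix(LFQExperiment(vdup, "g"))
  expect_equal(mdup["s1", "dup"], 1)
})

test_that("replicates correlate higher within than between conditions", {
  pair <- simulatePRC2Pair(syntheticConfig(n_proteins = 400, seed = 31))
  v <- cbind(intensities(pair$active), intensities(pair$inactive))
  x <- LFQExperiment(v, "g",
                     condition = rep(c("act", "ina"), each = 3))
  m <- sampleCorrelationMatrix(x)
  cond <- rep(c("act", "ina"), each = 3)
  same <- m[outer(cond, cond, "==") & upper.tri(m)]
  diff_ <- m[outer(cond, cond, "!=") & upper.tri(m)]
  expect_gt(mean(same), mean(diff_))
})
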