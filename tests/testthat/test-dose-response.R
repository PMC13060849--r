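test_that("background shift subtracts the plate's media mean", {
  plate <- data.frame(plate = "p1",
                      well = paste0("w", 1:10),
                      role = c(rep("media_only", 8), "drug", "zero_drug"),
                      dose = c(rep(NA, 8), 1e-8, NA),
                      drug = c(rep(NA, 8), "d", NA),
                      intensity = c(rep(10, 8), 110, 210))
  sh <- backgroundShift(plate)
  expect_equal(sh$shifted[9], 100)
  expect_equal(sh$shifted[10], 200)
  # translation invariance: adding a constant changes nothing
  plate2 <- plate; plate2$intensity <- plate$intensity + 55
  expect_equal(backgroundShift(plate2)$shifted, sh$shifted)
  noMedia <- plate[plate$role != "media_only", ]
  expect_error(backgroundShift(noMedia), class = "surfkit_data_error")
})

test_that("viability normalization is a ratio to the zero-drug mean", {
  plate <- data.frame(plate = "p1", well = paste0("w", 1:12),
                      role = c(rep("media_only", 4), rep("zero_drug", 4),
                               rep("drug", 4)),
                      dose = c(rep(NA, 8), 1e-9, 1e-8, 1e-7, 1e-6),
                      drug = c(rep(NA, 8), rep("d", 4)),
                      intensity = c(rep(100, 4), rep(1100, 4),
                                    1100, 600, 100, 350))
  v <- normalizeViability(plate)
  # well equal to zero-drug mean -> 1; equal to media mean -> 0
  expect_equal(v$viability, c(1, 0.5, 0, 0.25))
  # signal below background is a data error
  bad <- plate; bad$intensity[5:8] <- 50
  expect_error(normalizeViability(bad), class = "surfkit_data_error")
})

test_that("the viability pipeline is invariant to affine plate transforms", {
  tf <- doseResponseFit(b = 1.2, c = 0.05, d = 1, e = 3e-8)
  pl <- simulateViabilityPlate(tf, doses = 10^seq(-10, -6, length.out = 8),
                               noise_sd = 0.03, seed = 14)
  v1 <- normalizeViability(pl)
  pl2 <- pl; pl2$intensity <- 2.5 * pl$intensity + 300
  v2 <- normalizeViability(pl2)
  expect_equal(v1$viability, v2$viability, tolerance = 1e-12)
})

test_that("noiseless 4PL curves are recovered to high precision", {
  truth <- list(b = 2, c = 0, d = 1, e = 1e-8)
  pl <- simulateViabilityPlate(do.call(doseResponseFit, truth),
                               doses = 10^seq(-10.5, -5.5, length.out = 8),
                               noise_sd = 0, seed = 1)
  fit <- fit4PL(normalizeViability(pl))
  for (par in names(truth)) {
    est <- slot(fit, par)
    expect_lt(abs(est - truth[[par]]) / max(1, abs(truth[[par]])), 1e-6)
  }
  expect_true(fit@converged)
  expect_equal(ic50(fit), 1e-8, tolerance = 1e-6)
})

test_that("the fitted midpoint is the half-range crossing of the curve", {
  tf <- doseResponseFit(b = 1.7, c = 0.1, d = 0.95, e = 4e-9)
  pl <- simulateViabilityPlate(tf, doses = 10^seq(-11, -6, length.out = 10),
                               noise_sd = 0.02, seed = 33)
  fit <- fit4PL(normalizeViability(pl))
  # bisection on the fitted curve for f(x) = (c + d)/2
  half <- (fit@c + fit@d) / 2
  lo <- 1e-13; hi <- 1e-4
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (ll4Curve(mid, fit@b, fit@c, fit@d, fit@e) > half) lo <- mid
    else hi <- mid
  }
  expect_equal(sqrt(lo * hi), fit@e, tolerance = 1e-6)
})

test_that("flat plates yield a non-convergence flag, never an IC50", {
  set.seed(88)
  v <- data.frame(plate = "p", well = paste0("w", 1:32), drug = "d",
                  dose = rep(10^seq(-10, -6, length.out = 8), each = 4),
                  viability = 1 + rnorm(32, 0, 0.03))
  fit <- fit4PL(v)
  expect_false(fit@converged)
  expect_true(is.na(ic50(fit)))
  # and too few distinct doses is a data error
  v3 <- v[v$dose %in% unique(v$dose)[1:3], ]
  expect_error(fit4PL(v3), class = "surfkit_data_error")
})

test_that("full plate pipeline recovers IC50 within 20% at the design", {
  ok <- 0
  for (s in 1:40) {
    e <- 10^runif(1, -9.5, -7.5)
    tf <- doseResponseFit(b = 1.5, c = 0, d = 1, e = e)
    pl <- simulateViabilityPlate(tf, doses = e * 10^seq(2, -2,
                                                        length.out = 8),
                                 n_reps = 4, noise_sd = 0.05, seed = s)
    fit <- fit4PL(normalizeViability(pl))
    if (fit@converged && abs(ic50(fit) - e) / e <= 0.2) ok <- ok + 1
  }
  expect_gte(ok, 36)
})

test_that("density-potency correlation catches the inverse coupling", {
  # perfect monotone decrease -> rho exactly -1
  dens <- data.frame(sample = paste0("s", 1:5), antigen = "a",
                     antigens_per_cell = c(1e3, 1e4, 1e5, 1e6, 1e7))
  fits <- lapply(1:5, function(i)
    doseResponseFit(b = 1, c = 0, d = 1, e = 10^(-5 - i), drug = "d",
                    sample = paste0("s", i)))
  pc <- densityPotencyCorrelation(dens, fits)
  expect_equal(pc$rho, -1)
  expect_lt(pc$p, 0.05)
  # independent density and potency stay centered at zero
  set.seed(27)
  rhos <- replicate(50, {
    d <- data.frame(sample = paste0("s", 1:8), antigen = "a",
                    antigens_per_cell = 10^runif(8, 3, 6))
    f <- lapply(1:8, function(i)
      doseResponseFit(b = 1, c = 0, d = 1, e = 10^runif(1, -9, -6),
                      drug = "d", sample = paste0("s", i)))
    densityPotencyCorrelation(d, f)$rho
  })
  expect_lt(abs(mean(rhos)), 0.15)
  expect_error(densityPotencyCorrelation(dens[1:2, ], fits[1:2]),
               class = "surfkit_data_error")
})

test_that("non-converged fits are excluded from the potency pairing", {
  dens <- data.frame(sample = paste0("s", 1:4), antigen = "a",
                     antigens_per_cell = c(1e3, 1e4, 1e5, 1e6))
  fits <- c(lapply(1:3, function(i)
    doseResponseFit(b = 1, c = 0, d = 1, e = 10^(-6 - i), drug = "d",
                    sample = paste0("s", i))),
    list(doseResponseFit(b = NA_real_, c = NA_real_, d = NA_real_,
                         e = NA_real_, drug = "d", sample = "s4",
                         converged = FALSE)))
  pc <- densityPotencyCorrelation(dens, fits)
  expect_equal(pc$n, 3)
})
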