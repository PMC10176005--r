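# Map estimation: joint R2* fit, R1/A closed forms, MTsat, PD calibration

test_that("two-point single-contrast fit solves the log-linear system", {
  s <- multiEchoSeries("PDw", array(c(100, 81.873), c(1, 1, 1, 2)),
                       c(0.002, 0.010))
  fit <- fitEstatics(list(s))
  expect_equal(fit@r2star[1, 1, 1], log(100 / 81.873) / 0.008,
               tolerance = 1e-10)
  expect_equal(fit@r2star[1, 1, 1], 25, tolerance = 1e-4)
  expect_equal(fit@intercepts$PDw[1, 1, 1], 100 * exp(0.05),
               tolerance = 1e-4)
})

test_that("noiseless three-contrast data with shared decay is recovered exactly", {
  te <- seq(0.002, 0.014, by = 0.003)
  d <- c(3, 2, 2)
  r2s <- 30
  s0 <- c(MTw = 600, PDw = 900, T1w = 750)
  series <- lapply(names(s0), function(ct) {
    arr <- array(0, c(d, length(te)))
    for (k in seq_along(te)) arr[, , , k] <- s0[ct] * exp(-te[k] * r2s)
    multiEchoSeries(ct, arr, te)
  })
  fit <- fitEstatics(series)
  expect_true(all(fit@valid))
  expect_equal(max(abs(fit@r2star - r2s)), 0, tolerance = 1e-9)
  for (ct in names(s0))
    expect_equal(max(abs(fit@intercepts[[ct]] - s0[ct])), 0,
                 tolerance = 1e-6)
})

test_that("noisy joint fit is unbiased against a nonlinear least-squares oracle", {
  set.seed(21)
  te <- seq(0.0023, by = 0.0023, length.out = 6)
  r2s <- 22
  s0 <- c(MTw = 600, PDw = 900, T1w = 750)
  nvox <- 200
  sd <- 0.01 * max(s0)
  sig <- vapply(names(s0), function(ct)
    outer(s0[ct] * exp(-te * r2s), rep(1, nvox)) +
      matrix(rnorm(length(te) * nvox, 0, sd), length(te)),
    matrix(0, length(te), nvox))
  series <- lapply(names(s0), function(ct)
    multiEchoSeries(ct, array(aperm(sig[, , ct], c(2, 1)),
                              c(nvox, 1, 1, length(te))), te))
  fit <- fitEstatics(series)
  est <- fit@r2star[, 1, 1]

  oracle <- vapply(seq_len(nvox), function(v) {
    dat <- data.frame(y = c(sig[, v, 1], sig[, v, 2], sig[, v, 3]),
                      te = rep(te, 3),
                      ct = rep(names(s0), each = length(te)))
    nf <- stats::nls(y ~ (a1 * (ct == "MTw") + a2 * (ct == "PDw") +
                            a3 * (ct == "T1w")) * exp(-te * r),
                     data = dat,
                     start = list(a1 = 600, a2 = 900, a3 = 750, r = 20))
    stats::coef(nf)[["r"]]
  }, numeric(1))
  # both estimators unbiased within Monte-Carlo error, and close per voxel
  expect_lt(abs(mean(est) - r2s), 3 * stats::sd(est) / sqrt(nvox))
  expect_lt(abs(mean(est - oracle)), 3 * stats::sd(est - oracle) / sqrt(nvox) +
              0.02)
})

test_that("non-positive signals invalidate the voxel instead of erroring", {
  arr <- array(c(100, 0, 90, 50), c(2, 1, 1, 2))
  fit <- fitEstatics(list(multiEchoSeries("PDw", arr, c(0.002, 0.01))))
  expect_false(fit@valid[2, 1, 1])
  expect_true(is.na(fit@r2star[2, 1, 1]))
  expect_true(fit@valid[1, 1, 1])
})

test_that("R1/A closed form inverts its own approximation exactly and the exact FLASH model within 1%", {
  prot <- smallAngleProtocol()
  A <- 1000; r1 <- 1.0
  rational <- function(ct) {
    a <- prot@flipAngles[ct] * pi / 180
    tr <- prot@repetitionTimes[ct]
    A * a * tr * r1 / (a^2 / 2 + tr * r1)
  }
  sh <- c(1, 1, 1)
  res <- computeR1Amplitude(array(rational("T1w"), sh),
                            array(rational("PDw"), sh), prot)
  expect_equal(res$r1[1], r1, tolerance = 1e-12)
  expect_equal(res$amplitude[1], A, tolerance = 1e-12)

  exact <- function(ct) flashSignal(A, r1, 0, prot@flipAngles[ct],
                                    prot@repetitionTimes[ct], 0)
  res2 <- computeR1Amplitude(array(exact("T1w"), sh),
                             array(exact("PDw"), sh), prot)
  expect_equal(res2$r1[1], r1, tolerance = 0.01)
  expect_equal(res2$amplitude[1], A, tolerance = 0.01)
})

test_that("infeasible intercept pairs are flagged invalid, degenerate protocols error", {
  prot <- smallAngleProtocol()
  # equal intercepts with alpha_T1 > alpha_PD and equal TR admit no
  # positive R1 solution
  same <- array(500, c(1, 1, 1))
  res <- computeR1Amplitude(same, same * (4 / 10), prot)  # u1 == u2
  expect_false(res$valid[1])
  degenerate <- acquisitionProtocol(flipAngles = c(MTw = 6, PDw = 6,
                                                   T1w = 6))
  expect_error(computeR1Amplitude(same, same, degenerate), "degenerate")
})

test_that("MTsat is zero without saturation, increases with A, and round-trips", {
  prot <- smallAngleProtocol()
  a <- prot@flipAngles["MTw"] * pi / 180
  tr <- prot@repetitionTimes["MTw"]
  A <- 1000; r1 <- 1.0
  noMT <- A * a * tr * r1 / (a^2 / 2 + tr * r1)
  sh <- c(1, 1, 1)
  res <- computeMTsat(array(noMT, sh), array(A, sh), array(r1, sh), prot)
  expect_equal(res$mtsat[1], 0, tolerance = 1e-10)
  res2 <- computeMTsat(array(noMT, sh), array(2 * A, sh), array(r1, sh),
                       prot)
  expect_gt(res2$mtsat[1], res$mtsat[1])
  expect_false(computeMTsat(array(-1, sh), array(A, sh), array(r1, sh),
                            prot)$valid[1])

  # simulate -> estimate round trip at truth MTsat 2 p.u.
  truth <- parameterMaps(mtsat = array(2, sh), r1 = array(1.05, sh),
                         r2star = array(21, sh),
                         amplitude = array(800, sh))
  est <- estimateParameterMaps(simulateFlashSeries(truth, prot, 0), prot)
  expect_equal(mtsat(est)[1], 2, tolerance = 0.01)
})

test_that("PD calibration hits the target, is scale invariant, and preserves structure", {
  m <- array(5, c(2, 2, 2)); mask <- array(TRUE, c(2, 2, 2))
  expect_equal(calibratePD(m, mask, 69), array(69, c(2, 2, 2)))
  set.seed(1)
  a <- array(runif(8, 1, 3), c(2, 2, 2))
  expect_equal(calibratePD(3 * a, mask), calibratePD(a, mask),
               tolerance = 1e-12)
  expect_error(calibratePD(a, array(FALSE, c(2, 2, 2))), "empty")
  expect_error(calibratePD(array(0, c(2, 2, 2)), mask), "zero")
})

test_that("forward simulation matches hand-evaluated signals and decays as exp(-TE R2*)", {
  expect_equal(flashSignal(1000, 1, 0, 6, 0.025, 0), 85.9, tolerance = 1e-3)
  sh <- c(1, 1, 1)
  truth0 <- parameterMaps(mtsat = array(1.9, sh), r1 = array(1, sh),
                          r2star = array(0, sh), amplitude = array(1000, sh))
  ser <- simulateFlashSeries(truth0, smallAngleProtocol(), 0)
  for (ct in names(ser)) {
    echoes <- ser[[ct]]@data[1, 1, 1, ]
    expect_equal(max(abs(echoes - echoes[1])), 0, tolerance = 1e-10)
  }
  # zero saturation: MTw series equals the rational no-MT prediction
  truthNoMT <- parameterMaps(mtsat = array(0, sh), r1 = array(1, sh),
                             r2star = array(15, sh),
                             amplitude = array(1000, sh))
  prot <- smallAngleProtocol()
  ser2 <- simulateFlashSeries(truthNoMT, prot, 0)
  a <- prot@flipAngles["MTw"] * pi / 180
  tr <- prot@repetitionTimes["MTw"]
  pred <- 1000 * a * tr * 1 / (a^2 / 2 + tr * 1) *
    exp(-prot@echoTimes$MTw * 15)
  expect_equal(ser2$MTw@data[1, 1, 1, ], unname(pred), tolerance = 1e-10)
  expect_error(simulateFlashSeries(truthNoMT, prot, noiseSd = -1),
               "non-negative")
})

test_that("estimators are voxelwise independent: permuting voxels permutes outputs", {
  set.seed(4)
  n <- 12
  truth <- parameterMaps(mtsat = array(runif(n, 0.5, 3), c(n, 1, 1)),
                         r1 = array(runif(n, 0.5, 1.5), c(n, 1, 1)),
                         r2star = array(runif(n, 10, 30), c(n, 1, 1)),
                         amplitude = array(runif(n, 500, 1500), c(n, 1, 1)))
  prot <- smallAngleProtocol()
  perm <- sample(n)
  permuteMaps <- function(m) {
    for (s in c("mtsat", "r1", "r2star", "amplitude"))
      slot(m, s) <- array(slot(m, s)[perm, 1, 1], c(n, 1, 1))
    m
  }
  est1 <- estimateParameterMaps(simulateFlashSeries(truth, prot, 0), prot)
  est2 <- estimateParameterMaps(simulateFlashSeries(permuteMaps(truth),
                                                    prot, 0), prot)
  expect_equal(r2starMap(est2)[, 1, 1], r2starMap(est1)[perm, 1, 1],
               tolerance = 1e-12)
  expect_equal(mtsat(est2)[, 1, 1], mtsat(est1)[perm, 1, 1],
               tolerance = 1e-9)
})
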