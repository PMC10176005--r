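# Normal-appearing-tissue inference: medians, ARoC, status regression,
# permutation p values, FDR, post-hoc tests

test_that("tissue medians are robust and exclude invalid voxels", {
  sh <- c(4, 1, 1)
  maps <- parameterMaps(mtsat = array(c(1, 2, 3, 100), sh),
                        r1 = array(1, sh), r2star = array(20, sh),
                        amplitude = array(700, sh))
  masks <- list(NAWM = array(TRUE, sh))
  med <- extractTissueMedians(maps, masks, tissues = "NAWM",
                              parameters = "MTsat")
  expect_equal(med$median, 2.5)                   # robust to the outlier
  maps2 <- parameterMaps(mtsat = array(1.9, sh), r1 = array(1, sh),
                         r2star = array(20, sh), amplitude = array(700, sh))
  expect_equal(extractTissueMedians(maps2, masks, "NAWM", "MTsat")$median,
               1.9)
  # invalid voxels drop out of the median
  maps@valid <- array(c(TRUE, TRUE, TRUE, FALSE), sh)
  expect_equal(extractTissueMedians(maps, masks, "NAWM", "MTsat")$median, 2)
  expect_error(extractTissueMedians(maps, list(NAWM = array(FALSE, sh)),
                                    "NAWM", "MTsat"), "NAWM")
})

test_that("annual rate of change handles absolute and relative modes", {
  expect_equal(aroc(2.0, 2.1, 2), 0.05)
  expect_equal(aroc(2.0, 2.0, 7.3), 0)
  expect_equal(aroc(2.0, 2.0, 7.3, mode = "relative"), 0)
  expect_equal(aroc(80, 82, 2.5, mode = "relative"), 1)
  expect_error(aroc(2, 2.1, 0), "positive")
  expect_error(aroc(0, 1, 1, mode = "relative"), "non-zero")
})

test_that("status regression recovers the group-mean difference and R^2", {
  fit <- fitStatusGlm(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(fit@beta1, 2)        # mean(3,4) - mean(1,2)
  expect_equal(fit@beta0, 1.5)
  expect_equal(fit@r2, 0.8)         # SSB 4 / SST 5
  x <- c(0, 0, 0, 1, 1, 1)
  expect_equal(fitStatusGlm(as.numeric(x), x)@r2, 1)
  expect_equal(fitStatusGlm(c(1, 2, 3, 1, 2, 3), x)@beta1, 0)
  expect_equal(fitStatusGlm(c(1, 2, 3, 1, 2, 3), x)@r2, 0)
  # R^2 equals the squared point-biserial correlation
  set.seed(2)
  y <- rnorm(10); xx <- rep(c(0, 1), 5)
  expect_equal(fitStatusGlm(y, xx)@r2, cor(y, xx)^2, tolerance = 1e-12)
  expect_error(fitStatusGlm(y, rep(1, 10)), "constant")
  expect_warning(fitStatusGlm(rep(2, 6), x), "constant response")
})

test_that("exhaustive permutation p matches an independent enumeration oracle", {
  y <- c(0.1, 0.2, 0.15, 0.9, 1.0, 0.95)
  x <- c(0, 0, 0, 1, 1, 1)
  res <- permutationPvalue(y, x, mode = "exhaustive")
  expect_equal(res@p, 0)            # no permutation beats the separation
  expect_identical(res@n, 19L)      # choose(6,3) minus the identity
  oracle <- permOracle(y, x)
  expect_equal(res@p, oracle$p)
  expect_equal(res@rObs, oracle$rObs, tolerance = 1e-12)
  # a mixed instance with non-trivial p
  set.seed(31)
  y2 <- rnorm(7); x2 <- c(0, 0, 0, 1, 1, 1, 1)
  res2 <- permutationPvalue(y2, x2, mode = "exhaustive")
  oracle2 <- permOracle(y2, x2)
  expect_equal(res2@p, oracle2$p)
  expect_identical(res2@n, as.integer(oracle2$n))
})

test_that("sampled permutations are seeded, reproducible and never the identity", {
  y <- c(0.3, 0.1, 0.5, 0.9, 0.8, 1.2, 0.2, 0.7)
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  a <- permutationPvalue(y, x, n = 400, seed = 7)
  b <- permutationPvalue(y, x, n = 400, seed = 7)
  expect_identical(a@p, b@p)
  expect_identical(a@rPerm, b@rPerm)
  expect_false(identical(a@p,
                         permutationPvalue(y, x, n = 400, seed = 8)@p))
  expect_error(permutationPvalue(rep(1, 6), c(0, 0, 0, 1, 1, 1)),
               "constant")
  expect_error(permutationPvalue(y, x, n = 0), "n must be")
})

test_that("Benjamini-Hochberg step-up rejects per the hand-enumerated thresholds", {
  expect_identical(bhFdr(rep(1, 12)), integer(0))
  expect_identical(bhFdr(c(0.001, rep(0.5, 11))), 1L)
  expect_identical(bhFdr(seq(0.01, 0.12, by = 0.01)), integer(0))
  # all tiny: everything rejected
  expect_identical(bhFdr(rep(1e-5, 12)), 1:12)
  expect_error(bhFdr(numeric(0)), "empty")
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("post-hoc Welch test matches the closed formula", {
  v0 <- c(1.1, 0.9, 1.3, 0.8); v1 <- c(2.0, 2.2, 1.7, 2.4, 2.1)
  res <- posthocGroupTtest(c(v0, v1), c(0, 0, 0, 0, 1, 1, 1, 1, 1))
  se <- sqrt(var(v1) / 5 + var(v0) / 4)
  expect_equal(res$t, (mean(v1) - mean(v0)) / se, tolerance = 1e-12)
  dfW <- se^4 / ((var(v1) / 5)^2 / 4 + (var(v0) / 4)^2 / 3)
  expect_equal(res$df, dfW, tolerance = 1e-10)
  same <- c(1, 2, 3)
  res2 <- posthocGroupTtest(c(same, same), c(0, 0, 0, 1, 1, 1))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  expect_error(posthocGroupTtest(1:4, c(0, 1, 1, 1)), "at least 2")
})

test_that("the inference stage submits one family of 12 tests and flags programmed effects", {
  coh <- generatePhantom(phantomConfig(gridShape = c(16L, 16L, 16L),
                                       nLesions = 0L, seed = 31L))
  expect_true(all(c(0L, 1L) %in% coh@clinical$status))
  tab <- cohortArocTable(coh, seed = 5)
  expect_identical(nrow(tab), 17L * 3L * 4L)
  res <- runNabtInference(tab, coh@clinical[c("subject_id", "status")],
                          nPerm = 1000, seed = 6)
  expect_identical(nrow(res), 12L)
  expect_identical(sort(unique(res$tissue)), sort(c("NAWM", "NACGM",
                                                    "NADGM")))
  # the programmed NAWM/NACGM MTsat and R2* drifts are detected, with
  # positive status coefficients and significant post-hoc tests
  hit <- res$tissue %in% c("NAWM", "NACGM") &
         res$parameter %in% c("MTsat", "R2star")
  expect_true(all(res$rejected[hit]))
  expect_true(all(res$beta1[hit] > 0))
  expect_true(all(res$posthoc_p[hit] < 0.05))
  # deep GM carries no programmed effect
  expect_false(any(res$rejected[res$tissue == "NADGM"]))
})
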