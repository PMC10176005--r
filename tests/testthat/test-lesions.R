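# Lesion-area long table and area-by-time mixed model

test_that("one enlarging lesion yields 32 rows: 4 areas x 2 timepoints x 4 parameters", {
  coh <- generatePhantom(tinyPhantomConfig(nSubjects = 1L))
  subj <- coh@subjects[[1]]
  masks <- binarizeTissues(subj$T0$posteriors)
  areas <- buildLesionAreas(subj$T0$flair, subj$T0$lesion, subj$T1$lesion,
                            masks$NAWM | subj$T1$lesion)
  sel <- selectEnlargingLesions(areas)
  expect_length(sel$ids, 1L)
  lt <- buildLongTable(subj$T0$truth, subj$T1$truth, areas, sel$ids,
                       subjectId = subj$id)
  expect_identical(nrow(lt), 32L)
  expect_equal(lt$log_value, log(lt$median))
})

test_that("per-area medians reproduce the programmed core-to-NAWM gradient", {
  cfg <- tinyPhantomConfig(nSubjects = 1L, subjectCv = 0,
                           statusEffect = c(MTsat = 0, PD = 0, R1 = 0,
                                            R2star = 0))
  coh <- generatePhantom(cfg)
  subj <- coh@subjects[[1]]
  masks <- binarizeTissues(subj$T0$posteriors)
  areas <- buildLesionAreas(subj$T0$flair, subj$T0$lesion, subj$T1$lesion,
                            masks$NAWM | subj$T1$lesion)
  lt <- buildLongTable(subj$T0$truth, subj$T1$truth, areas,
                       selectEnlargingLesions(areas)$ids)
  getMed <- function(param, area, tp = "T0")
    lt$median[lt$parameter == param & lt$area == area & lt$timepoint == tp]
  for (p in c("MTsat", "R1", "R2star")) {
    expect_lt(getMed(p, "focal_flair"), getMed(p, "initial_peripheral"))
    expect_lt(getMed(p, "initial_peripheral"),
              getMed(p, "later_peripheral"))
    expect_lt(getMed(p, "later_peripheral"), getMed(p, "nawm"))
  }
  # reversed for PD (more free water towards the core)
  expect_gt(getMed("PD", "focal_flair"), getMed("PD", "initial_peripheral"))
  expect_gt(getMed("PD", "later_peripheral"), getMed("PD", "nawm"))
  # truth values are exact at the shell centres
  tt <- defaultTissueTruth()
  g <- cfg@peripheralGradient
  expect_equal(getMed("MTsat", "initial_peripheral"),
               tt["lesion", "MTsat"] +
                 g * (tt["NAWM", "MTsat"] - tt["lesion", "MTsat"]),
               tolerance = 1e-9)
})

test_that("non-positive medians are rejected by the log transform", {
  sh <- c(2, 2, 2)
  bad <- parameterMaps(mtsat = array(-1, sh), r1 = array(1, sh),
                       r2star = array(20, sh), amplitude = array(700, sh))
  areas <- new("AreaMasks",
               focalFlair = array(c(TRUE, rep(FALSE, 7)), sh),
               initialPeripheral = array(FALSE, sh),
               laterPeripheral = array(FALSE, sh),
               nawm = array(c(FALSE, TRUE, rep(FALSE, 6)), sh),
               lesionLabels = array(0L, sh), voxelSize = c(1, 1, 1))
  expect_error(buildLongTable(bad, bad, areas, integer(0)),
               "non-positive median")
})

test_that("with zero random variance the mixed-model F tests match a fixed-effects ANOVA oracle", {
  lt <- syntheticLongTable(nSubjects = 6, nLesions = 3, sd = 0.12,
                           timeEffect = 0.05, seed = 13)
  fit <- fitAreaTimeModel(lt)
  expect_true(all(as.data.frame(lme4::VarCorr(fit@model))$vcov[1:2] == 0))
  ols <- stats::lm(log_value ~ area * timepoint,
                   data = transform(lt,
                                    area = factor(area,
                                                  levels = c("focal_flair",
                                                             "initial_peripheral",
                                                             "later_peripheral",
                                                             "nawm")),
                                    timepoint = factor(timepoint)))
  oracleF <- stats::anova(ols)[1:3, "F value"]
  expect_true(fit@singular)
  expect_lt(max(abs(fit@anova[, "F value"] - oracleF)), 1e-6)
})

test_that("a pure area effect yields a large area F and null time and interaction tests", {
  lt <- syntheticLongTable(nSubjects = 8, nLesions = 3, sd = 0.1,
                           timeEffect = 0, seed = 5)
  fit <- fitAreaTimeModel(lt)
  av <- fit@anova
  expect_gt(av["area", "F value"], 100)
  expect_lt(av["area", "Pr(>F)"], 1e-10)
  expect_gt(av["timepoint", "Pr(>F)"], 0.05)
  expect_gt(av["area:timepoint", "Pr(>F)"], 0.05)
})

test_that("row order does not change the fit and a global scale shifts only the intercept", {
  lt <- syntheticLongTable(nSubjects = 5, nLesions = 2, seed = 3)
  f1 <- fitAreaTimeModel(lt)
  set.seed(1)
  f2 <- fitAreaTimeModel(lt[sample(nrow(lt)), ])
  expect_equal(f1@anova[, "F value"], f2@anova[, "F value"],
               tolerance = 1e-4)
  # multiply all medians by a constant: log shifts, F statistics unchanged
  lt3 <- lt
  lt3$median <- lt3$median * 7
  lt3$log_value <- log(lt3$median)
  f3 <- fitAreaTimeModel(lt3)
  expect_equal(f1@anova[, "F value"], f3@anova[, "F value"],
               tolerance = 1e-4)
  expect_equal(lme4::fixef(f3@model)[["(Intercept)"]] -
                 lme4::fixef(f1@model)[["(Intercept)"]], log(7),
               tolerance = 1e-6)
})

test_that("pairwise contrasts enumerate all 6 area pairs per timepoint with Tukey adjustment", {
  lt <- syntheticLongTable(nSubjects = 6, nLesions = 2, sd = 0.05,
                           seed = 17)
  fit <- fitAreaTimeModel(lt)
  ctr <- pairwiseAreaContrasts(fit)
  expect_identical(nrow(ctr), 12L)
  expect_identical(as.integer(table(ctr$timepoint)), c(6L, 6L))
  # two areas simulated identical: adjusted p near 1
  lt2 <- syntheticLongTable(nSubjects = 6, nLesions = 2, sd = 0.05,
                            areaMeans = c(focal_flair = 0,
                                          initial_peripheral = 0,
                                          later_peripheral = 1,
                                          nawm = 2), seed = 19)
  ctr2 <- pairwiseAreaContrasts(fitAreaTimeModel(lt2))
  same <- ctr2$contrast == "focal_flair - initial_peripheral"
  expect_true(all(ctr2$p_adj[same] > 0.5))
  expect_true(all(ctr2$p_adj[ctr2$contrast ==
                               "later_peripheral - nawm"] < 0.05))
})
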