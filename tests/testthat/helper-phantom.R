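# Shared fixtures, all generated in code.

# protocol inside the small-angle regime (all flip angles <= 10 degrees,
# TR * R1 <= 0.05 for brain-like R1), where the rational approximation of
# the FLASH equation is accurate to well under 1%
smallAngleProtocol <- function() {
  acquisitionProtocol(flipAngles = c(MTw = 6, PDw = 4, T1w = 10))
}

tinyPhantomConfig <- function(nSubjects = 3L, nLesions = 1L, seed = 42L,
                              ...) {
  phantomConfig(gridShape = c(24L, 24L, 24L), nSubjects = nSubjects,
                nLesions = nLesions, seed = seed, ...)
}

# null configuration: no programmed status effect or atrophy, small grid
nullPhantomConfig <- function(seed = 1L, ...) {
  phantomConfig(gridShape = c(16L, 16L, 16L), nLesions = 0L,
                statusEffect = c(MTsat = 0, PD = 0, R1 = 0, R2star = 0),
                atrophyPctYr = 0, seed = seed, ...)
}

# independent sphere rasterization: voxel centre within radius of centre
rasterSphere <- function(dims, center, radius, voxelSize = c(1, 1, 1)) {
  xs <- (seq_len(dims[1]) - 0.5) * voxelSize[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxelSize[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxelSize[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

# exhaustive permutation p value computed independently with lm()
permOracle <- function(y, x) {
  rsq <- function(xx) summary(stats::lm(y ~ xx))$r.squared
  n1 <- sum(x == 1)
  combs <- utils::combn(length(x), n1)
  rObs <- rsq(x)
  rPerm <- numeric(0)
  for (j in seq_len(ncol(combs))) {
    xx <- rep(0, length(x))
    xx[combs[, j]] <- 1
    if (all(xx == x)) next
    rPerm <- c(rPerm, rsq(xx))
  }
  list(p = sum(rPerm > rObs) / (length(rPerm) + 1), n = length(rPerm),
       rObs = rObs)
}

# balanced synthetic long-format lesion table (every unit observed in all
# four areas at both timepoints, so that all ANOVA types coincide) with
# chosen effects and no subject-level variance
syntheticLongTable <- function(nSubjects = 5, nLesions = 2,
                               areaMeans = c(focal_flair = 0,
                                             initial_peripheral = 0.3,
                                             later_peripheral = 0.6,
                                             nawm = 0.9),
                               timeEffect = 0, sd = 0.1, seed = 1,
                               parameter = "MTsat") {
  set.seed(seed)
  g <- expand.grid(subject_id = sprintf("s%02d", seq_len(nSubjects)),
                   unit = as.character(seq_len(nLesions)),
                   area = names(areaMeans),
                   timepoint = c("T0", "T1"), stringsAsFactors = FALSE)
  g$parameter <- parameter
  g$log_value <- areaMeans[g$area] + timeEffect * (g$timepoint == "T1") +
    stats::rnorm(nrow(g), 0, sd)
  g$median <- exp(g$log_value)
  g
}
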