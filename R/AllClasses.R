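#' @import methods
NULL

.CONTRASTS <- c("MTw", "PDw", "T1w")
.TISSUES <- c("NAWM", "NACGM", "NADGM", "CSF", "lesion")
.PARAMETERS <- c("MTsat", "PD", "R1", "R2star")
.NA_TISSUES <- c("NAWM", "NACGM", "NADGM")
.AREAS <- c("focal_flair", "initial_peripheral", "later_peripheral", "nawm")

.emptyArr <- function() array(numeric(0), dim = c(0L, 0L, 0L))
.emptyLog <- function() array(logical(0), dim = c(0L, 0L, 0L))

#' AcquisitionProtocol: flip angles, repetition and echo times of an MPM run
#'
#' Holds the acquisition parameters of the three multi-echo FLASH series
#' (MT-, PD- and T1-weighted) needed by the map estimators: per-contrast
#' flip angle (degrees at the interface), repetition time (seconds) and a
#' strictly increasing list of echo times (seconds).
#'
#' @slot flipAngles named numeric, degrees, names `MTw`, `PDw`, `T1w`.
#' @slot repetitionTimes named numeric, seconds.
#' @slot echoTimes named list of numeric vectors, seconds, strictly
#'   increasing within each contrast.
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  representation(flipAngles = "numeric", repetitionTimes = "numeric",
                 echoTimes = "list"))

setValidity("AcquisitionProtocol", function(object) {
  msg <- character(0)
  for (slotval in list(object@flipAngles, object@repetitionTimes,
                       object@echoTimes))
    if (!all(.CONTRASTS %in% names(slotval)))
      msg <- c(msg, "slots must be named with MTw, PDw, T1w")
  if (any(object@flipAngles <= 0) || any(object@flipAngles >= 90))
    msg <- c(msg, "flip angles must lie in (0, 90) degrees")
  if (any(object@repetitionTimes <= 0))
    msg <- c(msg, "repetition times must be positive")
  for (ct in .CONTRASTS) {
    te <- object@echoTimes[[ct]]
    if (length(te) < 1L || any(te < 0) || is.unsorted(te, strictly = TRUE))
      msg <- c(msg, sprintf("%s echo times must be >= 0, strictly increasing",
                            ct))
  }
  if (length(msg)) msg else TRUE
})

#' MultiEchoSeries: one 4D multi-echo FLASH acquisition
#'
#' @slot contrast one of `MTw`, `PDw`, `T1w`.
#' @slot data 4D array (x, y, z, echo) of non-negative intensities.
#' @slot echoTimes numeric vector of echo times (s), one per 4th-dim slice.
#' @exportClass MultiEchoSeries
setClass("MultiEchoSeries",
  representation(contrast = "character", data = "array",
                 echoTimes = "numeric"))

setValidity("MultiEchoSeries", function(object) {
  msg <- character(0)
  if (!object@contrast %in% .CONTRASTS)
    msg <- c(msg, "contrast must be one of MTw, PDw, T1w")
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, echo)")
  else if (dim(object@data)[4] != length(object@echoTimes))
    msg <- c(msg, "4th dimension must match the number of echo times")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' EstaticsFit: joint R2* decay fit across the three weighted series
#'
#' Result of the log-linear least-squares fit with one R2* slope shared by
#' all contrasts and one TE=0 intercept per contrast.
#'
#' @slot r2star 3D array, s^-1, negative fits clipped to 0.
#' @slot intercepts named list of 3D arrays, extrapolated S(TE=0).
#' @slot valid logical 3D array, FALSE where any input signal was
#'   non-positive.
#' @slot clipped logical 3D array, TRUE where a negative fitted slope was
#'   clipped to 0.
#' @slot rss 3D array, residual sum of squares in the log domain.
#' @exportClass EstaticsFit
setClass("EstaticsFit",
  representation(r2star = "array", intercepts = "list", valid = "array",
                 clipped = "array", rss = "array"))

#' ParameterMaps: voxelwise MTsat, PD, R1, R2* and amplitude maps
#'
#' MTsat and PD are in percent units at the interface, R1 and R2* in s^-1;
#' the amplitude A is in arbitrary signal units, proportional to proton
#' density. Slots may be empty (0 x 0 x 0) when a quantity has not been
#' computed yet (e.g. PD before calibration).
#'
#' @slot mtsat,pd,r1,r2star,amplitude 3D arrays on one grid.
#' @slot voxelSize numeric length-3, mm.
#' @slot valid logical 3D array marking voxels where estimation succeeded.
#' @exportClass ParameterMaps
setClass("ParameterMaps",
  representation(mtsat = "array", pd = "array", r1 = "array",
                 r2star = "array", amplitude = "array",
                 voxelSize = "numeric", valid = "array"))

setValidity("ParameterMaps", function(object) {
  dims <- lapply(list(object@mtsat, object@pd, object@r1, object@r2star,
                      object@amplitude, object@valid), dim)
  dims <- Filter(function(d) !identical(d, c(0L, 0L, 0L)), dims)
  if (length(dims) == 0L) return("at least one map must be non-empty")
  if (length(unique(dims)) > 1L) return("all maps must share one grid")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers (mm)")
  TRUE
})

#' TissuePosteriors: posterior probability volumes per tissue class
#'
#' @slot posteriors named list of 3D arrays (`NAWM`, `NACGM`, `NADGM`,
#'   `CSF`, `lesion`) with values in \[0, 1\] summing to at most 1 per voxel.
#' @slot voxelSize numeric length-3, mm.
#' @exportClass TissuePosteriors
setClass("TissuePosteriors",
  representation(posteriors = "list", voxelSize = "numeric"))

setValidity("TissuePosteriors", function(object) {
  msg <- character(0)
  if (!all(.TISSUES %in% names(object@posteriors)))
    msg <- c(msg, paste("posteriors must contain:",
                        paste(.TISSUES, collapse = ", ")))
  else {
    dims <- unique(lapply(object@posteriors, dim))
    if (length(dims) > 1L) msg <- c(msg, "posteriors must share one grid")
    total <- Reduce(`+`, lapply(object@posteriors[.TISSUES], as.numeric))
    rng <- range(unlist(lapply(object@posteriors, range)))
    if (rng[1] < 0 || rng[2] > 1)
      msg <- c(msg, "posterior values must lie in [0, 1]")
    if (any(total > 1 + 1e-6))
      msg <- c(msg, "per-voxel posterior sum exceeds 1")
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' AreaMasks: the four mutually exclusive lesion-related areas
#'
#' Focal FLAIR lesion, initial peripheral lesion (T0 periphery beyond the
#' FLAIR core), later peripheral lesion (T1 growth beyond the full T0
#' lesion), and NAWM (all white matter voxels in none of the three), plus
#' an integer labelling of lesion components on the union of the three
#' lesion areas.
#'
#' @slot focalFlair,initialPeripheral,laterPeripheral,nawm logical 3D
#'   arrays, pairwise disjoint.
#' @slot lesionLabels integer 3D array, 0 outside lesions.
#' @slot voxelSize numeric length-3, mm.
#' @exportClass AreaMasks
setClass("AreaMasks",
  representation(focalFlair = "array", initialPeripheral = "array",
                 laterPeripheral = "array", nawm = "array",
                 lesionLabels = "array", voxelSize = "numeric"))

setValidity("AreaMasks", function(object) {
  m <- list(object@focalFlair, object@initialPeripheral,
            object@laterPeripheral, object@nawm)
  if (length(unique(lapply(m, dim))) > 1L)
    return("area masks must share one grid")
  overlap <- Reduce(`+`, lapply(m, as.integer))
  if (any(overlap > 1L)) return("area masks must be pairwise disjoint")
  TRUE
})

#' PhantomConfig: parameters of the synthetic two-timepoint cohort
#'
#' See [phantomConfig()] for the meaning and defaults of each slot.
#'
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(gridShape = "integer", voxelSize = "numeric",
                 nSubjects = "integer", nLesions = "integer",
                 lesionRadiusFlair = "numeric", lesionRadiusT0 = "numeric",
                 lesionRadiusT1 = "numeric", tissueTruth = "matrix",
                 peripheralGradient = "numeric", statusEffect = "numeric",
                 atrophyPctYr = "numeric", mapNoiseFrac = "numeric",
                 subjectCv = "numeric", pActivityMid = "numeric",
                 pActivityEnd = "numeric", intervalRangeMonths = "numeric",
                 seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character(0)
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be 3 integers >= 8")
  if (any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be positive")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nLesions < 0L) msg <- c(msg, "nLesions must be >= 0")
  if (object@nLesions > 0L) {
    if (object@lesionRadiusFlair <= 0 || object@lesionRadiusT0 <= 0 ||
        object@lesionRadiusT1 <= 0)
      msg <- c(msg, "lesion radii must be positive when nLesions > 0")
    if (object@lesionRadiusT1 < object@lesionRadiusT0)
      msg <- c(msg, "lesionRadiusT1 must be >= lesionRadiusT0")
    if (object@lesionRadiusFlair > object@lesionRadiusT0)
      msg <- c(msg, "lesionRadiusFlair must be <= lesionRadiusT0")
  }
  if (!all(rownames(object@tissueTruth) == .TISSUES) ||
      !all(colnames(object@tissueTruth) == .PARAMETERS))
    msg <- c(msg, "tissueTruth must be a 5 x 4 matrix (tissues x parameters)")
  else if (any(object@tissueTruth <= 0))
    msg <- c(msg, "tissueTruth values must be strictly positive")
  if (object@peripheralGradient < 0 || object@peripheralGradient > 1)
    msg <- c(msg, "peripheralGradient must lie in [0, 1]")
  if (!all(names(object@statusEffect) == .PARAMETERS))
    msg <- c(msg, "statusEffect must be named by the four parameters")
  if (object@mapNoiseFrac < 0 || object@subjectCv < 0)
    msg <- c(msg, "noise levels must be non-negative")
  for (p in c(object@pActivityMid, object@pActivityEnd))
    if (p < 0 || p > 1) msg <- c(msg, "activity probabilities must be in [0, 1]")
  if (length(object@intervalRangeMonths) != 2L ||
      any(object@intervalRangeMonths <= 0) ||
      diff(object@intervalRangeMonths) < 0)
    msg <- c(msg, "intervalRangeMonths must be a positive increasing pair")
  if (length(msg)) msg else TRUE
})

#' PhantomCohort: a synthetic two-timepoint cohort with known ground truth
#'
#' @slot subjects list, one element per subject, each holding per-timepoint
#'   tissue posteriors, focal FLAIR mask, full lesion mask and ground-truth
#'   [ParameterMaps-class], plus the subject's status label and interval.
#' @slot clinical data.frame with the generated clinical records and the
#'   derived disease-activity status.
#' @slot config the [PhantomConfig-class] that generated the cohort.
#' @exportClass PhantomCohort
setClass("PhantomCohort",
  representation(subjects = "list", clinical = "data.frame",
                 config = "PhantomConfig"))

#' ArocRegression: OLS fit of an annual rate of change on disease status
#'
#' @slot beta0,beta1 intercept and status effect of Y = b0 + b1 X + e.
#' @slot residuals numeric residual vector.
#' @slot r2 observed coefficient of determination.
#' @slot n number of observations.
#' @exportClass ArocRegression
setClass("ArocRegression",
  representation(beta0 = "numeric", beta1 = "numeric",
                 residuals = "numeric", r2 = "numeric", n = "integer"))

#' PermutationResult: permutation inference on a status regression
#'
#' @slot n number of permutations used.
#' @slot rPerm permuted R^2 values.
#' @slot rObs observed R^2.
#' @slot p permutation p value, #(Rpi > Robs) / (n + 1).
#' @slot seed seed used in sampling mode (NA in exhaustive mode).
#' @slot mode "sample" or "exhaustive".
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(n = "integer", rPerm = "numeric", rObs = "numeric",
                 p = "numeric", seed = "integer", mode = "character"))

setValidity("PermutationResult", function(object) {
  if (object@p < 0 || object@p > object@n / (object@n + 1))
    return("p must lie in [0, n/(n+1)]")
  TRUE
})

#' MixedModelFit: area-by-time mixed model on log lesion medians
#'
#' @slot model the underlying `lmerModLmerTest` fit.
#' @slot anova data.frame of type-III F tests (area, time, area:time).
#' @slot dfMethod "Kenward-Roger" or "Satterthwaite" (which denominator-df
#'   approximation was actually used).
#' @slot parameter which qMRI parameter was modelled.
#' @slot singular logical, TRUE if a variance component collapsed to zero.
#' @exportClass MixedModelFit
setClass("MixedModelFit",
  representation(model = "ANY", anova = "data.frame", dfMethod = "character",
                 parameter = "character", singular = "logical"))
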