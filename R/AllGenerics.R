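# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname ParameterMaps-class
#' @param object,x an object.
#' @param ... unused.
#' @export
setGeneric("mtsat", function(x, ...) standardGeneric("mtsat"))
#' @rdname ParameterMaps-class
#' @export
setGeneric("pdMap", function(x, ...) standardGeneric("pdMap"))
#' @rdname ParameterMaps-class
#' @export
setGeneric("r1Map", function(x, ...) standardGeneric("r1Map"))
#' @rdname ParameterMaps-class
#' @export
setGeneric("r2starMap", function(x, ...) standardGeneric("r2starMap"))
#' @rdname ParameterMaps-class
#' @export
setGeneric("amplitudeMap", function(x, ...) standardGeneric("amplitudeMap"))
#' @rdname ParameterMaps-class
#' @export
setGeneric("validMask", function(x, ...) standardGeneric("validMask"))
#' @rdname ParameterMaps-class
#' @export
setGeneric("voxelSize", function(x, ...) standardGeneric("voxelSize"))

#' @rdname AcquisitionProtocol-class
#' @param x an object.
#' @param ... unused.
#' @export
setGeneric("flipAngles", function(x, ...) standardGeneric("flipAngles"))
#' @rdname AcquisitionProtocol-class
#' @export
setGeneric("repetitionTimes",
           function(x, ...) standardGeneric("repetitionTimes"))
#' @rdname AcquisitionProtocol-class
#' @export
setGeneric("echoTimes", function(x, ...) standardGeneric("echoTimes"))

#' @rdname TissuePosteriors-class
#' @param x an object.
#' @param ... unused.
#' @export
setGeneric("posteriors", function(x, ...) standardGeneric("posteriors"))

#' @rdname AreaMasks-class
#' @param x an object.
#' @param which area name; one of `focal_flair`, `initial_peripheral`,
#'   `later_peripheral`, `nawm`.
#' @param ... unused.
#' @export
setGeneric("areaMask", function(x, which, ...) standardGeneric("areaMask"))
#' @rdname AreaMasks-class
#' @export
setGeneric("lesionLabels", function(x, ...) standardGeneric("lesionLabels"))

setMethod("mtsat", "ParameterMaps", function(x, ...) x@mtsat)
setMethod("pdMap", "ParameterMaps", function(x, ...) x@pd)
setMethod("r1Map", "ParameterMaps", function(x, ...) x@r1)
setMethod("r2starMap", "ParameterMaps", function(x, ...) x@r2star)
setMethod("amplitudeMap", "ParameterMaps", function(x, ...) x@amplitude)
setMethod("validMask", "ParameterMaps", function(x, ...) x@valid)
setMethod("voxelSize", "ParameterMaps", function(x, ...) x@voxelSize)
setMethod("voxelSize", "TissuePosteriors", function(x, ...) x@voxelSize)
setMethod("voxelSize", "AreaMasks", function(x, ...) x@voxelSize)

setMethod("flipAngles", "AcquisitionProtocol", function(x, ...) x@flipAngles)
setMethod("repetitionTimes", "AcquisitionProtocol",
          function(x, ...) x@repetitionTimes)
setMethod("echoTimes", "AcquisitionProtocol", function(x, ...) x@echoTimes)
setMethod("echoTimes", "MultiEchoSeries", function(x, ...) x@echoTimes)

setMethod("posteriors", "TissuePosteriors", function(x, ...) x@posteriors)

setMethod("areaMask", "AreaMasks", function(x, which, ...) {
  slotname <- switch(match.arg(which, .AREAS),
                     focal_flair = "focalFlair",
                     initial_peripheral = "initialPeripheral",
                     later_peripheral = "laterPeripheral",
                     nawm = "nawm")
  slot(x, slotname)
})
setMethod("lesionLabels", "AreaMasks", function(x, ...) x@lesionLabels)

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol\n")
  for (ct in .CONTRASTS)
    cat(sprintf("  %s: flip %g deg, TR %g ms, %d echoes (%g-%g ms)\n", ct,
                object@flipAngles[ct], 1000 * object@repetitionTimes[ct],
                length(object@echoTimes[[ct]]),
                1000 * min(object@echoTimes[[ct]]),
                1000 * max(object@echoTimes[[ct]])))
})

setMethod("show", "ParameterMaps", function(object) {
  d <- .mapsDim(object)
  cat(sprintf("ParameterMaps on a %s grid (%s mm voxels)\n",
              paste(d, collapse = " x "),
              paste(object@voxelSize, collapse = " x ")))
  avail <- c(MTsat = length(object@mtsat) > 0, PD = length(object@pd) > 0,
             R1 = length(object@r1) > 0, R2star = length(object@r2star) > 0,
             A = length(object@amplitude) > 0)
  cat("  maps:", paste(names(avail)[avail], collapse = ", "), "\n")
  if (length(object@valid))
    cat(sprintf("  valid voxels: %d / %d\n", sum(object@valid),
                length(object@valid)))
})

setMethod("show", "MultiEchoSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultiEchoSeries (%s): %s grid, %d echoes\n", object@contrast,
              paste(d[1:3], collapse = " x "), d[4]))
})

setMethod("show", "TissuePosteriors", function(object) {
  cat(sprintf("TissuePosteriors on a %s grid: %s\n",
              paste(dim(object@posteriors[[1]]), collapse = " x "),
              paste(names(object@posteriors), collapse = ", ")))
})

setMethod("show", "AreaMasks", function(object) {
  cat("AreaMasks (voxel counts):\n")
  cat(sprintf("  focal FLAIR %d | initial peripheral %d | later peripheral %d | NAWM %d\n",
              sum(object@focalFlair), sum(object@initialPeripheral),
              sum(object@laterPeripheral), sum(object@nawm)))
  cat(sprintf("  %d labelled lesion component(s)\n",
              length(setdiff(unique(as.integer(object@lesionLabels)), 0L))))
})

setMethod("show", "PhantomCohort", function(object) {
  cfg <- object@config
  cat(sprintf("PhantomCohort: %d subjects, grid %s, %d lesion(s)/subject\n",
              cfg@nSubjects, paste(cfg@gridShape, collapse = " x "),
              cfg@nLesions))
  cat(sprintf("  disease-activity status: %d stable/improving, %d active\n",
              sum(object@clinical$status == 1),
              sum(object@clinical$status == 0)))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult (%s): n = %d, R2_obs = %.4f, p = %.4g\n",
              object@mode, object@n, object@rObs, object@p))
})

setMethod("show", "MixedModelFit", function(object) {
  cat(sprintf("MixedModelFit for %s (df: %s%s)\n", object@parameter,
              object@dfMethod,
              if (object@singular) "; singular variance component" else ""))
  print(object@anova)
})

.mapsDim <- function(maps) {
  for (s in list(maps@mtsat, maps@pd, maps@r1, maps@r2star, maps@amplitude,
                 maps@valid))
    if (length(s)) return(dim(s))
  c(0L, 0L, 0L)
}
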