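#' Construct an acquisition protocol
#'
#' Describes the three multi-echo FLASH series of a multiparameter-mapping
#' (MPM) session. Defaults mimic a standard 3T MPM protocol: 6 echoes at
#' 2.3 ms spacing, 25 ms repetition time, flip angles 6 (MTw), 6 (PDw) and
#' 21 (T1w) degrees.
#'
#' @param flipAngles named numeric vector of flip angles in degrees
#'   (`MTw`, `PDw`, `T1w`).
#' @param repetitionTimes named numeric vector of repetition times in
#'   seconds.
#' @param echoTimes named list of echo-time vectors in seconds, strictly
#'   increasing within each contrast.
#' @return An [AcquisitionProtocol-class] object.
#' @examples
#' acquisitionProtocol()
#' @export
acquisitionProtocol <- function(
    flipAngles = c(MTw = 6, PDw = 6, T1w = 21),
    repetitionTimes = c(MTw = 0.025, PDw = 0.025, T1w = 0.025),
    echoTimes = list(MTw = seq(0.0023, by = 0.0023, length.out = 6),
                     PDw = seq(0.0023, by = 0.0023, length.out = 6),
                     T1w = seq(0.0023, by = 0.0023, length.out = 6))) {
  new("AcquisitionProtocol",
      flipAngles = flipAngles[.CONTRASTS],
      repetitionTimes = repetitionTimes[.CONTRASTS],
      echoTimes = echoTimes[.CONTRASTS])
}

#' Construct a multi-echo series
#'
#' @param contrast one of `"MTw"`, `"PDw"`, `"T1w"`.
#' @param data 4D array (x, y, z, echo).
#' @param echoTimes echo times in seconds, one per echo.
#' @return A [MultiEchoSeries-class] object.
#' @export
multiEchoSeries <- function(contrast, data, echoTimes) {
  new("MultiEchoSeries", contrast = contrast, data = data,
      echoTimes = as.numeric(echoTimes))
}

#' Construct a set of parameter maps
#'
#' @param mtsat,pd,r1,r2star,amplitude 3D arrays on one grid; omit (NULL)
#'   any quantity not available. MTsat and PD in percent units, R1 and R2*
#'   in s^-1.
#' @param voxelSize voxel edge lengths in mm.
#' @param valid logical array of voxels with trustworthy values; defaults
#'   to all TRUE.
#' @return A [ParameterMaps-class] object.
#' @export
parameterMaps <- function(mtsat = NULL, pd = NULL, r1 = NULL, r2star = NULL,
                          amplitude = NULL, voxelSize = c(1, 1, 1),
                          valid = NULL) {
  take <- function(x) if (is.null(x)) .emptyArr() else x
  if (is.null(valid)) {
    d <- NULL
    for (x in list(mtsat, pd, r1, r2star, amplitude))
      if (!is.null(x)) { d <- dim(x); break }
    valid <- array(TRUE, dim = d)
  }
  new("ParameterMaps", mtsat = take(mtsat), pd = take(pd), r1 = take(r1),
      r2star = take(r2star), amplitude = take(amplitude),
      voxelSize = as.numeric(voxelSize), valid = valid)
}

#' Construct tissue posterior probability volumes
#'
#' @param posteriors named list of 3D arrays with probabilities for
#'   `NAWM`, `NACGM`, `NADGM`, `CSF` and `lesion`.
#' @param voxelSize voxel edge lengths in mm.
#' @return A [TissuePosteriors-class] object.
#' @export
tissuePosteriors <- function(posteriors, voxelSize = c(1, 1, 1)) {
  new("TissuePosteriors",
      posteriors = lapply(posteriors[.TISSUES], function(x) x + 0),
      voxelSize = as.numeric(voxelSize))
}

# extract a named parameter map, mapping field names to slots
.getParam <- function(maps, parameter) {
  switch(parameter,
         MTsat = maps@mtsat, PD = maps@pd, R1 = maps@r1,
         R2star = maps@r2star, A = maps@amplitude,
         stop("unknown parameter: ", parameter))
}
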