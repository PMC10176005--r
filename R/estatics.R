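#' Joint R2* estimation across multi-echo series (ESTATICS-style fit)
#'
#' Fits, per voxel, ordinary least squares on the log signal
#' \eqn{\ln S_c(TE) = \ln S_c(0) - TE \cdot R2^*} with the decay slope
#' shared across all supplied contrasts and one TE=0 intercept per
#' contrast. Extrapolation to TE=0 removes the R2* weighting from the
#' per-contrast intercepts, which feed the R1/A/MTsat closed forms.
#'
#' Voxels with any non-positive signal in any echo are flagged invalid
#' (not an error). Negative fitted slopes (possible under noise) are
#' clipped to 0 and flagged in `clipped`.
#'
#' @param series list of 1 to 3 [MultiEchoSeries-class] objects on one
#'   grid, at most one per contrast.
#' @param weighted if TRUE, per-voxel weighted least squares with weights
#'   proportional to the squared signal (first-order variance
#'   stabilization of the log transform); default unweighted.
#' @return An [EstaticsFit-class] object.
#' @examples
#' s <- multiEchoSeries("PDw", array(c(100, 81.873), c(1, 1, 1, 2)),
#'                      c(0.002, 0.010))
#' fit <- fitEstatics(list(s))
#' fit@r2star  # 25 s^-1
#' @export
fitEstatics <- function(series, weighted = FALSE) {
  stopifnot(length(series) >= 1L, length(series) <= 3L)
  cts <- vapply(series, function(s) s@contrast, character(1))
  if (anyDuplicated(cts)) stop("duplicate contrasts in series list")
  dims <- lapply(series, function(s) dim(s@data)[1:3])
  if (length(unique(dims)) > 1L) stop("series grids do not match")
  d <- dims[[1]]
  nvox <- prod(d)

  te <- unlist(lapply(series, function(s) s@echoTimes))
  cidx <- rep(seq_along(series), vapply(series, function(s)
    length(s@echoTimes), integer(1)))
  nobs <- length(te)
  npar <- length(series) + 1L
  if (nobs < npar)
    stop("need at least ", npar, " echoes in total for identifiability")

  X <- matrix(0, nobs, npar)
  X[cbind(seq_len(nobs), cidx)] <- 1
  X[, npar] <- -te

  Y <- matrix(0, nobs, nvox)
  for (i in seq_along(series))
    Y[cidx == i, ] <- matrix(aperm(series[[i]]@data, c(4, 1, 2, 3)),
                             nrow = sum(cidx == i))
  valid <- colSums(Y <= 0) == 0L

  logY <- log(pmax(Y, .Machine$double.xmin))
  if (!weighted) {
    beta <- solve(crossprod(X), crossprod(X, logY))
    resid <- logY - X %*% beta
    rssv <- colSums(resid^2)
  } else {
    beta <- matrix(NA_real_, npar, nvox)
    rssv <- rep(NA_real_, nvox)
    for (v in which(valid)) {
      w <- Y[, v]^2
      fitv <- stats::lm.wfit(X, logY[, v], w)
      beta[, v] <- fitv$coefficients
      rssv[v] <- sum(fitv$residuals^2 * w) / mean(w)
    }
  }
  slope <- beta[npar, ]
  clipped <- valid & !is.na(slope) & slope < 0
  slope[clipped] <- 0
  slope[!valid] <- NA_real_

  intercepts <- list()
  for (i in seq_along(series)) {
    s0 <- exp(beta[i, ])
    s0[!valid] <- NA_real_
    intercepts[[cts[i]]] <- array(s0, dim = d)
  }
  rssv[!valid] <- NA_real_
  new("EstaticsFit",
      r2star = array(slope, dim = d),
      intercepts = intercepts,
      valid = array(valid, dim = d),
      clipped = array(clipped, dim = d),
      rss = array(rssv, dim = d))
}

#' Closed-form R1 and amplitude from the T1w and PDw TE=0 intercepts
#'
#' Solves the pair of small-flip-angle (rational) approximations of the
#' FLASH signal,
#' \eqn{S_c \approx A \alpha_c \frac{TR_c R1}{\alpha_c^2/2 + TR_c R1}},
#' for the amplitude A and longitudinal relaxation rate R1. The two
#' contrasts must differ in flip angle and/or repetition time. Voxels with
#' non-positive intercepts or without a positive (A, R1) solution are
#' flagged invalid.
#'
#' @param sT1w0,sPDw0 3D arrays of TE=0 intercepts for the T1w and PDw
#'   contrasts (from [fitEstatics()]).
#' @param protocol an [AcquisitionProtocol-class].
#' @return List with 3D arrays `r1` (s^-1), `amplitude`, and logical
#'   `valid`.
#' @export
computeR1Amplitude <- function(sT1w0, sPDw0, protocol) {
  if (!identical(dim(sT1w0), dim(sPDw0)))
    stop("intercept grids do not match")
  a1 <- unname(protocol@flipAngles["T1w"]) * pi / 180
  a2 <- unname(protocol@flipAngles["PDw"]) * pi / 180
  tr1 <- unname(protocol@repetitionTimes["T1w"])
  tr2 <- unname(protocol@repetitionTimes["PDw"])
  if (isTRUE(all.equal(a1, a2)) && isTRUE(all.equal(tr1, tr2)))
    stop("degenerate protocol: T1w and PDw have identical flip angle and TR")

  u1 <- sT1w0 / a1
  u2 <- sPDw0 / a2
  A <- u1 * u2 * (a1^2 * tr2 - a2^2 * tr1) /
       (u1 * a1^2 * tr2 - u2 * a2^2 * tr1)
  r1 <- u1 * a1^2 / (2 * tr1 * (A - u1))

  valid <- is.finite(sT1w0) & is.finite(sPDw0) & sT1w0 > 0 & sPDw0 > 0 &
           is.finite(A) & is.finite(r1) & A > u1 & A > u2 & r1 > 0
  A[!valid] <- NA_real_
  r1[!valid] <- NA_real_
  list(r1 = r1, amplitude = A, valid = valid)
}

#' MT saturation from the MTw TE=0 intercept
#'
#' Computes the per-excitation fractional saturation of the longitudinal
#' magnetization due to the MT prepulse,
#' \deqn{\delta = \left(\frac{A\,\alpha_{MT}}{S_{MT}(0)} - 1\right) R1\,
#'   TR_{MT} - \frac{\alpha_{MT}^2}{2},}
#' returned in percent units (100 x the fraction). MTsat is, by
#' construction, minimally sensitive to T1 and B1 compared with the MT
#' ratio.
#'
#' @param sMTw0 3D array of MTw TE=0 intercepts.
#' @param amplitude,r1 3D arrays from [computeR1Amplitude()].
#' @param protocol an [AcquisitionProtocol-class].
#' @return List with the 3D array `mtsat` (percent units) and logical
#'   `valid`.
#' @export
computeMTsat <- function(sMTw0, amplitude, r1, protocol) {
  a <- protocol@flipAngles["MTw"] * pi / 180
  tr <- protocol@repetitionTimes["MTw"]
  valid <- is.finite(sMTw0) & sMTw0 > 0 & is.finite(amplitude) &
           is.finite(r1)
  delta <- (amplitude * a / sMTw0 - 1) * r1 * tr - a^2 / 2
  delta[!valid] <- NA_real_
  list(mtsat = 100 * delta, valid = valid)
}

#' Calibrate the amplitude map to percent-unit proton density
#'
#' The FLASH amplitude A is proportional to proton density; a single
#' global factor rescales it so that the median over a reference mask
#' (conventionally NAWM) equals a target percent-unit value. Ratios
#' between voxels are untouched.
#'
#' @param amplitude 3D amplitude array.
#' @param referenceMask logical 3D array, non-empty.
#' @param targetPu target median in percent units within the mask;
#'   default 69 (a conventional NAWM water content).
#' @return 3D PD array in percent units.
#' @export
calibratePD <- function(amplitude, referenceMask, targetPu = 69) {
  if (!any(referenceMask)) stop("reference mask is empty")
  med <- stats::median(amplitude[referenceMask], na.rm = TRUE)
  if (!is.finite(med) || med == 0)
    stop("median amplitude over the reference mask is zero or undefined")
  amplitude * (targetPu / med)
}

#' Estimate MTsat, PD, R1 and R2* maps from three multi-echo series
#'
#' Runs the full map-estimation chain: joint R2* fit with TE=0
#' extrapolation ([fitEstatics()]), closed-form R1 and amplitude from the
#' T1w/PDw intercepts ([computeR1Amplitude()]), MT saturation from the MTw
#' intercept ([computeMTsat()]), and optional PD calibration
#' ([calibratePD()]). Nominal flip angles are assumed (no transmit-field
#' correction).
#'
#' @param series named list of three [MultiEchoSeries-class] objects
#'   (`MTw`, `PDw`, `T1w`).
#' @param protocol an [AcquisitionProtocol-class].
#' @param voxelSize voxel edge lengths in mm.
#' @param referenceMask optional logical array; if supplied, PD is
#'   calibrated to `targetPu` median within it.
#' @param targetPu PD calibration target, percent units.
#' @param weighted passed to [fitEstatics()].
#' @return A [ParameterMaps-class] object (PD empty if no reference mask).
#' @export
estimateParameterMaps <- function(series, protocol, voxelSize = c(1, 1, 1),
                                  referenceMask = NULL, targetPu = 69,
                                  weighted = FALSE) {
  for (ct in .CONTRASTS)
    if (!ct %in% names(series)) stop("series list must contain ", ct)
  fit <- fitEstatics(series[.CONTRASTS], weighted = weighted)
  ra <- computeR1Amplitude(fit@intercepts[["T1w"]], fit@intercepts[["PDw"]],
                           protocol)
  mt <- computeMTsat(fit@intercepts[["MTw"]], ra$amplitude, ra$r1, protocol)
  valid <- fit@valid & ra$valid & mt$valid
  pd <- if (!is.null(referenceMask))
    calibratePD(ra$amplitude, referenceMask & valid, targetPu)
  parameterMaps(mtsat = mt$mtsat, pd = pd, r1 = ra$r1, r2star = fit@r2star,
                amplitude = ra$amplitude, voxelSize = voxelSize,
                valid = valid)
}
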