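#' Steady-state spoiled gradient-echo (FLASH) signal
#'
#' Evaluates the exact steady-state FLASH signal
#' \deqn{S(TE) = A \sin\alpha \frac{1 - e^{-TR \cdot R1}}{1 - \cos\alpha\,
#'   e^{-TR \cdot R1}} e^{-TE \cdot R2^*}.}
#'
#' @param A signal amplitude (arbitrary units, proportional to proton
#'   density).
#' @param r1 longitudinal relaxation rate, s^-1.
#' @param r2star effective transverse relaxation rate, s^-1.
#' @param alphaDeg flip angle in degrees.
#' @param tr repetition time, s.
#' @param te echo time(s), s.
#' @return Signal value(s); vectorized over all arguments.
#' @examples
#' flashSignal(1000, r1 = 1, r2star = 0, alphaDeg = 6, tr = 0.025, te = 0)
#' @export
flashSignal <- function(A, r1, r2star, alphaDeg, tr, te) {
  a <- alphaDeg * pi / 180
  e1 <- exp(-tr * r1)
  A * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te * r2star)
}

# TE=0 MT-weighted signal consistent with the MTsat definition: chosen so
# that delta = (A*alpha/S - 1) * R1 * TR - alpha^2/2 holds exactly for the
# true A, R1 and delta (delta as a fraction, not percent).
.mtwSignal0 <- function(A, r1, deltaFrac, alphaDeg, tr) {
  a <- alphaDeg * pi / 180
  A * a / (1 + (deltaFrac + a^2 / 2) / (r1 * tr))
}

#' Simulate the three multi-echo FLASH series from ground-truth maps
#'
#' Forward-simulates MTw, PDw and T1w multi-echo series from true A, R1,
#' R2* and MTsat maps. PDw and T1w follow the exact steady-state FLASH
#' signal; the MTw series is attenuated such that the MT saturation
#' estimator recovers the true MTsat exactly when fed the true A and R1.
#' Optive additive Gaussian noise is drawn per voxel and echo.
#'
#' @param truth a [ParameterMaps-class] object with non-empty `amplitude`,
#'   `r1`, `r2star` and `mtsat` maps (MTsat in percent units).
#' @param protocol an [AcquisitionProtocol-class].
#' @param noiseSd standard deviation of additive zero-mean Gaussian noise,
#'   in signal units; 0 gives the exact forward model.
#' @param seed integer seed for the noise draw.
#' @param rician if TRUE, apply Rician (magnitude) noise instead: the
#'   modulus of the complex signal with independent Gaussian noise of sd
#'   `noiseSd` on both channels.
#' @return Named list of three [MultiEchoSeries-class] objects
#'   (`MTw`, `PDw`, `T1w`).
#' @export
simulateFlashSeries <- function(truth, protocol, noiseSd = 0, seed = 1L,
                                rician = FALSE) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  stopifnot(is(truth, "ParameterMaps"), is(protocol, "AcquisitionProtocol"))
  for (s in c("amplitude", "r1", "r2star", "mtsat"))
    if (!length(slot(truth, s)))
      stop("truth maps must include ", s)
  d <- dim(truth@r1)
  set.seed(seed)
  out <- list()
  for (ct in .CONTRASTS) {
    te <- protocol@echoTimes[[ct]]
    if (length(te) == 0L) stop("empty echo-time list for ", ct)
    alpha <- protocol@flipAngles[ct]
    tr <- protocol@repetitionTimes[ct]
    s0 <- if (ct == "MTw") {
      .mtwSignal0(truth@amplitude, truth@r1, truth@mtsat / 100, alpha, tr)
    } else {
      flashSignal(truth@amplitude, truth@r1, 0, alpha, tr, 0)
    }
    arr <- array(0, dim = c(d, length(te)))
    for (k in seq_along(te)) {
      sig <- s0 * exp(-te[k] * truth@r2star)
      if (noiseSd > 0) {
        if (rician) {
          sig <- sqrt((sig + stats::rnorm(length(sig), 0, noiseSd))^2 +
                      stats::rnorm(length(sig), 0, noiseSd)^2)
        } else {
          sig <- sig + stats::rnorm(length(sig), 0, noiseSd)
        }
      }
      arr[, , , k] <- sig
    }
    out[[ct]] <- multiEchoSeries(ct, arr, te)
  }
  out
}
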