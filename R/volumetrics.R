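#' Brain volume fractions from exclusive tissue masks
#'
#' Computes total intracranial volume and the standard fractions by exact
#' voxel-count arithmetic:
#' TIV = volume(NAWM + GM + CSF + lesions),
#' BPF = volume(NAWM + GM + lesions) / TIV,
#' GMF = volume(GM) / TIV, LF = volume(lesions) / TIV,
#' where GM = NACGM + NADGM.
#'
#' @param tissueMasks named list of logical arrays with elements `NAWM`,
#'   `NACGM`, `NADGM`, `CSF` (from [binarizeTissues()]), pairwise disjoint
#'   with the lesion mask.
#' @param lesionMask logical array.
#' @param voxelSize voxel edge lengths in mm.
#' @return List with `TIV` (mm^3), `BPF`, `GMF`, `LF`.
#' @examples
#' # 500 NAWM + 600 GM + 300 CSF + 10 lesion voxels at 1 mm^3
#' # gives TIV 1410, BPF 1110/1410, GMF 600/1410, LF 10/1410
#' @export
computeFractions <- function(tissueMasks, lesionMask,
                             voxelSize = c(1, 1, 1)) {
  voxVol <- prod(voxelSize)
  vol <- function(m) sum(m != 0) * voxVol
  vNawm <- vol(tissueMasks$NAWM)
  vGm <- vol(tissueMasks$NACGM) + vol(tissueMasks$NADGM)
  vCsf <- vol(tissueMasks$CSF)
  vLes <- vol(lesionMask)
  tiv <- vNawm + vGm + vCsf + vLes
  if (tiv == 0) stop("total intracranial volume is zero")
  list(TIV = tiv, BPF = (vNawm + vGm + vLes) / tiv, GMF = vGm / tiv,
       LF = vLes / tiv)
}

#' Annualized percentage change
#'
#' Percentage change between two sessions divided by the interscan
#' interval in years: `100 * (v1 - v0) / v0 / (intervalMonths / 12)`.
#'
#' @param v0,v1 values at the first and second session; `v0` must be
#'   positive.
#' @param intervalMonths interscan interval in months, positive.
#' @return Percent per year; vectorized.
#' @examples
#' annualizedPercentChange(1, 0.99, 12)   # -1 %/yr
#' annualizedPercentChange(0.80, 0.78, 30)  # -1 %/yr
#' @export
annualizedPercentChange <- function(v0, v1, intervalMonths) {
  if (any(v0 <= 0)) stop("v0 must be positive")
  if (any(intervalMonths <= 0)) stop("interval must be positive")
  100 * (v1 - v0) / v0 / (intervalMonths / 12)
}

#' One-sample t test against zero
#'
#' Standard two-sided one-sample t test of the mean against 0 with
#' n - 1 degrees of freedom, as applied to annualized volume changes.
#'
#' @param values numeric vector, n >= 2, non-degenerate.
#' @return List with `t`, `df`, `p`.
#' @export
oneSampleTTest <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0)
    stop("zero sample variance: t statistic undefined")
  ht <- stats::t.test(values, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
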