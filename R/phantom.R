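# Synthetic two-timepoint phantom cohort with known ground truth.
#
# Anatomy is nested ellipsoids (CSF > cortical GM ring > WM) with two deep
# GM blobs inside the WM, and spherical WM lesions with concentric
# peripheral shells. No template registration, field inhomogeneity or
# realistic cortical folding is attempted: the phantom reproduces the
# statistical structure the analysis assumes, not brain anatomy.

#' Default ground-truth tissue parameter values
#'
#' Plausible literature-like values for a 3T MPM protocol; configuration
#' data, not empirical claims. MTsat and PD in percent units, R1 and R2*
#' in s^-1.
#'
#' @return 5 x 4 matrix (tissues x parameters).
#' @export
defaultTissueTruth <- function() {
  matrix(c(
    # MTsat,  PD,   R1,   R2star
      1.9,    69,   1.05, 21,    # NAWM
      0.9,    80,   0.62, 15,    # NACGM
      1.2,    75,   0.75, 25,    # NADGM
      0.05,  100,   0.25,  1,    # CSF
      1.0,    85,   0.70, 15     # lesion core
  ), nrow = 5, byrow = TRUE,
  dimnames = list(.TISSUES, .PARAMETERS))
}

#' Configure the synthetic phantom cohort
#'
#' Defaults encode the study conditions the pipeline is meant for: 17
#' subjects scanned twice 14-61 months apart, around 30% of whom show
#' disease activity in both evaluation intervals, mild whole-brain
#' atrophy, enlarging WM lesions with a core-to-NAWM microstructural
#' gradient, and a positive annual drift of NAWM/NACGM MTsat and R2* in
#' stable/improving (status 1) subjects with the reported effect
#' magnitudes.
#'
#' @param gridShape 3 integers, voxels per axis.
#' @param voxelSize mm per axis.
#' @param nSubjects number of subjects.
#' @param nLesions lesions per subject (0 allowed).
#' @param lesionRadiusFlair,lesionRadiusT0,lesionRadiusT1 radii (mm) of
#'   the focal FLAIR core, the full T0 lesion and the full T1 lesion;
#'   `flair <= T0 <= T1`.
#' @param tissueTruth 5 x 4 matrix of ground-truth parameter values, see
#'   [defaultTissueTruth()].
#' @param peripheralGradient fraction g in \[0, 1\]: the initial
#'   peripheral shell sits at g of the way from lesion-core to NAWM
#'   values, the later peripheral shell at (1 + g) / 2.
#' @param statusEffect named additive per-year shift of NAWM and NACGM
#'   truth values applied only to status-1 subjects at T1 (units of each
#'   parameter per year).
#' @param atrophyPctYr annualized parenchymal volume change, percent per
#'   year (negative = atrophy), implemented by shrinking the outer GM
#'   boundary at T1; CSF fills the space so TIV is constant.
#' @param mapNoiseFrac voxelwise sd of observation noise on parameter
#'   maps, as a fraction of the local true value (see
#'   [perturbParameterMaps()]).
#' @param subjectCv between-subject coefficient of variation of tissue
#'   values (one multiplicative factor per subject and parameter,
#'   identical at both timepoints).
#' @param pActivityMid,pActivityEnd probability of disease activity in
#'   the first and second evaluation interval.
#' @param intervalRangeMonths range the interscan interval is drawn from.
#' @param seed master seed of the cohort.
#' @return A validated [PhantomConfig-class] object.
#' @export
phantomConfig <- function(gridShape = c(32L, 32L, 32L),
                          voxelSize = c(1, 1, 1),
                          nSubjects = 17L, nLesions = 3L,
                          lesionRadiusFlair = 1.5, lesionRadiusT0 = 2.2,
                          lesionRadiusT1 = 3,
                          tissueTruth = defaultTissueTruth(),
                          peripheralGradient = 0.4,
                          statusEffect = c(MTsat = 0.039, PD = 0, R1 = 0,
                                           R2star = 0.295),
                          atrophyPctYr = -0.67,
                          mapNoiseFrac = 0.02,
                          subjectCv = 0.05,
                          pActivityMid = 0.55, pActivityEnd = 0.55,
                          intervalRangeMonths = c(14, 61),
                          seed = 1L) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), nSubjects = as.integer(nSubjects),
      nLesions = as.integer(nLesions),
      lesionRadiusFlair = lesionRadiusFlair,
      lesionRadiusT0 = lesionRadiusT0, lesionRadiusT1 = lesionRadiusT1,
      tissueTruth = tissueTruth, peripheralGradient = peripheralGradient,
      statusEffect = statusEffect[.PARAMETERS],
      atrophyPctYr = atrophyPctYr, mapNoiseFrac = mapNoiseFrac,
      subjectCv = subjectCv, pActivityMid = pActivityMid,
      pActivityEnd = pActivityEnd,
      intervalRangeMonths = as.numeric(intervalRangeMonths),
      seed = as.integer(seed))
}

# derive a stage seed from a master seed, staying within 32-bit range
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483629)
}

# mm-space ellipsoid mask: ((x-c)/r)^2 summed over axes <= 1
.ellipsoid <- function(coords, center, radii) {
  dx2 <- ((coords$x - center[1]) / radii[1])^2
  dy2 <- ((coords$y - center[2]) / radii[2])^2
  dz2 <- ((coords$z - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

.sphere <- function(coords, center, radius) {
  .ellipsoid(coords, center, rep(radius, 3))
}

#' Generate a synthetic clinical table
#'
#' Draws per-subject clinical records with the schema of the cohort
#' clinical table: EDSS trajectory, new-lesion and relapse flags at the
#' mid- and end-interval evaluations, and the interscan interval. Each
#' active evaluation realizes exactly one activity mechanism (new lesion,
#' relapse, or a threshold-crossing EDSS progression), so passing the
#' record through [scoreClinicalTable()] reproduces the intended status by
#' construction.
#'
#' @param nSubjects number of records, >= 1.
#' @param seed integer seed.
#' @param pActivityMid,pActivityEnd activity probabilities in \[0, 1\].
#' @param intervalRangeMonths interval range (months), drawn uniformly on
#'   the integers.
#' @return data.frame with the clinical schema plus `status_intended`.
#' @export
generateClinicalTable <- function(nSubjects, seed = 1L,
                                  pActivityMid = 0.55,
                                  pActivityEnd = 0.55,
                                  intervalRangeMonths = c(14, 61)) {
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  for (p in c(pActivityMid, pActivityEnd))
    if (p < 0 || p > 1) stop("activity probabilities must lie in [0, 1]")
  if (any(intervalRangeMonths <= 0)) stop("interval range must be positive")
  set.seed(seed)
  thr <- function(e0) ifelse(e0 <= 4, 1.0, 0.5)
  edss0 <- sample(seq(1, 6.5, by = 0.5), nSubjects, replace = TRUE)
  interval <- sample(seq(intervalRangeMonths[1], intervalRangeMonths[2]),
                     nSubjects, replace = TRUE)
  mech <- c("lesion", "relapse", "progression")
  activeMid <- stats::runif(nSubjects) < pActivityMid
  activeEnd <- stats::runif(nSubjects) < pActivityEnd
  typeMid <- sample(mech, nSubjects, replace = TRUE)
  typeEnd <- sample(mech, nSubjects, replace = TRUE)
  progMid <- activeMid & typeMid == "progression"
  progEnd <- activeEnd & typeEnd == "progression"
  data.frame(
    subject_id = sprintf("sim-%03d", seq_len(nSubjects)),
    edss_t0 = edss0,
    edss_mid = edss0 + ifelse(progMid, thr(edss0), 0),
    edss_t1 = edss0 + ifelse(progEnd, thr(edss0), 0),
    new_lesion_mid = ifelse(activeMid & typeMid == "lesion", "yes", "none"),
    relapse_mid = ifelse(activeMid & typeMid == "relapse", "yes", "none"),
    new_lesion_end = ifelse(activeEnd & typeEnd == "lesion", "yes", "none"),
    relapse_end = ifelse(activeEnd & typeEnd == "relapse", "yes", "none"),
    interval_months = interval,
    status_intended = ifelse(activeMid & activeEnd, 0L, 1L),
    stringsAsFactors = FALSE)
}

#' Generate a two-timepoint phantom cohort with known ground truth
#'
#' Builds, per subject and timepoint, crisp tissue posterior volumes
#' (NAWM, NACGM, NADGM, CSF, lesion), the focal FLAIR lesion mask, the
#' full lesion mask (FLAIR core plus peripheral shell) and noise-free
#' ground-truth parameter maps. Lesions are spheres that grow from the T0
#' to the T1 radius; parameter values inside the peripheral shells
#' interpolate between lesion-core and NAWM truth (see
#' [phantomConfig()]), identically at both timepoints, so that area
#' differences carry no time effect. Status-1 subjects additionally
#' receive the configured per-year additive shift of NAWM and NACGM
#' values at T1. Deterministic for a fixed seed.
#'
#' @param config a [PhantomConfig-class] from [phantomConfig()].
#' @return A [PhantomCohort-class] object.
#' @export
generatePhantom <- function(config) {
  validObject(config)
  gridMm <- config@gridShape * config@voxelSize
  coords <- list(x = (seq_len(config@gridShape[1]) - 0.5) * config@voxelSize[1],
                 y = (seq_len(config@gridShape[2]) - 0.5) * config@voxelSize[2],
                 z = (seq_len(config@gridShape[3]) - 0.5) * config@voxelSize[3])
  center <- gridMm / 2
  half <- gridMm / 2
  rCsf <- 0.92 * half
  rGm <- 0.80 * half
  rWm <- 0.60 * half
  rDgm <- 0.28 * min(rWm)
  dgmCenters <- list(center + c(0.5 * rWm[1], 0, 0),
                     center - c(0.5 * rWm[1], 0, 0))

  clinical <- scoreClinicalTable(generateClinicalTable(
    config@nSubjects, seed = .deriveSeed(config@seed, 1L),
    pActivityMid = config@pActivityMid, pActivityEnd = config@pActivityEnd,
    intervalRangeMonths = config@intervalRangeMonths))
  stopifnot(all(clinical$status == clinical$status_intended))

  truthMat <- config@tissueTruth
  g <- config@peripheralGradient
  fLater <- (1 + g) / 2

  set.seed(.deriveSeed(config@seed, 2L))
  subjects <- vector("list", config@nSubjects)
  margin <- 0.5
  for (s in seq_len(config@nSubjects)) {
    years <- clinical$interval_months[s] / 12
    status <- clinical$status[s]

    # lesion centres: T1 sphere fully inside the WM ellipsoid, away from
    # the deep GM blobs and from each other
    centres <- list()
    if (config@nLesions > 0L) {
      shrink <- rWm - config@lesionRadiusT1 - margin
      if (any(shrink <= 0))
        stop("grid too small to contain lesions inside white matter")
      tries <- 0L
      while (length(centres) < config@nLesions) {
        tries <- tries + 1L
        if (tries > 2000L) stop("lesion placement failed after 2000 retries")
        if (tries %% 100L == 0L) centres <- list()  # restart a stuck layout
        cand <- center + (2 * stats::runif(3) - 1) * shrink
        if (sum(((cand - center) / shrink)^2) > 1) next
        # keep the FLAIR core clear of the deep GM blobs; partial overlap
        # of the outer shells with DGM is tolerated (masks exclude it)
        if (any(vapply(dgmCenters, function(dc)
          sqrt(sum((cand - dc)^2)) <
            config@lesionRadiusFlair + rDgm + margin, logical(1)))) next
        # surfaces at least 2 voxel diagonals apart so distinct lesions
        # never touch under 26-connectivity after rasterization
        if (length(centres) && any(vapply(centres, function(cc)
          sqrt(sum((cand - cc)^2)) < 2 * config@lesionRadiusT1 +
            2 * max(config@voxelSize), logical(1)))) next
        centres[[length(centres) + 1L]] <- cand
      }
    }
    unionSpheres <- function(radius) {
      m <- array(FALSE, dim = config@gridShape)
      for (cc in centres) m <- m | .sphere(coords, cc, radius)
      m
    }
    flair <- unionSpheres(config@lesionRadiusFlair)
    fullT0 <- unionSpheres(config@lesionRadiusT0)
    fullT1 <- unionSpheres(config@lesionRadiusT1)

    subjFac <- exp(stats::rnorm(length(.PARAMETERS), 0, config@subjectCv))
    names(subjFac) <- .PARAMETERS

    makeTimepoint <- function(tp) {
      fAtro <- if (tp == "T1")
        (1 + config@atrophyPctYr / 100 * years)^(1 / 3) else 1
      gmOuter <- .ellipsoid(coords, center, rGm * fAtro)
      csf <- .ellipsoid(coords, center, rCsf) & !gmOuter
      wmAll <- .ellipsoid(coords, center, rWm)
      gmRing <- gmOuter & !wmAll
      dgm <- Reduce(`|`, lapply(dgmCenters, function(dc)
        .sphere(coords, dc, rDgm)))
      lesion <- if (tp == "T0") fullT0 else fullT1
      nawm <- wmAll & !dgm & !lesion
      nadgm <- dgm & !lesion
      post <- tissuePosteriors(
        list(NAWM = nawm, NACGM = gmRing, NADGM = nadgm, CSF = csf,
             lesion = lesion), config@voxelSize)

      maps <- list()
      for (p in .PARAMETERS) {
        arr <- array(0, dim = config@gridShape)
        arr[csf] <- truthMat["CSF", p]
        arr[gmRing] <- truthMat["NACGM", p]
        arr[wmAll] <- truthMat["NAWM", p]
        arr[dgm] <- truthMat["NADGM", p]
        core <- truthMat["lesion", p]
        nawmV <- truthMat["NAWM", p]
        arr[fullT1 & !fullT0] <- core + fLater * (nawmV - core)
        arr[fullT0 & !flair] <- core + g * (nawmV - core)
        arr[flair] <- core
        arr <- arr * subjFac[p]
        if (tp == "T1" && status == 1L && config@statusEffect[p] != 0)
          arr[nawm | gmRing] <- arr[nawm | gmRing] +
            config@statusEffect[p] * years
        maps[[p]] <- arr
      }
      truth <- parameterMaps(mtsat = maps$MTsat, pd = maps$PD,
                             r1 = maps$R1, r2star = maps$R2star,
                             amplitude = maps$PD * 10,
                             voxelSize = config@voxelSize)
      list(posteriors = post, flair = flair, lesion = lesion, truth = truth)
    }
    subjects[[s]] <- list(id = clinical$subject_id[s], status = status,
                          intervalYears = years,
                          T0 = makeTimepoint("T0"), T1 = makeTimepoint("T1"))
  }
  new("PhantomCohort", subjects = subjects, clinical = clinical,
      config = config)
}

#' Add voxelwise observation noise to parameter maps
#'
#' Multiplies every non-empty map by `1 + N(0, frac)` per voxel,
#' emulating map-level measurement noise proportional to the local value.
#'
#' @param maps a [ParameterMaps-class] object.
#' @param frac noise fraction (sd of the relative perturbation).
#' @param seed integer seed.
#' @return A [ParameterMaps-class] object.
#' @export
perturbParameterMaps <- function(maps, frac, seed = 1L) {
  if (frac < 0) stop("frac must be non-negative")
  if (frac == 0) return(maps)
  set.seed(seed)
  for (s in c("mtsat", "pd", "r1", "r2star", "amplitude")) {
    m <- slot(maps, s)
    if (length(m))
      slot(maps, s) <- m * (1 + stats::rnorm(length(m), 0, frac))
  }
  maps
}

#' Write a phantom cohort to NIfTI volumes and a clinical CSV
#'
#' One NIfTI file per subject, timepoint and quantity (tissue posteriors,
#' FLAIR and full lesion masks, ground-truth maps with the `_MTsat`,
#' `_PD`, `_R1`, `_R2s` suffix convention) plus `clinical.csv`.
#'
#' @param cohort a [PhantomCohort-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writePhantom <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- cohort@config@voxelSize
  files <- character(0)
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr + 0)
    RNifti::pixdim(img) <- vox
    RNifti::writeNifti(img, path)
    path
  }
  for (subj in cohort@subjects) {
    for (tp in c("T0", "T1")) {
      el <- subj[[tp]]
      base <- file.path(dir, paste0(subj$id, "_", tp))
      for (ts in .TISSUES)
        files <- c(files, wr(el$posteriors@posteriors[[ts]],
                             paste0(base, "_posterior-", ts, ".nii.gz")))
      files <- c(files, wr(el$flair, paste0(base, "_mask-flair.nii.gz")),
                 wr(el$lesion, paste0(base, "_mask-lesion.nii.gz")))
      sfx <- c(MTsat = "_MTsat", PD = "_PD", R1 = "_R1", R2star = "_R2s")
      for (p in .PARAMETERS)
        files <- c(files, wr(.getParam(el$truth, p),
                             paste0(base, sfx[p], ".nii.gz")))
    }
  }
  clin <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort@clinical, clin, row.names = FALSE)
  invisible(c(files, clin))
}
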