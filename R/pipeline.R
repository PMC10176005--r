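# End-to-end orchestration: simulate -> fit maps -> segment areas ->
# volumetrics -> status -> normal-appearing-tissue inference -> lesion
# model, with a JSON manifest and deterministic seeding (all stage seeds
# derive from one master seed).

.MAP_SUFFIX <- c(MTsat = "_MTsat", PD = "_PD", R1 = "_R1", R2star = "_R2s",
                 A = "_A")

#' Write parameter maps as NIfTI volumes
#'
#' One file per available map, using the `_MTsat`, `_PD`, `_R1`, `_R2s`
#' (and `_A`) filename suffix convention.
#'
#' @param maps a [ParameterMaps-class].
#' @param prefix path prefix; files are `<prefix><suffix>.nii.gz`.
#' @return Invisibly, the files written.
#' @export
writeParameterMaps <- function(maps, prefix) {
  slots <- c(MTsat = "mtsat", PD = "pd", R1 = "r1", R2star = "r2star",
             A = "amplitude")
  files <- character(0)
  for (p in names(slots)) {
    arr <- slot(maps, slots[p])
    if (!length(arr)) next
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- maps@voxelSize
    f <- paste0(prefix, .MAP_SUFFIX[p], ".nii.gz")
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read parameter maps from NIfTI volumes
#'
#' @param prefix path prefix as used by [writeParameterMaps()]; missing
#'   quantities are left empty.
#' @return A [ParameterMaps-class].
#' @export
readParameterMaps <- function(prefix) {
  rd <- function(p) {
    f <- paste0(prefix, .MAP_SUFFIX[p], ".nii.gz")
    if (!file.exists(f)) return(NULL)
    img <- RNifti::readNifti(f)
    structure(array(as.numeric(img), dim = dim(img)),
              pixdim = RNifti::pixdim(img))
  }
  arrs <- lapply(c("MTsat", "PD", "R1", "R2star", "A"), rd)
  names(arrs) <- c("MTsat", "PD", "R1", "R2star", "A")
  vox <- c(1, 1, 1)
  for (a in arrs) if (!is.null(a)) { vox <- attr(a, "pixdim"); break }
  strip <- function(a) { attr(a, "pixdim") <- NULL; a }
  arrs <- lapply(arrs, function(a) if (is.null(a)) NULL else strip(a))
  parameterMaps(mtsat = arrs$MTsat, pd = arrs$PD, r1 = arrs$R1,
                r2star = arrs$R2star, amplitude = arrs$A,
                voxelSize = as.numeric(vox[seq_len(3)]))
}

# observed maps for one subject/timepoint under either map source; for
# flash mode PD is left uncalibrated here and scaled per subject with a
# single factor from the T0 session (see .calibrateSubject), so that the
# calibration does not erase longitudinal PD change within the reference
# tissue
.observeMaps <- function(subjTp, config, protocol, mapSource, flashNoiseSd,
                         seed) {
  if (mapSource == "truth")
    return(perturbParameterMaps(subjTp$truth, config@mapNoiseFrac, seed))
  series <- simulateFlashSeries(subjTp$truth, protocol,
                                noiseSd = flashNoiseSd, seed = seed)
  estimateParameterMaps(series, protocol, voxelSize = config@voxelSize)
}

# one PD calibration factor per subject, anchored at the T0 NAWM median
.calibrateSubject <- function(obsT0, obsT1, nawmT0, targetPu = 69) {
  ref <- nawmT0 & obsT0@valid
  med <- stats::median(obsT0@amplitude[ref], na.rm = TRUE)
  obsT0@pd <- obsT0@amplitude * (targetPu / med)
  obsT1@pd <- obsT1@amplitude * (targetPu / med)
  list(T0 = obsT0, T1 = obsT1)
}

#' Run the full longitudinal pipeline on a simulated cohort
#'
#' Orchestrates the seven analysis stages on a phantom cohort and writes
#' their tabular outputs and a JSON manifest (seed, configuration,
#' stage outputs with md5 checksums, package version) to `outDir`.
#' Deterministic stages are bit-identical across reruns with the same
#' configuration and seed.
#'
#' @param outDir output directory.
#' @param config a [PhantomConfig-class]; its seed is replaced by `seed`.
#' @param protocol an [AcquisitionProtocol-class] (used when
#'   `mapSource = "flash"`).
#' @param seed master seed; every stage derives its own.
#' @param nPerm permutations per status test (default 5000).
#' @param q FDR level (default 0.05).
#' @param arocMode `"absolute"` or `"relative"`.
#' @param mapSource `"flash"` simulates the three multi-echo series and
#'   re-estimates the maps; `"truth"` perturbs the ground-truth maps
#'   directly with map-level noise.
#' @param flashNoiseSd additive signal noise for `mapSource = "flash"`.
#' @param writeVolumes also write all phantom volumes as NIfTI.
#' @return Invisibly, a list with the cohort and the per-stage result
#'   tables.
#' @export
runPipeline <- function(outDir, config = phantomConfig(),
                        protocol = acquisitionProtocol(), seed = 1L,
                        nPerm = 5000, q = 0.05, arocMode = "absolute",
                        mapSource = c("flash", "truth"), flashNoiseSd = 1,
                        writeVolumes = FALSE) {
  mapSource <- match.arg(mapSource)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  note <- function(stage, files) stages[[stage]] <<- files
  wtab <- function(x, name) {
    f <- file.path(outDir, name)
    utils::write.csv(x, f, row.names = FALSE)
    f
  }

  # stage 1: simulate
  config@seed <- .deriveSeed(seed, 1L)
  cohort <- generatePhantom(config)
  simFiles <- wtab(cohort@clinical, "clinical.csv")
  if (writeVolumes)
    simFiles <- c(simFiles, writePhantom(cohort, file.path(outDir,
                                                           "volumes")))
  note("simulate", simFiles)

  # stage 2: map estimation (or map-level observation)
  nSub <- length(cohort@subjects)
  observed <- vector("list", nSub)
  for (s in seq_len(nSub)) {
    observed[[s]] <- list()
    for (tp in c("T0", "T1"))
      observed[[s]][[tp]] <- .observeMaps(
        cohort@subjects[[s]][[tp]], config, protocol, mapSource,
        flashNoiseSd, seed = .deriveSeed(seed, 100L + 2L * s + (tp == "T1")))
    if (mapSource == "flash")
      observed[[s]] <- .calibrateSubject(
        observed[[s]]$T0, observed[[s]]$T1,
        binarizeTissues(cohort@subjects[[s]]$T0$posteriors)$NAWM)
  }
  note("fit-mpm", sprintf("in-memory maps (%s mode), %d subjects",
                          mapSource, nSub))

  # stage 3: lesion areas
  areasBySubj <- vector("list", nSub)
  areaRows <- list()
  for (s in seq_len(nSub)) {
    subj <- cohort@subjects[[s]]
    masksT0 <- binarizeTissues(subj$T0$posteriors)
    flair <- cleanLesionMask(subj$T0$flair, config@voxelSize)
    lesT0 <- cleanLesionMask(subj$T0$lesion, config@voxelSize)
    lesT1 <- cleanLesionMask(subj$T1$lesion, config@voxelSize)
    wm <- masksT0$NAWM | lesT0 | lesT1
    areas <- buildLesionAreas(flair, lesT0, lesT1, wm, config@voxelSize)
    sel <- selectEnlargingLesions(areas)
    areasBySubj[[s]] <- list(areas = areas, ids = sel$ids)
    if (length(sel$ids)) {
      cnt <- sel$counts[sel$counts$id %in% sel$ids, ]
      voxVol <- prod(config@voxelSize)
      areaRows[[s]] <- data.frame(
        subject_id = subj$id, lesion_id = rep(cnt$id, 3),
        area = rep(c("focal_flair", "initial_peripheral",
                     "later_peripheral"), each = nrow(cnt)),
        volume_mm3 = c(cnt$focal, cnt$initial, cnt$later) * voxVol)
    }
  }
  lesionTab <- if (length(areaRows)) do.call(rbind, areaRows) else
    data.frame(subject_id = character(0), lesion_id = integer(0),
               area = character(0), volume_mm3 = numeric(0))
  note("segment-areas", wtab(lesionTab, "lesion_areas.csv"))

  # stage 4: volumetrics
  volRows <- list()
  for (s in seq_len(nSub)) {
    subj <- cohort@subjects[[s]]
    for (tp in c("T0", "T1")) {
      masks <- binarizeTissues(subj[[tp]]$posteriors)
      fr <- computeFractions(masks, masks$lesion, config@voxelSize)
      volRows[[length(volRows) + 1L]] <-
        data.frame(subject_id = subj$id, timepoint = tp, TIV = fr$TIV,
                   BPF = fr$BPF, GMF = fr$GMF, LF = fr$LF)
    }
  }
  vol <- do.call(rbind, volRows)
  v0 <- vol[vol$timepoint == "T0", ]
  v1 <- vol[vol$timepoint == "T1", ]
  chg <- data.frame(
    subject_id = v0$subject_id,
    dBPF_pct_yr = annualizedPercentChange(v0$BPF, v1$BPF,
                                          cohort@clinical$interval_months),
    dGMF_pct_yr = annualizedPercentChange(v0$GMF, v1$GMF,
                                          cohort@clinical$interval_months),
    dLF_pct_yr = if (all(v0$LF > 0))
      annualizedPercentChange(v0$LF, v1$LF, cohort@clinical$interval_months)
      else NA_real_)
  note("volumetrics", c(wtab(vol, "volumetrics.csv"),
                        wtab(chg, "volumetric_changes.csv")))

  # stage 5: clinical status
  note("status", wtab(cohort@clinical[c("subject_id", "neda_mid",
                                        "neda_end", "status")],
                      "status.csv"))

  # stage 6: normal-appearing-tissue inference
  arocRows <- list()
  for (s in seq_len(nSub)) {
    subj <- cohort@subjects[[s]]
    med <- lapply(c(T0 = "T0", T1 = "T1"), function(tp)
      extractTissueMedians(observed[[s]][[tp]],
                           binarizeTissues(subj[[tp]]$posteriors)))
    tab <- med$T0
    names(tab)[names(tab) == "median"] <- "median_t0"
    tab$median_t1 <- med$T1$median
    tab$subject_id <- subj$id
    tab$interval_years <- subj$intervalYears
    tab$aroc <- aroc(tab$median_t0, tab$median_t1, subj$intervalYears,
                     mode = arocMode)
    arocRows[[s]] <- tab
  }
  arocTab <- do.call(rbind, arocRows)
  nabt <- runNabtInference(arocTab,
                           cohort@clinical[c("subject_id", "status")],
                           nPerm = nPerm, seed = .deriveSeed(seed, 300L),
                           q = q)
  note("nabt", c(wtab(arocTab, "aroc.csv"), wtab(nabt, "nabt_results.csv")))

  # stage 7: lesion mixed model
  longRows <- list()
  for (s in seq_len(nSub)) {
    ids <- areasBySubj[[s]]$ids
    if (!length(ids)) next
    longRows[[s]] <- buildLongTable(observed[[s]]$T0, observed[[s]]$T1,
                                    areasBySubj[[s]]$areas, ids,
                                    subjectId = cohort@subjects[[s]]$id)
  }
  lesionRes <- list()
  lesionFiles <- character(0)
  if (length(longRows) >= 2L) {
    longTab <- do.call(rbind, longRows)
    lesionFiles <- wtab(longTab, "lesion_long_table.csv")
    for (p in .PARAMETERS) {
      fit <- fitAreaTimeModel(longTab, parameter = p)
      ctr <- pairwiseAreaContrasts(fit)
      av <- cbind(effect = rownames(fit@anova), fit@anova,
                  df_method = fit@dfMethod)
      lesionFiles <- c(lesionFiles,
                       wtab(av, sprintf("lesion_model_%s.csv", p)),
                       wtab(ctr, sprintf("lesion_contrasts_%s.csv", p)))
      lesionRes[[p]] <- list(fit = fit, contrasts = ctr)
    }
  }
  note("lesions", if (length(lesionFiles)) lesionFiles else
    "skipped: fewer than 2 subjects with enlarging lesions")

  manifest <- list(
    seed = seed, nPerm = nPerm, q = q, arocMode = arocMode,
    mapSource = mapSource,
    package = as.character(utils::packageVersion("qmritrack")),
    config = list(gridShape = config@gridShape,
                  voxelSize = config@voxelSize,
                  nSubjects = config@nSubjects, nLesions = config@nLesions,
                  lesionRadii = c(config@lesionRadiusFlair,
                                  config@lesionRadiusT0,
                                  config@lesionRadiusT1),
                  peripheralGradient = config@peripheralGradient,
                  statusEffect = as.list(config@statusEffect),
                  atrophyPctYr = config@atrophyPctYr,
                  mapNoiseFrac = config@mapNoiseFrac,
                  subjectCv = config@subjectCv,
                  binarizationThreshold = 0.2,
                  lesionMinVolumeMm3 = 10, connectivity = 26),
    stages = stages,
    checksums = as.list(tools::md5sum(Filter(file.exists,
                                             unlist(stages)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, volumetrics = vol, changes = chg,
                 arocTable = arocTab, nabt = nabt, lesion = lesionRes,
                 manifest = manifest))
}
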