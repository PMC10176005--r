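#' Label connected components in a 3D binary mask
#'
#' Foreground voxels are vertices of an adjacency graph (26- or
#' 6-neighbourhood); connected components are found with igraph. Labels
#' are positive integers in order of first (column-major) occurrence, 0
#' for background.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param connectivity 26 (default; faces, edges and corners) or 6
#'   (faces only).
#' @return Integer 3D array of component labels.
#' @export
labelComponents <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  mask <- mask != 0
  lab <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)

  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[offsets$dx != 0 | offsets$dy != 0 | offsets$dz != 0, ]
  if (connectivity == 6)
    offsets <- offsets[abs(offsets$dx) + abs(offsets$dy) +
                       abs(offsets$dz) == 1, ]
  # keep one direction per neighbour pair
  keep <- offsets$dz > 0 | (offsets$dz == 0 & offsets$dy > 0) |
          (offsets$dz == 0 & offsets$dy == 0 & offsets$dx > 0)
  offsets <- offsets[keep, ]

  vmap <- integer(prod(d))
  vmap[idx] <- seq_along(idx)
  pos <- arrayInd(idx, d)
  edges <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nx <- pos[, 1] + offsets$dx[r]
    ny <- pos[, 2] + offsets$dy[r]
    nz <- pos[, 3] + offsets$dz[r]
    ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] &
          nz >= 1L & nz <= d[3]
    nlin <- nx[ok] + (ny[ok] - 1L) * d[1] + (nz[ok] - 1L) * d[1] * d[2]
    hit <- mask[nlin]
    if (any(hit))
      edges <- c(edges, rbind(vmap[idx[ok][hit]], vmap[nlin[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel in order of first occurrence for determinism
  first <- match(unique(memb), memb)
  relabel <- integer(max(memb))
  relabel[memb[sort(first)]] <- seq_along(first)
  lab[idx] <- relabel[memb]
  lab
}

#' Binarize tissue posterior maps into exclusive masks
#'
#' Each voxel is assigned to the single tissue class with the highest
#' posterior probability, provided that probability strictly exceeds the
#' threshold; otherwise the voxel stays unassigned. Exact ties are broken
#' by a fixed priority order: lesion, NAWM, NACGM, NADGM, CSF.
#'
#' @param posteriors a [TissuePosteriors-class] object.
#' @param threshold assignment threshold in \[0, 1); default 0.2.
#' @return Named list of logical 3D arrays (`NAWM`, `NACGM`, `NADGM`,
#'   `CSF`, `lesion`), pairwise disjoint.
#' @export
binarizeTissues <- function(posteriors, threshold = 0.2) {
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  stopifnot(is(posteriors, "TissuePosteriors"))
  priority <- c("lesion", "NAWM", "NACGM", "NADGM", "CSF")
  d <- dim(posteriors@posteriors[[1]])
  P <- vapply(posteriors@posteriors[priority], as.numeric,
              numeric(prod(d)))
  top <- max.col(P, ties.method = "first")
  pmax_ <- P[cbind(seq_len(nrow(P)), top)]
  assigned <- pmax_ > threshold
  out <- lapply(seq_along(priority), function(i)
    array(assigned & top == i, dim = d))
  names(out) <- priority
  out[.TISSUES]
}

#' Remove small lesion components
#'
#' Connected components with volume strictly below `minVolumeMm3`
#' (default 10 mm^3), which likely arise from segmentation errors, are
#' removed; all others are untouched. Idempotent.
#'
#' @param mask binary (logical or 0/1) 3D array.
#' @param voxelSize voxel edge lengths in mm.
#' @param minVolumeMm3 strict volume cutoff in mm^3.
#' @param connectivity passed to [labelComponents()].
#' @return Logical 3D array.
#' @export
cleanLesionMask <- function(mask, voxelSize = c(1, 1, 1), minVolumeMm3 = 10,
                            connectivity = 26) {
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary")
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim = dim(mask)))
  voxVol <- prod(voxelSize)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * voxVol >= minVolumeMm3)
  array(lab %in% keep, dim = dim(mask))
}

#' Build the four exclusive lesion-related areas
#'
#' From the focal FLAIR lesion mask at T0, the full (segmentation-derived)
#' lesion masks at T0 and T1, and a white-matter mask, constructs:
#' focal FLAIR lesion; initial peripheral lesion (full T0 lesion minus the
#' FLAIR core); later peripheral lesion (full T1 lesion minus the full T0
#' lesion); and NAWM (white matter in none of the three). The FLAIR mask
#' is intersected with the T0 lesion mask first so that containment holds
#' by construction. Disjointness is guaranteed by the set differences.
#'
#' @param flairT0 logical 3D array, focal FLAIR lesion mask at T0.
#' @param lesionT0,lesionT1 logical 3D arrays, full lesion masks.
#' @param wmMask logical 3D array of all white-matter voxels (including
#'   lesions).
#' @param voxelSize voxel edge lengths in mm.
#' @param connectivity connectivity for lesion component labelling.
#' @return An [AreaMasks-class] object.
#' @export
buildLesionAreas <- function(flairT0, lesionT0, lesionT1, wmMask,
                             voxelSize = c(1, 1, 1), connectivity = 26) {
  dims <- list(dim(flairT0), dim(lesionT0), dim(lesionT1), dim(wmMask))
  if (length(unique(dims)) > 1L) stop("mask grids do not match")
  flairT0 <- flairT0 != 0; lesionT0 <- lesionT0 != 0
  lesionT1 <- lesionT1 != 0; wmMask <- wmMask != 0
  if (any(flairT0 & !lesionT0))
    message("focal FLAIR mask not contained in T0 lesion mask; intersecting")
  focal <- flairT0 & lesionT0
  initial <- lesionT0 & !focal
  later <- lesionT1 & !lesionT0
  nawm <- wmMask & !focal & !initial & !later
  union <- focal | initial | later
  new("AreaMasks", focalFlair = focal, initialPeripheral = initial,
      laterPeripheral = later, nawm = nawm,
      lesionLabels = labelComponents(union, connectivity),
      voxelSize = as.numeric(voxelSize))
}

#' Select enlarging lesions
#'
#' A lesion (connected component of the union of the three lesion-related
#' areas) is enlarging when it is present in all three masks: it overlaps
#' the focal FLAIR, initial peripheral and later peripheral areas by at
#' least one voxel each. Only such lesions support a lesion-by-lesion
#' longitudinal comparison.
#'
#' @param areas an [AreaMasks-class] object.
#' @return List with `ids` (integer vector of retained component labels,
#'   possibly empty) and `counts` (data.frame of per-component voxel
#'   counts in each area).
#' @export
selectEnlargingLesions <- function(areas) {
  stopifnot(is(areas, "AreaMasks"))
  lab <- areas@lesionLabels
  nid <- max(lab)
  if (nid == 0L)
    return(list(ids = integer(0),
                counts = data.frame(id = integer(0), focal = integer(0),
                                    initial = integer(0),
                                    later = integer(0))))
  tab <- function(m) tabulate(lab[m & lab > 0L], nbins = nid)
  counts <- data.frame(id = seq_len(nid),
                       focal = tab(areas@focalFlair),
                       initial = tab(areas@initialPeripheral),
                       later = tab(areas@laterPeripheral))
  ids <- counts$id[counts$focal >= 1L & counts$initial >= 1L &
                   counts$later >= 1L]
  list(ids = as.integer(ids), counts = counts)
}
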