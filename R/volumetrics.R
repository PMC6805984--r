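## Volumetric imaging parameters from binary masks.
##
## The surface surrogates follow the shell convention: the "outer
## surface" TSAO is the volume of the outermost 1 mm layer of the tumor
## (ATV minus its 1 mm contraction) and the "inner surface" TSAI the
## 1 mm layer gained by enlarging the lumen (ITC). Morphology is done in
## physical millimetres so the 1 mm margin is isotropic even on
## anisotropic CT grids where slices are thicker than 1 mm.

voxelVolumeCm3 <- function(grid) prod(grid@spacing) / 1000

## Voxel-center coordinates per axis, centred on the grid (mm).
voxelCoords <- function(grid) {
  lapply(1:3, function(a)
    (seq_len(grid@shape[a]) - (grid@shape[a] + 1) / 2) * grid@spacing[a])
}

## All integer voxel offsets whose physical center-to-center Euclidean
## norm is <= d mm, excluding the zero offset. Distances are between
## voxel centers (the Euclidean distance transform convention), so the
## effective margin carries an O(spacing) quantization bias relative to
## continuous-geometry erosion; shell estimates converge to their closed
## forms as the grid is refined.
physOffsets <- function(spacing, d) {
  k <- floor(d / spacing)
  g <- as.matrix(expand.grid(i = -k[1]:k[1], j = -k[2]:k[2], l = -k[3]:k[3]))
  nrm2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  g[nrm2 <= d^2 & nrm2 > 0, , drop = FALSE]
}

## out[v] = a[v + o], padded where v + o falls outside the grid.
lookupShift <- function(a, o, pad) {
  d <- dim(a)
  out <- array(pad, d)
  v1 <- max(1L, 1L - o[1]):min(d[1], d[1] - o[1])
  v2 <- max(1L, 1L - o[2]):min(d[2], d[2] - o[2])
  v3 <- max(1L, 1L - o[3]):min(d[3], d[3] - o[3])
  if (length(v1) && length(v2) && length(v3))
    out[v1, v2, v3] <- a[v1 + o[1], v2 + o[2], v3 + o[3]]
  out
}

#' @describeIn maskVolume member voxel count times voxel volume.
#' @export
setMethod("maskVolume", "BinaryMask", function(x) {
  sum(x@voxels) * voxelVolumeCm3(x@grid)
})

#' Contract a mask by a physical distance
#'
#' Retains exactly the voxels whose Euclidean center-to-center distance
#' (in physical mm, honoring anisotropic spacing) to the nearest
#' in-grid complement voxel exceeds `distance` — the distance-transform
#' convention. `distance = 0` is the identity. Space outside the grid
#' does not erode the mask.
#'
#' @param mask a [BinaryMask-class].
#' @param distance contraction distance in mm, >= 0.
#' @return the contracted [BinaryMask-class].
#' @examples
#' m <- makeSolidPhantom("sphere", 10, imageGrid(c(25L, 25L, 25L), rep(1, 3)))
#' maskVolume(contractMask(m, 1))
#' @export
contractMask <- function(mask, distance) {
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0)
    stop("'distance' must be a single non-negative number of mm")
  if (distance == 0) return(mask)
  v <- mask@voxels
  if (!any(v)) return(mask)
  off <- physOffsets(mask@grid@spacing, distance)
  for (r in seq_len(nrow(off))) {
    v <- v & lookupShift(mask@voxels, off[r, ], pad = TRUE)
    if (!any(v)) break
  }
  binaryMask(v, grid = mask@grid)
}

#' Expand a mask by a physical distance
#'
#' Adds exactly the complement voxels whose Euclidean center-to-center
#' distance in physical mm to the nearest member voxel is at most
#' `distance`; the result is a superset of the input. An expansion that would extend
#' beyond the grid raises an error rather than silently clipping.
#'
#' @param mask a [BinaryMask-class].
#' @param distance expansion distance in mm, >= 0.
#' @return the expanded [BinaryMask-class].
#' @export
expandMask <- function(mask, distance) {
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0)
    stop("'distance' must be a single non-negative number of mm")
  if (distance == 0) return(mask)
  a <- mask@voxels
  if (!any(a)) return(mask)
  d <- dim(a)
  v <- a
  off <- physOffsets(mask@grid@spacing, distance)
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    # a member at u would reach u - o; error if that leaves the grid
    clip1 <- if (o[1] > 0) any(a[seq_len(min(o[1], d[1])), , ]) else
             if (o[1] < 0) any(a[(d[1] + max(o[1], -d[1]) + 1L):d[1], , ]) else FALSE
    clip2 <- if (o[2] > 0) any(a[, seq_len(min(o[2], d[2])), ]) else
             if (o[2] < 0) any(a[, (d[2] + max(o[2], -d[2]) + 1L):d[2], ]) else FALSE
    clip3 <- if (o[3] > 0) any(a[, , seq_len(min(o[3], d[3]))]) else
             if (o[3] < 0) any(a[, , (d[3] + max(o[3], -d[3]) + 1L):d[3]]) else FALSE
    if (clip1 || clip2 || clip3)
      stop("expansion by ", distance, " mm would extend beyond the grid; ",
           "enlarge the grid instead of clipping")
    v <- v | lookupShift(a, o, pad = FALSE)
  }
  binaryMask(v, grid = mask@grid)
}

#' Outer shell surface surrogate (TSAO)
#'
#' Volume of the outermost `thickness`-mm layer of the tumor mask:
#' `maskVolume(atv) - maskVolume(contractMask(atv, thickness))`. By the
#' shell convention this value is reported as the outer "surface area".
#'
#' @param atv tumor [BinaryMask-class].
#' @param thickness shell thickness in mm (default 1).
#' @return shell volume in cm^3 (paper-unit surface value).
#' @export
shellOutside <- function(atv, thickness = 1) {
  if (!any(atv@voxels)) {
    warning("empty mask: outer shell is 0")
    return(0)
  }
  maskVolume(atv) - maskVolume(contractMask(atv, thickness))
}

#' Inner shell surface surrogate (TSAI)
#'
#' Volume gained by enlarging the lumen mask by `thickness` mm:
#' `maskVolume(expandMask(itc, thickness)) - maskVolume(itc)`.
#'
#' @param itc lumen [BinaryMask-class].
#' @param thickness shell thickness in mm (default 1).
#' @return shell volume in cm^3 (paper-unit surface value).
#' @export
shellInside <- function(itc, thickness = 1) {
  if (!any(itc@voxels)) {
    warning("empty mask: inner shell is 0")
    return(0)
  }
  maskVolume(expandMask(itc, thickness)) - maskVolume(itc)
}

#' Real tumor volume (RTV)
#'
#' ATV volume minus the volume of the lumen contained in it. When the
#' lumen extends outside the tumor contour it is reconciled by
#' intersection with a warning.
#'
#' @param atv,itc [BinaryMask-class] objects on one grid.
#' @return RTV in cm^3.
#' @export
realTumorVolume <- function(atv, itc) {
  if (!identical(dim(atv@voxels), dim(itc@voxels)))
    stop("masks must share one grid")
  if (any(itc@voxels & !atv@voxels))
    warning("ITC extends outside ATV; using the intersection")
  maskVolume(atv) - sum(atv@voxels & itc@voxels) * voxelVolumeCm3(atv@grid)
}

#' Tumor compactness score
#'
#' TC = RTV / TSA^1.5 with RTV in cm^3 and TSA the shell-convention
#' total surface value.
#'
#' @param rtv real tumor volume, cm^3 (>= 0).
#' @param tsa total surface value (> 0).
#' @return the compactness score.
#' @examples
#' tumorCompactness(45.49, 11.30)
#' @export
tumorCompactness <- function(rtv, tsa) {
  if (any(tsa <= 0)) stop("'tsa' must be > 0")
  if (any(rtv < 0)) stop("'rtv' must be >= 0")
  rtv / tsa^1.5
}

#' Maximum longitudinal length (TML)
#'
#' Occupied-slice extent along the longitudinal axis: (last occupied
#' slice - first occupied slice + 1) times the slice spacing, in cm. A
#' single-slice mask therefore has TML equal to one slice spacing.
#'
#' @param mask non-empty [BinaryMask-class].
#' @return TML in cm.
#' @export
maxLongitudinalLength <- function(mask) {
  occ <- which(apply(mask@voxels, 1, any))
  if (!length(occ)) stop("TML of an empty mask is undefined")
  (max(occ) - min(occ) + 1) * mask@grid@spacing[1] / 10
}

#' Maximum transverse diameter (TMD)
#'
#' Maximum over axial slices of the in-plane Feret diameter (largest
#' pairwise distance between member voxel centers), in cm. By default
#' the lumen is included in the measurement, mirroring the difficulty of
#' excluding the intracavitary space on CT; with `includeLumen = FALSE`
#' the lumen voxels are removed first, but the Feret span is still taken
#' across the remaining voxels (an enclosing annulus keeps its full
#' outer diameter).
#'
#' @param mask non-empty tumor [BinaryMask-class].
#' @param includeLumen logical (default TRUE).
#' @param itc lumen mask, required when `includeLumen = FALSE`.
#' @return TMD in cm.
#' @export
maxTransverseDiameter <- function(mask, includeLumen = TRUE, itc = NULL) {
  v <- mask@voxels
  if (!includeLumen) {
    if (is.null(itc)) stop("'itc' is required when includeLumen = FALSE")
    v <- v & !itc@voxels
  }
  if (!any(v)) stop("TMD of an empty mask is undefined")
  sp <- mask@grid@spacing
  best <- 0
  for (s in seq_len(dim(v)[1])) {
    sl <- v[s, , ]
    n <- sum(sl)
    if (n == 0L) next
    idx <- which(sl, arr.ind = TRUE)
    pts <- cbind(idx[, 1] * sp[2], idx[, 2] * sp[3])
    if (n > 3L) pts <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(pts) == 1L) next
    d2 <- as.matrix(stats::dist(pts))
    best <- max(best, max(d2))
  }
  best / 10
}

#' @describeIn extractFeatures computes all nine parameters plus the
#'   true-area variant; the identities RTV = ATV - ITC, TSA = TSAO + TSAI
#'   and TC = RTV/TSA^1.5 hold exactly by construction.
#' @param thickness shell thickness in mm (default 1).
#' @export
setMethod("extractFeatures", "StructureSet", function(x, thickness = 1) {
  atvVol <- maskVolume(x@atv)
  itcVol <- sum(x@atv@voxels & x@itc@voxels) * voxelVolumeCm3(x@atv@grid)
  rtv <- atvVol - itcVol
  tsao <- shellOutside(x@atv, thickness)
  tsai <- if (any(x@itc@voxels)) shellInside(x@itc, thickness) else 0
  tsa <- tsao + tsai
  tc <- if (tsa > 0) tumorCompactness(rtv, tsa) else NA_real_
  new("VolumetricFeatures",
      atv = atvVol, itc = itcVol, rtv = rtv,
      tsao = tsao, tsai = tsai, tsa = tsa, tc = tc,
      tml = maxLongitudinalLength(x@atv),
      tmd = maxTransverseDiameter(x@atv),
      trueSurface = tsa / (thickness / 10))
})

#' Coerce VolumetricFeatures to a one-row data.frame
#'
#' Column names follow the export convention `atv_cm3 ... tmd_cm`.
#'
#' @param x a [VolumetricFeatures-class].
#' @param row.names,optional,... ignored, for generic consistency.
#' @method as.data.frame VolumetricFeatures
#' @export
as.data.frame.VolumetricFeatures <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(atv_cm3 = x@atv, itc_cm3 = x@itc, rtv_cm3 = x@rtv,
             tsao = x@tsao, tsai = x@tsai, tsa = x@tsa, tc = x@tc,
             tml_cm = x@tml, tmd_cm = x@tmd,
             true_surface_cm2 = x@trueSurface)
}
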