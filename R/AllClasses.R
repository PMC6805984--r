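
#' ImageGrid: a regular 3D voxel lattice with physical spacing
#'
#' Describes the geometry of a CT-like voxel grid. Axis 1 is the
#' longitudinal (cranio-caudal) direction by convention; axes 2 and 3 are
#' the in-plane row and column directions.
#'
#' @slot shape integer vector of length 3, number of voxels per axis
#'   (longitudinal, row, column); all components >= 1.
#' @slot spacing numeric vector of length 3, physical voxel spacing in mm
#'   (slice spacing, in-plane row, in-plane column); all components > 0.
#'
#' @seealso [imageGrid()], [BinaryMask-class]
#' @export
setClass("ImageGrid",
         representation(shape = "integer", spacing = "numeric"))

setValidity("ImageGrid", function(object) {
  msg <- character(0)
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "'shape' must be 3 integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageGrid
#'
#' @param shape integer triple: voxels along (longitudinal, row, column).
#' @param spacing numeric triple: voxel spacing in mm along the same axes.
#'   Defaults to routine pelvic CT geometry, 3.0 mm slices with
#'   0.98 x 0.98 mm in-plane resolution.
#' @return An [ImageGrid-class] object.
#' @examples
#' imageGrid(c(40L, 64L, 64L))
#' @export
imageGrid <- function(shape, spacing = c(3.0, 0.98, 0.98)) {
  new("ImageGrid", shape = as.integer(shape), spacing = as.numeric(spacing))
}

#' BinaryMask: a binary segmentation on an ImageGrid
#'
#' @slot grid an [ImageGrid-class].
#' @slot voxels logical 3D array of membership, dim equal to the grid shape.
#' @export
setClass("BinaryMask",
         representation(grid = "ImageGrid", voxels = "array"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@voxels))
    return("'voxels' must be a logical array")
  if (!identical(dim(object@voxels), as.integer(object@grid@shape)))
    return("dim(voxels) must equal the grid shape")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param voxels logical 3D array (axis 1 longitudinal).
#' @param grid an [ImageGrid-class]; when missing, a grid with default
#'   spacing and the array's shape is built.
#' @param spacing spacing used when `grid` is missing.
#' @return A [BinaryMask-class].
#' @export
binaryMask <- function(voxels, grid = NULL, spacing = c(3.0, 0.98, 0.98)) {
  storage.mode(voxels) <- "logical"
  if (is.null(grid)) grid <- imageGrid(dim(voxels), spacing)
  new("BinaryMask", grid = grid, voxels = voxels)
}

#' StructureSet: paired tumor (ATV) and lumen (ITC) masks
#'
#' The approximate tumor volume (ATV) is the delineated outer tumor
#' contour including the enclosed intestinal lumen; the intestinal tube
#' cavity (ITC) is the lumen at the tumor's level. Both masks live on one
#' grid and, after reconciliation, every ITC voxel is also an ATV voxel.
#'
#' @slot atv tumor outer-contour [BinaryMask-class].
#' @slot itc lumen [BinaryMask-class] on the same grid.
#' @export
setClass("StructureSet",
         representation(atv = "BinaryMask", itc = "BinaryMask"))

setValidity("StructureSet", function(object) {
  g1 <- object@atv@grid; g2 <- object@itc@grid
  if (!identical(g1@shape, g2@shape) ||
      !isTRUE(all.equal(g1@spacing, g2@spacing)))
    return("ATV and ITC masks must share one grid")
  TRUE
})

#' Construct a StructureSet
#'
#' ITC voxels outside the ATV are reconciled by intersection (with a
#' warning), since the lumen is assumed to lie within the delineated
#' tumor region.
#'
#' @param atv,itc [BinaryMask-class] objects on a common grid.
#' @param reconcile logical; intersect ITC with ATV when ITC is not
#'   contained in ATV (default TRUE).
#' @return A [StructureSet-class].
#' @export
structureSet <- function(atv, itc, reconcile = TRUE) {
  if (reconcile && any(itc@voxels & !atv@voxels)) {
    warning("ITC extends outside ATV; reconciling by intersection")
    itc <- binaryMask(itc@voxels & atv@voxels, grid = itc@grid)
  }
  new("StructureSet", atv = atv, itc = itc)
}

#' VolumetricFeatures: the nine per-patient imaging parameters
#'
#' Volumes are in cm^3. Following the source convention, the surface
#' parameters TSAO/TSAI/TSA are 1-mm shell volumes reported numerically
#' as "surface areas"; `trueSurface` divides TSA by the 0.1 cm shell
#' thickness to give a genuine area estimate in cm^2. Tumor compactness
#' is TC = RTV / TSA^1.5.
#'
#' @slot atv,itc,rtv volumes in cm^3.
#' @slot tsao,tsai,tsa shell-volume surface surrogates.
#' @slot tc compactness score (dimensionless by convention).
#' @slot tml,tmd maximum longitudinal length / transverse diameter, cm.
#' @slot trueSurface shell-derived surface area estimate, cm^2.
#' @export
setClass("VolumetricFeatures",
         representation(atv = "numeric", itc = "numeric", rtv = "numeric",
                        tsao = "numeric", tsai = "numeric", tsa = "numeric",
                        tc = "numeric", tml = "numeric", tmd = "numeric",
                        trueSurface = "numeric"))

setValidity("VolumetricFeatures", function(object) {
  v <- c(object@atv, object@itc, object@rtv, object@tsao, object@tsai,
         object@tsa, object@tml, object@tmd)
  if (any(!is.finite(v)) || any(v < 0))
    return("all volumetric parameters must be finite and >= 0")
  TRUE
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Geometry ranges are sampled uniformly per patient; the outcome model
#' is a logistic model on the coded real tumor volume and tumor
#' compactness (defaults are the published all-patient equation
#' constants). Covariate stratum probabilities default to the published
#' cohort's frequencies.
#'
#' @slot nPatients number of patients.
#' @slot lumenRadius,wallThickness,tumorLength,angularCoverage,irregularity
#'   two-element min/max ranges (mm, except coverage which is a fraction
#'   in (0, 1]).
#' @slot spacing default grid spacing in mm.
#' @slot trueModel named numeric: intercept, rtv (coefficient on coded
#'   RTV) and tc (coefficient on coded TC) of the generative logistic
#'   outcome model.
#' @slot covariateProbs list of per-factor stratum probabilities.
#' @export
setClass("CohortSpec",
         representation(nPatients = "integer",
                        lumenRadius = "numeric",
                        wallThickness = "numeric",
                        tumorLength = "numeric",
                        angularCoverage = "numeric",
                        irregularity = "numeric",
                        spacing = "numeric",
                        trueModel = "numeric",
                        covariateProbs = "list"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  rng <- function(x) length(x) == 2L && all(is.finite(x)) && x[1] <= x[2]
  if (object@nPatients < 0L) msg <- c(msg, "nPatients must be >= 0")
  for (s in c("lumenRadius", "wallThickness", "tumorLength")) {
    x <- slot(object, s)
    if (!rng(x) || x[1] <= 0) msg <- c(msg, paste0("'", s, "' must be a positive min/max range"))
  }
  if (!rng(object@angularCoverage) || object@angularCoverage[1] <= 0 ||
      object@angularCoverage[2] > 1)
    msg <- c(msg, "'angularCoverage' range must lie in (0, 1]")
  if (!rng(object@irregularity) || object@irregularity[1] < 0)
    msg <- c(msg, "'irregularity' range must be >= 0")
  if (!all(c("intercept", "rtv", "tc") %in% names(object@trueModel)))
    msg <- c(msg, "'trueModel' needs named elements intercept, rtv, tc")
  for (nm in names(object@covariateProbs)) {
    p <- object@covariateProbs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      msg <- c(msg, paste0("covariate probabilities for '", nm, "' must sum to 1"))
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: simulated structures, clinical records and features
#'
#' @slot structures list of [StructureSet-class] (empty in analytic mode).
#' @slot clinical data.frame of clinical records (one row per patient).
#' @slot features data.frame of volumetric features (one row per patient).
#' @slot spec the generating [CohortSpec-class].
#' @export
setClass("SyntheticCohort",
         representation(structures = "list", clinical = "data.frame",
                        features = "data.frame", spec = "CohortSpec"))

#' PublishedModel: a frozen published logistic prediction equation
#'
#' Four equations are provided: Z1/Z2 fitted on all patients, Z3/Z4 on
#' the non-mucinous adenocarcinoma subgroup; Z1/Z3 use the coded real
#' tumor volume, Z2/Z4 the coded approximate tumor volume, each together
#' with the coded tumor compactness.
#'
#' @slot name one of "Z1", "Z2", "Z3", "Z4".
#' @slot cohort "all" or "non_mucinous".
#' @slot intercept numeric intercept on the log-odds scale.
#' @slot volumeTerm "rtv_code" or "atv_code".
#' @slot volumeCoef,tcCoef coefficients on the coded volume and coded
#'   compactness.
#' @export
setClass("PublishedModel",
         representation(name = "character", cohort = "character",
                        intercept = "numeric", volumeTerm = "character",
                        volumeCoef = "numeric", tcCoef = "numeric"))

#' ROCResult: an ROC curve with cutoff and predictive-value panel
#'
#' @slot points data.frame with columns threshold, sensitivity,
#'   specificity (one row per distinct score plus -Inf/+Inf sentinels).
#' @slot auc area under the curve (after orientation correction).
#' @slot orientation "positive" (score >= cutoff is test-positive) or
#'   "negative" (score <= cutoff is test-positive).
#' @slot cutoff optimal cutoff on the score's natural scale.
#' @slot sensitivity,specificity,ppv,npv metrics at the cutoff.
#' @slot prevalence event prevalence in the evaluated data.
#' @export
setClass("ROCResult",
         representation(points = "data.frame", auc = "numeric",
                        orientation = "character", cutoff = "numeric",
                        sensitivity = "numeric", specificity = "numeric",
                        ppv = "numeric", npv = "numeric",
                        prevalence = "numeric"))
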