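## Synthetic voxel phantoms and cohorts.
##
## Phantoms use center-inclusion voxelization: a voxel belongs to a
## solid iff its center point lies inside. Closed intervals are used for
## radial boundaries and half-open intervals for axis-aligned extents,
## so aligned boxes and cylinder lengths voxelize exactly.

## Run code under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## Coordinates of the voxel center nearest the grid center (mm).
nearestCenter <- function(grid) {
  vapply(voxelCoords(grid), function(cc) cc[which.min(abs(cc))], numeric(1))
}

checkExtent <- function(grid, center, halfSpan) {
  cc <- voxelCoords(grid)
  for (a in 1:3) {
    lo <- min(cc[[a]]) - grid@spacing[a] / 2
    hi <- max(cc[[a]]) + grid@spacing[a] / 2
    if (center[a] - halfSpan[a] < lo || center[a] + halfSpan[a] > hi)
      stop("solid exceeds the physical extent of the grid along axis ", a)
  }
}

#' Voxelize an analytic solid, with its closed form attached
#'
#' Supported solids: `sphere` (dimensions = radius), `box` (dimensions =
#' edge lengths along the three axes), `cylinder` (dimensions = radius,
#' length; axis longitudinal) and `hollow_cylinder` (dimensions = inner
#' radius, outer radius, length). All dimensions in mm. The analytic
#' volume (cm^3) and surface area (cm^2) are attached as the
#' `"closedForm"` attribute for oracle use.
#'
#' @param kind solid type.
#' @param dimensions numeric dimensions in mm (see above).
#' @param grid target [ImageGrid-class].
#' @param center solid center in grid-centered mm coordinates; defaults
#'   to the voxel center nearest the grid center, so sub-voxel solids
#'   capture exactly one voxel.
#' @return a [BinaryMask-class] with attribute `closedForm`.
#' @examples
#' g <- imageGrid(c(45L, 45L, 45L), rep(1, 3))
#' s <- makeSolidPhantom("sphere", 20, g)
#' c(voxel = maskVolume(s), analytic = closedForm(s)$volume_cm3)
#' @export
makeSolidPhantom <- function(kind = c("sphere", "box", "cylinder",
                                      "hollow_cylinder"),
                             dimensions, grid, center = NULL) {
  kind <- match.arg(kind)
  if (is.null(center)) center <- nearestCenter(grid)
  cc <- voxelCoords(grid)
  z <- cc[[1]] - center[1]; y <- cc[[2]] - center[2]; x <- cc[[3]] - center[3]
  inplane2 <- outer(y^2, x^2, "+")
  mask <- switch(kind,
    sphere = {
      r <- dimensions[1]
      checkExtent(grid, center, rep(r, 3))
      cf <- list(volume_cm3 = 4 / 3 * pi * r^3 / 1000,
                 surface_cm2 = 4 * pi * r^2 / 100)
      outer(z^2, inplane2, "+") <= r^2
    },
    box = {
      L <- dimensions[1:3]
      checkExtent(grid, center, L / 2)
      cf <- list(volume_cm3 = prod(L) / 1000,
                 surface_cm2 = 2 * (L[1] * L[2] + L[1] * L[3] + L[2] * L[3]) / 100)
      inz <- z >= -L[1] / 2 & z < L[1] / 2
      iny <- y >= -L[2] / 2 & y < L[2] / 2
      inx <- x >= -L[3] / 2 & x < L[3] / 2
      outer(inz, outer(iny, inx, "&"), "&")
    },
    cylinder = {
      r <- dimensions[1]; L <- dimensions[2]
      checkExtent(grid, center, c(L / 2, r, r))
      cf <- list(volume_cm3 = pi * r^2 * L / 1000,
                 surface_cm2 = (2 * pi * r * L + 2 * pi * r^2) / 100)
      inz <- z >= -L / 2 & z < L / 2
      outer(inz, inplane2 <= r^2, "&")
    },
    hollow_cylinder = {
      ri <- dimensions[1]; ro <- dimensions[2]; L <- dimensions[3]
      if (ri >= ro) stop("inner radius must be smaller than outer radius")
      checkExtent(grid, center, c(L / 2, ro, ro))
      cf <- list(volume_cm3 = pi * (ro^2 - ri^2) * L / 1000,
                 surface_cm2 = (2 * pi * (ri + ro) * L +
                                2 * pi * (ro^2 - ri^2)) / 100)
      inz <- z >= -L / 2 & z < L / 2
      outer(inz, inplane2 <= ro^2 & inplane2 > ri^2, "&")
    })
  out <- binaryMask(mask, grid = grid)
  attr(out, "closedForm") <- cf
  out
}

#' Closed-form volume and surface of a phantom
#'
#' @param x a [BinaryMask-class] produced by [makeSolidPhantom()].
#' @return list with `volume_cm3` and `surface_cm2`, or NULL.
#' @export
closedForm <- function(x) attr(x, "closedForm")

## Band-limited sinusoidal radial perturbation of the outer wall, as a
## function of angle; seeded and normalized to the requested amplitude.
wallPerturbation <- function(irregularity, nModes = 4L) {
  if (irregularity <= 0) return(function(theta) 0 * theta)
  m <- 2:(1 + nModes)
  a <- stats::runif(nModes, -1, 1)
  phi <- stats::runif(nModes, 0, 2 * pi)
  thetaFine <- seq(-pi, pi, length.out = 720)
  raw <- function(theta)
    colSums(a * sin(outer(m, theta) + phi))
  peak <- max(abs(raw(thetaFine)))
  if (peak == 0) return(function(theta) 0 * theta)
  function(theta) irregularity * raw(theta) / peak
}

#' Grid sized to hold an annular tumor phantom with margin
#'
#' @param lumenRadius,wallThickness,length,irregularity geometry in mm.
#' @param spacing grid spacing in mm.
#' @param margin extra physical margin in mm (default 3; must leave room
#'   for the 1 mm lumen enlargement).
#' @return an [ImageGrid-class].
#' @export
annularGrid <- function(lumenRadius, wallThickness, length, irregularity = 0,
                        spacing = c(3.0, 0.98, 0.98), margin = 3) {
  rOut <- lumenRadius + wallThickness + irregularity + margin
  nIn <- function(extent, sp) {
    n <- ceiling(extent / sp)
    if (n %% 2L == 0L) n <- n + 1L   # odd: a voxel center sits at the grid center
    as.integer(n)
  }
  imageGrid(c(nIn(length + 2 * max(spacing[1], margin), spacing[1]),
              nIn(2 * rOut, spacing[2]), nIn(2 * rOut, spacing[3])),
            spacing)
}

#' Annular (hollow-organ) tumor phantom around a cylindrical lumen
#'
#' The lumen (ITC) is a cylinder of the given radius and length; the
#' tumor (ATV) is the lumen plus an annular wall of the given thickness
#' covering the given angular fraction of the circumference, optionally
#' with a smooth seeded sinusoidal perturbation of the outer radius.
#' The lumen is contained in the tumor by construction.
#'
#' @param lumenRadius,wallThickness,length geometry in mm (> 0).
#' @param angularCoverage fraction of the circumference covered by the
#'   wall, in (0, 1].
#' @param irregularity amplitude of the outer-radius perturbation, mm.
#' @param grid target [ImageGrid-class]; defaults to [annularGrid()].
#' @param seed integer seed for the perturbation (reproducible).
#' @return a [StructureSet-class].
#' @examples
#' ss <- makeAnnularTumor(8, 10, 60, grid = annularGrid(8, 10, 60, spacing = rep(1, 3)))
#' realTumorVolume(atvMask(ss), itcMask(ss))
#' @export
makeAnnularTumor <- function(lumenRadius, wallThickness, length,
                             angularCoverage = 1, irregularity = 0,
                             grid = NULL, seed = 1L) {
  if (lumenRadius <= 0 || wallThickness <= 0 || length <= 0)
    stop("lumenRadius, wallThickness and length must be > 0")
  if (angularCoverage <= 0 || angularCoverage > 1)
    stop("angularCoverage must be in (0, 1]")
  if (irregularity < 0) stop("irregularity must be >= 0")
  if (is.null(grid))
    grid <- annularGrid(lumenRadius, wallThickness, length, irregularity)
  center <- nearestCenter(grid)
  checkExtent(grid, center,
              c(length / 2, rep(lumenRadius + wallThickness + irregularity, 2)))
  cc <- voxelCoords(grid)
  z <- cc[[1]] - center[1]; y <- cc[[2]] - center[2]; x <- cc[[3]] - center[3]
  rho <- sqrt(outer(y^2, x^2, "+"))
  theta <- atan2(outer(rep(1, grid@shape[2]), x), outer(y, rep(1, grid@shape[3])))
  inz <- z >= -length / 2 & z < length / 2
  lumen2d <- rho <= lumenRadius
  pert <- withSeed(seed, wallPerturbation(irregularity))
  rOuter <- lumenRadius + wallThickness + pmax(pert(as.numeric(theta)),
                                               -0.9 * wallThickness)
  wall2d <- rho > lumenRadius & rho <= matrix(rOuter, nrow = nrow(rho)) &
    abs(theta) <= pi * angularCoverage
  itc <- outer(inz, lumen2d, "&")
  atv <- outer(inz, lumen2d | wall2d, "&")
  structureSet(binaryMask(atv, grid = grid), binaryMask(itc, grid = grid))
}

defaultCovariateProbs <- function() {
  list(gender = c(male = 46, female = 33) / 79,
       ct = c(`2` = 11, `3` = 54, `4` = 14) / 79,
       cn = c(`0` = 11, `1` = 39, `2` = 29) / 79,
       histology = c(`non-mucinous` = 69, mucinous = 3,
                     `mucinous-feature` = 7) / 79,
       cd44v6 = c(`-` = 33, `+` = 21, `++` = 17, `+++` = 8) / 79)
}

#' Construct a CohortSpec
#'
#' Defaults emulate the published cohort: 79 patients, geometry ranges
#' chosen so the feature distribution spans the printed medians/ranges
#' (narrow collapsed lumen, wall thicker than the lumen radius), outcome
#' model equal to the published all-patient equation on coded RTV and
#' TC, and covariate stratum probabilities equal to the printed cohort
#' frequencies.
#'
#' @param nPatients cohort size (default 79).
#' @param lumenRadius,wallThickness,tumorLength,angularCoverage,irregularity
#'   min/max sampling ranges (mm; coverage a fraction).
#' @param spacing default grid spacing in mm.
#' @param trueModel named numeric (intercept, rtv, tc) of the generative
#'   logistic outcome model on the coded predictors.
#' @param covariateProbs list of per-factor stratum probabilities.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 79L,
                       lumenRadius = c(5, 7),
                       wallThickness = c(6, 20),
                       tumorLength = c(30, 100),
                       angularCoverage = c(0.6, 1),
                       irregularity = c(0, 2),
                       spacing = c(3.0, 0.98, 0.98),
                       trueModel = c(intercept = -1.705, rtv = -1.298,
                                     tc = 1.2999),
                       covariateProbs = defaultCovariateProbs()) {
  new("CohortSpec", nPatients = as.integer(nPatients),
      lumenRadius = as.numeric(lumenRadius),
      wallThickness = as.numeric(wallThickness),
      tumorLength = as.numeric(tumorLength),
      angularCoverage = as.numeric(angularCoverage),
      irregularity = as.numeric(irregularity),
      spacing = as.numeric(spacing), trueModel = trueModel,
      covariateProbs = covariateProbs)
}

runifRange <- function(n, r) stats::runif(n, r[1], r[2])

## Closed-form feature set of an ideal (zero-irregularity) annular
## phantom; used by the analytic cohort path.
analyticAnnularFeatures <- function(r, w, L, cov) {
  itc <- pi * r^2 * L / 1000
  rtv <- cov * pi * ((r + w)^2 - r^2) * L / 1000
  sAtv <- cov * 2 * pi * (r + w) * L + (1 - cov) * 2 * pi * r * L +
    2 * (cov * pi * ((r + w)^2 - r^2) + pi * r^2) +
    ifelse(cov < 1, 2 * w * L, 0)
  sItc <- 2 * pi * r * L + 2 * pi * r^2
  tsao <- sAtv * 1 / 1000          # 1 mm shell volume, cm^3
  tsai <- sItc * 1 / 1000
  tsa <- tsao + tsai
  data.frame(atv_cm3 = itc + rtv, itc_cm3 = itc, rtv_cm3 = rtv,
             tsao = tsao, tsai = tsai, tsa = tsa,
             tc = rtv / tsa^1.5,
             tml_cm = L / 10, tmd_cm = 2 * (r + w) / 10,
             true_surface_cm2 = tsa / 0.1)
}

#' Simulate a synthetic cohort of phantoms, covariates and outcomes
#'
#' Per patient: annular-tumor geometry is sampled from the spec ranges,
#' volumetric features are computed (either from full voxel phantoms or
#' from the zero-irregularity closed forms), coded into ordinal strata,
#' and the pCR outcome is drawn as Bernoulli with probability
#' `plogis(intercept + b_rtv * rtv_code + b_tc * tc_code)`. Regression
#' grade for non-pCR patients is split 2 vs 3 with probability 0.6/0.4.
#' Fully reproducible given the seed.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer seed.
#' @param method `"voxel"` (default; builds and measures voxel phantoms)
#'   or `"analytic"` (closed-form features; fast path for large
#'   Monte-Carlo studies).
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(spec, seed = 1L, method = c("voxel", "analytic")) {
  method <- match.arg(method)
  n <- spec@nPatients
  withSeed(seed, {
    geo <- data.frame(r = runifRange(n, spec@lumenRadius),
                      w = runifRange(n, spec@wallThickness),
                      L = runifRange(n, spec@tumorLength),
                      cov = runifRange(n, spec@angularCoverage),
                      irr = runifRange(n, spec@irregularity))
    pertSeeds <- if (n) sample.int(.Machine$integer.max - 1L, n) else integer(0)
    cp <- spec@covariateProbs
    clin <- data.frame(
      patient_id = if (n) sprintf("P%03d", seq_len(n)) else character(0),
      age = round(pmin(80, pmax(30, stats::rnorm(n, 58.5, 9.5))), 1),
      gender = sample(names(cp$gender), n, TRUE, cp$gender),
      ct = as.integer(sample(names(cp$ct), n, TRUE, cp$ct)),
      cn = as.integer(sample(names(cp$cn), n, TRUE, cp$cn)),
      histology = sample(names(cp$histology), n, TRUE, cp$histology),
      cea = round(stats::rlnorm(n, log(4.27), 0.85), 2),
      cd44v6 = sample(names(cp$cd44v6), n, TRUE, cp$cd44v6),
      stringsAsFactors = FALSE)
    structures <- list()
    if (method == "voxel") {
      feats <- vector("list", n)
      structures <- vector("list", n)
      for (i in seq_len(n)) {
        g <- annularGrid(geo$r[i], geo$w[i], geo$L[i], geo$irr[i],
                         spacing = spec@spacing)
        ss <- makeAnnularTumor(geo$r[i], geo$w[i], geo$L[i], geo$cov[i],
                               geo$irr[i], grid = g, seed = pertSeeds[i])
        structures[[i]] <- ss
        feats[[i]] <- as.data.frame(extractFeatures(ss))
      }
      features <- if (n) do.call(rbind, feats) else
        analyticAnnularFeatures(numeric(0), numeric(0), numeric(0), numeric(0))
    } else {
      features <- analyticAnnularFeatures(geo$r, geo$w, geo$L, geo$cov)
    }
    rownames(features) <- NULL
    rtvCode <- codeInterval(features$rtv_cm3, "rtv")
    tcCode <- codeInterval(features$tc, "tc")
    eta <- spec@trueModel["intercept"] + spec@trueModel["rtv"] * rtvCode +
      spec@trueModel["tc"] * tcCode
    p <- stats::plogis(eta)
    pcr <- stats::rbinom(n, 1L, p)
    rcrg <- ifelse(pcr == 1L, 1L,
                   ifelse(stats::runif(n) < 0.6, 2L, 3L))
    clin$rcrg <- as.integer(rcrg)
    clin$pcr <- as.integer(pcr)
    clin$true_prob <- as.numeric(p)
    new("SyntheticCohort", structures = structures, clinical = clin,
        features = features, spec = spec)
  })
}

#' @rdname accessors
#' @export
setMethod("clinicalTable", "SyntheticCohort", function(x) x@clinical)

#' @rdname accessors
#' @export
setMethod("featureTable", "SyntheticCohort", function(x) x@features)

#' Number of patients in a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @export
setMethod("length", "SyntheticCohort", function(x) nrow(x@clinical))

specAsList <- function(spec) {
  list(nPatients = spec@nPatients, lumenRadius = spec@lumenRadius,
       wallThickness = spec@wallThickness, tumorLength = spec@tumorLength,
       angularCoverage = spec@angularCoverage,
       irregularity = spec@irregularity, spacing = spec@spacing,
       trueModel = as.list(spec@trueModel),
       covariateProbs = lapply(spec@covariateProbs, as.list))
}

listAsSpec <- function(x) {
  cohortSpec(nPatients = x$nPatients, lumenRadius = unlist(x$lumenRadius),
             wallThickness = unlist(x$wallThickness),
             tumorLength = unlist(x$tumorLength),
             angularCoverage = unlist(x$angularCoverage),
             irregularity = unlist(x$irregularity),
             spacing = unlist(x$spacing),
             trueModel = unlist(x$trueModel),
             covariateProbs = lapply(x$covariateProbs, unlist))
}

#' Read a CohortSpec from a YAML configuration file
#'
#' @param path YAML file with any subset of the [cohortSpec()] fields.
#' @return a [CohortSpec-class].
#' @export
readCohortSpec <- function(path) {
  x <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("nPatients", "lumenRadius", "wallThickness", "tumorLength",
               "angularCoverage", "irregularity", "spacing"))
    if (!is.null(x[[nm]])) args[[nm]] <- unlist(x[[nm]])
  if (!is.null(x$trueModel)) args$trueModel <- unlist(x$trueModel)
  if (!is.null(x$covariateProbs))
    args$covariateProbs <- lapply(x$covariateProbs, unlist)
  do.call(cohortSpec, args)
}

maskToNifti <- function(mask) {
  arr <- aperm(array(as.integer(mask@voxels), dim(mask@voxels)), c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask@grid@spacing[c(3, 2, 1)]
  img
}

niftiToMask <- function(img) {
  sp <- RNifti::pixdim(img)[c(3, 2, 1)]
  arr <- aperm(img[, , , drop = FALSE] != 0, c(3, 2, 1))
  binaryMask(arr, grid = imageGrid(dim(arr), sp))
}

#' Write a cohort to disk (NIfTI masks + CSV tables + JSON manifest)
#'
#' One `.nii.gz` file per structure per patient (voxel spacing encoded
#' in the header), `clinical.csv` and `features.csv` tables, and a
#' `manifest.json` linking them and recording the generating spec.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  clin <- cohort@clinical
  n <- nrow(clin)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    id <- clin$patient_id[i]
    files <- c(atv = file.path(dir, paste0(id, "_atv.nii.gz")),
               itc = file.path(dir, paste0(id, "_itc.nii.gz")))
    if (length(cohort@structures) >= i && !is.null(cohort@structures[[i]])) {
      ss <- cohort@structures[[i]]
      RNifti::writeNifti(maskToNifti(ss@atv), files["atv"])
      RNifti::writeNifti(maskToNifti(ss@itc), files["itc"])
      entries[[i]] <- list(patient_id = id, atv = basename(files["atv"]),
                           itc = basename(files["itc"]))
    } else {
      entries[[i]] <- list(patient_id = id)
    }
  }
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort@features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  manifest <- list(n_patients = n, patients = entries,
                   spec = specAsList(cohort@spec))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort previously written by [writeCohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a [SyntheticCohort-class].
#' @export
readCohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath)
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character",
                                         cd44v6 = "character"))
  feats <- utils::read.csv(file.path(dir, "features.csv"))
  structures <- lapply(manifest$patients, function(e) {
    if (length(e$atv) != 1L) return(NULL)
    structureSet(niftiToMask(RNifti::readNifti(file.path(dir, e$atv))),
                 niftiToMask(RNifti::readNifti(file.path(dir, e$itc))))
  })
  if (all(vapply(structures, is.null, logical(1)))) structures <- list()
  new("SyntheticCohort", structures = structures, clinical = clin,
      features = feats, spec = listAsSpec(manifest$spec))
}
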