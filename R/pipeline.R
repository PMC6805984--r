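## End-to-end orchestration: phantoms-or-files -> volumetrics -> coding
## -> regression -> ROC, assembled into a machine-readable report whose
## sections mirror the published result tables.

featurePairList <- function() {
  list(c("atv_cm3", "rtv_cm3"), c("tml_cm", "rtv_cm3"),
       c("tmd_cm", "rtv_cm3"), c("tsa", "rtv_cm3"),
       c("tml_cm", "tc"), c("tmd_cm", "tc"), c("tsa", "tc"),
       c("atv_cm3", "tc"), c("rtv_cm3", "tc"))
}

#' Median / min-max summary of the volumetric features
#'
#' @param features feature data.frame (columns `atv_cm3 ... tmd_cm`).
#' @return data.frame with one row per parameter: `median`, `min`,
#'   `max`.
#' @export
summarizeFeatures <- function(features) {
  if (nrow(features) < 1L) stop("need at least one patient")
  cols <- intersect(c("atv_cm3", "itc_cm3", "rtv_cm3", "tsao", "tsai",
                      "tsa", "tc", "tml_cm", "tmd_cm"), names(features))
  do.call(rbind, lapply(cols, function(cl) {
    x <- features[[cl]]
    data.frame(parameter = cl, median = stats::median(x),
               min = min(x), max = max(x))
  }))
}

#' Pipeline configuration
#'
#' Either a synthetic cohort spec (`spec`) or a directory previously
#' written by [writeCohort()] (`inputDir`) must be given.
#'
#' @param spec a [CohortSpec-class] for synthetic input.
#' @param inputDir directory with masks + tables for file input.
#' @param seed integer seed driving simulation (and any other
#'   randomness).
#' @param thickness shell thickness in mm (default 1).
#' @param subgroup logical; also analyze the non-mucinous subgroup
#'   (default TRUE).
#' @param pEnter,pRemove stepwise thresholds.
#' @param vifThreshold collinearity exclusion threshold (default 10).
#' @param rocCriterion cutoff criterion (default "youden").
#' @param method feature path for simulation: "voxel" or "analytic".
#' @return a validated config (list).
#' @export
pipelineConfig <- function(spec = NULL, inputDir = NULL, seed = 1L,
                           thickness = 1, subgroup = TRUE,
                           pEnter = 0.05, pRemove = 0.10,
                           vifThreshold = 10, rocCriterion = "youden",
                           method = "voxel") {
  if (is.null(spec) && is.null(inputDir))
    stop("provide either a cohort spec or an input directory")
  if (!is.null(inputDir) && !dir.exists(inputDir))
    stop("input directory does not exist: ", inputDir)
  if (thickness <= 0) stop("thickness must be > 0")
  structure(list(spec = spec, inputDir = inputDir, seed = as.integer(seed),
                 thickness = thickness, subgroup = subgroup,
                 pEnter = pEnter, pRemove = pRemove,
                 vifThreshold = vifThreshold, rocCriterion = rocCriterion,
                 method = method),
            class = "pipelineConfig")
}

rocPanelRow <- function(name, scores, labels, criterion) {
  r <- rocPanel(scores, labels, criterion = criterion)
  data.frame(score = name, auc = r@auc, orientation = r@orientation,
             cutoff = r@cutoff, sensitivity = r@sensitivity,
             specificity = r@specificity, ppv = r@ppv, npv = r@npv)
}

## Collinearity diagnostics run on measurement-scale values: ordinal
## clinical codes plus the raw volumetric features (binning the volumes
## into five strata would mask the near-exact ATV/RTV linear dependence
## the screen exists to catch). Excluded features are then dropped from
## the coded logistic design.
vifFeatureMap <- c(atv_cm3 = "atv_code", rtv_cm3 = "rtv_code",
                   tsai = "tsai_code", tsao = "tsao_code",
                   tsa = "tsa_code", tc = "tc_code",
                   tml_cm = "tml_code", tmd_cm = "tmd_code")

analyzeCohortTables <- function(features, clinical, config) {
  codes <- codePredictors(clinical, features)
  pcr <- clinical$pcr
  out <- list(n = nrow(clinical), pcr_events = sum(pcr))
  constant <- names(codes)[vapply(codes, function(x) length(unique(x)) < 2L,
                                  logical(1))]
  if (length(constant)) {
    message("dropping constant factor(s): ", paste(constant, collapse = ", "))
    out$dropped_constant <- constant
    codes <- codes[setdiff(names(codes), constant)]
  }
  out$feature_summary <- summarizeFeatures(features)
  out$correlations <- spearmanMatrix(features, featurePairList())
  out$univariate <- univariateTable(codes, pcr)
  vifDesign <- cbind(codes[intersect(c("age_code", "gender_code", "ct_code",
                                       "cn_code", "histology_code",
                                       "cea_code", "cd44v6_code"),
                                     names(codes))],
                     features[names(vifFeatureMap)])
  out$collinearity <- vifScreen(vifDesign, threshold = config$vifThreshold)
  keptCodes <- vapply(out$collinearity$kept, function(nm) {
    if (nm %in% names(vifFeatureMap)) vifFeatureMap[[nm]] else nm
  }, character(1))
  design <- codes[unname(keptCodes)]
  out$multivariate <- forwardStepwiseLogistic(design, pcr,
                                              pEnter = config$pEnter,
                                              pRemove = config$pRemove)
  out$multivariate$fit <- NULL   # keep the report serializable
  ## published-equation evaluation and ROC panels
  zs <- c("Z1", "Z2", "Z3", "Z4")
  zProbs <- lapply(zs, function(nm) {
    m <- publishedModel(nm)
    vcode <- codes[[m@volumeTerm]]
    evaluatePublishedModel(m, vcode, codes$tc_code)
  })
  names(zProbs) <- zs
  panels <- list()
  for (nm in zs)
    panels[[nm]] <- rocPanelRow(nm, zProbs[[nm]], pcr, config$rocCriterion)
  for (feat in c("atv_cm3", "rtv_cm3", "tml_cm", "tc", "tsa"))
    panels[[feat]] <- rocPanelRow(feat, features[[feat]], pcr,
                                  config$rocCriterion)
  out$roc <- do.call(rbind, panels)
  rownames(out$roc) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, computes volumetric features, codes
#' predictors, runs the correlation / univariate / collinearity /
#' stepwise-multivariate / calibration pipeline, evaluates the published
#' equations, and assembles ROC panels. Identical config + seed gives an
#' identical report.
#'
#' @param config a [pipelineConfig()].
#' @return an `analysisReport` (list) with sections `cohort`,
#'   `feature_summary`, `correlations`, `univariate`, `collinearity`,
#'   `multivariate`, `roc`, optional `non_mucinous`, and `provenance`.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(spec = cohortSpec(nPatients = 40L), seed = 7,
#'                       method = "analytic")
#' rep <- runPipeline(cfg)
#' rep$feature_summary
#' }
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "pipelineConfig")) stop("need a pipelineConfig")
  stage <- "input"
  report <- tryCatch({
    cohort <- if (!is.null(config$inputDir)) readCohort(config$inputDir)
              else simulateCohort(config$spec, seed = config$seed,
                                  method = config$method)
    message("stage input: ", length(cohort), " patients")
    stage <- "analysis"
    full <- analyzeCohortTables(cohort@features, cohort@clinical, config)
    out <- list(cohort = list(n = length(cohort),
                              pcr_events = sum(cohort@clinical$pcr)))
    out <- c(out, full[setdiff(names(full), c("n", "pcr_events"))])
    if (isTRUE(config$subgroup)) {
      stage <- "subgroup"
      sub <- subsetNonMucinous(cohort)
      message("stage subgroup: ", length(cohort), " -> ", length(sub),
              " non-mucinous patients")
      if (length(sub) > 0 && sum(sub@clinical$pcr) > 0 &&
          sum(sub@clinical$pcr) < length(sub)) {
        out$non_mucinous <- analyzeCohortTables(sub@features, sub@clinical,
                                                config)
      } else {
        out$non_mucinous <- list(skipped = "subgroup degenerate: one outcome class")
      }
    }
    out$provenance <- list(
      seed = config$seed, method = config$method,
      thickness = config$thickness,
      pEnter = config$pEnter, pRemove = config$pRemove,
      vifThreshold = config$vifThreshold,
      package = as.character(utils::packageVersion("pcrvol")))
    class(out) <- "analysisReport"
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  report
}

#' Write an analysis report to JSON (+ per-table CSV exports)
#'
#' @param report an `analysisReport` from [runPipeline()].
#' @param dir output directory.
#' @return invisibly, the JSON path.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  for (nm in c("feature_summary", "correlations", "univariate", "roc")) {
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(path)
}
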