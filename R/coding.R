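## Ordinal stratum coding of clinical values and volumetric features.
##
## Intervals follow the printed "> a and <= b" pattern: every bin above
## the first is left-open/right-closed, the first bin is closed at its
## upper bound, and the last is open above. The printed age strata leave
## gaps for fractional ages (e.g. between 40 and 41); they are repaired
## to the contiguous intervals <=40, (40,50], (50,60], (60,70], >70 so
## the coding is total on the non-negative reals while preserving the
## printed integer behavior.

codingBreaks <- list(
  age = c(40, 50, 60, 70),
  tml = c(5, 8, 11),
  tmd = c(3, 5, 7),
  atv = c(35, 70, 105, 140),
  rtv = c(35, 70, 105, 140),
  tsai = c(2, 4, 6),
  tsao = c(10, 20, 30),
  tsa = c(10, 20, 30),
  tc = c(1, 1.5, 2, 2.5),
  cea = 5)

#' Map a non-negative value to its ordinal stratum code
#'
#' @param x numeric values (>= 0 for volumetric features).
#' @param what one of `"age"`, `"tml"`, `"tmd"`, `"atv"`, `"rtv"`,
#'   `"tsai"`, `"tsao"`, `"tsa"`, `"tc"`, `"cea"`.
#' @return integer codes starting at 1 (first stratum).
#' @examples
#' codeInterval(1.21, "tc")   # 2
#' codeInterval(1.0, "tc")    # boundary belongs to the lower stratum
#' @export
codeInterval <- function(x, what) {
  br <- codingBreaks[[what]]
  if (is.null(br)) stop("unknown coding factor: ", what)
  if (!what %in% c("age") && any(x < 0, na.rm = TRUE))
    stop("negative value for '", what, "'")
  as.integer(cut(x, c(-Inf, br, Inf), right = TRUE))
}

#' Binarize a CD44v6 immunohistochemistry score
#'
#' Low expression comprises the '-' and '+' staining scores (code 0);
#' high expression comprises '++' and '+++' (code 1).
#'
#' @param score character vector with values in `-`, `+`, `++`, `+++`.
#' @return integer 0 (low) / 1 (high).
#' @export
binarizeCD44v6 <- function(score) {
  ok <- score %in% c("-", "+", "++", "+++")
  if (any(!ok)) stop("unknown CD44v6 score: ", paste(score[!ok], collapse = ", "))
  as.integer(score %in% c("++", "+++"))
}

histologyCode <- function(histology) {
  h <- tolower(histology)
  out <- integer(length(h))
  nonMuc <- grepl("non-?mucinous", h)
  muc <- !nonMuc & grepl("mucinous", h)
  if (any(!nonMuc & !muc))
    stop("unrecognized histology: ",
         paste(unique(histology[!nonMuc & !muc]), collapse = ", "))
  out[muc] <- 1L
  out
}

#' Code volumetric features into their ordinal strata
#'
#' @param features a [VolumetricFeatures-class] or a data.frame with
#'   columns `tml_cm`, `tmd_cm`, `atv_cm3`, `rtv_cm3`, `tsai`, `tsao`,
#'   `tsa`, `tc`.
#' @return data.frame of integer columns `tml_code ... tc_code`.
#' @export
codeVolumetric <- function(features) {
  if (is(features, "VolumetricFeatures"))
    features <- as.data.frame(features)
  data.frame(tml_code = codeInterval(features$tml_cm, "tml"),
             tmd_code = codeInterval(features$tmd_cm, "tmd"),
             atv_code = codeInterval(features$atv_cm3, "atv"),
             rtv_code = codeInterval(features$rtv_cm3, "rtv"),
             tsai_code = codeInterval(features$tsai, "tsai"),
             tsao_code = codeInterval(features$tsao, "tsao"),
             tsa_code = codeInterval(features$tsa, "tsa"),
             tc_code = codeInterval(features$tc, "tc"))
}

#' Code clinical covariates into their ordinal strata
#'
#' Age is coded into five decade strata, gender male = 1 / female = 2,
#' cT 2/3/4 to 1/2/3, cN kept as 0/1/2, histology 0 for non-mucinous
#' adenocarcinoma and 1 for mucinous adenocarcinoma or adenocarcinoma
#' with mucinous features, CEA dichotomized at the 5 ng/ml clinical
#' reference, and CD44v6 binarized into low/high expression.
#'
#' @param record data.frame with columns `age`, `gender`, `ct`, `cn`,
#'   `histology`, `cea`, `cd44v6` (one row per patient).
#' @return data.frame of integer columns `age_code ... cd44v6_code`.
#' @export
codeClinical <- function(record) {
  if (!all(record$gender %in% c("male", "female")))
    stop("gender must be 'male' or 'female'")
  if (!all(record$ct %in% 2:4)) stop("cT must be in 2..4")
  if (!all(record$cn %in% 0:2)) stop("cN must be in 0..2")
  if (any(record$cea < 0)) stop("CEA must be >= 0")
  data.frame(age_code = codeInterval(record$age, "age"),
             gender_code = ifelse(record$gender == "male", 1L, 2L),
             ct_code = as.integer(record$ct) - 1L,
             cn_code = as.integer(record$cn),
             histology_code = histologyCode(record$histology),
             cea_code = codeInterval(record$cea, "cea"),
             cd44v6_code = binarizeCD44v6(record$cd44v6))
}

#' Full 15-factor coded predictor table
#'
#' Binds the clinical and volumetric codings into the design table used
#' by all regression models, in the printed factor order.
#'
#' @param clinical clinical data.frame (see [codeClinical()]).
#' @param features feature data.frame (see [codeVolumetric()]).
#' @return data.frame of the 15 `_code` columns.
#' @export
codePredictors <- function(clinical, features) {
  cbind(codeClinical(clinical), codeVolumetric(features))
}

#' Restrict a cohort to non-mucinous adenocarcinoma patients
#'
#' Drops patients with mucinous adenocarcinoma or adenocarcinoma with
#' mucinous features (histology code 1).
#'
#' @param cohort a [SyntheticCohort-class], or a clinical data.frame
#'   with a `histology` column.
#' @return the filtered object, same class as the input.
#' @export
subsetNonMucinous <- function(cohort) {
  if (is(cohort, "SyntheticCohort")) {
    keep <- histologyCode(cohort@clinical$histology) == 0L
    if (!any(keep)) warning("no non-mucinous patients remain")
    new("SyntheticCohort",
        structures = if (length(cohort@structures))
          cohort@structures[keep] else list(),
        clinical = cohort@clinical[keep, , drop = FALSE],
        features = cohort@features[keep, , drop = FALSE],
        spec = cohort@spec)
  } else {
    keep <- histologyCode(cohort$histology) == 0L
    if (!any(keep)) warning("no non-mucinous patients remain")
    cohort[keep, , drop = FALSE]
  }
}
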