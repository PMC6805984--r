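#' @describeIn imageGrid display method
#' @param object an ImageGrid
#' @export
setMethod("show", "ImageGrid", function(object) {
  cat("ImageGrid:", paste(object@shape, collapse = " x "),
      "voxels;", paste(object@spacing, collapse = " x "), "mm\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask on", paste(object@grid@shape, collapse = " x "),
      "grid (", paste(object@grid@spacing, collapse = " x "), "mm ):",
      sum(object@voxels), "member voxels,",
      sprintf("%.3f cm^3\n", maskVolume(object)))
})

setMethod("show", "StructureSet", function(object) {
  cat("StructureSet\n  ATV:", sum(object@atv@voxels), "voxels (",
      sprintf("%.2f cm^3", maskVolume(object@atv)), ")\n  ITC:",
      sum(object@itc@voxels), "voxels (",
      sprintf("%.2f cm^3", maskVolume(object@itc)), ")\n")
})

setMethod("show", "VolumetricFeatures", function(object) {
  df <- as.data.frame(object)
  cat("VolumetricFeatures\n")
  print(round(unlist(df), 4))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nPatients, "patients\n",
      " lumen radius", paste(object@lumenRadius, collapse = "-"), "mm,",
      "wall", paste(object@wallThickness, collapse = "-"), "mm,",
      "length", paste(object@tumorLength, collapse = "-"), "mm\n",
      " outcome model: logit(p) =",
      sprintf("%.4g %+.4g*rtv_code %+.4g*tc_code\n",
              object@trueModel["intercept"], object@trueModel["rtv"],
              object@trueModel["tc"]))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@clinical), "patients,",
      sum(object@clinical$pcr), "pCR events;",
      if (length(object@structures)) "voxel structures attached"
      else "analytic features only", "\n")
})

setMethod("show", "PublishedModel", function(object) {
  cat(sprintf("PublishedModel %s (%s cohort): logit(p) = %.4g %+.4g*%s %+.4g*tc_code\n",
              object@name, object@cohort, object@intercept,
              object@volumeCoef, object@volumeTerm, object@tcCoef))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC %.3f (%s orientation)", object@auc,
              object@orientation))
  if (is.finite(object@cutoff))
    cat(sprintf("; cutoff %.4g: se %.3f sp %.3f ppv %.3f npv %.3f",
                object@cutoff, object@sensitivity, object@specificity,
                object@ppv, object@npv))
  cat("\n")
})
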