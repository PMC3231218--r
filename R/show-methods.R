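setMethod("show", "OpticalSetup", function(object) {
  cat("OpticalSetup:", object@dims[1], "x", object@dims[2], "grid\n")
  cat("  wavelength:", object@wavelength * 1e9, "nm;  pixel pitch:",
      paste(object@pixelPitch * 1e6, collapse = " x "), "um\n")
  cat("  default distance:", object@distance * 1e6, "um\n")
})

setMethod("show", "ComplexField", function(object) {
  cat("ComplexField:", nrow(object@values), "x", ncol(object@values),
      "complex values at z =", object@planeZ * 1e6, "um\n")
  cat("  amplitude range: [", format(min(Mod(object@values)), digits = 4),
      ",", format(max(Mod(object@values)), digits = 4), "]\n")
})

setMethod("show", "PhaseObject", function(object) {
  cat("PhaseObject <", object@classLabel, ">: ",
      sum(object@support), " support pixels\n", sep = "")
  ph <- object@phaseMap[object@support]
  cat("  phase (rad): mean", format(mean(ph), digits = 4),
      " sd", format(stats::sd(ph), digits = 4), "\n")
})

setMethod("show", "Hologram", function(object) {
  cat("Hologram:", nrow(object@intensity), "x", ncol(object@intensity),
      "; A_r =", object@refAmplitude, "\n")
  if (!is.null(object@meta$weakObjectRatio))
    cat("  weak-object ratio max|A_h|/A_r =",
        format(object@meta$weakObjectRatio, digits = 4), "\n")
})

setMethod("show", "TargetMask", function(object) {
  cat("TargetMask:", object@nPixels, "pixels on the", object@channel,
      "channel\n")
})

setMethod("show", "SamplingSegment", function(object) {
  cat("SamplingSegment: n =", object@n, "from the", object@channel,
      "channel of '", object@sourceId, "'\n")
})

setMethod("show", "VarianceRatioResult", function(object) {
  cat("Variance-ratio (F) test:\n")
  cat("  F =", format(object@statistic, digits = 5),
      " df = (", object@dof[1], ",", object@dof[2], ")",
      " p =", format(object@pValue, digits = 4),
      " [", object@pMode, "]\n")
  cat("  acceptance interval: [",
      format(object@acceptInterval[1], digits = 4), ",",
      format(object@acceptInterval[2], digits = 4), "] at alpha =",
      object@alpha, "->", object@decision, "\n")
})

setMethod("show", "EcdfTestResult", function(object) {
  cat("ECDF discriminant test:\n")
  cat("  Lambda =", format(object@statistic, digits = 5),
      " null size =", length(object@nullStatistics),
      " p =", format(object@pValue, digits = 4),
      " ->", object@decision, "\n")
})

setMethod("show", "RocResult", function(object) {
  cat("ROC:", length(object@thresholds), "thresholds, AUC =",
      format(object@auc, digits = 5),
      if (!is.na(object@n)) paste0("(n = ", object@n, ")") else "", "\n")
})

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig:", length(object@classes), "classes (",
      paste(vapply(object@classes, `[[`, "", "label"), collapse = ", "),
      ")\n")
  cat("  n =", object@n, " m =", object@m, " alpha =", object@alpha,
      " tests:", paste(object@tests, collapse = "+"), "\n")
  cat("  sample sizes:", paste(object@sampleSizes, collapse = ", "),
      " seed =", object@seed, "\n")
})
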