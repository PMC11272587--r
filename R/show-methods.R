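setMethod("show", "AgeGrid", function(object) {
  cat("AgeGrid:", object@nBins, "bins of", object@binWidth,
      "yr spanning 0 -", object@maxAge, "yr\n")
})

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig '", object@name, "'\n", sep = "")
  cat("  challenge mix P1..P4:",
      paste(signif(object@challengeMix, 3), collapse = " "), "\n")
  cat("  competence:", object@competenceForm,
      "| cooperation:", object@cooperationForm, "\n")
  cat("  costs (MJ kg-1 yr-1): Bb", object@Bb, "Br", object@Br,
      "Bs", object@Bs, "\n")
  cat("  grid:", object@grid@nBins, "bins x", object@grid@binWidth, "yr\n")
})

setMethod("show", "Genotype", function(object) {
  cat("Genotype:", nrow(object@efforts), "age bins x 3 growth efforts",
      "(y_b, y_r, y_s)\n")
  cat("  effort range:",
      paste(signif(range(object@efforts), 3), collapse = " .. "), "\n")
})

setMethod("show", "Phenotype", function(object) {
  n <- nrow(object@traits)
  aAd <- .adultBin(object@grid)
  cat("Phenotype over", n, "age bins (", object@grid@binWidth, "yr )\n")
  cat("  at", object@grid@ages[aAd], "yr: brain",
      signif(object@traits[aAd, 1], 4), "kg, follicles",
      signif(object@traits[aAd, 2], 4), "kg, body",
      signif(sum(object@traits[aAd, 1:3]), 4), "kg, skill",
      signif(object@traits[aAd, 4], 4), "TB\n")
})

setMethod("show", "EvoTrajectory", function(object) {
  n <- length(object@tau)
  cat("EvoTrajectory:", n, "records, tau", object@tau[1], "-",
      object@tau[n], "\n")
  d <- object@diagnostics
  cat("  adult brain:", signif(d$adultBrain_kg[1], 3), "->",
      signif(d$adultBrain_kg[n], 3), "kg; adult body:",
      signif(d$adultBody_kg[1], 3), "->", signif(d$adultBody_kg[n], 3),
      "kg\n")
  cat("  scenarios:", paste(unique(object@scenarioNames), collapse = " -> "),
      "\n")
})

setMethod("show", "SurveyResult", function(object) {
  cat("SurveyResult: n =", object@n, "( seed", object@seed, ")\n")
  cat("  non-failed fraction:", signif(object@nonFailedFraction, 4), "\n")
  cat("  log-log allometry among non-failed: slope",
      signif(object@slope, 4), ", R2", signif(object@r2, 4), "\n")
})
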