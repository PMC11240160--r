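#' @rdname ReferencePanel-class
setMethod("dosages", "ReferencePanel", function(x) x@dosages)
#' @rdname Cohort-class
setMethod("dosages", "Cohort", function(x) x@dosages)

#' @rdname ReferencePanel-class
setMethod("variantInfo", "ReferencePanel", function(x) x@variants)
#' @rdname Cohort-class
setMethod("variantInfo", "Cohort", function(x) x@variants)

#' @rdname ReferencePanel-class
setMethod("nVariants", "ReferencePanel", function(x) ncol(x@dosages))
#' @rdname Cohort-class
setMethod("nVariants", "Cohort", function(x) ncol(x@dosages))

#' @rdname ReferencePanel-class
setMethod("nIndividuals", "ReferencePanel", function(x) nrow(x@dosages))
#' @rdname Cohort-class
setMethod("nIndividuals", "Cohort", function(x) nrow(x@dosages))

#' @rdname Cohort-class
setMethod("covariates", "Cohort", function(x) x@covariates)
#' @rdname Cohort-class
setMethod("phenotypes", "Cohort", function(x) x@pheno)
#' @rdname Cohort-class
setMethod("fractureEvents", "Cohort", function(x) x@events)
#' @rdname Cohort-class
setMethod("discoveryFlag", "Cohort", function(x) x@discovery)

#' @rdname ShapeAnnotation-class
setMethod("landmarks", "ShapeAnnotation", function(x) x@points)
#' @rdname ShapeAnnotation-class
setMethod("pixelSpacing", "ShapeAnnotation",
          function(x) c(x = x@spacingX, y = x@spacingY))

#' @rdname InstrumentSet-class
setMethod("instrumentData", "InstrumentSet", function(x) x@data)

setMethod("show", "ShapeAnnotation", function(object) {
  cat("ShapeAnnotation: 85 landmarks, pixel spacing (",
      object@spacingX, ", ", object@spacingY, ") mm/px\n", sep = "")
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "variants,",
      length(unique(object@block)), "LD blocks (rho =", object@rho, ")\n")
})

setMethod("show", "CausalArchitecture", function(object) {
  cat("CausalArchitecture:",
      sum(object@fnwEffects != 0), "FNW /",
      sum(object@bmdEffects != 0), "FN-BMD causal variants;",
      length(object@sharedInverseIds), "shared inverse,",
      length(object@sharedPositiveIds), "shared positive;",
      "target FNW variance", object@targetFnwVariance, "\n")
})

setMethod("show", "Cohort", function(object) {
  ev <- object@events
  cat("Cohort:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "variants; follow-up", object@followupYr, "yr\n")
  for (s in c("hip_any", "fn", "trochanteric", "forearm"))
    cat(sprintf("  %-12s %5d incident, %4d prevalent\n", s,
                sum(ev[[paste0("event_", s)]]),
                sum(ev[[paste0("prevalent_", s)]])))
  cat("  discovery subsample:", sum(object@discovery), "\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet:", nrow(object@data), "instruments;",
      "exposure(s):", paste(object@exposureNames, collapse = " + "),
      "-> outcome:", object@outcomeName, "\n")
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s] %s: estimate %.4f (se %.4f), OR %.3f (95%% CI %.3f-%.3f)\n",
              object@method, object@exposure, object@estimate, object@se,
              object@or, exp(object@ciLow), exp(object@ciHigh)))
  cat(sprintf("  Q = %.2f (p = %.3g), %s effects, %d SNPs\n",
              object@cochranQ, object@qP, object@effectsModel,
              as.integer(object@nSnps)))
  if (!is.na(object@eggerIntercept))
    cat(sprintf("  Egger intercept %.4f (p = %.3g)\n",
                object@eggerIntercept, object@eggerInterceptP))
  if (length(object@outliersRemoved))
    cat("  outliers removed:", paste(object@outliersRemoved, collapse = ", "),
        "\n")
})

#' Convert an MRResult to a one-row data.frame
#'
#' @param x an MRResult.
#' @param row.names,optional,... ignored, present for the generic.
#' @return one-row data.frame with the estimate, CI, OR, heterogeneity and
#'   bookkeeping columns.
#' @export
as.data.frame.MRResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(method = x@method, exposure = x@exposure, estimate = x@estimate,
             se = x@se, ci_low = x@ciLow, ci_high = x@ciHigh, or = x@or,
             or_ci_low = exp(x@ciLow), or_ci_high = exp(x@ciHigh),
             cochran_q = x@cochranQ, q_p = x@qP,
             effects_model = x@effectsModel,
             egger_intercept = x@eggerIntercept,
             egger_intercept_p = x@eggerInterceptP,
             n_snps = x@nSnps,
             outliers_removed = paste(x@outliersRemoved, collapse = ";"),
             stringsAsFactors = FALSE)
}
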