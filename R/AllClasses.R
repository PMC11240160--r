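#' @import methods
NULL

#' ShapeAnnotation: an 85-point proximal femur landmark set
#'
#' Holds one hip image's landmark annotation: 85 ordered (x, y) points in
#' image pixel coordinates (x rightward, y downward) together with the pixel
#' spacing needed to convert to millimetres. Point indices are 1-based;
#' points 6-12 trace the inferior femoral neck contour and points 32-38 the
#' superior contour.
#'
#' @slot points numeric 85 x 2 matrix of (x, y) pixel coordinates.
#' @slot spacingX mm per pixel along x (DICOM column spacing).
#' @slot spacingY mm per pixel along y (DICOM row spacing).
#' @export
setClass("ShapeAnnotation",
  representation(points = "matrix", spacingX = "numeric", spacingY = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@points) || ncol(object@points) != 2L)
      msg <- c(msg, "points must be a numeric matrix with 2 columns")
    if (nrow(object@points) != 85L)
      msg <- c(msg, sprintf("annotation must have exactly 85 points, got %d",
                            nrow(object@points)))
    if (length(object@spacingX) != 1L || !is.finite(object@spacingX) ||
        object@spacingX <= 0)
      msg <- c(msg, "spacingX must be a single positive number")
    if (length(object@spacingY) != 1L || !is.finite(object@spacingY) ||
        object@spacingY <= 0)
      msg <- c(msg, "spacingY must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' ReferencePanel: dosage matrix plus variant metadata for LD computation
#'
#' Individuals x variants allele-dosage matrix (values in [0, 2]) with
#' per-variant metadata (id, chromosome, position, effect/other allele,
#' frequency, imputation INFO) and the LD-block structure used to generate
#' it. Dosage columns within a block are correlated; blocks are independent.
#'
#' @slot dosages numeric matrix, individuals x variants, entries in [0, 2].
#' @slot variants data.frame with columns snp, chr, pos, ea, oa, eaf, info.
#' @slot block integer vector, block index per variant.
#' @slot rho within-block latent autoregressive correlation.
#' @export
setClass("ReferencePanel",
  representation(dosages = "matrix", variants = "data.frame",
                 block = "integer", rho = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("snp", "chr", "pos", "ea", "oa", "eaf", "info")
    if (!all(need %in% names(object@variants)))
      msg <- c(msg, paste("variants must have columns:",
                          paste(need, collapse = ", ")))
    if (ncol(object@dosages) != nrow(object@variants))
      msg <- c(msg, "dosage columns must match variant rows")
    if (length(object@block) != nrow(object@variants))
      msg <- c(msg, "block must have one entry per variant")
    rng <- range(object@dosages)
    if (rng[1] < 0 || rng[2] > 2)
      msg <- c(msg, "dosages must lie in [0, 2]")
    if ("pos" %in% names(object@variants)) {
      bychr <- split(object@variants$pos, object@variants$chr)
      if (!all(vapply(bychr, function(p) all(diff(p) > 0), logical(1))))
        msg <- c(msg, "positions must be strictly increasing within chromosome")
    }
    if (length(msg)) msg else TRUE
  })

#' CausalArchitecture: ground-truth genetic model for the two bone traits
#'
#' Per-variant causal effects on standardized femoral neck width (FNW) and
#' femoral neck BMD, the identities of variants shared between the traits
#' (mostly with opposite signs; an "LRP5-like" minority with the same sign),
#' the fraction of FNW variance the causal set should explain, and per-site
#' log hazard ratios per SD of each trait used to generate fracture
#' outcomes.
#'
#' @slot variantIds ids of causal variants (union over both traits).
#' @slot fnwEffects named numeric, per-variant effect on FNW (SD units).
#' @slot bmdEffects named numeric, per-variant effect on FN-BMD (SD units).
#' @slot sharedInverseIds variants affecting both traits with opposite sign.
#' @slot sharedPositiveIds variants affecting both traits with the same sign.
#' @slot targetFnwVariance fraction of FNW variance from the causal set.
#' @slot logHr named list with elements fnw and bmd, each a named numeric
#'   over sites hip_any, fn, trochanteric, forearm: log hazard ratio per SD.
#' @export
setClass("CausalArchitecture",
  representation(variantIds = "character", fnwEffects = "numeric",
                 bmdEffects = "numeric", sharedInverseIds = "character",
                 sharedPositiveIds = "character",
                 targetFnwVariance = "numeric", logHr = "list"),
  validity = function(object) {
    msg <- character()
    v <- object@targetFnwVariance
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      msg <- c(msg, "targetFnwVariance must lie in (0, 1)")
    sites <- c("hip_any", "fn", "trochanteric", "forearm")
    for (tr in c("fnw", "bmd")) {
      if (is.null(object@logHr[[tr]]) ||
          !all(sites %in% names(object@logHr[[tr]])))
        msg <- c(msg, sprintf("logHr$%s must name sites %s", tr,
                              paste(sites, collapse = ", ")))
    }
    if (!all(names(object@fnwEffects) %in% object@variantIds) ||
        !all(names(object@bmdEffects) %in% object@variantIds))
      msg <- c(msg, "effect names must be a subset of variantIds")
    if (length(msg)) msg else TRUE
  })

#' Cohort: individual-level data for association and survival analyses
#'
#' Dosages, covariates (sex, age, genotyping chip, 20 ancestry PCs,
#' anthropometry), the two bone phenotypes, per-site fracture events with
#' follow-up times and prevalent flags, and a discovery-subsample flag
#' marking individuals used for the FNW association scan (excluded from
#' genetic-risk-score survival analyses).
#'
#' @slot dosages numeric matrix, individuals x variants.
#' @slot variants variant metadata as in \linkS4class{ReferencePanel}.
#' @slot covariates data.frame: sex (0/1), age, chip, pc1..pc20, height,
#'   weight, bmi.
#' @slot pheno data.frame: fnw_mm, fnw_sd, bmd_sd.
#' @slot events data.frame with, per site s in hip_any/fn/trochanteric/
#'   forearm, columns event_s (0/1 incident), time_s (years, in
#'   (0, followup]), prevalent_s (0/1 event before baseline).
#' @slot discovery logical, membership in the FNW GWAS discovery subsample.
#' @slot followupYr administrative censoring horizon (years).
#' @export
setClass("Cohort",
  representation(dosages = "matrix", variants = "data.frame",
                 covariates = "data.frame", pheno = "data.frame",
                 events = "data.frame", discovery = "logical",
                 followupYr = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@dosages)
    if (nrow(object@covariates) != n || nrow(object@pheno) != n ||
        nrow(object@events) != n || length(object@discovery) != n)
      msg <- c(msg, "all components must cover the same individuals")
    sites <- c("hip_any", "fn", "trochanteric", "forearm")
    need <- c(paste0("event_", sites), paste0("time_", sites),
              paste0("prevalent_", sites))
    if (!all(need %in% names(object@events)))
      msg <- c(msg, "events must have event_/time_/prevalent_ per site")
    else {
      for (s in sites) {
        tt <- object@events[[paste0("time_", s)]]
        if (any(tt <= 0 | tt > object@followupYr + 1e-9))
          msg <- c(msg, sprintf("time_%s must lie in (0, followup]", s))
      }
      caseOf <- function(s) object@events[[paste0("event_", s)]] |
        object@events[[paste0("prevalent_", s)]]
      imp <- caseOf("fn") | caseOf("trochanteric")
      if (any(imp & !caseOf("hip_any")))
        msg <- c(msg, "fn and trochanteric events must imply hip_any")
    }
    if (length(msg)) msg else TRUE
  })

#' InstrumentSet: harmonized exposure-outcome effect table
#'
#' One row per genetic instrument after allele harmonization: exposure
#' effect gamma and its SE, outcome effect Gamma (log odds) and its SE,
#' optionally a second exposure, all expressed for a common effect allele.
#'
#' @slot data data.frame with columns snp, ea, oa, eaf, beta_exp, se_exp,
#'   beta_out, se_out and optionally beta_exp2, se_exp2.
#' @slot exposureNames character, one or two exposure labels.
#' @slot outcomeName outcome label.
#' @slot nExp,nOut,nExp2 sample sizes of the source association scans.
#' @export
setClass("InstrumentSet",
  representation(data = "data.frame", exposureNames = "character",
                 outcomeName = "character", nExp = "numeric",
                 nOut = "numeric", nExp2 = "numeric"),
  prototype(nExp = NA_real_, nOut = NA_real_, nExp2 = NA_real_),
  validity = function(object) {
    msg <- character()
    need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
    if (!all(need %in% names(object@data)))
      msg <- c(msg, paste("instrument data must have columns:",
                          paste(need, collapse = ", ")))
    else {
      if (anyDuplicated(object@data$snp))
        msg <- c(msg, "duplicate instrument snp ids")
      if (any(object@data$se_exp <= 0) || any(object@data$se_out <= 0))
        msg <- c(msg, "all standard errors must be positive")
    }
    if (length(msg)) msg else TRUE
  })

#' MRResult: one causal-effect estimate
#'
#' @slot method estimator label (ivw, egger, weighted_median, lasso, mvmr).
#' @slot exposure exposure label.
#' @slot estimate log odds of outcome per SD of exposure.
#' @slot se standard error of the estimate.
#' @slot ciLow,ciHigh 95\% confidence limits (estimate +/- 1.96 se).
#' @slot or exp(estimate), odds ratio per SD.
#' @slot cochranQ,qP heterogeneity statistic and its p-value.
#' @slot effectsModel "fixed" or "random".
#' @slot eggerIntercept,eggerInterceptP directional-pleiotropy test
#'   (Egger only, NA otherwise).
#' @slot nSnps number of instruments used.
#' @slot outliersRemoved instrument ids removed (LASSO only).
#' @export
setClass("MRResult",
  representation(method = "character", exposure = "character",
                 estimate = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", or = "numeric",
                 cochranQ = "numeric", qP = "numeric",
                 effectsModel = "character", eggerIntercept = "numeric",
                 eggerInterceptP = "numeric", nSnps = "numeric",
                 outliersRemoved = "character"),
  prototype(eggerIntercept = NA_real_, eggerInterceptP = NA_real_,
            outliersRemoved = character()))
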