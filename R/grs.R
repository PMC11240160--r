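#' Weighted genetic risk score
#'
#' score_i = sum_j w_j dosage_ij after aligning each variant's dosage to
#' the score's effect allele (dosage is flipped to 2 - dosage when the
#' effect allele is the cohort's other allele), then standardized to mean 0
#' and SD 1 over the analysis sample.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param variant_ids,weights,effect_alleles parallel vectors defining the
#'   score (unique ids, finite weights).
#' @param subset optional logical vector: the analysis sample over which
#'   the score is standardized (default everyone). The returned vector
#'   covers the whole cohort but is centred/scaled on the subset.
#' @return standardized numeric score of length \code{nIndividuals}.
#' @export
computeGrs <- function(cohort, variant_ids, weights, effect_alleles,
                       subset = NULL) {
  stopifnot(length(variant_ids) == length(weights),
            length(variant_ids) == length(effect_alleles))
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids in score")
  if (!all(is.finite(weights))) stop("weights must be finite")
  v <- variantInfo(cohort)
  idx <- match(variant_ids, v$snp)
  if (anyNA(idx))
    stop("score variants absent from cohort: ",
         paste(variant_ids[is.na(idx)], collapse = ", "))
  dos <- dosages(cohort)[, idx, drop = FALSE]
  for (k in seq_along(idx)) {
    if (effect_alleles[k] == v$ea[idx[k]]) next
    if (effect_alleles[k] == v$oa[idx[k]]) dos[, k] <- 2 - dos[, k]
    else stop("effect allele ", effect_alleles[k], " matches neither allele",
              " of ", variant_ids[k])
  }
  score <- drop(dos %*% weights)
  if (is.null(subset)) subset <- rep(TRUE, length(score))
  mu <- mean(score[subset]); sdv <- stats::sd(score[subset])
  if (!is.finite(sdv) || sdv < 1e-12) stop("zero score variance")
  (score - mu) / sdv
}

.siteSurv <- function(cohort, site, exclude_discovery) {
  ev <- fractureEvents(cohort)
  keep <- ev[[paste0("prevalent_", site)]] == 0       # incident-only design
  if (exclude_discovery) keep <- keep & !discoveryFlag(cohort)
  list(keep = keep,
       time = ev[[paste0("time_", site)]],
       event = ev[[paste0("event_", site)]])
}

#' Proportional-hazards fit for incident fracture
#'
#' Cox partial-likelihood fit (Efron tie handling) of incident events at
#' one site on the supplied model terms. Prevalent cases (events before
#' baseline) are always excluded; by default the FNW discovery subsample is
#' excluded too, so the risk-score weights and the survival analysis come
#' from disjoint samples. Terms may reference covariates (sex, age, bmi,
#' height, weight), any vector supplied through \code{scores}, and product
#' interactions written "a:b".
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param site fracture site label.
#' @param terms character vector of model terms, e.g.
#'   c("grs_fnw", "sex", "age") or c("grs_fnw", "sex", "age",
#'   "grs_fnw:age").
#' @param scores named list of full-cohort-length numeric vectors
#'   referenced by \code{terms} (e.g. standardized risk scores).
#' @param exclude_discovery drop the discovery subsample (default TRUE).
#' @param subset optional additional logical restriction.
#' @return list of class \code{"SurvivalFit"}: \code{terms} data.frame
#'   (term, coef, se, hr, ci_low, ci_high, p), \code{n}, \code{n_events},
#'   \code{site}, and the underlying \code{coxph} fit.
#' @export
coxFit <- function(cohort, site, terms, scores = list(),
                   exclude_discovery = TRUE, subset = NULL) {
  sv <- .siteSurv(cohort, site, exclude_discovery)
  keep <- sv$keep
  if (!is.null(subset)) keep <- keep & subset
  df <- covariates(cohort)[c("sex", "age", "bmi", "height", "weight")]
  for (nm in names(scores)) df[[nm]] <- scores[[nm]]
  df <- df[keep, , drop = FALSE]
  df$.time <- sv$time[keep]
  df$.event <- sv$event[keep]
  if (sum(df$.event) == 0) stop("no events at site ", site)
  if (sum(df$.event) < 10) stop("fewer than 10 events at site ", site)
  main <- terms[!grepl(":", terms)]
  inter <- terms[grepl(":", terms)]
  for (tm in inter) {
    pr <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(pr %in% main))
      stop("interaction ", tm, " requires both main effects in terms")
  }
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) || any(!is.finite(fit$coefficients)))
    stop("Cox model did not converge at site ", site)
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(term = rownames(co), coef = co[, "coef"],
                    se = co[, "se(coef)"], hr = exp(co[, "coef"]),
                    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(terms = tab, n = nrow(df), n_events = sum(df$.event),
                 site = site, fit = fit), class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat("SurvivalFit [", x$site, "]: ", x$n, " individuals, ",
      x$n_events, " events\n", sep = "")
  print(x$terms, digits = 4)
  invisible(x)
}

#' Interaction test with stratified fits
#'
#' Adds a product interaction term to the base Cox model and reports its
#' Wald test, alongside the two stratified fits obtained by splitting on
#' the second interacting variable (at \code{age_split} years when that
#' variable is age, otherwise at its median).
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param site fracture site.
#' @param interaction character pair, e.g. c("grs_fnw", "age") or
#'   c("grs_fnw", "grs_bmd").
#' @param scores named list of score vectors (full cohort length).
#' @param covars additional main-effect covariates (default sex and age).
#' @param age_split split point in years for age-stratified fits (default
#'   71.7, the median age at hip fracture; use "median" to recompute from
#'   the data).
#' @param exclude_discovery drop the discovery subsample (default TRUE).
#' @return list: coef, se, p of the product term; \code{stratified}, a list
#'   of two SurvivalFit objects (below/above the split).
#' @export
testInteraction <- function(cohort, site, interaction, scores = list(),
                            covars = c("sex", "age"), age_split = 71.7,
                            exclude_discovery = TRUE) {
  stopifnot(length(interaction) == 2L)
  main <- unique(c(interaction, covars))
  term <- paste(interaction, collapse = ":")
  full <- coxFit(cohort, site, c(main, term), scores,
                 exclude_discovery = exclude_discovery)
  row <- full$terms[full$terms$term == term, ]
  if (nrow(row) == 0L)
    stop("interaction term ", term, " dropped from fit (collinear?)")

  splitvar <- interaction[2]
  vals <- if (splitvar %in% names(scores)) scores[[splitvar]]
          else covariates(cohort)[[splitvar]]
  cut <- if (identical(age_split, "median") || splitvar != "age")
    stats::median(vals) else age_split
  strat_terms <- setdiff(main, splitvar)
  lo <- coxFit(cohort, site, strat_terms, scores,
               exclude_discovery = exclude_discovery, subset = vals <= cut)
  hi <- coxFit(cohort, site, strat_terms, scores,
               exclude_discovery = exclude_discovery, subset = vals > cut)
  list(coef = row$coef, se = row$se, p = row$p, split_at = cut,
       stratified = list(below = lo, above = hi), fit = full)
}

#' Binarize two risk scores into four additive-risk groups
#'
#' High FNW risk = top \code{cutoff_pct}\% of the FNW score; high
#' low-BMD risk = bottom \code{cutoff_pct}\% of the BMD score. Groups:
#' 1 = no/no (reference), 2 = yes/no, 3 = no/yes, 4 = yes/yes. The
#' partition is exhaustive and disjoint.
#'
#' @param score_fnw,score_bmd standardized score vectors of equal length.
#' @param cutoff_pct one of 50, 25, 10 (other values need
#'   \code{allow_other = TRUE} and warn).
#' @param allow_other permit non-standard cutoffs.
#' @return list: \code{group} (integer 1-4), \code{cutoff_pct},
#'   \code{definitions}.
#' @export
binarizeGroups <- function(score_fnw, score_bmd, cutoff_pct = 50,
                           allow_other = FALSE) {
  if (length(score_fnw) != length(score_bmd))
    stop("scores must have equal length")
  if (!cutoff_pct %in% c(50, 25, 10)) {
    if (!allow_other) stop("cutoff_pct must be one of 50, 25, 10")
    warning("non-standard cutoff ", cutoff_pct, "%")
  }
  q <- cutoff_pct / 100
  high_fnw <- score_fnw >= stats::quantile(score_fnw, 1 - q, names = FALSE)
  low_bmd <- score_bmd <= stats::quantile(score_bmd, q, names = FALSE)
  group <- 1L + high_fnw * 1L + low_bmd * 2L
  list(group = group, cutoff_pct = cutoff_pct,
       definitions = c(`1` = "no high FNW / no low BMD",
                       `2` = "high FNW / no low BMD",
                       `3` = "no high FNW / low BMD",
                       `4` = "high FNW / low BMD"))
}

#' Hazard ratios of the binarized risk groups
#'
#' Cox fit of incident events at one site on indicators for groups 2-4
#' versus group 1 (no/no), with sex and baseline age as base covariates.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param groups result of \code{\link{binarizeGroups}} (full cohort
#'   length).
#' @param site fracture site.
#' @param exclude_discovery drop the discovery subsample (default TRUE).
#' @return a SurvivalFit whose group terms are named group2..group4.
#' @export
groupHazardRatios <- function(cohort, groups, site,
                              exclude_discovery = TRUE) {
  g <- groups$group
  sv <- .siteSurv(cohort, site, exclude_discovery)
  for (k in 1:4) {
    if (sum(sv$event[sv$keep & g == k]) < 1)
      stop("no events in group ", k)
  }
  scores <- list(group2 = as.numeric(g == 2L),
                 group3 = as.numeric(g == 3L),
                 group4 = as.numeric(g == 4L))
  coxFit(cohort, site, c("group2", "group3", "group4", "sex", "age"),
         scores, exclude_discovery = exclude_discovery)
}
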