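#' Build the sex-stratified standardized FNW analysis phenotype
#'
#' Within each sex, femoral neck width (mm) is regressed on age, genotyping
#' chip and the first 20 ancestry principal components by least squares;
#' the residuals are standardized (mean 0, SD 1) per sex and recombined in
#' cohort order into a single quantitative outcome.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @return numeric vector of length \code{nIndividuals(cohort)}.
#' @export
preparePhenotype <- function(cohort) {
  covs <- covariates(cohort)
  y <- phenotypes(cohort)$fnw_mm
  need <- c("sex", "age", "chip", paste0("pc", 1:20))
  miss <- setdiff(need, names(covs))
  if (length(miss))
    stop("missing covariates: ", paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(covs[need]) | !is.finite(y)
  if (any(bad))
    stop("missing covariate or phenotype values for individuals: ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  out <- numeric(length(y))
  for (s in unique(covs$sex)) {
    idx <- covs$sex == s
    X <- cbind(1, as.matrix(covs[idx, c("age", "chip", paste0("pc", 1:20))]))
    r <- stats::lm.fit(X, y[idx])$residuals
    if (stats::sd(r) < 1e-10)
      stop("zero residual variance within sex ", s)
    out[idx] <- (r - mean(r)) / stats::sd(r)
  }
  out
}

#' Per-variant quantitative association scan
#'
#' Simple least-squares regression of the prepared phenotype on each allele
#' dosage (with intercept). Variants failing the minor-allele-frequency or
#' imputation-quality filters, and monomorphic variants, are excluded and
#' counted in the \code{"filtered"} attribute of the result.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param phenotype numeric vector aligned to the cohort (see
#'   \code{\link{preparePhenotype}}).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param info_min variants kept require INFO strictly greater than this
#'   (default 0.3).
#' @param subset optional logical vector restricting the analysis sample
#'   (e.g. the discovery subsample).
#' @return summary-statistic data.frame (snp, chr, pos, ea, oa, eaf, beta,
#'   se, p, n, info) with attribute \code{filtered}: named counts of
#'   exclusions.
#' @export
runQuantGwas <- function(cohort, phenotype, maf_min = 0.01, info_min = 0.3,
                         subset = NULL) {
  dos <- dosages(cohort)
  v <- variantInfo(cohort)
  if (length(phenotype) != nrow(dos))
    stop("phenotype must align with the cohort")
  if (!is.null(subset)) {
    dos <- dos[subset, , drop = FALSE]
    phenotype <- phenotype[subset]
  }
  n <- nrow(dos)
  eaf_emp <- colMeans(dos) / 2
  maf <- pmin(eaf_emp, 1 - eaf_emp)
  xc <- sweep(dos, 2L, colMeans(dos))
  sxx <- colSums(xc^2)
  keep <- maf >= maf_min & v$info > info_min & sxx > 0
  filtered <- c(maf = sum(maf < maf_min),
                info = sum(v$info <= info_min),
                monomorphic = sum(sxx == 0 & maf >= maf_min))
  yc <- phenotype - mean(phenotype)
  syy <- sum(yc^2)
  sxy <- drop(crossprod(xc, yc))
  beta <- sxy / pmax(sxx, 1e-300)
  rss <- syy - beta * sxy
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / pmax(sxx, 1e-300))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  out <- data.frame(snp = v$snp, chr = v$chr, pos = v$pos, ea = v$ea,
                    oa = v$oa, eaf = eaf_emp, beta = beta, se = se, p = p,
                    n = n, info = v$info,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filtered") <- filtered
  out
}

#' Per-variant binary association scan for a fracture site
#'
#' Logistic regression of case status on allele dosage adjusted for age and
#' sex, one variant at a time. Case status is the incident event at the
#' requested site, plus prevalent cases when \code{include_prevalent} is
#' TRUE. Records with detected complete separation (or otherwise unusable
#' standard errors) are flagged \code{usable = FALSE} so downstream steps
#' can exclude them.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param event_site one of "hip_any", "fn", "trochanteric", "forearm".
#' @param include_prevalent include pre-baseline cases (default TRUE).
#' @param maf_min,info_min variant filters as in \code{\link{runQuantGwas}}.
#' @param variants optional variant ids to restrict the scan to.
#' @param subset optional logical vector restricting the sample.
#' @return summary-statistic data.frame with additional columns n_cases and
#'   usable; beta is the log odds per effect-allele copy.
#' @export
runBinaryGwas <- function(cohort, event_site,
                          include_prevalent = TRUE,
                          maf_min = 0.01, info_min = 0.3,
                          variants = NULL, subset = NULL) {
  stopifnot(event_site %in% c("hip_any", "fn", "trochanteric", "forearm"))
  ev <- fractureEvents(cohort)
  y <- ev[[paste0("event_", event_site)]]
  if (include_prevalent)
    y <- as.integer(y | ev[[paste0("prevalent_", event_site)]])
  covs <- covariates(cohort)
  dos <- dosages(cohort)
  v <- variantInfo(cohort)
  if (!is.null(variants)) {
    idx <- match(variants, v$snp)
    if (anyNA(idx))
      stop("variants absent from cohort: ",
           paste(variants[is.na(idx)], collapse = ", "))
    dos <- dos[, idx, drop = FALSE]
    v <- v[idx, , drop = FALSE]
  }
  keep_ind <- if (is.null(subset)) rep(TRUE, nrow(dos)) else subset
  y <- y[keep_ind]
  dos <- dos[keep_ind, , drop = FALSE]
  age <- covs$age[keep_ind]; sex <- covs$sex[keep_ind]
  if (sum(y) < 10) stop("fewer than 10 cases at site ", event_site)

  eaf_emp <- colMeans(dos) / 2
  maf <- pmin(eaf_emp, 1 - eaf_emp)
  keep <- maf >= maf_min & v$info > info_min
  res <- data.frame(snp = v$snp, chr = v$chr, pos = v$pos, ea = v$ea,
                    oa = v$oa, eaf = eaf_emp,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n = length(y), n_cases = sum(y), info = v$info,
                    usable = FALSE, stringsAsFactors = FALSE)
  base <- cbind(1, age, sex)
  for (j in which(keep)) {
    X <- cbind(base, dos = dos[, j])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    p <- ncol(X)
    Rq <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    Rq[lower.tri(Rq)] <- 0
    cv <- tryCatch(chol2inv(Rq), error = function(e) NULL)
    if (is.null(cv)) next
    b <- fit$coefficients[p]
    s <- sqrt(cv[p, p])
    ok <- is.finite(b) && is.finite(s) && s < 100 && abs(b) < 15
    res$beta[j] <- b
    res$se[j] <- s
    res$p[j] <- 2 * stats::pnorm(-abs(b / s))
    res$usable[j] <- ok
  }
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
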