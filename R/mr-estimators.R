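## Two-sample MR estimators. Throughout, gamma = instrument-exposure effect
## (SD units), Gamma = instrument-outcome effect (log odds), theta_j =
## Gamma_j / gamma_j the per-instrument Wald ratio, and w_j =
## gamma_j^2 / se(Gamma_j)^2 the inverse-variance weight (first-order delta
## method: se(theta_j) = se(Gamma_j) / |gamma_j|, ignoring se(gamma)).

.mrResult <- function(method, exposure, estimate, se, q = NA_real_,
                      qp = NA_real_, model = "fixed",
                      egger_int = NA_real_, egger_int_p = NA_real_,
                      n_snps = NA_real_, outliers = character()) {
  new("MRResult", method = method, exposure = exposure,
      estimate = estimate, se = se,
      ciLow = estimate - 1.96 * se, ciHigh = estimate + 1.96 * se,
      or = exp(estimate), cochranQ = q, qP = qp, effectsModel = model,
      eggerIntercept = egger_int, eggerInterceptP = egger_int_p,
      nSnps = n_snps, outliersRemoved = outliers)
}

.dropZeroGamma <- function(d, which = "beta_exp") {
  z <- d[[which]] == 0
  if (any(z)) {
    warning("excluding ", sum(z), " instrument(s) with zero exposure effect")
    d <- d[!z, , drop = FALSE]
  }
  d
}

#' Wald ratio for a single instrument
#'
#' theta = Gamma / gamma with first-order delta-method standard error
#' se(Gamma) / |gamma|.
#'
#' @param gamma,se_gamma exposure effect and SE (SE unused by the
#'   first-order SE but kept for the record).
#' @param Gamma,se_Gamma outcome effect and SE.
#' @return list(estimate, se).
#' @export
waldRatio <- function(gamma, se_gamma, Gamma, se_Gamma) {
  if (gamma == 0) stop("zero exposure effect")
  list(estimate = Gamma / gamma, se = se_Gamma / abs(gamma))
}

#' Inverse-variance-weighted MR
#'
#' Combines per-instrument Wald ratios with weights gamma^2 / se(Gamma)^2
#' (equivalent to zero-intercept weighted regression of Gamma on gamma).
#' Fixed-effects SE is 1 / sqrt(sum w). Cochran's Q over the ratios is
#' tested against chi-squared with J - 1 df; when its p-value is below
#' 0.05 a multiplicative random-effects model scales the SE by
#' sqrt(Q / (J - 1)), never below the fixed-effects SE.
#'
#' @param instr an \linkS4class{InstrumentSet} (>= 2 usable instruments).
#' @param exposure 1 or 2: which exposure column to use.
#' @return an \linkS4class{MRResult}.
#' @export
mrIvw <- function(instr, exposure = 1) {
  gcol <- if (exposure == 1) "beta_exp" else "beta_exp2"
  d <- .dropZeroGamma(instr@data, gcol)
  J <- nrow(d)
  if (J < 2) stop("IVW requires at least 2 instruments")
  g <- d[[gcol]]
  th <- d$beta_out / g
  w <- g^2 / d$se_out^2
  est <- sum(w * th) / sum(w)
  se_f <- 1 / sqrt(sum(w))
  Q <- sum(w * (th - est)^2)
  qp <- stats::pchisq(Q, df = J - 1, lower.tail = FALSE)
  model <- "fixed"; se <- se_f
  if (qp < 0.05) {
    model <- "random"
    se <- se_f * max(1, sqrt(Q / (J - 1)))
  }
  .mrResult("ivw", instr@exposureNames[min(exposure,
                                           length(instr@exposureNames))],
            est, se, Q, qp, model, n_snps = J)
}

#' MR-Egger regression
#'
#' Weighted regression of Gamma on gamma with an intercept (weights
#' 1 / se(Gamma)^2), after orienting all rows so gamma >= 0. The slope is
#' the causal estimate; the intercept and its p-value index directional
#' horizontal pleiotropy. Multiplicative random-effects scaling as in IVW
#' (df = J - 2).
#'
#' @param instr an \linkS4class{InstrumentSet} (>= 3 instruments).
#' @return an \linkS4class{MRResult}.
#' @export
mrEgger <- function(instr) {
  d <- instr@data
  if (nrow(d) < 3) stop("Egger regression requires at least 3 instruments")
  flip <- sign(d$beta_exp)
  flip[flip == 0] <- 1
  g <- d$beta_exp * flip
  G <- d$beta_out * flip
  w <- 1 / d$se_out^2
  X <- cbind(1, g)
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  coefs <- unname(drop(V %*% (XtW %*% G)))
  resid <- G - drop(X %*% coefs)
  J <- nrow(d)
  Q <- sum(w * resid^2)
  qp <- stats::pchisq(Q, df = J - 2, lower.tail = FALSE)
  infl <- 1
  model <- "fixed"
  if (qp < 0.05) {
    model <- "random"
    infl <- max(1, sqrt(Q / (J - 2)))
  }
  se <- sqrt(diag(V)) * infl
  int_p <- 2 * stats::pnorm(-abs(coefs[1] / se[1]))
  .mrResult("egger", instr@exposureNames[1], coefs[2], se[2], Q, qp, model,
            egger_int = coefs[1], egger_int_p = int_p, n_snps = J)
}

#' Weighted median MR
#'
#' Orders the Wald ratios and interpolates the ratio at cumulative
#' normalized weight 0.5, using s_j = (sum_{k<=j} w_k - w_j / 2) / sum w.
#' Consistent when at least half the weight comes from valid instruments.
#' The SE is a parametric bootstrap resampling (gamma_j, Gamma_j) from
#' their normal sampling distributions.
#'
#' @param instr an \linkS4class{InstrumentSet} (>= 3 instruments).
#' @param n_boot bootstrap draws (default 5000, minimum 100).
#' @param seed integer seed for the bootstrap.
#' @return an \linkS4class{MRResult}.
#' @export
mrWeightedMedian <- function(instr, n_boot = 5000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  d <- .dropZeroGamma(instr@data)
  if (nrow(d) < 3) stop("weighted median requires at least 3 instruments")
  wm <- function(g, G, se_out) {
    th <- G / g
    w <- g^2 / se_out^2
    o <- order(th)
    th <- th[o]; w <- w[o]
    s <- (cumsum(w) - w / 2) / sum(w)
    stats::approx(s, th, xout = 0.5, rule = 2)$y
  }
  est <- wm(d$beta_exp, d$beta_out, d$se_out)
  set.seed(seed)
  J <- nrow(d)
  boots <- vapply(seq_len(n_boot), function(i) {
    gb <- stats::rnorm(J, d$beta_exp, d$se_exp)
    Gb <- stats::rnorm(J, d$beta_out, d$se_out)
    gb[gb == 0] <- 1e-12
    wm(gb, Gb, d$se_out)
  }, numeric(1))
  .mrResult("weighted_median", instr@exposureNames[1], est,
            stats::sd(boots), n_snps = J)
}

#' MR-LASSO outlier-robust estimate
#'
#' Fits Gamma_j = theta gamma_j + alpha_j with an L1 penalty on the
#' per-instrument intercepts alpha_j (weights 1 / se(Gamma)^2; theta
#' unpenalized). The tuning parameter is chosen by the heterogeneity
#' stopping rule: walking the penalty path from large to small, the
#' largest lambda whose retained set (alpha_j = 0) yields an IVW Cochran Q
#' p-value of at least 0.05. Instruments with nonzero intercepts at that
#' lambda are reported as outliers and the final estimate is IVW on the
#' retained set. With a homogeneous instrument set the penalty never
#' activates and the estimate equals plain IVW.
#'
#' @param instr an \linkS4class{InstrumentSet} (>= 4 instruments).
#' @return an \linkS4class{MRResult}.
#' @export
mrLasso <- function(instr) {
  d <- .dropZeroGamma(instr@data)
  J <- nrow(d)
  if (J < 4) stop("MR-LASSO requires at least 4 instruments")
  ivwOn <- function(keep) {
    sub <- instr
    sub@data <- d[keep, , drop = FALSE]
    mrIvw(sub)
  }
  qpOf <- function(keep) {
    g <- d$beta_exp[keep]; th <- d$beta_out[keep] / g
    w <- g^2 / d$se_out[keep]^2
    est <- sum(w * th) / sum(w)
    Q <- sum(w * (th - est)^2)
    stats::pchisq(Q, df = sum(keep) - 1, lower.tail = FALSE)
  }
  all_keep <- rep(TRUE, J)
  if (qpOf(all_keep) >= 0.05) {             # lambda -> infinity limit
    res <- ivwOn(all_keep)
    return(.mrResult("lasso", instr@exposureNames[1], res@estimate, res@se,
                     res@cochranQ, res@qP, res@effectsModel, n_snps = J))
  }
  w <- 1 / d$se_out^2
  X <- cbind(d$beta_exp, diag(J))
  fit <- glmnet::glmnet(X, d$beta_out, weights = w, intercept = FALSE,
                        standardize = FALSE,
                        penalty.factor = c(0, rep(1, J)),
                        nlambda = 200, lambda.min.ratio = 1e-4)
  alphas <- as.matrix(fit$beta[-1, , drop = FALSE])  # J x nlambda
  chosen <- NULL
  for (k in seq_len(ncol(alphas))) {        # lambda descending
    keep <- alphas[, k] == 0
    if (sum(keep) < 2) break
    if (qpOf(keep) >= 0.05) { chosen <- keep; break }
  }
  if (is.null(chosen) || sum(chosen) < 3)
    stop("fewer than 3 instruments retained; LASSO not advisable here")
  res <- ivwOn(chosen)
  .mrResult("lasso", instr@exposureNames[1], res@estimate, res@se,
            res@cochranQ, res@qP, res@effectsModel,
            n_snps = sum(chosen), outliers = d$snp[!chosen])
}

#' Multivariable MR
#'
#' Zero-intercept weighted regression of the outcome effects on both
#' exposure effect columns (weights 1 / se(Gamma)^2), giving each
#' exposure's causal effect conditional on the other. Cochran's Q uses
#' J - 2 df; multiplicative random-effects SE scaling as in IVW.
#'
#' @param instr an \linkS4class{InstrumentSet} with a second exposure
#'   (>= 3 instruments).
#' @return list of two \linkS4class{MRResult} objects, one per exposure.
#' @export
mrMvmr <- function(instr) {
  d <- instr@data
  if (is.null(d$beta_exp2)) stop("mrMvmr needs a second exposure")
  J <- nrow(d)
  if (J < 3) stop("MVMR requires at least 3 instruments")
  nm <- rep_len(instr@exposureNames, 2L)
  X <- cbind(d$beta_exp, d$beta_exp2)
  # a degenerate all-zero exposure column drops out of the fit; its result
  # is NA and the other exposure reduces to its univariable regression
  active <- which(colSums(X != 0) > 0)
  if (length(active) == 0L) stop("both exposure effect columns are zero")
  Xa <- X[, active, drop = FALSE]
  if (qr(Xa)$rank < length(active))
    stop("rank-deficient design: exposures ",
         paste(nm, collapse = " and "), " are collinear")
  w <- 1 / d$se_out^2
  XtW <- t(Xa * w)
  V <- solve(XtW %*% Xa)
  coefs_a <- drop(V %*% (XtW %*% d$beta_out))
  resid <- d$beta_out - drop(Xa %*% coefs_a)
  df <- J - length(active)
  Q <- sum(w * resid^2)
  qp <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  infl <- 1; model <- "fixed"
  if (qp < 0.05) {
    model <- "random"
    infl <- max(1, sqrt(Q / df))
  }
  ses_a <- sqrt(diag(V)) * infl
  coefs <- ses <- rep(NA_real_, 2L)
  coefs[active] <- coefs_a
  ses[active] <- ses_a
  list(.mrResult("mvmr", nm[1], coefs[1], ses[1], Q, qp, model, n_snps = J),
       .mrResult("mvmr", nm[2], coefs[2], ses[2], Q, qp, model, n_snps = J))
}
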