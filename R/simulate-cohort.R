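#' Construct a causal architecture for the two bone traits
#'
#' Builds the ground-truth genetic model the cohort simulator consumes:
#' \code{n_fnw} variants affecting femoral neck width and \code{n_bmd}
#' affecting femoral neck BMD, with \code{n_shared_inverse} variants
#' affecting both traits with opposite signs and \code{n_shared_positive}
#' "LRP5-like" variants affecting both with the same sign. Effects are
#' expressed per SD of dosage (standardized-genotype scale) and scaled so
#' the theoretical variance explained — the sum of squared effects for an
#' unlinked causal set — equals \code{target_fnw_variance} (resp.
#' \code{target_bmd_variance}). Causal
#' variants are placed at most one per LD block so they are mutually
#' unlinked. Per-site log hazard ratios per SD of each trait default to the
#' pattern in which wider necks raise hip and femoral-neck fracture hazard
#' but not trochanteric or forearm hazard, while higher BMD lowers hazard
#' at every site.
#'
#' @param panel a \linkS4class{ReferencePanel} supplying variant ids and
#'   frequencies.
#' @param n_fnw,n_bmd causal set sizes (defaults 71 and 49).
#' @param n_shared_inverse,n_shared_positive overlap sizes (defaults 12, 1).
#' @param target_fnw_variance,target_bmd_variance fractions of trait
#'   variance explained by each causal set.
#' @param log_hr named list with numeric elements \code{fnw} and \code{bmd},
#'   each naming sites hip_any, fn, trochanteric, forearm.
#' @param seed integer seed.
#' @return a \linkS4class{CausalArchitecture}.
#' @export
simulateArchitecture <- function(panel, n_fnw = 71, n_bmd = 49,
                                 n_shared_inverse = 12,
                                 n_shared_positive = 1,
                                 target_fnw_variance = 0.076,
                                 target_bmd_variance = 0.10,
                                 log_hr = NULL, seed = 1) {
  if (is.null(log_hr))
    log_hr <- list(
      fnw = c(hip_any = log(1.5), fn = log(1.6),
              trochanteric = 0, forearm = 0),
      bmd = c(hip_any = log(0.45), fn = log(0.45),
              trochanteric = log(0.55), forearm = log(0.70)))
  set.seed(seed)
  v <- variantInfo(panel)
  blocks <- panel@block
  n_shared <- n_shared_inverse + n_shared_positive
  n_total <- n_fnw + n_bmd - n_shared
  one_per_block <- vapply(split(seq_len(nrow(v)), blocks), `[`, 1L, 1L)
  if (length(one_per_block) < n_total)
    stop("panel has too few LD blocks for the requested causal sets")
  pick <- sort(sample(one_per_block, n_total))
  ids <- v$snp[pick]
  eaf <- v$eaf[pick]
  names(eaf) <- ids
  fnw_ids <- ids[seq_len(n_fnw)]
  shared_ids <- ids[seq_len(n_shared)]
  bmd_ids <- c(shared_ids, ids[seq.int(n_fnw + 1L, length.out = n_bmd - n_shared)])
  shared_pos <- shared_ids[seq_len(n_shared_positive)]
  shared_inv <- setdiff(shared_ids, shared_pos)

  # effects act on standardized dosages, so the variance contributed by an
  # unlinked causal set is simply the sum of squared effects
  scale_to <- function(beta, target) beta * sqrt(target / sum(beta^2))
  b_fnw <- stats::rnorm(n_fnw); names(b_fnw) <- fnw_ids
  b_bmd <- stats::rnorm(n_bmd); names(b_bmd) <- bmd_ids
  b_bmd[shared_inv] <- -sign(b_fnw[shared_inv]) * abs(b_bmd[shared_inv])
  b_bmd[shared_pos] <- sign(b_fnw[shared_pos]) * abs(b_bmd[shared_pos])
  b_fnw <- scale_to(b_fnw, target_fnw_variance)
  b_bmd <- scale_to(b_bmd, target_bmd_variance)

  new("CausalArchitecture", variantIds = ids, fnwEffects = b_fnw,
      bmdEffects = b_bmd, sharedInverseIds = shared_inv,
      sharedPositiveIds = shared_pos,
      targetFnwVariance = target_fnw_variance, logHr = log_hr)
}

## FNW in mm per sex: UKB-scale means/SDs (males 34.6 (2.4), females 29.0 (2.0))
.fnwMmDefaults <- list(male = c(mean = 34.6, sd = 2.4),
                       female = c(mean = 29.0, sd = 2.0))

#' Simulate an individual-level cohort with fracture follow-up
#'
#' Draws \code{n} individuals from the panel's genotype-generating process
#' and builds: a standardized FNW liability equal to the causal genetic
#' value (variance \code{targetFnwVariance} of the architecture) plus a
#' body-size factor, an age effect and Gaussian noise scaled so the total
#' variance is 1; FNW in mm via per-sex means and SDs; an analogous
#' standardized FN-BMD; and per-site fracture times from an exponential
#' proportional-hazards model with log-hazard
#' \code{log_hr_fnw * FNW_sd + log_hr_bmd * BMD_sd}. Times are drawn over a
#' window starting \code{prevalent_window_yr} before baseline: events
#' before baseline are prevalent, events within \code{followup_yr} after
#' baseline are incident, later times are administratively censored.
#' hip_any is the union of femoral-neck and trochanteric events (its time
#' the earlier of the two), so fn or trochanteric events always imply
#' hip_any. A stated fraction is flagged as the GWAS discovery subsample.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param arch a \linkS4class{CausalArchitecture}; all its variants must be
#'   in the panel.
#' @param n cohort size (>= 100).
#' @param followup_yr censoring horizon after baseline (default 15.5).
#' @param seed integer seed.
#' @param discovery_fraction fraction flagged as discovery subsample.
#' @param prevalent_window_yr years of pre-baseline event capture.
#' @param baseline_hazard named per-year baseline hazards for sites fn,
#'   trochanteric, forearm.
#' @param body_size_loading loading of the shared body-size factor on
#'   standardized FNW.
#' @param age_effect effect of standardized age on standardized FNW.
#' @param fnw_mm_pars list with elements male/female, each c(mean, sd), mm.
#' @return a \linkS4class{Cohort}.
#' @export
simulateCohort <- function(panel, arch, n, followup_yr = 15.5, seed = 1,
                           discovery_fraction = 0.1,
                           prevalent_window_yr = 5,
                           baseline_hazard = c(fn = 8e-4,
                                               trochanteric = 5e-4,
                                               forearm = 1.5e-3),
                           body_size_loading = 0.3,
                           age_effect = 0.1,
                           fnw_mm_pars = .fnwMmDefaults) {
  if (n < 100) stop("n must be >= 100")
  v <- variantInfo(panel)
  miss <- setdiff(arch@variantIds, v$snp)
  if (length(miss))
    stop("causal variants absent from panel: ", paste(miss, collapse = ", "))
  set.seed(seed)
  dos <- .simulateDosages(n, v$eaf, panel@block, panel@rho)
  colnames(dos) <- v$snp

  std <- function(ids) {
    z <- dos[, ids, drop = FALSE]
    z <- sweep(z, 2L, colMeans(z))
    sd <- sqrt(colMeans(z^2))
    sweep(z, 2L, pmax(sd, 1e-12), `/`)
  }
  g_fnw <- if (length(arch@fnwEffects))
    drop(std(names(arch@fnwEffects)) %*% arch@fnwEffects) else numeric(n)
  g_bmd <- if (length(arch@bmdEffects))
    drop(std(names(arch@bmdEffects)) %*% arch@bmdEffects) else numeric(n)

  sex <- stats::rbinom(n, 1L, 0.48)               # 1 = male
  age_z <- stats::rnorm(n)
  age <- ifelse(sex == 1L, 64.5, 63.1) + 7.5 * age_z
  u <- stats::rnorm(n)                            # shared body-size factor
  height <- ifelse(sex == 1L, 177.3 + 6.6 * (0.6 * u + sqrt(1 - 0.36) * stats::rnorm(n)),
                              163.7 + 6.3 * (0.6 * u + sqrt(1 - 0.36) * stats::rnorm(n)))
  weight <- ifelse(sex == 1L, 83.3 + 13.4 * (0.5 * u + sqrt(1 - 0.25) * stats::rnorm(n)),
                              68.2 + 12.8 * (0.5 * u + sqrt(1 - 0.25) * stats::rnorm(n)))
  bmi <- weight / (height / 100)^2
  pcs <- matrix(stats::rnorm(n * 20L), n, 20L,
                dimnames = list(NULL, paste0("pc", 1:20)))
  chip <- stats::rbinom(n, 1L, 0.5)

  vg <- arch@targetFnwVariance
  noise_var <- 1 - vg - body_size_loading^2 - age_effect^2
  if (noise_var <= 0)
    stop("targetFnwVariance + loadings leave no room for noise variance")
  fnw_sd <- g_fnw + body_size_loading * u + age_effect * age_z +
    stats::rnorm(n, 0, sqrt(noise_var))
  vb <- sum(arch@bmdEffects^2)
  bmd_sd <- g_bmd + stats::rnorm(n, 0, sqrt(max(1 - vb, 1e-6)))

  mp <- fnw_mm_pars
  fnw_mm <- ifelse(sex == 1L,
                   mp$male["mean"] + mp$male["sd"] * fnw_sd,
                   mp$female["mean"] + mp$female["sd"] * fnw_sd)

  sites <- c("fn", "trochanteric", "forearm")
  ev <- data.frame(row.names = seq_len(n))
  lat <- list()
  for (s in sites) {
    lp <- arch@logHr$fnw[[s]] * fnw_sd + arch@logHr$bmd[[s]] * bmd_sd
    h <- baseline_hazard[[s]] * exp(lp)
    lat[[s]] <- stats::rexp(n, rate = pmax(h, 1e-12))
  }
  lat$hip_any <- pmin(lat$fn, lat$trochanteric)
  for (s in c("hip_any", sites)) {
    tt <- lat[[s]]
    prev <- tt <= prevalent_window_yr
    inc <- !prev & tt <= prevalent_window_yr + followup_yr
    time <- ifelse(prev, followup_yr,
                   pmin(tt - prevalent_window_yr, followup_yr))
    ev[[paste0("event_", s)]] <- as.integer(inc)
    ev[[paste0("time_", s)]] <- time
    ev[[paste0("prevalent_", s)]] <- as.integer(prev)
  }

  covs <- data.frame(sex = sex, age = age, chip = chip, pcs,
                     height = height, weight = weight, bmi = bmi)
  pheno <- data.frame(fnw_mm = as.numeric(fnw_mm), fnw_sd = fnw_sd,
                      bmd_sd = bmd_sd)
  disc <- seq_len(n) %in% sample.int(n, round(discovery_fraction * n))
  new("Cohort", dosages = dos, variants = v, covariates = covs,
      pheno = pheno, events = ev, discovery = disc, followupYr = followup_yr)
}
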