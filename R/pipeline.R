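#' Default pipeline configuration
#'
#' Desk-scale settings for the end-to-end chain. The causal sets are
#' smaller than the full architecture (their total variance explained is
#' unchanged) so that a few thousand individuals suffice for genome-wide
#' significant discovery; the thresholds block carries every filter the
#' association, pruning and risk-group stages use.
#'
#' @return nested named list; see the fields of the returned object.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    panel = list(n_individuals = 800, n_variants = 2000, block_size = 10,
                 within_block_rho = 0.8, eaf_min = 0.05, eaf_max = 0.5),
    architecture = list(n_fnw = 10, n_bmd = 8, n_shared_inverse = 3,
                        n_shared_positive = 1, target_fnw_variance = 0.076,
                        target_bmd_variance = 0.10),
    cohort = list(n = 12000, followup_yr = 15.5, discovery_fraction = 0.5,
                  prevalent_window_yr = 5),
    annotations = list(n = 25, pixel_spacing = 0.5, jitter_sd = 0.1),
    thresholds = list(p_gws = 5e-8, maf_min = 0.01, info_min = 0.3,
                      prune_r2 = 0.01, collinearity_r2 = 0.9,
                      palindrome_maf_max = 0.42, cutoffs = c(50, 25, 10)),
    ldsc = list(window_kb = 1000, maf_min = 0.05, n_blocks = 50),
    mr = list(sites = c("hip_any", "fn", "trochanteric", "forearm"),
              n_boot = 1000),
    grs = list(site = "hip_any"))
}

.validateConfig <- function(config) {
  def <- defaultPipelineConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(def[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(bad))
        stop("unknown config key(s) under ", nm, ": ",
             paste(bad, collapse = ", "))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else def[[nm]] <- config[[nm]]
  }
  th <- def$thresholds
  stopifnot(th$p_gws > 0, th$p_gws < 1,
            th$maf_min >= 0, th$maf_min < 0.5,
            th$info_min >= 0, th$info_min <= 1,
            th$prune_r2 > 0, th$prune_r2 <= 1,
            th$collinearity_r2 > 0, th$collinearity_r2 <= 1,
            all(th$cutoffs %in% c(50, 25, 10)))
  def
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the defaults of
#' \code{\link{defaultPipelineConfig}}; thresholds are range-checked.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  .validateConfig(yaml::read_yaml(path))
}

#' Run the full analysis chain on synthetic data
#'
#' Executes simulate (panel, architecture, cohort) -> neck-width geometry
#' round trip -> phenotype -> quantitative association scan on the
#' discovery subsample -> conditional/joint signal selection -> LD score
#' regression (heritabilities and FNW/FN-BMD genetic correlation) ->
#' univariable and multivariable Mendelian randomization against per-site
#' fracture outcome scans in the non-discovery sample -> weighted genetic
#' risk scores with Cox models and binarized risk groups. Per-stage
#' outputs, a JSON report (counts, estimates, truth-versus-estimate table)
#' and a log with seeds and filter bookkeeping are written under
#' \code{out_dir}. Rerunning with the same configuration reproduces the
#' report byte for byte; any stage failure aborts with the stage name,
#' leaving earlier outputs on disk.
#'
#' @param config a config list (see \code{\link{defaultPipelineConfig}}) or
#'   the path of a YAML file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report list.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        out_dir = "fnwpipe_out") {
  if (is.character(config)) config <- readPipelineConfig(config)
  else config <- .validateConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logpath <- file.path(out_dir, "pipeline.log")
  cat("fnwpipe pipeline log\nR version: ", R.version.string,
      "\nseed: ", config$seed, "\n", sep = "", file = logpath)
  logline <- function(...) cat(..., "\n", sep = "", file = logpath,
                               append = TRUE)
  stage <- function(name, expr) {
    logline("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(config = config)
  seed <- config$seed

  panel <- stage("simulate_panel", {
    p <- config$panel
    simulateReferencePanel(p$n_individuals, p$n_variants, p$block_size,
                           p$within_block_rho, c(p$eaf_min, p$eaf_max),
                           seed = seed)
  })
  arch <- stage("simulate_architecture", {
    a <- config$architecture
    simulateArchitecture(panel, a$n_fnw, a$n_bmd, a$n_shared_inverse,
                         a$n_shared_positive, a$target_fnw_variance,
                         a$target_bmd_variance, seed = seed + 1)
  })
  cohort <- stage("simulate_cohort", {
    cc <- config$cohort
    simulateCohort(panel, arch, cc$n, cc$followup_yr, seed = seed + 2,
                   discovery_fraction = cc$discovery_fraction,
                   prevalent_window_yr = cc$prevalent_window_yr)
  })
  stage("write_inputs", {
    writeCohortTsv(cohort, file.path(out_dir, "cohort.tsv"))
    writeArchitectureJson(arch, file.path(out_dir, "truth.json"))
  })

  report$fnw_geometry <- stage("fnw", {
    an <- config$annotations
    targets <- phenotypes(cohort)$fnw_mm[seq_len(an$n)]
    rec <- vapply(seq_len(an$n), function(i) {
      ann <- simulateShapeAnnotation(targets[i], an$pixel_spacing,
                                     an$jitter_sd, seed = seed + 100 + i)
      writeShapeAnnotation(ann, file.path(out_dir,
                                          sprintf("points_%03d.csv", i)))
      computeFNW(ann)$fnw_mm
    }, numeric(1))
    list(n = an$n, mean_abs_error_mm = mean(abs(rec - targets)),
         mean_target_mm = mean(targets), mean_recovered_mm = mean(rec))
  })

  th <- config$thresholds
  disc <- discoveryFlag(cohort)
  gwas_fnw <- stage("gwas", {
    ph <- preparePhenotype(cohort)
    g <- runQuantGwas(cohort, ph, th$maf_min, th$info_min, subset = disc)
    writeSumstats(g, file.path(out_dir, "gwas_fnw.ma"))
    logline("gwas_fnw filters: ",
            paste(names(attr(g, "filtered")), attr(g, "filtered"),
                  sep = "=", collapse = ", "))
    g
  })
  gwas_bmd <- stage("gwas_bmd", {
    b <- phenotypes(cohort)$bmd_sd
    ph <- (b - mean(b)) / stats::sd(b)
    g <- runQuantGwas(cohort, ph, th$maf_min, th$info_min, subset = disc)
    writeSumstats(g, file.path(out_dir, "gwas_bmd.ma"))
    g
  })

  signals <- stage("cojo", {
    s <- cojoSelect(gwas_fnw, panel, th$p_gws, th$collinearity_r2)
    if (nrow(s)) writeSumstats(s, file.path(out_dir, "cojo_fnw.ma"))
    s
  })
  report$gwas <- list(
    n_variants_tested = nrow(gwas_fnw),
    n_signals = nrow(signals),
    variance_explained = if (nrow(signals)) varianceExplained(signals)
                         else 0,
    maf_classes = as.list(if (nrow(signals)) classifyMaf(signals)
                          else c(common = 0L, low_frequency = 0L)))

  report$ldsc <- stage("ldsc", {
    lc <- config$ldsc
    ld <- computeLDScores(panel, lc$window_kb, lc$maf_min)
    utils::write.table(ld$ld, file.path(out_dir, "ldscores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    h1 <- ldscH2(gwas_fnw, ld, lc$n_blocks)
    h2 <- ldscH2(gwas_bmd, ld, lc$n_blocks)
    rg <- ldscRg(gwas_fnw, gwas_bmd, ld, lc$n_blocks)
    list(h2_fnw = h1$h2, h2_fnw_se = h1$h2_se,
         h2_bmd = h2$h2, h2_bmd_se = h2$h2_se,
         rg = rg$rg, rg_se = rg$rg_se, rg_p = rg$rg_p)
  })

  mr_out <- stage("mr", {
    ins_fnw <- selectInstruments(gwas_fnw, panel, th$p_gws, th$maf_min,
                                 th$prune_r2)
    ins_bmd <- selectInstruments(gwas_bmd, panel, th$p_gws, th$maf_min,
                                 th$prune_r2)
    res <- resolveCrossExposureLd(ins_fnw, ins_bmd, gwas_fnw, gwas_bmd,
                                  panel, th$prune_r2)
    logline("instruments: fnw ", length(ins_fnw), " -> ",
            length(res$instr_exp1), ", bmd ", length(ins_bmd), " -> ",
            length(res$instr_exp2), " after cross-exposure LD")
    union_ids <- union(res$instr_exp1, res$instr_exp2)
    rows <- list(); per_site <- list()
    for (site in config$mr$sites) {
      out_gwas <- runBinaryGwas(cohort, site, include_prevalent = TRUE,
                                maf_min = th$maf_min,
                                info_min = th$info_min,
                                variants = union_ids, subset = !disc)
      out_gwas <- out_gwas[out_gwas$usable, , drop = FALSE]
      instr <- harmonizeInstruments(gwas_fnw, out_gwas, gwas_bmd,
                                    snps = union_ids,
                                    palindrome_maf_max = th$palindrome_maf_max,
                                    exposure_names = c("fnw", "bmd"),
                                    outcome_name = site)
      logline("site ", site, ": ", nrow(instr@data),
              " harmonized instruments; dropped ",
              paste(names(attr(instr, "dropped")), attr(instr, "dropped"),
                    sep = "=", collapse = ", "))
      st <- steigerFilter(instr)
      instr <- st$instruments
      site_res <- list()
      if (nrow(instr@data) >= 2) site_res$ivw <- mrIvw(instr)
      if (nrow(instr@data) >= 3) {
        site_res$egger <- mrEgger(instr)
        site_res$median <- mrWeightedMedian(instr, config$mr$n_boot,
                                            seed = seed + 7)
        mv <- mrMvmr(instr)
        site_res$mvmr_fnw <- mv[[1]]
        site_res$mvmr_bmd <- mv[[2]]
      }
      if (nrow(instr@data) >= 4)
        site_res$lasso <- tryCatch(mrLasso(instr), error = function(e) NULL)
      per_site[[site]] <- site_res
      for (r in site_res)
        if (!is.null(r)) {
          df <- as.data.frame(r)
          df$site <- site
          rows[[length(rows) + 1L]] <- df
        }
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(out_dir, "mr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = tab, per_site = per_site,
         f_fnw = if (length(res$instr_exp1) > 0) {
           hs <- harmonizeInstruments(gwas_fnw, gwas_fnw,
                                      snps = res$instr_exp1)
           instrumentStrength(hs)
         } else NA_real_)
  })
  report$mr <- list(f_statistic_fnw = mr_out$f_fnw,
                    estimates = lapply(mr_out$per_site, function(s)
                      lapply(s, function(r)
                        if (is.null(r)) NULL else
                          list(estimate = r@estimate, se = r@se,
                               or = r@or, model = r@effectsModel))))

  report$grs <- stage("grs", {
    gsite <- config$grs$site
    ids_f <- if (nrow(signals)) signals$snp else character()
    if (length(ids_f) < 2) stop("too few FNW signals for a risk score")
    sub <- !disc
    grs_f <- computeGrs(cohort, ids_f, signals$joint_beta, signals$ea,
                        subset = sub)
    bmd_gws <- gwas_bmd[gwas_bmd$p < th$p_gws, , drop = FALSE]
    bmd_ids <- selectInstruments(gwas_bmd, panel, th$p_gws, th$maf_min,
                                 th$prune_r2)
    bmd_gws <- bmd_gws[bmd_gws$snp %in% bmd_ids, , drop = FALSE]
    if (nrow(bmd_gws) < 2) stop("too few FN-BMD signals for a risk score")
    grs_b <- computeGrs(cohort, bmd_gws$snp, bmd_gws$beta, bmd_gws$ea,
                        subset = sub)
    scores <- list(grs_fnw = grs_f, grs_bmd = grs_b)
    fit_f <- coxFit(cohort, gsite, c("grs_fnw", "sex", "age"), scores)
    fit_b <- coxFit(cohort, gsite, c("grs_bmd", "sex", "age"), scores)
    fit_j <- coxFit(cohort, gsite, c("grs_fnw", "grs_bmd", "sex", "age"),
                    scores)
    groups <- list()
    for (cp in th$cutoffs) {
      ga <- binarizeGroups(grs_f, grs_b, cp)
      gfit <- tryCatch(groupHazardRatios(cohort, ga, gsite),
                       error = function(e) NULL)
      groups[[as.character(cp)]] <- if (is.null(gfit)) NULL else
        gfit$terms[gfit$terms$term %in% c("group2", "group3", "group4"),
                   c("term", "hr", "ci_low", "ci_high")]
    }
    hrOf <- function(fit, term) {
      r <- fit$terms[fit$terms$term == term, ]
      list(hr = r$hr, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
    }
    list(site = gsite, n_events = fit_f$n_events,
         hr_fnw = hrOf(fit_f, "grs_fnw"), hr_bmd = hrOf(fit_b, "grs_bmd"),
         hr_fnw_joint = hrOf(fit_j, "grs_fnw"),
         hr_bmd_joint = hrOf(fit_j, "grs_bmd"),
         groups = groups)
  })

  report$truth_vs_estimate <- stage("report", {
    v <- variantInfo(panel)
    stdb <- function(eff) {
      p <- v$eaf[match(names(eff), v$snp)]
      eff * sqrt(2 * p * (1 - p))
    }
    b1 <- stdb(arch@fnwEffects); b2 <- stdb(arch@bmdEffects)
    shared <- intersect(names(arch@fnwEffects), names(arch@bmdEffects))
    gencov <- sum(b1[shared] * b2[shared])
    rg_true <- gencov / sqrt(sum(b1^2) * sum(b2^2))
    tab <- list(
      list(parameter = "fnw_variance_explained",
           truth = arch@targetFnwVariance,
           estimate = report$gwas$variance_explained),
      list(parameter = "n_fnw_causal",
           truth = sum(arch@fnwEffects != 0),
           estimate = report$gwas$n_signals),
      list(parameter = "rg_fnw_bmd", truth = rg_true,
           estimate = report$ldsc$rg))
    for (site in config$mr$sites) {
      est <- report$mr$estimates[[site]]
      tab[[length(tab) + 1L]] <- list(
        parameter = paste0("log_or_fnw_", site),
        truth = arch@logHr$fnw[[site]],
        estimate = if (!is.null(est$mvmr_fnw)) est$mvmr_fnw$estimate
                   else NA)
      tab[[length(tab) + 1L]] <- list(
        parameter = paste0("log_or_bmd_", site),
        truth = arch@logHr$bmd[[site]],
        estimate = if (!is.null(est$mvmr_bmd)) est$mvmr_bmd$estimate
                   else NA)
    }
    tab
  })

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logline("pipeline complete")
  invisible(report)
}
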