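#' Select approximately independent genetic instruments
#'
#' Candidates must pass the MAF filter and reach the association threshold;
#' they are then greedily pruned by LD: walking candidates in order of
#' ascending p-value (ties by chromosome and position), a variant is
#' accepted iff its squared panel correlation with every previously
#' accepted variant is below \code{r2_max}. Variants absent from the panel
#' are excluded with a warning.
#'
#' @param sumstats summary-statistic data.frame.
#' @param panel a \linkS4class{ReferencePanel} for LD.
#' @param p_max association threshold (default 5e-8, genome-wide).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param r2_max pairwise LD ceiling (default 0.01).
#' @return character vector of selected variant ids.
#' @export
selectInstruments <- function(sumstats, panel, p_max = 5e-8,
                              maf_min = 0.01, r2_max = 0.01) {
  maf <- pmin(sumstats$eaf, 1 - sumstats$eaf)
  cand <- sumstats[maf > maf_min & sumstats$p < p_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(character())
  inpanel <- cand$snp %in% variantInfo(panel)$snp
  if (any(!inpanel)) {
    warning("excluding ", sum(!inpanel), " candidate(s) absent from panel")
    cand <- cand[inpanel, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(character())
  cand <- cand[order(cand$p, cand$chr, cand$pos), , drop = FALSE]
  Rm <- panelCorrelation(panel, cand$snp)
  sel <- integer()
  for (j in seq_len(nrow(cand))) {
    if (!length(sel) || all(Rm[j, sel]^2 < r2_max)) sel <- c(sel, j)
  }
  cand$snp[sel]
}

#' Resolve LD between instruments of two exposures
#'
#' For every cross-exposure pair of instruments with squared correlation at
#' least \code{r2_flag}, one member is dropped: under the primary rule the
#' variant with the stronger (smaller-p) association with the second
#' exposure is kept and its partner removed from the other list; the
#' sensitivity mode keeps the first-exposure-stronger variant instead.
#' Pairs are processed in a deterministic order and every decision is
#' returned in the report.
#'
#' @param instr_exp1,instr_exp2 instrument id vectors for the two
#'   exposures.
#' @param sumstats1,sumstats2 the association tables the p-value comparison
#'   draws on (must contain every flagged variant).
#' @param panel a \linkS4class{ReferencePanel}.
#' @param r2_flag LD threshold for flagging (default 0.01).
#' @param prefer "exposure2" (primary rule) or "exposure1" (sensitivity).
#' @return list with adjusted \code{instr_exp1}, \code{instr_exp2} and a
#'   \code{report} data.frame (snp1, snp2, r2, kept, dropped_from).
#' @export
resolveCrossExposureLd <- function(instr_exp1, instr_exp2,
                                   sumstats1, sumstats2, panel,
                                   r2_flag = 0.01,
                                   prefer = c("exposure2", "exposure1")) {
  prefer <- match.arg(prefer)
  report <- data.frame(snp1 = character(), snp2 = character(),
                       r2 = numeric(), kept = character(),
                       dropped_from = character(), stringsAsFactors = FALSE)
  only1 <- sort(setdiff(instr_exp1, instr_exp2))
  only2 <- sort(setdiff(instr_exp2, instr_exp1))
  if (!length(only1) || !length(only2))
    return(list(instr_exp1 = instr_exp1, instr_exp2 = instr_exp2,
                report = report))
  Rm <- panelCorrelation(panel, c(only1, only2))
  pOf <- function(ss, id) {
    i <- match(id, ss$snp)
    if (is.na(i)) Inf else ss$p[i]
  }
  for (a in only1) {
    for (b in only2) {
      if (!(a %in% instr_exp1) || !(b %in% instr_exp2)) next
      r2 <- Rm[a, b]^2
      if (!is.finite(r2) || r2 < r2_flag) next
      ref_ss <- if (prefer == "exposure2") sumstats2 else sumstats1
      keep_a <- pOf(ref_ss, a) < pOf(ref_ss, b)
      if (keep_a) {
        instr_exp2 <- setdiff(instr_exp2, b)
        report <- rbind(report, data.frame(snp1 = a, snp2 = b, r2 = r2,
                                           kept = a,
                                           dropped_from = "exposure2"))
      } else {
        instr_exp1 <- setdiff(instr_exp1, a)
        report <- rbind(report, data.frame(snp1 = a, snp2 = b, r2 = r2,
                                           kept = b,
                                           dropped_from = "exposure1"))
      }
    }
  }
  list(instr_exp1 = instr_exp1, instr_exp2 = instr_exp2, report = report)
}

.complementAllele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

.isPalindromic <- function(ea, oa) {
  nchar(ea) == 1L & nchar(oa) == 1L & .complementAllele(ea) == oa
}

#' Harmonize exposure and outcome summary statistics into an instrument set
#'
#' Aligns every shared variant to the exposure's effect allele: identical
#' allele pairs are kept as-is; swapped pairs flip the outcome effect sign
#' and complement its frequency; strand-complemented pairs are resolved via
#' base complementation. Palindromic variants (A/T or C/G) cannot be
#' resolved from allele labels: when both frequencies are clearly away from
#' 0.5 (MAF below \code{palindrome_maf_max}) they are aligned by frequency
#' (a frequency mismatch implies a strand flip, so the outcome effect sign
#' is flipped); otherwise they are removed as non-clear strand.
#' Irreconcilable allele pairs and variants missing from any table are
#' dropped and counted.
#'
#' @param exposure,outcome summary-statistic data.frames (snp, ea, oa, eaf,
#'   beta, se, p, n).
#' @param second_exposure optional second exposure table (for multivariable
#'   analyses); only variants present in all tables are kept.
#' @param snps optional instrument id vector to restrict to.
#' @param palindrome_maf_max ambiguity threshold (default 0.42).
#' @param exposure_names,outcome_name labels carried in the result.
#' @return an \linkS4class{InstrumentSet}; attribute \code{dropped} counts
#'   removals by reason (missing, palindromic_ambiguous, irreconcilable).
#' @export
harmonizeInstruments <- function(exposure, outcome, second_exposure = NULL,
                                 snps = NULL, palindrome_maf_max = 0.42,
                                 exposure_names = "exposure",
                                 outcome_name = "outcome") {
  if (is.null(snps)) snps <- exposure$snp
  dropped <- c(missing = 0L, palindromic_ambiguous = 0L,
               irreconcilable = 0L)
  rows <- list()
  for (id in snps) {
    ie <- match(id, exposure$snp)
    io <- match(id, outcome$snp)
    i2 <- if (is.null(second_exposure)) 0L else match(id, second_exposure$snp)
    if (is.na(ie) || is.na(io) || (!is.null(second_exposure) && is.na(i2))) {
      dropped["missing"] <- dropped["missing"] + 1L
      next
    }
    ea <- exposure$ea[ie]; oa <- exposure$oa[ie]
    alignTo <- function(tab, i) {
      # returns c(sign, freq) aligning tab row i to (ea, oa), or NULL
      tea <- tab$ea[i]; toa <- tab$oa[i]
      if (tea == ea && toa == oa) return(list(sign = 1, eaf = tab$eaf[i]))
      if (tea == oa && toa == ea) return(list(sign = -1, eaf = 1 - tab$eaf[i]))
      if (nchar(tea) == 1L && nchar(toa) == 1L &&
          nchar(ea) == 1L && nchar(oa) == 1L) {
        cea <- .complementAllele(tea); coa <- .complementAllele(toa)
        if (cea == ea && coa == oa) return(list(sign = 1, eaf = tab$eaf[i]))
        if (cea == oa && coa == ea) return(list(sign = -1, eaf = 1 - tab$eaf[i]))
      }
      NULL
    }
    al_o <- alignTo(outcome, io)
    al_2 <- if (is.null(second_exposure)) list(sign = 1, eaf = NA_real_)
            else alignTo(second_exposure, i2)
    if (is.null(al_o) || is.null(al_2)) {
      dropped["irreconcilable"] <- dropped["irreconcilable"] + 1L
      next
    }
    if (.isPalindromic(ea, oa)) {
      mafs <- c(pmin(exposure$eaf[ie], 1 - exposure$eaf[ie]),
                pmin(al_o$eaf, 1 - al_o$eaf))
      if (any(mafs >= palindrome_maf_max)) {
        dropped["palindromic_ambiguous"] <- dropped["palindromic_ambiguous"] + 1L
        next
      }
      # align by frequency: mismatched sides of 0.5 imply a strand flip
      if ((exposure$eaf[ie] < 0.5) != (al_o$eaf < 0.5)) {
        al_o$sign <- -al_o$sign
        al_o$eaf <- 1 - al_o$eaf
      }
      if (!is.null(second_exposure) &&
          (exposure$eaf[ie] < 0.5) != (al_2$eaf < 0.5)) {
        al_2$sign <- -al_2$sign
        al_2$eaf <- 1 - al_2$eaf
      }
    }
    row <- data.frame(snp = id, ea = ea, oa = oa, eaf = exposure$eaf[ie],
                      beta_exp = exposure$beta[ie], se_exp = exposure$se[ie],
                      p_exp = exposure$p[ie],
                      beta_out = al_o$sign * outcome$beta[io],
                      se_out = outcome$se[io], eaf_out = al_o$eaf,
                      stringsAsFactors = FALSE)
    if (!is.null(second_exposure)) {
      row$beta_exp2 <- al_2$sign * second_exposure$beta[i2]
      row$se_exp2 <- second_exposure$se[i2]
    }
    rows[[length(rows) + 1L]] <- row
  }
  dat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), ea = character(), oa = character(),
               eaf = numeric(), beta_exp = numeric(), se_exp = numeric(),
               p_exp = numeric(), beta_out = numeric(), se_out = numeric(),
               eaf_out = numeric(), stringsAsFactors = FALSE)
  rownames(dat) <- NULL
  obj <- new("InstrumentSet", data = dat,
             exposureNames = if (is.null(second_exposure)) exposure_names
                             else rep_len(exposure_names, 2L),
             outcomeName = outcome_name,
             nExp = stats::median(exposure$n),
             nOut = stats::median(outcome$n),
             nExp2 = if (is.null(second_exposure)) NA_real_
                     else stats::median(second_exposure$n))
  attr(obj, "dropped") <- dropped
  obj
}

#' Steiger directionality filter
#'
#' Removes instruments that explain significantly more variance in the
#' outcome than in the exposure (evidence of reverse causation). Exposure
#' r2 per variant is beta^2 2 EAF (1 - EAF) for a standardized trait;
#' outcome r2 uses the observed-scale approximation z^2 / (z^2 + n) from
#' the logistic z-statistic. The one-sided test compares Fisher-transformed
#' correlations at level \code{alpha}.
#'
#' @param instr an \linkS4class{InstrumentSet}.
#' @param n_exp,n_out sample sizes (default: those stored in \code{instr}).
#' @param alpha one-sided removal level (default 0.05).
#' @return list: \code{instruments} (filtered InstrumentSet) and
#'   \code{report} (per-variant r2s, direction, steiger_p, removed).
#' @export
steigerFilter <- function(instr, n_exp = instr@nExp, n_out = instr@nOut,
                          alpha = 0.05) {
  if (!is.finite(n_exp) || !is.finite(n_out))
    stop("exposure and outcome sample sizes are required")
  d <- instr@data
  r2_exp <- d$beta_exp^2 * 2 * d$eaf * (1 - d$eaf)
  z_out <- d$beta_out / d$se_out
  r2_out <- z_out^2 / (z_out^2 + n_out)
  zf <- (atanh(sqrt(pmin(r2_exp, 0.999))) - atanh(sqrt(pmin(r2_out, 0.999)))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  p_rev <- stats::pnorm(zf)          # small when outcome r2 >> exposure r2
  removed <- p_rev < alpha
  report <- data.frame(snp = d$snp, r2_exposure = r2_exp,
                       r2_outcome = r2_out,
                       direction = ifelse(r2_exp >= r2_out,
                                          "exposure->outcome",
                                          "outcome->exposure"),
                       steiger_p = p_rev, removed = removed,
                       stringsAsFactors = FALSE)
  out <- instr
  out@data <- d[!removed, , drop = FALSE]
  rownames(out@data) <- NULL
  list(instruments = out, report = report)
}

#' Mean F-statistic of an instrument set
#'
#' F = mean over instruments of (gamma_j / se_j)^2, the usual summary-level
#' measure of instrument strength.
#'
#' @param instr an \linkS4class{InstrumentSet}.
#' @param which_exposure 1 or 2.
#' @return the F statistic.
#' @export
instrumentStrength <- function(instr, which_exposure = 1) {
  d <- instr@data
  if (nrow(d) == 0L) stop("empty instrument set")
  if (which_exposure == 1) mean((d$beta_exp / d$se_exp)^2)
  else {
    if (is.null(d$beta_exp2)) stop("no second exposure in instrument set")
    mean((d$beta_exp2 / d$se_exp2)^2)
  }
}
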