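#' Approximate conditional and joint signal selection from summary statistics
#'
#' Stepwise selection of conditionally independent association signals
#' using only marginal summary statistics plus an LD reference. Effects
#' are first moved to the standardized-genotype scale (b* = beta * SD of
#' dosage, with the phenotype at unit variance); joint effects for a
#' candidate set S are then b_joint = R_S^{-1} b_marginal where R_S is the
#' panel dosage-correlation matrix, with Var(b_joint) =
#' sigma^2 R_S^{-1} / n and sigma^2 = 1 - b_marginal' b_joint. Selection
#' starts from the smallest-p genome-wide significant variant and
#' repeatedly adds the candidate with the smallest conditional p-value
#' (two-sided normal test on b_cond / se_cond) while it stays below the
#' threshold. Candidates whose squared correlation with any selected
#' variant exceeds \code{collinearity_r2} are ineligible; a singular
#' conditioning matrix drops the offending candidate with a warning. Joint
#' effects are back-transformed to the allelic scale on return. Ties are
#' broken by smaller p, then by chromosome and position, so the result is
#' invariant to input row order.
#'
#' @param sumstats summary-statistic data.frame (snp, chr, pos, eaf, beta,
#'   se, p, n, ...) from a scan of a standardized phenotype.
#' @param panel a \linkS4class{ReferencePanel} containing the variants.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param collinearity_r2 maximum allowed r2 with the selected set
#'   (default 0.9).
#' @return data.frame of selected signals: the marginal record plus
#'   joint_beta, joint_se, conditional_p (the conditional p at selection
#'   time; marginal p for the first signal).
#' @export
cojoSelect <- function(sumstats, panel, p_threshold = 5e-8,
                       collinearity_r2 = 0.9) {
  ss <- sumstats[order(sumstats$p, sumstats$chr, sumstats$pos), , drop = FALSE]
  ss <- ss[ss$p < p_threshold, , drop = FALSE]
  empty <- ss[0, , drop = FALSE]
  empty$joint_beta <- empty$joint_se <- empty$conditional_p <- numeric(0)
  if (nrow(ss) == 0L) return(empty)
  miss <- setdiff(ss$snp, variantInfo(panel)$snp)
  if (length(miss))
    stop("sumstats variants absent from panel: ",
         paste(utils::head(miss, 5L), collapse = ", "))

  dos <- dosages(panel)[, ss$snp, drop = FALSE]
  sdg <- apply(dos, 2L, stats::sd)
  Rfull <- suppressWarnings(stats::cor(dos))
  Rfull[!is.finite(Rfull)] <- 0; diag(Rfull) <- 1
  bstd <- ss$beta * sdg                      # standardized-scale marginal
  nbar <- stats::median(ss$n)

  jointFit <- function(idx) {
    R <- Rfull[idx, idx, drop = FALSE]
    bj <- tryCatch(solve(R, bstd[idx]), error = function(e) NULL)
    if (is.null(bj)) return(NULL)
    sigma2 <- max(1 - sum(bstd[idx] * bj), 1e-8)
    Rin <- tryCatch(solve(R), error = function(e) NULL)
    if (is.null(Rin)) return(NULL)
    se <- sqrt(sigma2 * diag(Rin) / nbar)
    list(beta = bj, se = se, z = bj / se)
  }

  sel <- which.min(ss$p)                     # deterministic: ss pre-sorted
  cond_p <- ss$p[sel]
  repeat {
    cand <- setdiff(seq_len(nrow(ss)), sel)
    if (!length(cand)) break
    elig <- cand[vapply(cand, function(j)
      max(Rfull[j, sel]^2) <= collinearity_r2, logical(1))]
    if (!length(elig)) break
    best_j <- NA_integer_; best_p <- Inf
    for (j in elig) {
      ft <- jointFit(c(sel, j))
      if (is.null(ft)) {
        warning("singular conditioning matrix; dropping candidate ",
                ss$snp[j])
        next
      }
      pj <- 2 * stats::pnorm(-abs(ft$z[length(ft$z)]))
      if (pj < best_p) { best_p <- pj; best_j <- j }
    }
    if (!is.na(best_j) && best_p < p_threshold) {
      sel <- c(sel, best_j)
      cond_p <- c(cond_p, best_p)
    } else break
  }

  ft <- jointFit(sel)
  out <- ss[sel, , drop = FALSE]
  out$joint_beta <- ft$beta / sdg[sel]       # back to allelic scale
  out$joint_se <- ft$se / sdg[sel]
  out$conditional_p <- cond_p
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance of a standardized trait explained by a set of signals
#'
#' Sum over signals of 2 EAF (1 - EAF) beta^2, valid when the phenotype was
#' standardized to unit variance; additive over disjoint signal sets.
#'
#' @param signals data.frame with columns eaf and beta (allelic scale). A
#'   \code{joint_beta} column, when present, takes precedence over
#'   \code{beta}.
#' @param use_joint use joint betas when available (default TRUE).
#' @return fraction of variance explained.
#' @export
varianceExplained <- function(signals, use_joint = TRUE) {
  if (any(signals$eaf <= 0 | signals$eaf >= 1))
    stop("EAF must lie strictly inside (0, 1)")
  b <- if (use_joint && !is.null(signals$joint_beta)) signals$joint_beta
       else signals$beta
  sum(2 * signals$eaf * (1 - signals$eaf) * b^2)
}

#' Classify signals by minor allele frequency
#'
#' MAF = min(EAF, 1 - EAF). Low-frequency: 0.01 < MAF <= 0.05 (boundary
#' inclusive); common: MAF > 0.05. Variants at MAF <= 0.01, which should
#' have been removed by the association-scan filter, are counted separately
#' with a warning.
#'
#' @param signals data.frame with an eaf column.
#' @return named integer vector: common, low_frequency (and below_filter
#'   when any MAF <= 0.01 slipped through).
#' @export
classifyMaf <- function(signals) {
  maf <- pmin(signals$eaf, 1 - signals$eaf)
  eps <- 1e-9                              # guard the printed boundaries
  out <- c(common = sum(maf > 0.05 + eps),
           low_frequency = sum(maf > 0.01 + eps & maf <= 0.05 + eps))
  if (any(maf <= 0.01 + eps)) {
    warning(sum(maf <= 0.01 + eps),
            " variant(s) at MAF <= 1% should have been filtered upstream")
    out <- c(out, below_filter = sum(maf <= 0.01))
  }
  out
}

#' Annotate signals with the closest gene
#'
#' For each signal (1-based position) finds the feature minimizing the
#' distance to a set of BED intervals (0-based half-open): distance 0 when
#' the position falls inside the feature, otherwise base pairs to the
#' nearer boundary. Equal-distance ties report the upstream feature (the
#' one ending before the signal), deterministically.
#'
#' @param signals data.frame with columns chr and pos.
#' @param genes data.frame with columns chrom, start, end, name (BED
#'   conventions).
#' @return signals with added columns closest_gene and distance_to_gene.
#' @export
annotateNearestGene <- function(signals, genes) {
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene set")
  signals$closest_gene <- NA_character_
  signals$distance_to_gene <- NA_real_
  for (i in seq_len(nrow(signals))) {
    g <- genes[as.character(genes$chrom) == as.character(signals$chr[i]), ,
               drop = FALSE]
    if (nrow(g) == 0L) next
    lo <- g$start + 1L                       # 1-based inclusive interval
    hi <- g$end
    pos <- signals$pos[i]
    d <- ifelse(pos < lo, lo - pos, ifelse(pos > hi, pos - hi, 0))
    upstream <- hi < pos
    ord <- order(d, !upstream, g$start)      # prefer upstream on ties
    signals$closest_gene[i] <- g$name[ord[1]]
    signals$distance_to_gene[i] <- d[ord[1]]
  }
  signals
}

#' Load the 71 conditionally independent FNW signals
#'
#' Reads the packaged table of 71 conditionally independent genome-wide
#' significant femoral neck width variants (id, position, closest gene,
#' alleles, EAF, beta, SE, p).
#'
#' @return data.frame with 71 rows.
#' @export
fnwSignals <- function() {
  path <- system.file("extdata", "fnw_cojo_signals.tsv", package = "fnwpipe")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
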