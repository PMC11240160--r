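#' Compute LD scores from a reference panel
#'
#' For each variant j passing the MAF filter, l_j is the sum over variants
#' k within \code{window_kb} of the bias-adjusted squared dosage
#' correlation r2_adj = r2 - (1 - r2) / (n_ref - 2), including the self
#' term (which is exactly 1). The adjustment removes the finite-panel
#' upward bias of r2 so that cross terms average zero for unlinked pairs.
#'
#' @param panel a \linkS4class{ReferencePanel} (n_ref > 2 individuals).
#' @param window_kb window half-width in kb (default 1000).
#' @param maf_min minor-allele-frequency filter (default 0.05, the usual
#'   regression-SNP restriction).
#' @return list with elements \code{ld} (data.frame snp, chr, pos, l2),
#'   \code{window_kb}, \code{n_ref}, and \code{M} (number of scored
#'   variants, the regression denominator).
#' @export
computeLDScores <- function(panel, window_kb = 1000, maf_min = 0.05) {
  nref <- nIndividuals(panel)
  if (nref <= 2) stop("reference panel must have more than 2 individuals")
  if (window_kb < 0) stop("window_kb must be >= 0")
  v <- variantInfo(panel)
  keep <- pmin(v$eaf, 1 - v$eaf) > maf_min
  v <- v[keep, , drop = FALSE]
  dos <- dosages(panel)[, keep, drop = FALSE]
  if (nrow(v) == 0L) stop("no variants pass the MAF filter")
  w <- window_kb * 1000
  l2 <- rep(1, nrow(v))
  if (w > 0) {
    for (ch in unique(v$chr)) {
      idx <- which(v$chr == ch)
      pos <- v$pos[idx]
      # split into runs that a window cannot straddle
      grp <- cumsum(c(1, diff(pos) > w))
      for (g in unique(grp)) {
        gi <- idx[grp == g]
        if (length(gi) < 2L) next
        R2 <- suppressWarnings(stats::cor(dos[, gi, drop = FALSE]))^2
        R2[!is.finite(R2)] <- 0
        adj <- R2 - (1 - R2) / (nref - 2)
        inwin <- abs(outer(v$pos[gi], v$pos[gi], `-`)) <= w
        diag(inwin) <- FALSE
        l2[gi] <- 1 + rowSums(adj * inwin)
      }
    }
  }
  list(ld = data.frame(snp = v$snp, chr = v$chr, pos = v$pos, l2 = l2,
                       stringsAsFactors = FALSE),
       window_kb = window_kb, n_ref = nref, M = nrow(v))
}

# weighted regression of y on x with intercept, weights w; returns c(int, slope)
.wlsIntSlope <- function(x, y, w) {
  sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sl <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
  c(my - sl * mx, sl)
}

.ldscBlocks <- function(m, n_blocks) {
  if (n_blocks > m) {
    warning("more jackknife blocks than variants; reducing to ", m)
    n_blocks <- m
  }
  sort(rep_len(seq_len(n_blocks), m))
}

#' LD score regression heritability
#'
#' Regresses per-variant chi-squared statistics on n l_j / M with weights
#' 1 / l_j (single step): the slope estimates SNP heritability and the
#' intercept captures confounding/population structure (1 under the null).
#' Standard errors come from a leave-one-block-out jackknife over
#' \code{n_blocks} contiguous blocks.
#'
#' @param sumstats summary-statistic data.frame (snp, beta, se, n).
#' @param ld LD score set from \code{\link{computeLDScores}}.
#' @param n_blocks jackknife blocks (default 200, reduced when there are
#'   fewer variants).
#' @return list: h2, h2_se, intercept, intercept_se, mean_chi2, M,
#'   n_blocks.
#' @export
ldscH2 <- function(sumstats, ld, n_blocks = 200) {
  m <- match(ld$ld$snp, sumstats$snp)
  ok <- !is.na(m)
  if (!any(ok)) stop("no variants shared between sumstats and LD scores")
  ss <- sumstats[m[ok], , drop = FALSE]
  l2 <- pmax(ld$ld$l2[ok], 1)
  chi2 <- (ss$beta / ss$se)^2
  n <- stats::median(ss$n)
  x <- n * l2 / ld$M
  w <- 1 / l2
  blocks <- .ldscBlocks(length(x), n_blocks)
  B <- max(blocks)
  full <- .wlsIntSlope(x, chi2, w)
  jk <- vapply(seq_len(B), function(b) {
    k <- blocks != b
    .wlsIntSlope(x[k], chi2[k], w[k])
  }, numeric(2))
  se <- sqrt((B - 1) / B * rowSums((jk - rowMeans(jk))^2))
  list(h2 = full[2], h2_se = se[2], intercept = full[1],
       intercept_se = se[1], mean_chi2 = mean(chi2), M = ld$M,
       n_blocks = B)
}

#' Cross-trait LD score regression genetic correlation
#'
#' Regresses the per-variant product z1 * z2 on sqrt(n1 n2) l_j / M to
#' estimate the genetic covariance (the intercept absorbs sample overlap);
#' heritabilities come from \code{\link{ldscH2}} on each trait, and
#' rg = gencov / sqrt(h2_1 h2_2). The standard error and p-value of rg are
#' from a leave-one-block-out jackknife recomputing all three regressions.
#' Alleles are harmonized by id before use (swapped alleles flip the sign
#' of the second z; irreconcilable rows are dropped). Symmetric in its two
#' inputs.
#'
#' @param sumstats1,sumstats2 summary-statistic data.frames.
#' @param ld LD score set from \code{\link{computeLDScores}}.
#' @param n_blocks jackknife blocks (default 200).
#' @param alpha significance level for the flag (default 0.05 / 3, a
#'   Bonferroni correction for three look-ups).
#' @return list: h2_1, h2_2, gencov, rg, rg_se, rg_p, significant,
#'   intercept_1, intercept_2, cross_intercept, M, n_blocks. When either
#'   heritability estimate is non-positive, rg is NA and \code{error}
#'   describes why.
#' @export
ldscRg <- function(sumstats1, sumstats2, ld, n_blocks = 200,
                   alpha = 0.05 / 3) {
  m1 <- match(ld$ld$snp, sumstats1$snp)
  m2 <- match(ld$ld$snp, sumstats2$snp)
  ok <- !is.na(m1) & !is.na(m2)
  if (!any(ok)) stop("no variants shared across the three inputs")
  s1 <- sumstats1[m1[ok], , drop = FALSE]
  s2 <- sumstats2[m2[ok], , drop = FALSE]
  l2 <- pmax(ld$ld$l2[ok], 1)

  # allele harmonization: flip z2 where alleles are swapped, drop mismatches
  same <- s1$ea == s2$ea & s1$oa == s2$oa
  swap <- s1$ea == s2$oa & s1$oa == s2$ea
  flip <- ifelse(swap, -1, 1)
  keep <- same | swap
  s1 <- s1[keep, , drop = FALSE]; s2 <- s2[keep, , drop = FALSE]
  l2 <- l2[keep]; flip <- flip[keep]

  z1 <- s1$beta / s1$se
  z2 <- flip * s2$beta / s2$se
  n1 <- stats::median(s1$n); n2 <- stats::median(s2$n)
  M <- ld$M
  x1 <- n1 * l2 / M; x2 <- n2 * l2 / M
  xc <- sqrt(n1 * n2) * l2 / M
  w <- 1 / l2
  blocks <- .ldscBlocks(length(l2), n_blocks)
  B <- max(blocks)

  comp <- function(k) {
    h1 <- .wlsIntSlope(x1[k], z1[k]^2, w[k])
    h2 <- .wlsIntSlope(x2[k], z2[k]^2, w[k])
    gc <- .wlsIntSlope(xc[k], (z1 * z2)[k], w[k])
    rg <- if (h1[2] > 0 && h2[2] > 0) gc[2] / sqrt(h1[2] * h2[2]) else NA_real_
    c(h1 = h1[2], h2 = h2[2], gencov = gc[2], rg = rg,
      i1 = h1[1], i2 = h2[1], ic = gc[1])
  }
  full <- comp(rep(TRUE, length(l2)))
  if (!is.finite(full["rg"])) {
    return(list(h2_1 = full[["h1"]], h2_2 = full[["h2"]],
                gencov = full[["gencov"]], rg = NA_real_, rg_se = NA_real_,
                rg_p = NA_real_, significant = NA,
                intercept_1 = full[["i1"]], intercept_2 = full[["i2"]],
                cross_intercept = full[["ic"]], M = M, n_blocks = B,
                error = "non-positive heritability estimate"))
  }
  jk <- vapply(seq_len(B), function(b) comp(blocks != b)["rg"], numeric(1))
  jk[!is.finite(jk)] <- full["rg"]
  rg_se <- sqrt((B - 1) / B * sum((jk - mean(jk))^2))
  rg <- full[["rg"]]
  if (abs(rg) > 1) warning("estimated |rg| exceeds 1")
  rg_p <- 2 * stats::pnorm(-abs(rg / rg_se))
  list(h2_1 = full[["h1"]], h2_2 = full[["h2"]], gencov = full[["gencov"]],
       rg = rg, rg_se = rg_se, rg_p = rg_p, significant = rg_p < alpha,
       intercept_1 = full[["i1"]], intercept_2 = full[["i2"]],
       cross_intercept = full[["ic"]], M = M, n_blocks = B)
}
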