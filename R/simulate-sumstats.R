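#' Simulate GWAS summary statistics under a polygenic model
#'
#' Draws marginal association statistics for one or two traits directly on
#' the summary level, using the panel's empirical within-block LD. Causal
#' effects on the standardized scale are drawn per variant as
#' beta_j ~ N(0, h2 / M) (all variants causal); for two traits the pair
#' (beta1_j, beta2_j) is bivariate normal with correlation \code{rg}, so
#' \code{rg} is the true genetic correlation. Marginal standardized
#' estimates are R beta plus correlated sampling noise with covariance
#' (1 - h2) R / n, giving E[chi^2_j] = 1 + n h2 l_j / M — the LD score
#' regression model. The two samples are non-overlapping (independent
#' noise), so the cross-trait intercept is zero. Effects are returned on
#' the allelic scale (divided by the dosage SD implied by the allele
#' frequency).
#'
#' @param panel a \linkS4class{ReferencePanel} providing LD.
#' @param h2 SNP heritability of trait 1 (and trait 2 unless h2_2 given).
#' @param n GWAS sample size for trait 1.
#' @param seed integer seed.
#' @param rg if non-NULL, also simulate a second trait with this true
#'   genetic correlation.
#' @param h2_2,n2 heritability and sample size of the second trait.
#' @return a summary-statistic data.frame (columns snp, chr, pos, ea, oa,
#'   eaf, beta, se, p, n, info), or a list of two such data.frames when
#'   \code{rg} is given.
#' @export
simulatePolygenicSumstats <- function(panel, h2, n, seed = 1, rg = NULL,
                                      h2_2 = h2, n2 = n) {
  stopifnot(h2 > 0, h2 < 1, n > 1)
  set.seed(seed)
  v <- variantInfo(panel)
  M <- nrow(v)
  two <- !is.null(rg)
  if (two && abs(rg) > 1) stop("rg must lie in [-1, 1]")

  b1 <- stats::rnorm(M, 0, sqrt(h2 / M))
  if (two) {
    b2 <- rg * sqrt(h2_2 / h2) * b1 +
      sqrt(pmax(h2_2 * (1 - rg^2), 0) / M) * stats::rnorm(M)
  }
  z1 <- numeric(M)
  if (two) z2 <- numeric(M)
  dos <- dosages(panel)
  for (bk in unique(panel@block)) {
    idx <- which(panel@block == bk)
    Rb <- suppressWarnings(stats::cor(dos[, idx, drop = FALSE]))
    Rb[!is.finite(Rb)] <- 0; diag(Rb) <- 1
    L <- chol(Rb + diag(1e-8, length(idx)))
    mu1 <- Rb %*% b1[idx]
    z1[idx] <- sqrt(n) * (mu1 + crossprod(L, stats::rnorm(length(idx))) *
                            sqrt((1 - h2) / n))
    if (two) {
      mu2 <- Rb %*% b2[idx]
      z2[idx] <- sqrt(n2) * (mu2 + crossprod(L, stats::rnorm(length(idx))) *
                               sqrt((1 - h2_2) / n2))
    }
  }
  mk <- function(z, nn) {
    sdg <- sqrt(2 * v$eaf * (1 - v$eaf))
    se <- 1 / (sqrt(nn) * sdg)
    data.frame(snp = v$snp, chr = v$chr, pos = v$pos, ea = v$ea, oa = v$oa,
               eaf = v$eaf, beta = (z / sqrt(nn)) / sdg, se = se,
               p = 2 * stats::pnorm(-abs(z)), n = nn, info = v$info,
               stringsAsFactors = FALSE)
  }
  if (two) list(trait1 = mk(z1, n), trait2 = mk(z2, n2)) else mk(z1, n)
}
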