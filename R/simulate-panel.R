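## Genotypes are generated by latent-Gaussian thresholding: each haplotype
## carries a standard-normal latent vector with autoregressive correlation
## rho^|i-j| inside an LD block (independence across blocks); the allele is
## present when the latent value falls below qnorm(EAF). Dosage = sum of two
## independent haplotypes, so dosage correlation equals the haplotype allele
## correlation.

.simulateHaplotypes <- function(n_hap, eaf, block, rho) {
  m <- length(eaf)
  z <- matrix(0, n_hap, m)
  for (b in unique(block)) {
    idx <- which(block == b)
    e <- matrix(stats::rnorm(n_hap * length(idx)), n_hap, length(idx))
    z[, idx[1]] <- e[, 1]
    if (length(idx) > 1L) {
      sc <- sqrt(1 - rho^2)
      for (k in 2:length(idx))
        z[, idx[k]] <- rho * z[, idx[k - 1]] + sc * e[, k]
    }
  }
  thr <- stats::qnorm(eaf)
  # allele indicator per haplotype
  sweep(z, 2L, thr, `<`) + 0
}

.simulateDosages <- function(n, eaf, block, rho) {
  h1 <- .simulateHaplotypes(n, eaf, block, rho)
  h2 <- .simulateHaplotypes(n, eaf, block, rho)
  h1 + h2
}

#' Simulate a genotype reference panel with block LD structure
#'
#' Generates an individuals x variants allele-dosage matrix from
#' latent-Gaussian-threshold haplotypes: within each block of
#' \code{block_size} consecutive variants the latent normals follow an
#' AR(1) process with correlation \code{within_block_rho}^|i-j|; blocks are
#' mutually independent. Effect-allele frequencies are drawn uniformly from
#' \code{eaf_range}. Variants are placed on one chromosome, 1 kb apart
#' within a block with 10 Mb gaps between blocks, so window-based LD
#' measures do not straddle blocks. INFO is 1.0 throughout.
#'
#' @param n_individuals number of panel individuals (>= 50).
#' @param n_variants number of variants.
#' @param block_size variants per LD block.
#' @param within_block_rho latent AR(1) correlation in [0, 1).
#' @param eaf_range length-2 interval inside (0, 1) for allele frequencies.
#' @param seed integer seed; fixing it fixes every output.
#' @return a \linkS4class{ReferencePanel}.
#' @examples
#' p <- simulateReferencePanel(100, 20, block_size = 5,
#'                             within_block_rho = 0.8, seed = 1)
#' p
#' @export
simulateReferencePanel <- function(n_individuals, n_variants,
                                   block_size = 10,
                                   within_block_rho = 0.8,
                                   eaf_range = c(0.05, 0.5),
                                   seed = 1) {
  if (n_individuals < 50) stop("n_individuals must be >= 50")
  if (within_block_rho < 0 || within_block_rho >= 1)
    stop("within_block_rho must lie in [0, 1)")
  if (length(eaf_range) != 2L || any(eaf_range <= 0) || any(eaf_range >= 1))
    stop("eaf_range must be an interval inside (0, 1)")
  if (eaf_range[1] == eaf_range[2] && eaf_range[1] %in% c(0, 1))
    stop("degenerate eaf_range")
  set.seed(seed)
  eaf <- stats::runif(n_variants, eaf_range[1], eaf_range[2])
  block <- as.integer((seq_len(n_variants) - 1L) %/% block_size + 1L)
  dos <- .simulateDosages(n_individuals, eaf, block, within_block_rho)
  within <- (seq_len(n_variants) - 1L) %% block_size
  pos <- (block - 1) * 1e7 + within * 1000 + 1
  alleles <- c("A", "C", "G", "T")
  ea <- alleles[(seq_len(n_variants) - 1L) %% 4L + 1L]
  oa <- alleles[seq_len(n_variants) %% 4L + 1L]
  variants <- data.frame(
    snp = sprintf("rs%06d", seq_len(n_variants)),
    chr = 1L, pos = pos, ea = ea, oa = oa, eaf = eaf, info = 1.0,
    stringsAsFactors = FALSE)
  colnames(dos) <- variants$snp
  new("ReferencePanel", dosages = dos, variants = variants,
      block = block, rho = within_block_rho)
}

#' Squared dosage correlation between panel variants
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param ids optional variant ids to restrict to.
#' @return correlation matrix of dosages (not squared); square for r2.
#' @export
panelCorrelation <- function(panel, ids = NULL) {
  dos <- dosages(panel)
  if (!is.null(ids)) {
    miss <- setdiff(ids, colnames(dos))
    if (length(miss))
      stop("variants absent from panel: ", paste(miss, collapse = ", "))
    dos <- dos[, ids, drop = FALSE]
  }
  suppressWarnings(stats::cor(dos))
}
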