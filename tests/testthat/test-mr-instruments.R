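.pruningPanel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateReferencePanel(1500, 50, block_size = 5,
                                       within_block_rho = 0.9, seed = 81)
    cache
  }
})

.mkSumstats <- function(panel, p_values, betas = NULL) {
  v <- variantInfo(panel)
  if (is.null(betas)) betas <- rep(0.1, nrow(v))
  data.frame(snp = v$snp, chr = v$chr, pos = v$pos, ea = v$ea, oa = v$oa,
             eaf = v$eaf, beta = betas, se = 0.01, p = p_values,
             n = 38150, info = 1, stringsAsFactors = FALSE)
}

test_that("LD pruning keeps the smaller-p member of a linked pair", {
  p <- .pruningPanel()
  pv <- rep(0.5, 50)
  pv[1] <- 1e-20; pv[2] <- 1e-10          # same block, r2 >> 0.01
  ss <- .mkSumstats(p, pv)
  sel <- selectInstruments(ss, p)
  expect_identical(sel, "rs000001")
  # mutually unlinked candidates are all retained, order-independent
  pv2 <- rep(0.5, 50)
  pv2[c(1, 6, 11, 16)] <- c(1e-9, 1e-12, 1e-10, 1e-8)  # distinct blocks
  ss2 <- .mkSumstats(p, pv2)
  sel2 <- selectInstruments(ss2, p)
  expect_setequal(sel2, variantInfo(p)$snp[c(1, 6, 11, 16)])
  set.seed(1)
  sel3 <- selectInstruments(ss2[sample(50), ], p)
  expect_setequal(sel3, sel2)
})

test_that("greedy pruning equals an independent ordered-accept oracle", {
  p <- .pruningPanel()
  set.seed(82)
  pv <- 10^-runif(50, 6, 20)
  ss <- .mkSumstats(p, pv)
  sel <- selectInstruments(ss, p, p_max = 1e-5, r2_max = 0.01)
  # brute-force oracle written independently
  v <- variantInfo(p)
  R <- cor(dosages(p))
  ord <- order(pv, v$chr, v$pos)
  acc <- character()
  for (j in ord) {
    ok <- TRUE
    for (a in acc) if (R[v$snp[j], a]^2 >= 0.01) { ok <- FALSE; break }
    if (ok) acc <- c(acc, v$snp[j])
  }
  expect_identical(sel, acc)
})

test_that("cross-exposure LD resolution applies both preference rules", {
  p <- .pruningPanel()
  v <- variantInfo(p)
  # exposure-1 instrument rs000001 and exposure-2 instrument rs000002 are
  # in the same block (strongly linked, like the r2 = 0.73 pair)
  ss1 <- .mkSumstats(p, ifelse(v$snp == "rs000001", 1e-20, 0.5))
  ss2 <- .mkSumstats(p, ifelse(v$snp == "rs000002", 1e-30, 0.5))
  r <- resolveCrossExposureLd("rs000001", "rs000002", ss1, ss2, p,
                              prefer = "exposure2")
  expect_identical(r$instr_exp2, "rs000002")
  expect_length(r$instr_exp1, 0)           # FN-BMD-stronger SNP kept
  r2 <- resolveCrossExposureLd("rs000001", "rs000002", ss1, ss2, p,
                               prefer = "exposure1")
  expect_identical(r2$instr_exp1, "rs000001")
  expect_length(r2$instr_exp2, 0)
  expect_false(identical(r$report$kept, r2$report$kept))
  # disjoint unlinked lists are unchanged
  r3 <- resolveCrossExposureLd("rs000001", "rs000011", ss1, ss2, p)
  expect_identical(r3$instr_exp1, "rs000001")
  expect_identical(r3$instr_exp2, "rs000011")
  expect_equal(nrow(r3$report), 0)
})

test_that("three-way LD clusters resolve deterministically with a report", {
  p <- .pruningPanel()
  v <- variantInfo(p)
  ss1 <- .mkSumstats(p, ifelse(v$snp %in% c("rs000001", "rs000003"),
                               1e-15, 0.5))
  ss2 <- .mkSumstats(p, ifelse(v$snp == "rs000002", 1e-25, 0.5))
  r <- resolveCrossExposureLd(c("rs000001", "rs000003"), "rs000002",
                              ss1, ss2, p, prefer = "exposure2")
  rr <- resolveCrossExposureLd(c("rs000001", "rs000003"), "rs000002",
                               ss1, ss2, p, prefer = "exposure2")
  expect_identical(r, rr)
  # every drop is documented
  expect_equal(nrow(r$report),
               (2 - length(r$instr_exp1)) + (1 - length(r$instr_exp2)))
})

.harmTables <- function() {
  exposure <- data.frame(
    snp = c("v1", "v2", "v3", "v4", "v5"),
    ea = c("A", "C", "A", "A", "A"), oa = c("G", "G", "T", "T", "C"),
    eaf = c(0.3, 0.2, 0.48, 0.10, 0.25),
    beta = c(0.05, 0.04, 0.06, 0.07, 0.05), se = rep(0.01, 5),
    p = rep(1e-10, 5), n = 38150, stringsAsFactors = FALSE)
  outcome <- data.frame(
    snp = c("v1", "v2", "v3", "v4", "v6"),
    ea = c("G", "C", "A", "T", "A"), oa = c("A", "G", "T", "A", "C"),
    eaf = c(0.72, 0.21, 0.47, 0.88, 0.25),
    beta = c(-0.05, 0.02, 0.01, -0.03, 0.02), se = rep(0.02, 5),
    p = rep(0.01, 5), n = 300000, stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome)
}

test_that("harmonization flips swapped alleles and screens palindromes", {
  tb <- .harmTables()
  instr <- harmonizeInstruments(tb$exposure, tb$outcome)
  d <- instrumentData(instr)
  # v1: outcome alleles swapped -> sign flipped, frequency complemented
  expect_equal(d$beta_out[d$snp == "v1"], 0.05)
  expect_equal(d$eaf_out[d$snp == "v1"], 0.28)
  # v2: identical orientation kept as-is
  expect_equal(d$beta_out[d$snp == "v2"], 0.02)
  # v3: palindromic A/T with MAF 0.48 >= 0.42 -> removed, non-clear strand
  expect_false("v3" %in% d$snp)
  # v4: palindromic A/T, clear frequencies: label-swap alignment gives
  # freq(A) = 1 - 0.88 = 0.12, concordant with the exposure's 0.10, so the
  # hand-worked harmonization flips the sign once (swap) and stops
  expect_equal(d$beta_out[d$snp == "v4"], 0.03)
  expect_lt(abs(d$eaf_out[d$snp == "v4"] - 0.12), 1e-12)
  # v5 missing from the outcome -> dropped and counted
  expect_false("v5" %in% d$snp)
  drop <- attr(instr, "dropped")
  expect_equal(drop[["missing"]], 1L)
  expect_equal(drop[["palindromic_ambiguous"]], 1L)
})

test_that("irreconcilable allele pairs are dropped and counted", {
  tb <- .harmTables()
  out <- tb$outcome
  out$ea[out$snp == "v2"] <- "C"; out$oa[out$snp == "v2"] <- "A"
  instr <- harmonizeInstruments(tb$exposure, out)
  expect_false("v2" %in% instrumentData(instr)$snp)
  expect_equal(attr(instr, "dropped")[["irreconcilable"]], 1L)
})

test_that("Steiger filtering removes reverse-direction instruments only", {
  g <- c(0.10, 0.10, 0.002)
  G <- c(0.02, 0.02, 0.40)      # third variant: outcome >> exposure signal
  instr <- makeInstruments(g, G, se_g = 0.01, se_G = 0.004)
  st <- steigerFilter(instr)
  expect_identical(st$report$removed, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(instrumentData(st$instruments)), 2)
  # oracle: recompute the Steiger z for the removed variant directly
  r2e <- g[3]^2 * 2 * 0.3 * 0.7
  z <- G[3] / 0.004
  r2o <- z^2 / (z^2 + instr@nOut)
  zf <- (atanh(sqrt(r2e)) - atanh(sqrt(r2o))) /
    sqrt(1 / (instr@nExp - 3) + 1 / (instr@nOut - 3))
  expect_lt(pnorm(zf), 0.05)
  expect_equal(st$report$steiger_p[3], pnorm(zf))
  # comparable variance explained is retained (removal needs significance)
  instr_eq <- makeInstruments(c(0.1, 0.1, 0.1), c(0.02, 0.02, 0.02),
                              0.01, 0.02)
  st_eq <- steigerFilter(instr_eq)
  expect_false(any(st_eq$report$removed))
})

test_that("instrument strength is the mean squared t-ratio", {
  one <- makeInstruments(0.06, 0.01, se_g = 0.01, se_G = 0.02)
  expect_equal(instrumentStrength(one), 36)
  three <- makeInstruments(c(0.04, 0.05, 0.06), c(0, 0, 0),
                           se_g = 0.01, se_G = 0.02)
  expect_equal(instrumentStrength(three), (16 + 25 + 36) / 3)
  zero <- makeInstruments(c(0, 0), c(0, 0), se_g = 0.01, se_G = 0.02)
  expect_equal(instrumentStrength(zero), 0)
  empty <- new("InstrumentSet",
               data = data.frame(snp = character(), beta_exp = numeric(),
                                 se_exp = numeric(), beta_out = numeric(),
                                 se_out = numeric()),
               exposureNames = "e", outcomeName = "o")
  expect_error(instrumentStrength(empty), "empty")
})
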