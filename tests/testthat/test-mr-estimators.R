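test_that("IVW reproduces identical ratios and the Wald ratio delta method", {
  instr <- makeInstruments(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12),
                           se_g = 0.01, se_G = 0.02)
  r <- mrIvw(instr)
  expect_equal(r@estimate, 0.3)
  expect_equal(r@cochranQ, 0)
  expect_identical(r@effectsModel, "fixed")
  wr <- waldRatio(0.1, 0.01, 0.05, 0.05)
  expect_equal(wr$estimate, 0.5)
  expect_equal(wr$se, 0.5)
  expect_error(mrIvw(makeInstruments(0.1, 0.05, 0.01, 0.02)), "2")
  # zero-gamma instruments are excluded with a warning
  instr0 <- makeInstruments(c(0, 0.2, 0.4), c(0.03, 0.06, 0.12),
                            0.01, 0.02)
  expect_warning(r0 <- mrIvw(instr0), "zero exposure")
  expect_equal(r0@nSnps, 2)
})

test_that("IVW matches an independent weighted-least-squares oracle", {
  set.seed(91)
  g <- runif(5, 0.05, 0.2); G <- 0.35 * g + rnorm(5, 0, 0.02)
  seG <- runif(5, 0.01, 0.04)
  instr <- makeInstruments(g, G, se_g = 0.01, se_G = seG)
  r <- mrIvw(instr)
  # matrix oracle: zero-intercept WLS of G on g with weights 1/seG^2
  w <- 1 / seG^2
  est <- sum(w * g * G) / sum(w * g^2)
  se_f <- 1 / sqrt(sum(w * g^2))
  th <- G / g; wj <- g^2 / seG^2
  Q <- sum(wj * (th - est)^2)
  qp <- pchisq(Q, 4, lower.tail = FALSE)
  se <- if (qp < 0.05) se_f * max(1, sqrt(Q / 4)) else se_f
  expect_equal(r@estimate, est, tolerance = 1e-10)
  expect_equal(r@se, se, tolerance = 1e-10)
  expect_equal(r@cochranQ, Q, tolerance = 1e-10)
  # fixed-effects SE never exceeds the reported one
  expect_gte(r@se, se_f - 1e-12)
})

test_that("Egger solves exact linear systems and matches the WLS oracle", {
  g <- c(0.05, 0.1, 0.15, 0.2)
  instr <- makeInstruments(g, 0.4 * g, 0.01, 0.02)
  r <- mrEgger(instr)
  expect_equal(r@estimate, 0.4, tolerance = 1e-12)
  expect_equal(r@eggerIntercept, 0, tolerance = 1e-12)
  instr2 <- makeInstruments(g, 0.4 * g + 0.02, 0.01, 0.02)
  r2 <- mrEgger(instr2)
  expect_equal(r2@estimate, 0.4, tolerance = 1e-12)
  expect_equal(r2@eggerIntercept, 0.02, tolerance = 1e-12)
  # stochastic fixture vs independent weighted regression with intercept
  set.seed(92)
  gs <- runif(8, 0.05, 0.2); Gs <- 0.01 + 0.3 * gs + rnorm(8, 0, 0.02)
  seG <- runif(8, 0.01, 0.05)
  instr3 <- makeInstruments(gs, Gs, 0.01, seG)
  r3 <- mrEgger(instr3)
  o <- stats::lm(Gs ~ gs, weights = 1 / seG^2)
  expect_equal(r3@estimate, unname(coef(o)[2]), tolerance = 1e-10)
  expect_equal(r3@eggerIntercept, unname(coef(o)[1]), tolerance = 1e-10)
  expect_error(mrEgger(makeInstruments(g[1:2], g[1:2], 0.01, 0.02)), "3")
})

test_that("Egger orients exposure effects non-negative before fitting", {
  g <- c(0.05, -0.1, 0.15, -0.2)
  G <- 0.01 + 0.4 * g
  # flipping (gamma, Gamma) jointly leaves the oriented fit unchanged
  instr <- makeInstruments(g, G, 0.01, 0.02)
  flip <- makeInstruments(-g, -G, 0.01, 0.02)
  expect_equal(mrEgger(instr)@estimate, mrEgger(flip)@estimate,
               tolerance = 1e-12)
  o <- stats::lm(I(sign(g) * G) ~ I(abs(g)), weights = rep(1 / 0.02^2, 4))
  expect_equal(mrEgger(instr)@estimate, unname(coef(o)[2]),
               tolerance = 1e-10)
})

test_that("weighted median interpolates the cumulative-weight curve", {
  cst <- makeInstruments(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12),
                         0.01, 0.02)
  expect_equal(mrWeightedMedian(cst, 200, seed = 1)@estimate, 0.3)
  # hand-worked 5-instrument fixture with equal weights: ratios
  # (0.1, 0.2, 0.3, 0.8, 0.9), cumulative midpoints (0.1, 0.3, 0.5, ...)
  g <- rep(0.1, 5)
  G <- 0.1 * c(0.1, 0.2, 0.3, 0.8, 0.9)
  instr <- makeInstruments(g, G, 0.01, 0.02)
  expect_equal(mrWeightedMedian(instr, 200, seed = 1)@estimate, 0.3)
  expect_error(mrWeightedMedian(instr, 50), "n_boot")
  # bootstrap SE stable across seeds at the default draw count
  s1 <- mrWeightedMedian(instr, 5000, seed = 11)@se
  s2 <- mrWeightedMedian(instr, 5000, seed = 22)@se
  expect_lt(abs(s1 - s2) / s1, 0.05)
})

test_that("MR-LASSO agrees with IVW when instruments are homogeneous", {
  set.seed(93)
  g <- runif(6, 0.05, 0.2)
  G <- 0.3 * g + rnorm(6, 0, 0.005)
  instr <- makeInstruments(g, G, 0.01, 0.02)
  r <- mrLasso(instr)
  expect_length(r@outliersRemoved, 0)
  expect_equal(r@estimate, mrIvw(instr)@estimate, tolerance = 1e-8)
})

test_that("MR-LASSO flags a gross pleiotropic instrument like the subset oracle", {
  set.seed(94)
  J <- 8
  g <- runif(J, 0.08, 0.2)
  G <- 0.3 * g + rnorm(J, 0, 0.004)
  G[4] <- 5 * 0.3 * g[4]                    # gross outlier ratio
  instr <- makeInstruments(g, G, 0.01, 0.015)
  r <- mrLasso(instr)
  expect_identical(r@outliersRemoved, "s4")
  expect_lt(abs(r@estimate - 0.3), 2 * r@se)
  # subset-enumeration oracle: largest subset whose IVW Q-test is
  # admissible (p >= 0.05); outliers are its complement
  best <- NULL
  for (size in J:2) {
    combs <- utils::combn(J, size)
    admissible <- list()
    for (cidx in seq_len(ncol(combs))) {
      k <- combs[, cidx]
      w <- g[k]^2 / 0.015^2
      th <- G[k] / g[k]
      est <- sum(w * th) / sum(w)
      Q <- sum(w * (th - est)^2)
      if (pchisq(Q, length(k) - 1, lower.tail = FALSE) >= 0.05)
        admissible[[length(admissible) + 1L]] <- k
    }
    if (length(admissible)) { best <- admissible; break }
  }
  oracle_outliers <- setdiff(seq_len(J), best[[1]])
  expect_identical(r@outliersRemoved, paste0("s", oracle_outliers))
})

test_that("MVMR solves exact systems and degrades to IVW", {
  set.seed(95)
  g1 <- runif(6, 0.05, 0.2); g2 <- runif(6, -0.1, 0.1)
  G <- 0.5 * g1 - 0.8 * g2
  instr <- makeInstruments(g1, G, 0.01, 0.02, g2 = g2, se_g2 = 0.01)
  mv <- mrMvmr(instr)
  expect_equal(mv[[1]]@estimate, 0.5, tolerance = 1e-10)
  expect_equal(mv[[2]]@estimate, -0.8, tolerance = 1e-10)
  # all-zero second exposure: first estimate equals univariable IVW
  instr0 <- makeInstruments(g1, 0.5 * g1 + rnorm(6, 0, 0.01), 0.01, 0.02,
                            g2 = rep(0, 6), se_g2 = 0.01)
  mv0 <- mrMvmr(instr0)
  uni <- mrIvw(instr0)
  expect_equal(mv0[[1]]@estimate, uni@estimate, tolerance = 1e-8)
  expect_true(is.na(mv0[[2]]@estimate))
  # collinear exposures are refused with their names
  instrc <- makeInstruments(g1, G, 0.01, 0.02, g2 = 2 * g1, se_g2 = 0.01)
  expect_error(mrMvmr(instrc), "collinear")
})

test_that("all estimators are invariant to per-row sign flips", {
  set.seed(96)
  g <- runif(6, 0.05, 0.2); G <- 0.3 * g + rnorm(6, 0, 0.01)
  g2 <- runif(6, -0.1, 0.1)
  flip <- c(1, -1, 1, -1, -1, 1)
  a <- makeInstruments(g, G, 0.01, 0.02, g2 = g2, se_g2 = 0.01)
  b <- makeInstruments(flip * g, flip * G, 0.01, 0.02, g2 = flip * g2,
                       se_g2 = 0.01)
  expect_equal(mrIvw(a)@estimate, mrIvw(b)@estimate, tolerance = 1e-12)
  expect_equal(mrEgger(a)@estimate, mrEgger(b)@estimate, tolerance = 1e-12)
  expect_equal(mrWeightedMedian(a, 200, 5)@estimate,
               mrWeightedMedian(b, 200, 5)@estimate, tolerance = 1e-12)
  mva <- mrMvmr(a); mvb <- mrMvmr(b)
  expect_equal(mva[[1]]@estimate, mvb[[1]]@estimate, tolerance = 1e-12)
  expect_equal(mva[[2]]@estimate, mvb[[2]]@estimate, tolerance = 1e-12)
})

test_that("two-sample MVMR recovers planted conditional effects", {
  # two-sample design: 40 instruments per exposure, truth log(1.5) and
  # log(0.45); coverage of the 95% CI over 100 replicates
  th1 <- log(1.5); th2 <- log(0.45)
  cover1 <- cover2 <- 0L
  forearm_null <- 0L
  set.seed(97)
  for (r in 1:100) {
    g1t <- c(rnorm(40, 0, 0.06), rep(0, 40))
    g2t <- c(rnorm(40, 0, 0.02), rnorm(40, 0, 0.06))
    g1 <- g1t + rnorm(80, 0, 0.01)
    g2 <- g2t + rnorm(80, 0, 0.01)
    seG <- runif(80, 0.03, 0.06)
    G <- th1 * g1t + th2 * g2t + rnorm(80, 0, seG)
    instr <- makeInstruments(g1, G, 0.01, seG, g2 = g2, se_g2 = 0.01)
    mv <- mrMvmr(instr)
    if (mv[[1]]@ciLow <= th1 && th1 <= mv[[1]]@ciHigh) cover1 <- cover1 + 1L
    if (mv[[2]]@ciLow <= th2 && th2 <= mv[[2]]@ciHigh) cover2 <- cover2 + 1L
    # forearm-like null outcome: same instruments, zero causal effects
    Gn <- rnorm(80, 0, seG)
    mvn <- mrMvmr(makeInstruments(g1, Gn, 0.01, seG, g2 = g2,
                                  se_g2 = 0.01))
    if (abs(mvn[[1]]@estimate) < 2 * mvn[[1]]@se) forearm_null <- forearm_null + 1L
  }
  expect_gte(cover1, 90L)
  expect_gte(cover2, 90L)
  expect_gte(forearm_null, 90L)
})
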