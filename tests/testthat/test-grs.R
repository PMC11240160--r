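test_that("risk score equals the hand-aligned weighted dosage sum", {
  p <- tinyPanel(n = 300, m = 10, seed = 101)
  arch <- simulateArchitecture(p, 3, 2, 1, 0, seed = 1)
  co <- simulateCohort(p, arch, 500, seed = 2)
  v <- variantInfo(co)
  ids <- v$snp[1:10]
  w <- seq(-0.5, 0.4, by = 0.1)
  ea <- v$ea[1:10]
  ea[4] <- v$oa[4]                       # one flipped effect allele
  s <- computeGrs(co, ids, w, ea)
  # hand alignment oracle
  dos <- dosages(co)[, ids]
  dos[, 4] <- 2 - dos[, 4]
  raw <- drop(dos %*% w)
  expect_equal(s, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
  expect_lt(abs(mean(s)), 1e-8)
  expect_equal(sd(s), 1, tolerance = 1e-8)
  # single variant with unit weight is the standardized dosage
  s1 <- computeGrs(co, ids[1], 1, v$ea[1])
  expect_equal(s1, drop(scale(dosages(co)[, 1])), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(computeGrs(co, ids, rep(0, 10), ea), "zero score variance")
  expect_error(computeGrs(co, c("nope", ids[-1]), w, ea), "nope")
  expect_error(computeGrs(co, ids, w, rep("Z", 10)), "neither allele")
})

test_that("Cox fit is null-calibrated and matches a grid-search oracle", {
  # null covariate at scale
  set.seed(102)
  n <- 20000
  tt <- rexp(n, 0.02); ev <- as.integer(tt <= 15.5)
  co <- makeSurvCohort(n, pmin(tt, 15.5), ev, seed = 103)
  x <- rnorm(n)
  f <- coxFit(co, "hip_any", c("x", "sex", "age"), scores = list(x = x),
              exclude_discovery = FALSE)
  hr <- f$terms$hr[f$terms$term == "x"]
  expect_true(hr > 0.95 && hr < 1.05)

  # n = 8 hand fixture with a tie: partial likelihood grid oracle (Efron)
  time <- c(1, 2, 2, 3, 4, 5, 6, 7)
  status <- c(1, 1, 1, 0, 1, 0, 1, 1)
  z <- c(1, 0, 1, 0, 1, 1, 0, 0)
  efron_loglik <- function(b) {
    r <- exp(b * z)
    ll <- 0
    for (t in unique(time[status == 1])) {
      D <- which(time == t & status == 1)
      R <- which(time >= t)
      sR <- sum(r[R]); sD <- sum(r[D]); d <- length(D)
      ll <- ll + sum(b * z[D])
      for (k in seq_len(d) - 1) ll <- ll - log(sR - k / d * sD)
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  oracle_b <- grid[which.max(vapply(grid, efron_loglik, numeric(1)))]
  fit <- survival::coxph(survival::Surv(time, status) ~ z, ties = "efron")
  expect_lt(abs(unname(coef(fit)) - oracle_b), 1e-4)

  # two-group rate ratio 2 is recovered
  set.seed(104)
  n2 <- 20000
  grp <- rep(0:1, each = n2 / 2)
  tt2 <- rexp(n2, 0.01 * 2^grp)
  ev2 <- as.integer(tt2 <= 15.5)
  co2 <- makeSurvCohort(n2, pmin(tt2, 15.5), ev2, seed = 105)
  f2 <- coxFit(co2, "hip_any", c("g", "sex", "age"),
               scores = list(g = grp), exclude_discovery = FALSE)
  row <- f2$terms[f2$terms$term == "g", ]
  expect_lt(abs(row$coef - log(2)), 2 * row$se)
})

test_that("a planted per-SD score log-hazard of 0.1 is recovered", {
  set.seed(106)
  n <- 50000
  s <- rnorm(n)
  tt <- rexp(n, 0.005 * exp(0.1 * s))
  ev <- as.integer(tt <= 15.5)
  co <- makeSurvCohort(n, pmin(tt, 15.5), ev, seed = 107)
  expect_gt(sum(ev), 3000)
  f <- coxFit(co, "hip_any", c("grs", "sex", "age"),
              scores = list(grs = s), exclude_discovery = FALSE)
  row <- f$terms[f$terms$term == "grs", ]
  expect_lt(abs(row$coef - 0.1), 2 * row$se)
  expect_lt(abs(row$hr - 1.105), 0.05)
})

test_that("survival fits exclude prevalent cases and the discovery set", {
  p <- tinyPanel(n = 200, m = 10, seed = 108)
  arch <- simulateArchitecture(p, 3, 2, 1, 0, seed = 1)
  co <- simulateCohort(p, arch, 20000, seed = 109,
                       baseline_hazard = c(fn = 3e-3, trochanteric = 2e-3,
                                           forearm = 3e-3))
  s <- rnorm(20000)
  f_ex <- coxFit(co, "hip_any", c("grs", "sex", "age"),
                 scores = list(grs = s), exclude_discovery = TRUE)
  keep <- fractureEvents(co)$prevalent_hip_any == 0 & !discoveryFlag(co)
  expect_equal(f_ex$n, sum(keep))
  f_in <- coxFit(co, "hip_any", c("grs", "sex", "age"),
                 scores = list(grs = s), exclude_discovery = FALSE)
  expect_equal(f_in$n, sum(fractureEvents(co)$prevalent_hip_any == 0))
  # reversing score weights flips the fitted log-hazard sign
  f_neg <- coxFit(co, "hip_any", c("grs", "sex", "age"),
                  scores = list(grs = -s), exclude_discovery = TRUE)
  expect_equal(f_neg$terms$coef[f_neg$terms$term == "grs"],
               -f_ex$terms$coef[f_ex$terms$term == "grs"],
               tolerance = 1e-6)
})

test_that("interaction p-values are uniform under the null", {
  set.seed(110)
  pvals <- vapply(1:200, function(r) {
    n <- 2000
    s <- rnorm(n)
    tt <- rexp(n, 0.02)
    ev <- as.integer(tt <= 15.5)
    co <- makeSurvCohort(n, pmin(tt, 15.5), ev, seed = 300 + r)
    ti <- testInteraction(co, "hip_any", c("grs", "age"),
                          scores = list(grs = s),
                          exclude_discovery = FALSE)
    ti$p
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("an age-varying score effect is detected and stratified fits show it", {
  set.seed(111)
  hits <- 0L
  for (r in 1:100) {
    n <- 50000
    s <- rnorm(n)
    age <- rnorm(n, 64, 7.5)
    young <- age <= 71.7
    b <- ifelse(young, 0.3, 0.0)         # stronger effect below the split
    tt <- rexp(n, 0.008 * exp(b * s))
    ev <- as.integer(tt <= 15.5)
    co <- makeSurvCohort(n, pmin(tt, 15.5), ev, age = age, seed = 400 + r)
    ti <- testInteraction(co, "hip_any", c("grs", "age"),
                          scores = list(grs = s),
                          exclude_discovery = FALSE)
    if (ti$p < 0.05 && ti$coef < 0) hits <- hits + 1L
    if (r == 1) {
      lo <- ti$stratified$below$terms
      hi <- ti$stratified$above$terms
      expect_gt(lo$coef[lo$term == "grs"], hi$coef[hi$term == "grs"])
    }
  }
  expect_gte(hits, 80L)
})

test_that("binarized groups partition as expected under independence", {
  set.seed(112)
  n <- 100000
  sf <- rnorm(n); sb <- rnorm(n)
  g50 <- binarizeGroups(sf, sb, 50)
  shares <- tabulate(g50$group, 4) / n
  expect_true(all(abs(shares - 0.25) < 0.01))
  g10 <- binarizeGroups(sf, sb, 10)
  expect_lt(abs(mean(g10$group == 4) - 0.01), 0.005)
  # sort-based oracle for exact membership
  ord_f <- sort(sf, decreasing = TRUE)[n / 4]
  ord_b <- sort(sb)[n / 4]
  g25 <- binarizeGroups(sf, sb, 25)
  oracle <- 1L + (sf >= sort(sf)[n - n / 4 + 1]) * 1L + (sb <= sort(sb)[n / 4]) * 2L
  expect_identical(g25$group, oracle)
  expect_error(binarizeGroups(sf, sb, 30), "cutoff")
  expect_warning(binarizeGroups(sf, sb, 30, allow_other = TRUE), "cutoff")
  expect_error(binarizeGroups(sf, sb[1:10], 50), "length")
})

test_that("group hazard ratios recover planted additive risks", {
  set.seed(113)
  n <- 100000
  sf <- rnorm(n); sb <- rnorm(n)
  ga <- binarizeGroups(sf, sb, 10)
  # null: all groups share one hazard
  tt <- rexp(n, 0.01)
  co <- makeSurvCohort(n, pmin(tt, 15.5), as.integer(tt <= 15.5),
                       seed = 114)
  f0 <- groupHazardRatios(co, ga, "hip_any", exclude_discovery = FALSE)
  hrs <- f0$terms$hr[grepl("^group", f0$terms$term)]
  expect_true(all(hrs > 0.9 & hrs < 1.1))
  # planted doubled hazard in the yes/yes group
  rate <- 0.01 * ifelse(ga$group == 4L, 2, 1)
  tt2 <- rexp(n, rate)
  co2 <- makeSurvCohort(n, pmin(tt2, 15.5), as.integer(tt2 <= 15.5),
                        seed = 115)
  f2 <- groupHazardRatios(co2, ga, "hip_any", exclude_discovery = FALSE)
  g4 <- f2$terms[f2$terms$term == "group4", ]
  expect_lt(abs(g4$coef - log(2)), 2 * g4$se)
})

test_that("the yes/yes group dominates when both scores act additively", {
  set.seed(116)
  wins <- 0L
  for (r in 1:100) {
    n <- 20000
    sf <- rnorm(n); sb <- rnorm(n)
    # FNW raises hazard, BMD lowers it (its low tail raises risk)
    tt <- rexp(n, 0.01 * exp(0.25 * sf - 0.35 * sb))
    co <- makeSurvCohort(n, pmin(tt, 15.5), as.integer(tt <= 15.5),
                         seed = 500 + r)
    ga <- binarizeGroups(sf, sb, 25)
    f <- groupHazardRatios(co, ga, "hip_any", exclude_discovery = FALSE)
    hr <- setNames(f$terms$hr, f$terms$term)
    if (hr[["group4"]] >= max(hr[["group2"]], hr[["group3"]]))
      wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})
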