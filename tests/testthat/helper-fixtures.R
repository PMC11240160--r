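## Shared fixtures and independent oracles. Oracles deliberately avoid the
## package's own code paths.

# independent point-to-segment distance (projection form, written plainly)
oraclePointSegDist <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
  sqrt(sum((a + t * ab - p)^2))
}

# dense-sampling polyline distance oracle: sample k points per segment
# (including endpoints) on each polyline and take the minimum of their
# exact distances to the opposite polyline's segments
oraclePolylineDist <- function(A, B, k = 50) {
  densify <- function(P) {
    out <- list()
    for (i in seq_len(nrow(P) - 1)) {
      t <- seq(0, 1, length.out = k)
      out[[i]] <- cbind(P[i, 1] + t * (P[i + 1, 1] - P[i, 1]),
                        P[i, 2] + t * (P[i + 1, 2] - P[i, 2]))
    }
    do.call(rbind, out)
  }
  distTo <- function(pts, P) {
    best <- Inf
    for (i in seq_len(nrow(P) - 1)) {
      a <- P[i, ]; b <- P[i + 1, ]
      ab <- b - a; L2 <- sum(ab^2)
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) /
        max(L2, 1e-300)
      t <- pmin(1, pmax(0, t))
      dx <- a[1] + t * ab[1] - pts[, 1]
      dy <- a[2] + t * ab[2] - pts[, 2]
      best <- min(best, sqrt(min(dx * dx + dy * dy)))
    }
    best
  }
  min(distTo(densify(A), B), distTo(densify(B), A))
}

# panel with half unlinked variants and half strong-LD blocks, giving the
# wide LD-score spread that LD score regression needs
mixedLdPanel <- function(n_ref = 600, m_half = 2500, seed = 61) {
  p1 <- simulateReferencePanel(n_ref, m_half, 1, 0, seed = seed)
  p2 <- simulateReferencePanel(n_ref, m_half, 20, 0.95, seed = seed + 1)
  v2 <- variantInfo(p2)
  v2$chr <- 2L
  v2$snp <- sub("rs", "rx", v2$snp)
  d2 <- dosages(p2)
  colnames(d2) <- v2$snp
  new("ReferencePanel", dosages = cbind(dosages(p1), d2),
      variants = rbind(variantInfo(p1), v2),
      block = c(p1@block, max(p1@block) + p2@block), rho = 0.95)
}

# small reference panel shared across tests (unlinked unless stated)
tinyPanel <- function(n = 300, m = 40, bs = 1, rho = 0, seed = 11)
  simulateReferencePanel(n, m, block_size = bs, within_block_rho = rho,
                         seed = seed)

# build a Cohort container directly from survival ingredients, for tests
# that plant hazards without running the genotype simulator
makeSurvCohort <- function(n, time, event, prevalent = rep(0L, n),
                           sex = NULL, age = NULL, followup = 15.5,
                           seed = 1) {
  set.seed(seed)
  if (is.null(sex)) sex <- rep(0:1, length.out = n)
  if (is.null(age)) age <- rnorm(n, 64, 7.5)
  dos <- matrix(rbinom(n, 2, 0.3), n, 1,
                dimnames = list(NULL, "rs000001"))
  v <- data.frame(snp = "rs000001", chr = 1L, pos = 1, ea = "A", oa = "G",
                  eaf = 0.3, info = 1, stringsAsFactors = FALSE)
  pcs <- matrix(0, n, 20, dimnames = list(NULL, paste0("pc", 1:20)))
  covs <- data.frame(sex = sex, age = age, chip = 0L, pcs,
                     height = 170, weight = 75, bmi = 25.9)
  ev <- data.frame(row.names = seq_len(n))
  for (s in c("hip_any", "fn", "trochanteric", "forearm")) {
    ev[[paste0("event_", s)]] <- event
    ev[[paste0("time_", s)]] <- time
    ev[[paste0("prevalent_", s)]] <- prevalent
  }
  new("Cohort", dosages = dos, variants = v, covariates = covs,
      pheno = data.frame(fnw_mm = rnorm(n, 31.7, 3.5), fnw_sd = rnorm(n),
                         bmd_sd = rnorm(n)),
      events = ev, discovery = rep(FALSE, n), followupYr = followup)
}

# instrument set builder for estimator tests
makeInstruments <- function(g, G, se_g, se_G, g2 = NULL, se_g2 = NULL,
                            eaf = NULL, snp = NULL) {
  J <- length(g)
  if (is.null(eaf)) eaf <- rep(0.3, J)
  if (is.null(snp)) snp <- paste0("s", seq_len(J))
  d <- data.frame(snp = snp, ea = "A", oa = "G", eaf = eaf,
                  beta_exp = g, se_exp = se_g, beta_out = G, se_out = se_G,
                  stringsAsFactors = FALSE)
  if (!is.null(g2)) { d$beta_exp2 <- g2; d$se_exp2 <- se_g2 }
  new("InstrumentSet", data = d,
      exposureNames = if (is.null(g2)) "exp1" else c("exp1", "exp2"),
      outcomeName = "out", nExp = 38150, nOut = 300000,
      nExp2 = if (is.null(g2)) NA_real_ else 30000)
}
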