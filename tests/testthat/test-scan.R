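test_that("gaussian LOD scores match the direct RSS computation everywhere", {
  set.seed(21)
  n <- 80
  cr <- sim_cross("f2", sim_map(2, 3, 15), n = n, seed = 9)
  sm <- sim_spatial(n, seed = 10)
  gp <- calc_genoprob(cr, step = 8)
  y <- rnorm(n)
  cov1 <- rnorm(n)
  ss <- scan_self(gp, y, covariates = cbind(cov1))
  ni <- neighbor_identity(gp, sm, s = 40)
  sn <- scan_neighbor(gp, ni, y, covariates = cbind(cov1), self_scan = ss)
  X0 <- cbind(1, cov1)
  for (k in seq_len(nrow(ss))) {
    P <- gp$prob[, k, ]
    add <- drop(P %*% c(-1, 0, 1))
    dom <- P[, 2]
    expect_equal(ss$lod_self[k],
                 oracle_lod_gauss(y, X0, cbind(X0, add, dom)),
                 tolerance = 1e-8)
    # neighbor LOD: self effect fixed from its own fit, then z and z^2 added
    b <- stats::lm(y ~ cov1 + add + dom)$coefficients
    ghat <- b["add"] * add + b["dom"] * dom
    z <- ni$value[, k]
    expect_equal(sn$lod_nei[k],
                 oracle_lod_gauss(y, cbind(X0, ghat),
                                  cbind(X0, ghat, z, z^2)),
                 tolerance = 1e-8)
  }
})

test_that("noiseless traits recover the generating effects exactly", {
  # F2, y = self effects with a1 = 0.5, d1 = 0: reported 2a1 = 1 at the marker
  geno <- matrix(rep(1:3, each = 10), ncol = 1)
  cr <- det_cross(geno, 0, "f2")
  gp <- calc_genoprob(cr, error_prob = 0)
  y <- c(0.5, 0, -0.5)[geno[, 1]]
  ss <- scan_self(gp, y + rnorm(30, sd = 1e-8))
  expect_equal(ss$eff_2a1[1], 1, tolerance = 1e-4)
  expect_equal(ss$eff_d1[1], 0, tolerance = 1e-4)
  expect_gt(ss$lod_self[1], 50)

  # selfed RIL, y equals the mean neighbor identity: linear coefficient 2a2^2 = 2
  set.seed(22)
  geno2 <- matrix(sample(c(1L, 3L), 40, TRUE), ncol = 2)
  cr2 <- det_cross(geno2, c(0, 20), "riself")
  gp2 <- calc_genoprob(cr2, step = Inf, error_prob = 0)
  sm2 <- line_smap(20)
  ni2 <- neighbor_identity(gp2, sm2, s = 3)
  y2 <- ni2$value[, 1]
  sn2 <- scan_neighbor(gp2, ni2, y2 + rnorm(20, sd = 1e-9))
  expect_equal(sn2$eff_2a2sq[1], 2, tolerance = 1e-4)
  expect_gt(sn2$eff_2a2sq[1], 0) # positive: sharing alleles raises the trait
})

test_that("null traits give near-zero LOD on average and nesting keeps LODs non-negative", {
  set.seed(23)
  n <- 200
  cr <- sim_cross("f2", n = n, seed = 30)
  sm <- sim_spatial(n, seed = 31)
  gp <- calc_genoprob(cr, step = Inf)
  ni <- neighbor_identity(gp, sm, s = 30)
  mean_self <- mean_nei <- numeric(20)
  for (r in 1:20) {
    y <- rnorm(n)
    ss <- scan_self(gp, y)
    sn <- scan_neighbor(gp, ni, y, self_scan = ss)
    expect_true(all(ss$lod_self >= 0))
    expect_true(all(sn$lod_nei >= 0))
    mean_self[r] <- mean(ss$lod_self)
    mean_nei[r] <- mean(sn$lod_nei)
  }
  expect_lt(mean(mean_self), 0.5)
  expect_lt(mean(mean_nei), 0.5)
})

test_that("traits without neighbor effects keep LOD_nei low at the self QTL", {
  set.seed(24)
  lods <- numeric(20)
  cr <- sim_cross("f2", n = 150, seed = 40)
  sm <- sim_spatial(150, seed = 41)
  gp <- calc_genoprob(cr, step = Inf)
  ni <- neighbor_identity(gp, sm, s = 30)
  major <- 7
  add <- c(-1, 0, 1)[cr$geno[, major]]
  for (r in 1:20) {
    y <- 0.56 * add + rnorm(150)
    sn <- scan_neighbor(gp, ni, y)
    lods[r] <- sn$lod_nei[major]
  }
  expect_lt(mean(lods), 0.5)
})

test_that("backcross-linear and inbred-linear codings give identical neighbor LODs", {
  set.seed(25)
  n <- 60
  map <- sim_map(1, 4, 15)
  cr_bc <- sim_cross("backcross", map, n = n, seed = 50)
  # same two-genotype data relabelled as an inbred line (AB -> BB)
  geno_ril <- cr_bc$geno
  geno_ril[geno_ril == 2L] <- 3L
  cr_ril <- cross_population(geno_ril, map, "riself")
  sm <- sim_spatial(n, seed = 51)
  y <- rnorm(n)
  gp_bc <- calc_genoprob(cr_bc, step = Inf, error_prob = 0)
  gp_ril <- calc_genoprob(cr_ril, step = Inf, error_prob = 0)
  ni_bc <- neighbor_identity(gp_bc, sm, 30, coding = "backcross_linear")
  ni_ril <- neighbor_identity(gp_ril, sm, 30, coding = "inbred_linear")
  sn_bc <- scan_neighbor(gp_bc, ni_bc, y)
  sn_ril <- scan_neighbor(gp_ril, ni_ril, y)
  expect_equal(sn_bc$lod_nei, sn_ril$lod_nei, tolerance = 1e-8)
})

test_that("binomial LOD scores match the logistic deviance oracle", {
  set.seed(26)
  n <- 120
  cr <- sim_cross("riself", sim_map(1, 4, 15), n = n, seed = 60)
  sm <- sim_spatial(n, seed = 61)
  gp <- calc_genoprob(cr, step = Inf)
  add3 <- drop(gp$prob[, 3, ] %*% c(-1, 0, 1))
  y <- rbinom(n, 1, plogis(0.8 * add3))
  ss <- scan_self(gp, y, family = "binomial")
  expect_true(all(ss$lod_self >= 0))
  for (k in c(1, 3)) {
    add <- drop(gp$prob[, k, ] %*% c(-1, 0, 1))
    d0 <- glm(y ~ 1, family = binomial())$deviance
    d1 <- glm(y ~ scale(add), family = binomial())$deviance
    expect_equal(ss$lod_self[k], (d0 - d1) / (2 * log(10)), tolerance = 1e-6)
  }
  expect_gt(ss$lod_self[3], 1) # signal at the simulated locus
})

test_that("scan errors are informative", {
  cr <- sim_cross("f2", sim_map(1, 3, 10), n = 30, seed = 70)
  gp <- calc_genoprob(cr, step = Inf)
  expect_error(scan_self(gp, rep(1, 30)), "constant")
  expect_error(scan_self(gp, rnorm(10)), "does not match")
  expect_error(scan_self(gp, rnorm(30), family = "binomial"), "0/1")
})
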