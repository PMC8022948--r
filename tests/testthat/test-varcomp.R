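test_that("K1 equals a hand-computed cross-product on a tiny example", {
  # 2 individuals x 3 markers, zero-mean score columns so centering is a no-op
  pr <- array(0, c(2, 3, 3))
  pr[1, 1, ] <- c(1, 0, 0);   pr[2, 1, ] <- c(0, 0, 1)
  pr[1, 2, ] <- c(0.8, 0.2, 0); pr[2, 2, ] <- c(0, 0.2, 0.8)
  pr[1, 3, ] <- c(0, 1, 0);   pr[2, 3, ] <- c(0, 1, 0)
  gp <- manual_gp(pr, pos = c(0, 10, 20))
  K <- build_covariance(gp, line_smap(2), s = 2, standardize = FALSE)
  P1 <- cbind(c(-1, 1), c(-0.8, 0.8), c(0, 0)) # expected -1/0/1 scores
  expect_equal(unname(K$K1), tcrossprod(P1) / 2, tolerance = 1e-12)
  expect_equal(K$q, 3)
})

test_that("identical individuals are maximally similar and K matrices stay PSD", {
  pr <- array(0, c(3, 2, 3))
  pr[1, , 1] <- 1; pr[2, , 1] <- 1; pr[3, , 3] <- 1
  gp <- manual_gp(pr, pos = c(0, 10))
  K <- build_covariance(gp, line_smap(3), s = 3, standardize = FALSE)
  expect_equal(K$K1[1, 2], K$K1[1, 1], tolerance = 1e-12)

  set.seed(41)
  cr <- sim_cross("riself", n = 60, seed = 100)
  sm <- sim_spatial(60, seed = 101)
  gp2 <- calc_genoprob(cr, step = Inf)
  K2 <- build_covariance(gp2, sm, s = 30)
  expect_gt(min(eigen(K2$K1, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_gt(min(eigen(K2$K2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # K2 is even under a genome-wide allele swap (homozygote pair weights)
  gp_sw <- gp2
  gp_sw$prob <- gp2$prob[, , 3:1, drop = FALSE]
  dimnames(gp_sw$prob)[[3]] <- c("AA", "AB", "BB")
  gp_sw$cross_type <- "riself"
  K2_sw <- build_covariance(gp_sw, sm, s = 30)
  expect_equal(K2$K2, K2_sw$K2, tolerance = 1e-10)
})

test_that("REML matches a dense grid search over variance proportions", {
  set.seed(42)
  n <- 50
  cr <- sim_cross("f2", sim_map(2, 4, 15), n = n, seed = 110)
  sm <- sim_spatial(n, seed = 111)
  gp <- calc_genoprob(cr, step = Inf)
  K <- build_covariance(gp, sm, s = 40)
  L1 <- t(chol(K$K1 + diag(1e-6, n)))
  y <- drop(L1 %*% rnorm(n)) * 0.8 + rnorm(n)
  fit <- fit_varcomp(y, K)
  X <- matrix(1, n, 1)
  grid_best <- oracle_reml_grid(y, X, K$K1, K$K2, step = 0.02)
  expect_lt(abs(fit$loglik - grid_best), 0.05)
  expect_gte(fit$loglik, grid_best - 0.05) # optimizer at least as good as the grid
})

test_that("variance components shrink on null traits and recover equal shares", {
  set.seed(43)
  n <- 200
  cr <- sim_cross("f2", n = n, seed = 120)
  sm <- sim_spatial(n, seed = 121)
  gp <- calc_genoprob(cr, step = Inf)
  K <- build_covariance(gp, sm, s = 30)
  ok <- 0
  for (r in 1:20) {
    fit <- suppressWarnings(fit_varcomp(rnorm(n), K))
    g <- glance(fit)
    if (g$pve_self < 0.1 && g$pve_nei < 0.1) ok <- ok + 1
  }
  expect_gte(ok, 18)

  # equal thirds of variance from K1, K2, and noise at n = 400
  set.seed(44)
  n2 <- 400
  cr2 <- sim_cross("f2", n = n2, seed = 130)
  sm2 <- sim_spatial(n2, seed = 131)
  gp2 <- calc_genoprob(cr2, step = Inf)
  K2 <- build_covariance(gp2, sm2, s = 30)
  La <- t(chol(K2$K1 + diag(1e-6, n2)))
  Lb <- t(chol(K2$K2 + diag(1e-6, n2)))
  y2 <- drop(La %*% rnorm(n2)) + drop(Lb %*% rnorm(n2)) + rnorm(n2)
  fit2 <- fit_varcomp(y2, K2)
  g2 <- glance(fit2)
  expect_gt(g2$pve_self, 0.20); expect_lt(g2$pve_self, 0.46)
  expect_gt(g2$pve_nei, 0.20); expect_lt(g2$pve_nei, 0.46)
})

test_that("PVEs are normalized, scale-invariant, and h2 is the single-kernel fit", {
  set.seed(45)
  n <- 80
  cr <- sim_cross("riself", n = n, seed = 140)
  sm <- sim_spatial(n, seed = 141)
  gp <- calc_genoprob(cr, step = Inf)
  K <- build_covariance(gp, sm, s = 30)
  y <- drop(t(chol(K$K1 + diag(1e-6, n))) %*% rnorm(n)) + rnorm(n)
  fit <- suppressWarnings(fit_varcomp(y, K))
  tot <- sum(fit$sigma2)
  expect_equal(fit$pve$pve_self, unname(fit$sigma2[1] / tot), tolerance = 1e-12)
  expect_equal(fit$pve$pve_nei, unname(fit$sigma2[2] / tot), tolerance = 1e-12)
  expect_lte(fit$pve$pve_self + fit$pve$pve_nei, 1)

  fit_c <- suppressWarnings(fit_varcomp(10 * y, K))
  expect_equal(unname(fit_c$sigma2), unname(100 * fit$sigma2), tolerance = 1e-4)
  expect_equal(fit_c$pve$pve_self, fit$pve$pve_self, tolerance = 1e-6)

  h2 <- marker_h2(y, K)
  f1 <- attr(h2, "fit")
  expect_equal(as.numeric(h2), f1$theta[1] / sum(f1$theta), tolerance = 1e-12)
  expect_gte(as.numeric(h2), 0)
})

test_that("binary traits are fitted by PQL and profiled with RVE", {
  set.seed(46)
  n <- 120
  cr <- sim_cross("riself", n = n, seed = 150)
  sm <- sim_spatial(n, seed = 151)
  gp <- calc_genoprob(cr, step = Inf)
  K <- build_covariance(gp, sm, s = 30)
  eta <- drop(t(chol(K$K1 + diag(1e-6, n))) %*% rnorm(n))
  yb <- rbinom(n, 1, plogis(eta))
  fit <- suppressWarnings(fit_varcomp(yb, K, family = "binomial"))
  expect_named(fit$sigma2, c("sigma1_sq", "sigma2_sq"))
  expect_gte(glance(fit)$rve_nei, 0)

  prof <- suppressWarnings(
    delta_pve(gp, sm, yb, family = "binomial",
              scales = distance_scales(sm, 25)))
  expect_true("rve_nei" %in% names(prof))
  expect_true(is.numeric(attr(prof, "s_hat")))
})

test_that("the delta-PVE profile selects the increment-maximizing scale", {
  set.seed(47)
  n <- 150
  sc <- sim_scenario("additive", n = n, distance_percentile = 10, seed = 160)
  sim <- sim_phenotype(sc)
  gp <- calc_genoprob(sim$cross, step = Inf)
  prof <- delta_pve(gp, sim$smap, sim$y)
  expect_s3_class(prof, "pve_profile")
  usable <- prof$converged & is.finite(prof$delta_pve)
  expect_equal(attr(prof, "s_hat"),
               prof$s[usable][which.max(prof$delta_pve[usable])])
  # increments reconstruct the PVE levels over usable scales
  expect_equal(cumsum(prof$delta_pve[usable]), prof$pve_nei[usable],
               tolerance = 1e-10)
  # one usable scale: returned with a warning
  expect_warning(
    prof1 <- delta_pve(gp, sim$smap, sim$y,
                       scales = distance_scales(sim$smap, 50)[1, ]),
    "one candidate")
  expect_equal(attr(prof1, "s_hat"), distance_scales(sim$smap, 50)$s[1])
})
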