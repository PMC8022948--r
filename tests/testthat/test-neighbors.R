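test_that("distance scales are pairwise-distance percentiles", {
  # a single pairwise distance collapses every percentile to one scale
  sm <- tibble::tibble(id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  sc <- distance_scales(sm, 10)
  expect_equal(sc$s, 5)
  expect_equal(sc$percentile, 10) # smallest percentile kept on ties

  # 100 points on an integer grid vs a sort-based percentile oracle
  sm2 <- tibble::tibble(id = paste0("i", 1:100),
                        x = rep(1:10, 10), y = rep(1:10, each = 10))
  sc2 <- distance_scales(sm2, 10)
  d <- sort(as.vector(dist(cbind(sm2$x, sm2$y))))
  oracle_pct <- function(p) { # linear-interpolation percentile on sorted values
    h <- (length(d) - 1) * p + 1
    lo <- floor(h)
    d[lo] + (h - lo) * (d[min(lo + 1, length(d))] - d[lo])
  }
  expect_equal(sc2$s, vapply(sc2$percentile / 100, oracle_pct, 0))
  expect_true(all(diff(sc2$s) > 0))

  expect_error(distance_scales(tibble::tibble(id = 1:3, x = 1, y = 1)),
               "coincident")
  expect_error(distance_scales(sm, 60), "percentile_step")
})

test_that("pair codings encode the published genotype-identity weights", {
  Cq <- identity_coding("quadratic")
  expect_equal(Cq["AA", ], c(AA = 1, AB = 0.25, BB = -1))
  expect_equal(Cq["AB", ], c(AA = 0.25, AB = 0, BB = -0.25))
  expect_equal(Cq, t(Cq))
  Ca <- identity_coding("additive")
  expect_equal(Ca["AA", ], c(AA = 1, AB = 0.5, BB = -1))
  Ci <- identity_coding("inbred_linear")
  expect_equal(diag(Ci), c(AA = 1, AB = 0, BB = 1))
  expect_equal(Ci["AA", "BB"], -1)
  Cb <- identity_coding("backcross_linear")
  expect_equal(Cb[1:2, 1:2], matrix(c(1, -1, -1, 1), 2, 2,
                                    dimnames = list(c("AA", "AB"), c("AA", "AB"))))
})

test_that("deterministic pairs give the expected identity values", {
  # all AA with certainty: identity +1 everywhere (inbred coding)
  pr <- array(0, c(3, 2, 3)); pr[, , 1] <- 1
  gp <- manual_gp(pr, cross_type = "riself")
  ni <- neighbor_identity(gp, line_smap(3), s = 10, coding = "inbred_linear")
  expect_true(all(ni$value == 1))

  # opposite homozygotes: -1
  pr2 <- array(0, c(2, 1, 3)); pr2[1, 1, 1] <- 1; pr2[2, 1, 3] <- 1
  gp2 <- manual_gp(pr2, pos = 0, cross_type = "riself")
  ni2 <- neighbor_identity(gp2, line_smap(2), s = 2, coding = "inbred_linear")
  expect_equal(unname(ni2$value[, 1]), c(-1, -1))

  # focal AA, neighbor AB under the quadratic coding contributes 0.25
  pr3 <- array(0, c(2, 1, 3)); pr3[1, 1, 1] <- 1; pr3[2, 1, 2] <- 1
  gp3 <- manual_gp(pr3, pos = 0, cross_type = "f2")
  ni3 <- neighbor_identity(gp3, line_smap(2), s = 2, coding = "quadratic")
  expect_equal(unname(ni3$value[, 1]), c(0.25, 0.25))

  # both individuals p = (0.5, 0, 0.5): expected product cancels to 0
  pr4 <- array(0, c(2, 1, 3)); pr4[, 1, 1] <- 0.5; pr4[, 1, 3] <- 0.5
  gp4 <- manual_gp(pr4, pos = 0, cross_type = "riself")
  ni4 <- neighbor_identity(gp4, line_smap(2), s = 2, coding = "inbred_linear")
  expect_equal(unname(ni4$value[, 1]), c(0, 0))
})

test_that("identity equals a brute-force double sum for small deterministic sets", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    geno <- matrix(sample(1:3, n * 2, TRUE), n, 2)
    pr <- array(0, c(n, 2, 3))
    for (i in 1:n) for (k in 1:2) pr[i, k, geno[i, k]] <- 1
    gp <- manual_gp(pr, pos = c(0, 10))
    sm <- tibble::tibble(id = paste0("ind", 1:n),
                         x = runif(n, 0, 4), y = runif(n, 0, 4))
    s <- 2.5
    C <- identity_coding("quadratic")
    ni <- neighbor_identity(gp, sm, s, coding = "quadratic",
                            zero_policy = "drop")
    D <- as.matrix(dist(cbind(sm$x, sm$y)))
    for (i in 1:n) for (k in 1:2) {
      js <- setdiff(which(D[i, ] <= s), i)
      if (length(js) == 0) {
        expect_true(is.na(ni$value[i, k]))
      } else {
        expect_equal(unname(ni$value[i, k]),
                     mean(C[cbind(geno[i, k], geno[js, k])]), tolerance = 1e-12)
      }
    }
  }
})

test_that("identity is invariant under a genome-wide allele swap on homozygotes", {
  # the swap is even on homozygote pairs (a2^2 terms); heterozygote cross
  # terms (a2 d2) change sign with a2, so invariance is checked where it holds
  set.seed(12)
  n <- 12
  pr <- array(0, c(n, 3, 3))
  haa <- runif(n * 3)
  pr[, , 1] <- haa
  pr[, , 3] <- 1 - haa
  gp <- manual_gp(pr, pos = c(0, 10, 20), cross_type = "riself")
  gp_sw <- gp
  gp_sw$prob <- gp$prob[, , 3:1, drop = FALSE] # AA <-> BB
  dimnames(gp_sw$prob)[[3]] <- c("AA", "AB", "BB")
  sm <- tibble::tibble(id = paste0("ind", 1:n), x = runif(n, 0, 5), y = runif(n, 0, 5))
  for (cod in c("quadratic", "inbred_linear")) {
    ni <- neighbor_identity(gp, sm, 3, coding = cod, zero_policy = "drop")
    ni_sw <- neighbor_identity(gp_sw, sm, 3, coding = cod, zero_policy = "drop")
    expect_equal(ni$value, ni_sw$value, tolerance = 1e-12)
    # bounded by the largest coding weight after L-scaling
    expect_true(all(abs(ni$value) <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("neighbor counts grow with the scale and isolated individuals are flagged", {
  sm <- line_smap(6)
  cr <- sim_cross("riself", sim_map(1, 3, 10), n = 6, seed = 3)
  gp <- calc_genoprob(cr, step = Inf)
  Ls <- sapply(c(1, 2.5, 5, 10), function(s) {
    neighbor_identity(gp, sm, s)$L
  })
  expect_true(all(apply(Ls, 1, function(v) all(diff(v) >= 0))))

  sm_iso <- tibble::tibble(id = paste0("ind", 1:6),
                           x = c(1:5, 50), y = 0)
  expect_error(neighbor_identity(gp, sm_iso, 2), "ind6")
  ni <- neighbor_identity(gp, sm_iso, 2, zero_policy = "drop")
  expect_true(all(is.na(ni$value[6, ])))
  expect_true(all(!is.na(ni$value[1:5, ])))
})
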