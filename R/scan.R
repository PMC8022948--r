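# Genome scans: self-QTL effects (Haley-Knott regression on expected genotype
# scores), then neighbor QTL effects conditional on the fitted self effect.

# --- phenotype plumbing -----------------------------------------------------

resolve_phenotype <- function(pheno, trait = NULL, covariates = NULL,
                              family = "gaussian", n = NULL) {
  family <- match.arg(family, c("gaussian", "binomial"))
  if (is.data.frame(pheno)) {
    if (is.null(trait)) abort("`trait` must name a phenotype column")
    if (!trait %in% names(pheno)) abort(paste0("trait '", trait, "' not found"))
    y <- as.numeric(pheno[[trait]])
    Xc <- NULL
    if (!is.null(covariates) && length(covariates) > 0) {
      missing_cov <- setdiff(covariates, names(pheno))
      if (length(missing_cov) > 0) {
        abort(paste0("covariate(s) not found: ", paste(missing_cov, collapse = ", ")))
      }
      Xc <- stats::model.matrix(
        stats::reformulate(covariates), data = pheno)[, -1, drop = FALSE]
    }
  } else {
    y <- as.numeric(pheno)
    Xc <- covariates
    if (!is.null(Xc)) Xc <- as.matrix(Xc)
  }
  if (!is.null(n) && length(y) != n) {
    abort("phenotype length does not match the number of individuals")
  }
  if (anyNA(y)) abort("phenotype contains missing values; subset first")
  if (stats::sd(y) < 1e-12) abort("phenotype is constant; nothing to map")
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    abort("binomial family requires a 0/1 trait")
  }
  X <- cbind(`(Intercept)` = rep(1, length(y)), Xc)
  if (qr(X)$rank < ncol(X)) abort("covariate matrix is rank deficient")
  list(y = y, X = X, family = family, trait = trait %||% "trait",
       covariates = if (is.null(Xc)) character(0) else colnames(Xc))
}

# --- likelihood fits --------------------------------------------------------

# gaussian log-likelihood at the least-squares fit
fit_gaussian <- function(X, y) {
  f <- stats::lm.fit(X, y)
  rss <- max(sum(f$residuals^2), 1e-280) # keep noiseless fits finite
  n <- length(y)
  list(ll = -n / 2 * (log(2 * pi * rss / n) + 1), coef = f$coefficients,
       rss = rss, fitted = f$fitted.values)
}

# logistic log-likelihood (= -deviance/2 for 0/1 data); ridge fallback keeps
# the fit finite under separation
fit_binomial <- function(X, y, ridge_note = NULL) {
  f <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                       control = list(maxit = 100)))
  ok <- f$converged && all(is.finite(f$coefficients)) &&
    max(abs(f$coefficients)) < 50
  if (!ok) {
    if (!is.null(ridge_note) && !isTRUE(ridge_note$warned)) {
      warn("logistic fit did not converge cleanly; using a small ridge penalty")
      ridge_note$warned <- TRUE
    }
    f <- ridge_logistic(X, y)
  }
  list(ll = -f$deviance / 2, coef = f$coefficients,
       fitted = f$fitted.values)
}

ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p) # intercept unpenalized
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / W
    XtW <- t(X * W)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- stats::plogis(pmin(pmax(drop(X %*% beta), -30), 30))
  dev <- -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(coefficients = drop(beta), deviance = dev, fitted.values = mu)
}

fit_ll <- function(X, y, family, ridge_note = NULL) {
  if (family == "gaussian") fit_gaussian(X, y) else fit_binomial(X, y, ridge_note)
}

# --- self scan --------------------------------------------------------------

#' Genome scan for self-QTL effects
#'
#' Haley-Knott regression of the trait on the standardized expected additive
#' genotype score (codes -1, 0, 1 for AA, AB, BB) and, for F2 crosses, the
#' dominance score (codes 0, 1, 0), plus covariates. `lod_self` is the log10
#' likelihood ratio against the covariates-only model; for a gaussian trait it
#' equals `(n/2) * log10(RSS_null / RSS_full)`.
#'
#' The reported additive effect `eff_2a1` is the fitted difference between
#' homozygote means (the trait change when both alleles are replaced), and
#' `eff_d1` the heterozygote deviation from the homozygote midpoint.
#'
#' @param gp A [calc_genoprob()] result.
#' @param pheno Numeric trait vector, or a data frame holding `trait` and any
#'   `covariates` columns.
#' @param trait,covariates Column names used when `pheno` is a data frame.
#' @param family `"gaussian"` or `"binomial"` (logistic scan for 0/1 traits).
#' @return A `neiqtl_scan` tibble with one row per grid position: `chr`,
#'   `pos`, `marker`, `is_marker`, `eff_2a1`, `eff_d1`, `lod_self`. The fitted
#'   per-position self effect (needed by [scan_neighbor()]) is carried in
#'   attributes.
#' @export
scan_self <- function(gp, pheno, trait = NULL, covariates = NULL,
                      family = "gaussian") {
  stopifnot(inherits(gp, "geno_probs"))
  n <- dim(gp$prob)[1]
  ph <- resolve_phenotype(pheno, trait, covariates, family, n = n)
  y <- ph$y
  X0 <- ph$X
  if (n <= ncol(X0) + 3) abort("too few individuals for the scan design")
  ridge_note <- new.env()
  null_fit <- fit_ll(X0, y, ph$family, ridge_note)

  q <- dim(gp$prob)[2]
  lod <- eff_a <- eff_d <- rep(NA_real_, q)
  ll <- rep(NA_real_, q)
  self_eff <- matrix(0, n, q)
  use_dom <- gp$cross_type == "f2"

  for (k in seq_len(q)) {
    sc <- self_scores(gp, k)
    za <- std_score(sc$add)
    zd <- if (use_dom) std_score(sc$dom) else NULL
    Xk <- X0
    if (za$sd > 0) Xk <- cbind(Xk, add = za$z)
    if (use_dom && zd$sd > 0) Xk <- cbind(Xk, dom = zd$z)
    f <- fit_ll(Xk, y, ph$family, ridge_note)
    ll[k] <- f$ll
    lod[k] <- max((f$ll - null_fit$ll) / log(10), 0)
    b_add <- if (za$sd > 0) unname(f$coef["add"]) / za$sd else 0
    b_dom <- if (use_dom && zd$sd > 0) unname(f$coef["dom"]) / zd$sd else 0
    if (is.na(b_add)) b_add <- 0
    if (is.na(b_dom)) b_dom <- 0
    eff_a[k] <- -2 * b_add             # homozygote difference ybar_AA - ybar_BB
    eff_d[k] <- if (use_dom) b_dom else NA_real_
    self_eff[, k] <- b_add * sc$add + b_dom * (if (use_dom) sc$dom else 0)
  }

  out <- tibble(
    chr = gp$grid$chr, pos = gp$grid$pos, marker = gp$grid$marker,
    is_marker = gp$grid$is_marker,
    eff_2a1 = eff_a, eff_d1 = eff_d, lod_self = lod
  )
  class(out) <- unique(c("neiqtl_scan", class(out)))
  attr(out, "self_effect") <- self_eff
  attr(out, "ll_self") <- ll
  attr(out, "ll_null") <- null_fit$ll
  attr(out, "y") <- y
  attr(out, "X0") <- X0
  attr(out, "family") <- ph$family
  attr(out, "cross_type") <- gp$cross_type
  attr(out, "trait") <- ph$trait
  out
}

# --- neighbor scan ----------------------------------------------------------

#' Genome scan for neighbor QTL effects
#'
#' At each position the fitted self-QTL effect (from the self scan's additive
#' and dominance estimates at that position) enters as a single covariate, and
#' the trait is regressed on the standardized conditional neighbor genotypic
#' identity `z` — quadratically (`z` and `z^2`) for F2 crosses, linearly for
#' two-genotype crosses. `lod_nei` is the log10 likelihood ratio of the
#' neighbor model over the self model; a positive `eff_2a2sq` means the trait
#' increases when neighbors share the same alleles.
#'
#' @inheritParams scan_self
#' @param ni A [neighbor_identity()] at the chosen scale (same coding family
#'   as the cross: quadratic for F2, linear otherwise).
#' @param self_scan Optional [scan_self()] result on the same data (computed
#'   if omitted).
#' @return A `neiqtl_scan` tibble with the self columns plus `eff_2a2sq`
#'   (signed additive neighbor effect), `eff_d2sq` (quadratic term, floored at
#'   0), `d2_floored`, and `lod_nei`.
#' @export
scan_neighbor <- function(gp, ni, pheno, trait = NULL, covariates = NULL,
                          family = "gaussian", self_scan = NULL) {
  stopifnot(inherits(gp, "geno_probs"), inherits(ni, "neighbor_identity"))
  if (!identical(ni$ids, gp$ids)) abort("gp and ni cover different individuals")
  if (ncol(ni$value) != dim(gp$prob)[2]) {
    abort("gp and ni were computed on different grids")
  }
  self_scan <- self_scan %||%
    scan_self(gp, pheno, trait, covariates, family)
  y <- attr(self_scan, "y")
  X0 <- attr(self_scan, "X0")
  fam <- attr(self_scan, "family")
  self_eff <- attr(self_scan, "self_effect")
  quadratic <- ni$coding == "quadratic"
  keep <- !is.na(ni$value[, 1])
  ridge_note <- new.env()

  q <- ncol(ni$value)
  lod <- e_a2 <- e_d2 <- rep(NA_real_, q)
  floored <- rep(FALSE, q)
  ll_nei <- rep(NA_real_, q)

  for (k in seq_len(q)) {
    z_raw <- ni$value[keep, k]
    zs <- std_score(z_raw)
    X_red <- cbind(X0[keep, , drop = FALSE], self_eff[keep, k])
    f_red <- fit_ll(X_red, y[keep], fam, ridge_note)
    Xf <- X_red
    if (zs$sd > 0) {
      Xf <- cbind(Xf, z = zs$z)
      if (quadratic) Xf <- cbind(Xf, z2 = zs$z^2)
    }
    f_full <- fit_ll(Xf, y[keep], fam, ridge_note)
    ll_nei[k] <- f_full$ll
    lod[k] <- max((f_full$ll - f_red$ll) / log(10), 0)
    if (zs$sd > 0) {
      b1 <- unname(f_full$coef["z"])
      if (is.na(b1)) b1 <- 0
      if (quadratic) {
        b2 <- unname(f_full$coef["z2"])
        if (is.na(b2)) b2 <- 0
        c2 <- b2 / zs$sd^2
        c1 <- b1 / zs$sd - 2 * zs$mean * b2 / zs$sd^2
        e_a2[k] <- 2 * c1
        floored[k] <- c2 < 0
        e_d2[k] <- max(c2, 0)
      } else {
        e_a2[k] <- 2 * b1 / zs$sd
        e_d2[k] <- NA_real_
      }
    }
  }

  out <- as_tibble(self_scan)
  out$eff_2a2sq <- e_a2
  out$eff_d2sq <- e_d2
  out$d2_floored <- floored
  out$lod_nei <- lod
  class(out) <- unique(c("neiqtl_scan", class(out)))
  for (a in c("self_effect", "ll_self", "ll_null", "y", "X0", "family",
              "cross_type", "trait")) {
    attr(out, a) <- attr(self_scan, a)
  }
  attr(out, "ll_nei") <- ll_nei
  attr(out, "s") <- ni$s
  attr(out, "coding") <- ni$coding
  out
}

#' One-call neighbor QTL scan
#'
#' Convenience wrapper: runs the ΔPVE scale selection (unless `s` is given),
#' computes the neighbor identity at the chosen scale, and returns the joint
#' self + neighbor scan. The PVE profile (when computed) is attached as
#' attribute `"pve_profile"`.
#'
#' @inheritParams scan_self
#' @param smap Spatial map (`id`, `x`, `y`).
#' @param s Spatial scale, or `"auto"` (default) to select it by [delta_pve()].
#' @param percentile_step Passed to [distance_scales()] when `s = "auto"`.
#' @param coding Identity coding (default by cross type).
#' @return A `neiqtl_scan` tibble (see [scan_neighbor()]).
#' @export
scan_neiqtl <- function(gp, smap, pheno, trait = NULL, covariates = NULL,
                        family = "gaussian", s = "auto",
                        percentile_step = 10, coding = NULL) {
  profile <- NULL
  if (identical(s, "auto")) {
    profile <- delta_pve(gp, smap, pheno, trait = trait,
                         covariates = covariates, family = family,
                         percentile_step = percentile_step)
    s <- attr(profile, "s_hat")
  }
  ni <- neighbor_identity(gp, smap, s, coding = coding)
  out <- scan_neighbor(gp, ni, pheno, trait = trait, covariates = covariates,
                       family = family)
  attr(out, "pve_profile") <- profile
  out
}

#' @export
tidy.neiqtl_scan <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.neiqtl_scan <- function(x, ...) {
  tibble(
    n = length(attr(x, "y")),
    family = attr(x, "family"),
    cross_type = attr(x, "cross_type"),
    max_lod_self = max(x$lod_self, na.rm = TRUE),
    max_lod_nei = if ("lod_nei" %in% names(x)) max(x$lod_nei, na.rm = TRUE) else NA_real_,
    s = attr(x, "s") %||% NA_real_
  )
}
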