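# Two-kernel variance components: genome-wide self similarity (K1), neighbor
# identity similarity (K2), AI-REML for gaussian traits, PQL for binary ones.

#' Genome-wide self and neighbor covariance matrices
#'
#' `K1 = P1 P1' / (q - 1)` from column-centered expected self-genotype scores
#' (codes -1, 0, 1) at every grid position — a marker-based kinship matrix —
#' and `K2 = P2 P2' / (q - 1)` from column-centered conditional neighbor
#' identities at scale `s` (additive-polygenic pair coding for F2; the
#' cross's +/-1 product coding for two-genotype crosses, where the additive
#' table is separable and carries no pair interaction). With
#' `source = "phenotype"` the neighbor structure is instead built from the
#' standardized mean phenotype of neighbors within `s` (used to check whether
#' neighbor phenotypes, not genotypes, drive a signal).
#'
#' @inheritParams neighbor_identity
#' @param source `"genotype"` (default) or `"phenotype"`.
#' @param pheno Trait values (required for `source = "phenotype"`).
#' @param standardize Standardize columns of P1/P2 to mean 0, variance 1
#'   before the cross-product (default TRUE). Standardization puts the
#'   average diagonal of both kernels near 1 regardless of the spatial scale,
#'   so the variance components (and hence the PVE profile across scales) are
#'   on a common footing; with `FALSE` the columns are only centered, which
#'   lets positions with larger identity variance dominate.
#' @return A `genome_covariance` object: `K1`, `K2`, `q`, `s`, `source`.
#' @export
build_covariance <- function(gp, smap, s, source = c("genotype", "phenotype"),
                             pheno = NULL, standardize = TRUE) {
  stopifnot(inherits(gp, "geno_probs"))
  source <- match.arg(source)
  q <- dim(gp$prob)[2]
  if (q < 2) abort("need at least two grid positions to build covariances")
  K1 <- attr(gp, "cached_K1") %||% self_kinship(gp, standardize = standardize)

  if (source == "genotype") {
    ni <- neighbor_identity(gp, smap, s, coding = kernel_coding(gp$cross_type))
    P2 <- ni$value
    if (anyNA(P2)) abort("zero-neighbor individuals at this scale; choose another s")
    P2 <- center_cols(P2, standardize)
    K2 <- tcrossprod(P2) / (q - 1)
  } else {
    if (is.null(pheno)) abort("`pheno` required for source = 'phenotype'")
    y <- as.numeric(pheno)
    smap <- validate_spatial(smap)
    smap <- smap[match(gp$ids, smap$id), ]
    D <- as.matrix(stats::dist(cbind(smap$x, smap$y)))
    A <- (D <= s)
    diag(A) <- FALSE
    L <- rowSums(A)
    if (any(L == 0)) abort("zero-neighbor individuals at this scale; choose another s")
    yn <- drop(A %*% y) / L
    yn <- (yn - mean(yn)) / max(stats::sd(yn), 1e-12)
    K2 <- tcrossprod(yn)
  }
  dimnames(K1) <- dimnames(K2) <- list(gp$ids, gp$ids)
  structure(list(K1 = K1, K2 = K2, q = q, s = s, source = source),
            class = "genome_covariance")
}

# pair coding used for the genome-wide neighbor kernel: the additive
# polygenic table for three-genotype crosses; for two-genotype crosses the
# additive table degenerates into a separable (self + neighbor-mean) score
# with no genuine pair interaction, so the cross's own +/-1 product coding is
# used instead
kernel_coding <- function(cross_type) {
  switch(cross_type,
    f2 = "additive",
    riself = "inbred_linear",
    backcross = "backcross_linear"
  )
}

# center (optionally variance-standardize) columns; constant columns are
# centered only
center_cols <- function(P, standardize = TRUE) {
  P <- scale(P, center = TRUE, scale = FALSE)
  if (standardize) {
    s <- apply(P, 2, stats::sd)
    s[!is.finite(s) | s < 1e-12] <- 1
    P <- sweep(P, 2, s, `/`)
  }
  P
}

# marker-based kinship from expected additive scores at all grid positions
self_kinship <- function(gp, standardize = TRUE) {
  n <- dim(gp$prob)[1]
  q <- dim(gp$prob)[2]
  P1 <- matrix(0, n, q)
  for (k in seq_len(q)) P1[, k] <- self_scores(gp, k)$add
  P1 <- center_cols(P1, standardize)
  K1 <- tcrossprod(P1) / (q - 1)
  dimnames(K1) <- list(gp$ids, gp$ids)
  K1
}

# --- AI-REML ----------------------------------------------------------------

# Restricted maximum likelihood for V = sum_k theta_k V_k. Average
# information updates with EM warm-up, projection of variance components onto
# [0, Inf), log-likelihood backtracking, and a derivative-free polish if the
# gradient has not vanished at maxit. `fixed` marks components whose theta is
# held at its initial value (used by the PQL working model).
aireml <- function(y, X, Vlist, init = NULL, fixed = NULL,
                   tol = 1e-6, maxit = 200) {
  n <- length(y)
  m <- length(Vlist)
  vy <- stats::var(y)
  theta <- init %||% rep(vy / m, m)
  fixed <- fixed %||% rep(FALSE, m)
  free <- which(!fixed)
  floor_at <- vy * 1e-8

  # restricted log-likelihood, gradient, and the vectors the AI matrix needs
  parts <- function(theta, with_grad = TRUE) {
    V <- Reduce(`+`, Map(`*`, theta, Vlist))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      V <- V + diag(vy * 1e-6, n)
      ch <- chol(V)
    }
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    Cxx <- solve(XtViX)
    bhat <- drop(Cxx %*% crossprod(ViX, y))
    Py <- drop(Vi %*% y - ViX %*% (Cxx %*% crossprod(ViX, y)))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                    sum(y * Py))
    out <- list(ll = ll, beta = bhat)
    if (with_grad) {
      VkPy <- lapply(Vlist, function(Vk) drop(Vk %*% Py))
      trPVk <- vapply(seq_len(m), function(k) {
        sum(Vi * Vlist[[k]]) - sum(ViX * (Vlist[[k]] %*% (ViX %*% Cxx)))
      }, numeric(1))
      score <- vapply(seq_len(m), function(k) {
        -0.5 * (trPVk[k] - sum(Py * VkPy[[k]]))
      }, numeric(1))
      PVkPy <- lapply(VkPy, function(t_) {
        drop(Vi %*% t_ - ViX %*% (Cxx %*% crossprod(ViX, t_)))
      })
      AI <- matrix(0, m, m)
      for (k in seq_len(m)) for (l in k:m) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(VkPy[[k]] * PVkPy[[l]])
      }
      out$score <- score
      out$AI <- AI
      out$em_num <- vapply(seq_len(m), function(k) {
        sum(Py * VkPy[[k]]) - trPVk[k]
      }, numeric(1))
    }
    out
  }

  converged <- FALSE
  pp <- parts(theta)
  it <- 0
  stalled <- 0
  ll_prev <- -Inf
  while (it < maxit) {
    it <- it + 1
    # near-unidentifiable kernels (e.g. collinear K1/K2) make AI steps crawl;
    # hand a stalled fit to the quasi-Newton polish below
    if (it > 4 && pp$ll - ll_prev < 2e-3) {
      stalled <- stalled + 1
      if (stalled >= 4) break
    } else {
      stalled <- 0
    }
    ll_prev <- pp$ll
    g <- pp$score[free]
    at_bound <- theta[free] <= floor_at & g < 0
    if (max(c(0, abs(g[!at_bound]))) < tol * max(1, abs(pp$ll))) {
      converged <- TRUE
      break
    }
    active <- free[!(theta[free] <= floor_at & pp$score[free] < 0)]
    theta[setdiff(free, active)] <- 0
    if (length(active) == 0) {
      converged <- TRUE
      break
    }
    if (it <= 2) {
      # EM warm-up: stable, keeps components non-negative
      for (k in active) {
        theta[k] <- max(theta[k] + max(theta[k], floor_at)^2 *
                          pp$em_num[k] / n, 0)
      }
      pp <- parts(theta)
      next
    }
    delta <- tryCatch(
      solve(pp$AI[active, active, drop = FALSE] +
              diag(1e-10, length(active)), pp$score[active]),
      error = function(e) NULL)
    moved <- FALSE
    if (!is.null(delta)) {
      # projected AI step with log-likelihood backtracking
      step <- 1
      for (half in 1:12) {
        cand <- theta
        cand[active] <- pmax(theta[active] + step * delta, 0)
        pc <- parts(cand)
        if (pc$ll >= pp$ll - 1e-10) {
          theta <- cand
          pp <- pc
          moved <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!moved) {
      # EM fallback step
      for (k in active) {
        theta[k] <- max(theta[k] + max(theta[k], floor_at)^2 *
                          pp$em_num[k] / n, 0)
      }
      pp <- parts(theta)
    }
    theta[free][theta[free] < floor_at] <- 0
  }

  if (!converged && length(free) > 0) {
    # quasi-Newton polish on log-variance components (gradient from the
    # REML score; the zero boundary maps to the log-scale lower bound)
    obj <- function(lt) {
      th <- theta
      th[free] <- exp(lt)
      -parts(th, with_grad = FALSE)$ll
    }
    grad <- function(lt) {
      th <- theta
      th[free] <- exp(lt)
      -parts(th)$score[free] * exp(lt)
    }
    start <- log(pmax(theta[free], floor_at))
    op <- tryCatch(
      stats::optim(start, obj, grad, method = "L-BFGS-B",
                   lower = log(floor_at), upper = log(vy * 1e6),
                   control = list(maxit = 100, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(op) && -op$value >= pp$ll - 1e-8) {
      theta[free] <- exp(op$par)
      theta[free][theta[free] <= floor_at] <- 0
      pp <- parts(theta)
      g <- pp$score[free]
      at_bound <- theta[free] <= floor_at & g < 0
      converged <- op$convergence == 0 ||
        max(c(0, abs(g[!at_bound]))) < 100 * tol * max(1, abs(pp$ll))
    }
  }

  list(theta = theta, beta = pp$beta, loglik = pp$ll, converged = converged,
       iterations = it)
}

#' Fit the two-kernel variance-component model
#'
#' Gaussian traits: REML estimates of (sigma1^2, sigma2^2, sigma_e^2) for
#' `Var(y) = sigma1^2 K1 + sigma2^2 K2 + sigma_e^2 I` by average-information
#' REML with EM warm-up and non-negativity projection. Binary traits:
#' penalized quasi-likelihood for the logistic mixed model, returning sigma1^2
#' and sigma2^2 only (no residual variance exists on the liability scale
#' there, which is why the profile switches to RVE).
#'
#' @param pheno Trait vector, or data frame with `trait`/`covariates`.
#' @param K A [build_covariance()] result (or list with `K1`, `K2`).
#' @inheritParams scan_self
#' @return A `varcomp` object: `sigma2` (named variance components), `beta`,
#'   `loglik` (restricted, gaussian only), `pve` tibble, `converged`, `family`.
#' @export
fit_varcomp <- function(pheno, K, trait = NULL, covariates = NULL,
                        family = "gaussian") {
  n <- nrow(K$K1)
  ph <- resolve_phenotype(pheno, trait, covariates, family, n = n)
  if (n < 10) abort("too few individuals for variance-component estimation")
  if (ph$family == "gaussian") {
    # fit on the unit-variance scale: REML estimates transform exactly, so
    # results are invariant to trait rescaling by construction
    sdy <- stats::sd(ph$y)
    fit <- aireml(ph$y / sdy, ph$X, list(K$K1, K$K2, diag(n)))
    sig <- setNames(fit$theta * sdy^2, c("sigma1_sq", "sigma2_sq", "sigma_e_sq"))
    tot <- sum(sig)
    ll <- fit$loglik - (n - ncol(ph$X)) * log(sdy)
    pve <- tibble(pve_self = unname(sig[1] / tot),
                  pve_nei = unname(sig[2] / tot))
    out <- list(sigma2 = sig, beta = fit$beta * sdy, loglik = ll,
                converged = fit$converged, iterations = fit$iterations,
                pve = pve, family = "gaussian")
  } else {
    fit <- pql_binomial(ph$y, ph$X, list(K$K1, K$K2))
    sig <- setNames(fit$theta[1:2], c("sigma1_sq", "sigma2_sq"))
    pve <- tibble(rve_nei = unname(sig[2]) / max(unname(sig[1]), 1e-12))
    out <- list(sigma2 = sig, beta = fit$beta, loglik = NA_real_,
                converged = fit$converged, iterations = fit$iterations,
                pve = pve, family = "binomial")
  }
  if (!out$converged) {
    warn("variance-component fit did not converge; estimates are flagged")
  }
  structure(out, class = "varcomp")
}

# PQL for the two-kernel logistic mixed model: iterate the working linear
# mixed model z = eta + W^-1 (y - mu), Var = s1 K1 + s2 K2 + W^-1
pql_binomial <- function(y, X, Klist, maxit = 50, tol = 1e-4) {
  n <- length(y)
  eta <- qlogis(pmin(pmax((y + 0.5) / 2, 0.05), 0.95))
  theta <- c(0.1, 0.1)
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(pmin(pmax(eta, -30), 30))
    W <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / W
    fit <- aireml(z, X, c(Klist, list(diag(1 / W, n))),
                  init = c(theta, 1), fixed = c(FALSE, FALSE, TRUE),
                  maxit = 100)
    theta_new <- fit$theta[1:2]
    # BLUP of the combined random effect
    V <- fit$theta[1] * Klist[[1]] + fit$theta[2] * Klist[[2]] + diag(1 / W, n)
    Vi <- chol2inv(chol(V))
    ViX <- Vi %*% X
    Cxx <- solve(crossprod(X, ViX))
    Pz <- drop(Vi %*% z - ViX %*% (Cxx %*% crossprod(ViX, z)))
    u <- drop((fit$theta[1] * Klist[[1]] + fit$theta[2] * Klist[[2]]) %*% Pz)
    eta_new <- drop(X %*% fit$beta) + u
    if (max(abs(theta_new - theta)) < tol &&
        max(abs(eta_new - eta)) < 10 * tol) {
      theta <- theta_new
      eta <- eta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
    eta <- eta_new
  }
  list(theta = c(theta, NA_real_), beta = fit$beta, converged = converged,
       iterations = it)
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("<varcomp> %s (%sconverged, %d iterations)\n", x$family,
              if (x$converged) "" else "NOT ", x$iterations))
  print(round(x$sigma2, 6))
  print(x$pve)
  invisible(x)
}

#' @export
tidy.varcomp <- function(x, ...) {
  tibble(component = names(x$sigma2), estimate = unname(x$sigma2))
}

#' @export
glance.varcomp <- function(x, ...) {
  bind_cols(x$pve, tibble(loglik = x$loglik, converged = x$converged,
                          family = x$family))
}

#' Marker heritability from the self kinship alone
#'
#' `h^2 = sigma1^2 / (sigma1^2 + sigma_e^2)` from the single-kernel model, the
#' two-kernel model with the neighbor variance and scale forced to zero.
#'
#' @inheritParams fit_varcomp
#' @return A single numeric heritability (attribute `fit` holds the REML fit).
#' @export
marker_h2 <- function(pheno, K, trait = NULL, covariates = NULL) {
  n <- nrow(K$K1)
  ph <- resolve_phenotype(pheno, trait, covariates, "gaussian", n = n)
  fit <- aireml(ph$y, ph$X, list(K$K1, diag(n)))
  h2 <- fit$theta[1] / sum(fit$theta)
  attr(h2, "fit") <- fit
  h2
}
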