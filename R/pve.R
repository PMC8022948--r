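# Effective neighbor distance by the incremental-PVE (delta-PVE) criterion.

#' Profile neighbor PVE across spatial scales and select the effective
#' distance
#'
#' Fits the two-kernel variance-component model at each candidate scale and
#' profiles `PVE_nei` (gaussian) or `RVE_nei` (binomial). The increment
#' `delta_pve` at the first scale is the PVE itself (the increment from
#' s = 0); at later scales it is the difference from the previous usable
#' scale. The effective distance `s_hat` is the scale maximizing the
#' increment, ties resolved toward the smaller scale.
#'
#' Scales at which some individual has no neighbor, or at which the REML/PQL
#' fit fails, are kept in the profile with `converged = FALSE` and skipped by
#' the increment/argmax computation; if no scale is usable an error lists the
#' per-scale diagnostics.
#'
#' @inheritParams scan_neiqtl
#' @param scales Optional [distance_scales()] tibble (computed from `smap`
#'   with `percentile_step` when omitted).
#' @return A `pve_profile` tibble: `s`, `percentile`, `pve_self`,
#'   `pve_nei` (or `rve_nei`), `delta_pve`, `converged`; attributes `s_hat`
#'   and `h2` (gaussian marker heritability).
#' @export
delta_pve <- function(gp, smap, pheno, trait = NULL, covariates = NULL,
                      family = "gaussian", scales = NULL,
                      percentile_step = 10) {
  stopifnot(inherits(gp, "geno_probs"))
  smap <- validate_spatial(smap)
  scales <- scales %||% distance_scales(smap, percentile_step)
  if (nrow(scales) < 1) abort("no candidate scales")
  if (nrow(scales) == 1) {
    warn("only one candidate scale; it is returned as s_hat without profiling")
  }

  n_s <- nrow(scales)
  pve_self <- pve_nei <- rep(NA_real_, n_s)
  conv <- rep(FALSE, n_s)
  notes <- rep(NA_character_, n_s)
  K1 <- self_kinship(gp)
  attr(gp, "cached_K1") <- K1
  h2 <- if (family == "gaussian") {
    as.numeric(marker_h2(pheno, list(K1 = K1), trait = trait,
                         covariates = covariates))
  } else {
    NA_real_
  }
  for (i in seq_len(n_s)) {
    res <- tryCatch(suppressWarnings({
      K <- build_covariance(gp, smap, scales$s[i])
      fit_varcomp(pheno, K, trait = trait, covariates = covariates,
                  family = family)
    }), error = function(e) e)
    if (inherits(res, "error")) {
      notes[i] <- conditionMessage(res)
      next
    }
    conv[i] <- res$converged
    if (family == "gaussian") {
      pve_self[i] <- res$pve$pve_self
      pve_nei[i] <- res$pve$pve_nei
    } else {
      pve_self[i] <- NA_real_
      pve_nei[i] <- res$pve$rve_nei
    }
  }
  usable <- which(conv & is.finite(pve_nei))
  if (length(usable) == 0) {
    abort(paste0("all scale fits failed:\n",
                 paste0("  s = ", signif(scales$s, 4), ": ",
                        ifelse(is.na(notes), "did not converge", notes),
                        collapse = "\n")))
  }
  dp <- rep(NA_real_, n_s)
  prev <- 0
  for (i in usable) {
    dp[i] <- pve_nei[i] - prev
    prev <- pve_nei[i]
  }
  s_hat <- scales$s[usable[which.max(dp[usable])]]

  out <- tibble(
    s = scales$s, percentile = scales$percentile,
    pve_self = pve_self, pve_nei = pve_nei, delta_pve = dp,
    converged = conv
  )
  if (family == "binomial") names(out)[names(out) == "pve_nei"] <- "rve_nei"
  class(out) <- unique(c("pve_profile", class(out)))
  attr(out, "s_hat") <- s_hat
  attr(out, "h2") <- h2
  attr(out, "family") <- family
  out
}

#' @export
glance.pve_profile <- function(x, ...) {
  nei_col <- intersect(c("pve_nei", "rve_nei"), names(x))[1]
  at <- which(x$s == attr(x, "s_hat"))
  tibble(
    s_hat = attr(x, "s_hat"),
    percentile_hat = x$percentile[at],
    pve_nei_hat = x[[nei_col]][at],
    h2 = attr(x, "h2"),
    family = attr(x, "family")
  )
}
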