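# Genome-wide significance by trait permutation.

#' Permutation thresholds for genome-wide LOD scores
#'
#' Permutes the trait (rows of the phenotype and covariates jointly) against
#' the fixed genotype/spatial structure, reruns the full stepwise scan, and
#' records the genome-wide maximum `lod_self` and `lod_nei` per permutation.
#' Thresholds are empirical `1 - alpha` percentiles (nearest rank) of those
#' maxima, computed separately for the self and neighbor scans.
#'
#' @inheritParams scan_neighbor
#' @param n_perm Number of permutations (999 reproduces the conventional
#'   genome-wide test; at least `1/alpha` are required for any requested
#'   level).
#' @param alphas Significance levels (default 0.05 significant, 0.10
#'   suggestive).
#' @param seed RNG seed, recorded in the result.
#' @return A `perm_thresholds` object with the per-permutation maxima, a
#'   `thresholds` tibble (`alpha`, `lod_self`, `lod_nei`), `n_perm`, `seed`.
#' @export
perm_threshold <- function(gp, ni, pheno, trait = NULL, covariates = NULL,
                           family = "gaussian", n_perm = 999,
                           alphas = c(0.05, 0.1), seed = NULL) {
  if (n_perm < ceiling(1 / min(alphas)) - 1) {
    abort(sprintf("n_perm = %d is too small for alpha = %g", n_perm, min(alphas)))
  }
  n <- dim(gp$prob)[1]
  ph <- resolve_phenotype(pheno, trait, covariates, family, n = n)
  if (!is.null(seed)) set.seed(seed)
  max_self <- max_nei <- numeric(n_perm)
  Xc <- ph$X[, -1, drop = FALSE]
  has_cov <- ncol(Xc) > 0
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    yb <- ph$y[idx]
    covb <- if (has_cov) Xc[idx, , drop = FALSE] else NULL
    ss <- scan_self(gp, yb, covariates = covb, family = family)
    sn <- scan_neighbor(gp, ni, yb, covariates = covb, family = family,
                        self_scan = ss)
    max_self[b] <- max(ss$lod_self, na.rm = TRUE)
    max_nei[b] <- max(sn$lod_nei, na.rm = TRUE)
  }
  thr <- tibble(
    alpha = sort(alphas),
    lod_self = as.numeric(stats::quantile(max_self, 1 - sort(alphas), type = 1)),
    lod_nei = as.numeric(stats::quantile(max_nei, 1 - sort(alphas), type = 1))
  )
  structure(
    list(max_self = max_self, max_nei = max_nei, thresholds = thr,
         n_perm = n_perm, seed = seed, alphas = sort(alphas)),
    class = "perm_thresholds"
  )
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf("<perm_thresholds> %d permutations (seed %s)\n", x$n_perm,
              x$seed %||% "unset"))
  print(x$thresholds)
  invisible(x)
}

#' @export
tidy.perm_thresholds <- function(x, ...) {
  x$thresholds
}
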