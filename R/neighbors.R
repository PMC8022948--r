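# Spatial scales and conditional neighbor genotypic identity.

#' Candidate spatial scales from pairwise distance percentiles
#'
#' Categorizes the pairwise Euclidean distance distribution of a spatial map
#' into percentile scales, the candidate set over which the effective neighbor
#' distance is profiled.
#'
#' @param smap Spatial map: data frame with columns `id`, `x`, `y`.
#' @param percentile_step Percentile increment in (0, 50]; scales are taken at
#'   `percentile_step, 2*percentile_step, ..., 100` percent (linear
#'   interpolation), then deduplicated keeping the smallest percentile per
#'   distinct distance.
#' @return Tibble (class `distance_scales`) with columns `percentile`, `s`,
#'   strictly increasing in `s`.
#' @export
distance_scales <- function(smap, percentile_step = 10) {
  smap <- validate_spatial(smap)
  if (nrow(smap) < 2) abort("need at least two individuals")
  if (!is.numeric(percentile_step) || percentile_step <= 0 || percentile_step > 50) {
    abort("`percentile_step` must lie in (0, 50]")
  }
  d <- as.vector(stats::dist(cbind(smap$x, smap$y)))
  if (all(d < .Machine$double.eps)) {
    abort("all individuals are coincident; pairwise distances are all zero")
  }
  pr <- seq(percentile_step, 100, by = percentile_step)
  q <- as.numeric(stats::quantile(d, pr / 100, type = 7))
  out <- tibble(percentile = pr, s = q)
  out <- out[q > 0, ]
  out <- out[!duplicated(out$s), ]
  class(out) <- unique(c("distance_scales", class(out)))
  out
}

validate_spatial <- function(smap) {
  smap <- as_tibble(smap)
  if (!all(c("id", "x", "y") %in% names(smap))) {
    abort("spatial map needs columns id, x, y")
  }
  if (any(!is.finite(smap$x)) || any(!is.finite(smap$y))) {
    abort("spatial coordinates contain non-finite values")
  }
  if (anyDuplicated(smap$id)) abort("duplicated individual ids in spatial map")
  smap$id <- as.character(smap$id)
  smap
}

#' Genotype-pair codings for neighbor identity
#'
#' Returns the 3 x 3 weight matrix `C[v, w]` applied to ordered genotype pairs
#' (focal `v`, neighbor `w`; rows/columns ordered AA, AB, BB):
#'
#' * `"quadratic"`: the nine-combination encoding used for the F2 quadratic
#'   regression — AA/AA = BB/BB = 1, AA/AB = 0.25, AB/AB = 0, AB/BB = -0.25,
#'   AA/BB = -1 (and symmetric).
#' * `"additive"`: the additive-polygenic coding used for the genome-wide
#'   similarity matrix K2 — as above but with 0.5 in place of 0.25.
#' * `"inbred_linear"`: product of self codes AA = 1, BB = -1 (selfed RILs).
#' * `"backcross_linear"`: product of symmetric self codes AA = 1, AB = -1
#'   (the backcross constraint d2 = -a2 makes the pair effects proportional to
#'   this product, so the backcross and inbred linear models are equivalent).
#'
#' @param name Coding name.
#' @return A 3 x 3 numeric matrix with attribute `coding`.
#' @export
identity_coding <- function(name = c("quadratic", "additive",
                                     "inbred_linear", "backcross_linear")) {
  name <- match.arg(name)
  C <- switch(name,
    quadratic = matrix(c(1, 0.25, -1,
                         0.25, 0, -0.25,
                         -1, -0.25, 1), 3, 3, byrow = TRUE),
    additive = matrix(c(1, 0.5, -1,
                        0.5, 0, -0.5,
                        -1, -0.5, 1), 3, 3, byrow = TRUE),
    inbred_linear = outer(c(1, 0, -1), c(1, 0, -1)),
    backcross_linear = outer(c(1, -1, 0), c(1, -1, 0))
  )
  dimnames(C) <- list(GENO_CODES, GENO_CODES)
  attr(C, "coding") <- name
  C
}

default_coding <- function(cross_type) {
  switch(cross_type,
    f2 = "quadratic",
    riself = "inbred_linear",
    backcross = "backcross_linear"
  )
}

#' Conditional neighbor genotypic identity
#'
#' For each focal individual i and grid position, computes the expected
#' genotype-pair weight summed over neighbors within distance `s`,
#' `sum_{j in N(i,s)} sum_v sum_w p_iv p_jw C[v, w] / L_i`, where `p` are the
#' conditional genotype probabilities, `C` the pair coding, and `L_i` the
#' focal individual's neighbor count. Neighborhoods are closed balls
#' (distance <= s) excluding the focal individual.
#'
#' @param gp A [calc_genoprob()] result.
#' @param smap Spatial map (`id`, `x`, `y`), covering all individuals in `gp`.
#' @param s Spatial scale (> 0), same units as the coordinates.
#' @param coding Coding name for [identity_coding()]; default chosen by cross
#'   type (quadratic for F2, linear for two-genotype crosses).
#' @param zero_policy What to do with individuals that have no neighbor at
#'   `s`: `"error"` (default — the scale is rejected with a diagnostic naming
#'   them) or `"drop"` (their identity is set `NA` and downstream fits exclude
#'   them).
#' @return A `neighbor_identity` object: `value` (individuals x positions
#'   matrix), `L` (neighbor counts), `s`, `coding`, `ids`.
#' @export
neighbor_identity <- function(gp, smap, s, coding = NULL,
                              zero_policy = c("error", "drop")) {
  stopifnot(inherits(gp, "geno_probs"))
  zero_policy <- match.arg(zero_policy)
  if (!is.numeric(s) || length(s) != 1 || s <= 0) abort("`s` must be a positive scalar")
  smap <- validate_spatial(smap)
  if (!all(gp$ids %in% smap$id)) {
    abort("spatial map is missing individuals present in the genotype data")
  }
  smap <- smap[match(gp$ids, smap$id), ]
  coding <- coding %||% default_coding(gp$cross_type)
  C <- identity_coding(coding)

  D <- as.matrix(stats::dist(cbind(smap$x, smap$y)))
  A <- (D <= s)
  diag(A) <- FALSE
  L <- rowSums(A)
  if (any(L == 0)) {
    isolated <- gp$ids[L == 0]
    if (zero_policy == "error") {
      abort(paste0("scale s = ", signif(s, 4), " leaves ", length(isolated),
                   " individual(s) with no neighbor: ",
                   paste(head(isolated, 5), collapse = ", "),
                   if (length(isolated) > 5) ", ..." else ""))
    }
  }
  n <- dim(gp$prob)[1]
  q <- dim(gp$prob)[2]
  val <- matrix(NA_real_, n, q, dimnames = dimnames(gp$prob)[1:2])
  Lsafe <- pmax(L, 1)
  for (k in seq_len(q)) {
    P <- gp$prob[, k, , drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    NP <- (A %*% P) / Lsafe
    val[, k] <- rowSums((P %*% C) * NP)
  }
  val[L == 0, ] <- NA_real_
  structure(
    list(value = val, L = L, s = s, coding = coding, ids = gp$ids,
         grid = gp$grid),
    class = "neighbor_identity"
  )
}

#' @export
print.neighbor_identity <- function(x, ...) {
  cat(sprintf("<neighbor_identity> s = %.4g, coding = %s\n", x$s, x$coding))
  cat(sprintf("  %d individuals x %d positions; neighbor counts %d-%d\n",
              nrow(x$value), ncol(x$value), min(x$L), max(x$L)))
  invisible(x)
}

#' @export
tidy.neighbor_identity <- function(x, ...) {
  tibble(
    id = rep(x$ids, times = ncol(x$value)),
    marker = rep(colnames(x$value), each = nrow(x$value)),
    pos = rep(x$grid$pos, each = nrow(x$value)),
    s = x$s,
    value = as.vector(x$value)
  )
}
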