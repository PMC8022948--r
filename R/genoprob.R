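# Hidden-Markov conditional genotype probabilities along each chromosome.
# States are the cross-specific genotypes; transitions come from the map
# function applied to inter-position cM gaps; emissions allow a symmetric
# genotyping-error rate and treat missing calls as uninformative.

cross_states <- function(cross_type) {
  switch(cross_type,
    f2 = 1:3,          # AA, AB, BB
    backcross = 1:2,   # AA, AB
    riself = c(1L, 3L) # AA, BB
  )
}

cross_init <- function(cross_type) {
  switch(cross_type,
    f2 = c(0.25, 0.5, 0.25),
    backcross = c(0.5, 0.5),
    riself = c(0.5, 0.5)
  )
}

# genotype-to-genotype transition matrix across a meiotic recombination
# fraction r; selfed RILs use the expanded fraction R = 2r/(1+2r)
trans_matrix <- function(r, cross_type) {
  switch(cross_type,
    backcross = matrix(c(1 - r, r, r, 1 - r), 2, 2, byrow = TRUE),
    riself = {
      R <- 2 * r / (1 + 2 * r)
      matrix(c(1 - R, R, R, 1 - R), 2, 2, byrow = TRUE)
    },
    f2 = {
      # two independent meioses, no interference
      matrix(c(
        (1 - r)^2,     2 * r * (1 - r),     r^2,
        r * (1 - r),   (1 - r)^2 + r^2,     r * (1 - r),
        r^2,           2 * r * (1 - r),     (1 - r)^2
      ), 3, 3, byrow = TRUE)
    }
  )
}

#' Conditional genotype probabilities at markers and pseudomarkers
#'
#' Forward-backward probabilities `Pr(g = AA/AB/BB | observed markers)` for
#' every individual at every grid position, per chromosome. This is the first
#' step of the neighbor QTL algorithm and matches standard interval-mapping
#' practice: transitions between adjacent grid positions are derived from the
#' cM gap through the map function, emissions allow a genotyping error rate
#' `error_prob`, and missing genotypes emit uniformly.
#'
#' @param cross A [cross_population()].
#' @param step Pseudomarker spacing in cM passed to [insert_pseudomarkers()]
#'   (ignored when `grid` is supplied); `Inf` evaluates at markers only.
#' @param error_prob Genotyping error rate in `[0, 0.5)`.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @param grid Optional precomputed [insert_pseudomarkers()] grid.
#' @return A `geno_probs` object: `prob` is an individuals x positions x 3
#'   array (states AA, AB, BB; the absent state of a two-genotype cross is an
#'   all-zero slice), plus the grid and settings used.
#' @export
calc_genoprob <- function(cross, step = 1, error_prob = 1e-4,
                          map_function = "haldane", grid = NULL) {
  stopifnot(inherits(cross, "cross_pop"))
  if (!is.numeric(error_prob) || error_prob < 0 || error_prob >= 0.5) {
    abort("`error_prob` must lie in [0, 0.5)")
  }
  mfs <- get_map_function(map_function)
  grid <- grid %||% insert_pseudomarkers(cross$map, step)
  if (!all(cross$map$marker %in% grid$marker)) {
    abort("grid does not contain every observed marker of the cross map")
  }
  states <- cross_states(cross$cross_type)
  K <- length(states)
  init <- cross_init(cross$cross_type)
  n <- nrow(cross$geno)
  prob <- array(0, dim = c(n, nrow(grid), 3L),
                dimnames = list(cross$ids, grid$marker, GENO_CODES))

  for (cc in unique(grid$chr)) {
    gidx <- which(grid$chr == cc)
    gc <- grid[gidx, ]
    Tn <- nrow(gc)
    # emissions: n x K per position
    E <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      if (is.na(gc$geno_col[t])) {
        E[[t]] <- matrix(1, n, K)
      } else {
        obs <- cross$geno[, gc$geno_col[t]]
        Em <- matrix(1, n, K)
        seen <- !is.na(obs)
        for (k in seq_len(K)) {
          Em[seen, k] <- ifelse(obs[seen] == states[k],
                                1 - error_prob,
                                if (K == 2) error_prob else error_prob / 2)
        }
        E[[t]] <- Em
      }
    }
    r <- if (Tn > 1) mfs$mf(diff(gc$pos)) else numeric(0)
    Tr <- lapply(r, trans_matrix, cross_type = cross$cross_type)

    # scaled forward pass
    alpha <- vector("list", Tn)
    a <- sweep(E[[1]], 2, init, `*`)
    alpha[[1]] <- a / rowSums(a)
    for (t in seq_len(Tn - 1)) {
      a <- (alpha[[t]] %*% Tr[[t]]) * E[[t + 1]]
      alpha[[t + 1]] <- a / rowSums(a)
    }
    # scaled backward pass
    beta <- vector("list", Tn)
    beta[[Tn]] <- matrix(1, n, K)
    if (Tn > 1) {
      for (t in rev(seq_len(Tn - 1))) {
        b <- (beta[[t + 1]] * E[[t + 1]]) %*% t(Tr[[t]])
        beta[[t]] <- b / rowSums(b)
      }
    }
    for (t in seq_len(Tn)) {
      post <- alpha[[t]] * beta[[t]]
      post <- post / rowSums(post)
      prob[, gidx[t], states] <- post
    }
  }

  structure(
    list(prob = prob, grid = grid, cross_type = cross$cross_type,
         error_prob = error_prob, map_function = map_function,
         ids = cross$ids),
    class = "geno_probs"
  )
}

#' @export
print.geno_probs <- function(x, ...) {
  cat(sprintf("<geno_probs> %s: %d individuals x %d positions (%d markers, %d pseudomarkers)\n",
              x$cross_type, dim(x$prob)[1], dim(x$prob)[2],
              sum(x$grid$is_marker), sum(!x$grid$is_marker)))
  cat(sprintf("  error_prob = %g, map function = %s\n",
              x$error_prob, x$map_function))
  invisible(x)
}

#' Tidy genotype probabilities into long format
#'
#' @param x A `geno_probs` object.
#' @param ... Unused.
#' @return Tibble with columns `id`, `chr`, `pos`, `marker`, `state`,
#'   `probability` (the long-CSV export layout).
#' @export
tidy.geno_probs <- function(x, ...) {
  d <- dim(x$prob)
  tibble(
    id = rep(x$ids, times = d[2] * 3),
    marker = rep(rep(x$grid$marker, each = d[1]), times = 3),
    chr = rep(rep(x$grid$chr, each = d[1]), times = 3),
    pos = rep(rep(x$grid$pos, each = d[1]), times = 3),
    state = rep(GENO_CODES, each = d[1] * d[2]),
    probability = as.vector(x$prob)
  )
}

# expected additive (-1,0,1) and dominance (0,1,0) scores at one position
self_scores <- function(gp, k) {
  P <- gp$prob[, k, , drop = TRUE]
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  list(add = as.vector(P %*% c(-1, 0, 1)), dom = P[, 2])
}
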