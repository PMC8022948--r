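# Synthetic crosses, spatial maps, and neighbor-effect traits; the benchmark
# harness that exercises the whole pipeline.

#' Default synthetic genetic map
#'
#' Multiple chromosomes with evenly spaced markers, the marker density typical
#' of sparse experimental-cross maps.
#'
#' @param n_chr Number of chromosomes.
#' @param n_mar Markers per chromosome.
#' @param spacing Marker spacing in cM.
#' @return A [genetic_map()] tibble.
#' @export
sim_map <- function(n_chr = 5, n_mar = 6, spacing = 12) {
  genetic_map(
    chr = rep(as.character(seq_len(n_chr)), each = n_mar),
    marker = paste0("c", rep(seq_len(n_chr), each = n_mar), "m",
                    rep(seq_len(n_mar), n_chr)),
    pos = rep(spacing * (seq_len(n_mar) - 1), n_chr)
  )
}

#' Simulate genotypes of an experimental cross
#'
#' Genotypes are generated chromosome-wise by the cross-appropriate Markov
#' chain, with Haldane transition probabilities derived from the cM gaps
#' (selfed RILs use the expanded recombination fraction R = 2r/(1+2r)).
#'
#' @param cross_type `"f2"`, `"backcross"`, or `"riself"`.
#' @param map A [genetic_map()] (default [sim_map()]).
#' @param n Number of individuals.
#' @param seed RNG seed.
#' @return A [cross_population()].
#' @export
sim_cross <- function(cross_type, map = sim_map(), n = 200, seed = NULL) {
  cross_type <- normalize_cross_type(cross_type)
  map <- validate_genetic_map(as_tibble(map))
  if (nrow(map) == 0) abort("empty genetic map")
  if (n < 2) abort("need n >= 2 individuals")
  if (!is.null(seed)) set.seed(seed)

  sim_chain <- function(n, n_mar, r) {
    # alleles 0/1 along one meiotic product
    g <- matrix(0L, n, n_mar)
    g[, 1] <- stats::rbinom(n, 1, 0.5)
    for (k in seq_len(n_mar - 1)) {
      sw <- stats::rbinom(n, 1, r[k])
      g[, k + 1] <- ifelse(sw == 1L, 1L - g[, k], g[, k])
    }
    g
  }

  geno <- matrix(NA_integer_, n, nrow(map))
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    r <- mf_haldane(diff(map$pos[idx]))
    if (cross_type == "f2") {
      g1 <- sim_chain(n, length(idx), r)
      g2 <- sim_chain(n, length(idx), r)
      geno[, idx] <- 1L + g1 + g2
    } else if (cross_type == "backcross") {
      geno[, idx] <- 1L + sim_chain(n, length(idx), r)
    } else {
      R <- 2 * r / (1 + 2 * r)
      geno[, idx] <- 1L + 2L * sim_chain(n, length(idx), R)
    }
  }
  cross_population(geno, map, cross_type)
}

#' Simulate a uniform spatial map
#'
#' Individual positions sampled independently from `Unif(1, 100)` on both
#' axes, the continuous two-dimensional arrangement used by the benchmark.
#'
#' @param n Number of individuals.
#' @param seed RNG seed.
#' @param lower,upper Support of the uniform distribution.
#' @return A spatial-map tibble (`id`, `x`, `y`).
#' @export
sim_spatial <- function(n, seed = NULL, lower = 1, upper = 100) {
  if (n < 2) abort("need n >= 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  tibble(id = paste0("ind", seq_len(n)),
         x = stats::runif(n, lower, upper),
         y = stats::runif(n, lower, upper))
}

#' Define a simulation scenario
#'
#' Encodes the benchmark's trait-generating conditions: the cross design, the
#' neighbor-effect mode (relative dominance `d2/a2`), the true effective
#' distance as a percentile of pairwise distances, and the share of
#' phenotypic variance attributable to neighbor effects.
#'
#' Scenario presets follow the benchmark's parameterization relative to the
#' major additive self effect: `additive` (d2 = 0.25 a2), `dominant`
#' (d2 = a2), `overdominant` (d2 = 1.25 a2) for F2; `backcross-additive`
#' (d2 = -a2, forced by the two-genotype design); `neighbor-phenotype`
#' replaces the genotype-identity component by the scaled mean phenotype of
#' neighbors (the false-positive control).
#'
#' @param scenario One of `"additive"`, `"dominant"`, `"overdominant"`,
#'   `"backcross-additive"`, `"neighbor-phenotype"`.
#' @param cross_type Cross design; dominance scenarios require `"f2"`.
#' @param distance_percentile True effective distance, as a percentile of the
#'   pairwise Euclidean distance distribution.
#' @param pve_nei Neighbor share of phenotypic variance, in (0, 1); enforced
#'   empirically per replicate.
#' @param n Individuals.
#' @param a1 Major additive self effect before trait standardization (default
#'   0.56 for F2/RIL, 0.28 for backcross, the benchmark's signal strengths).
#' @param major Index of the marker carrying the major neighbor effect
#'   (default: drawn at random).
#' @param major_self Index of the marker carrying the major self effect
#'   (default: a random marker different from `major` — self and neighbor
#'   QTLs are decoupled, as when a trait with its own QTL architecture
#'   receives neighbor effects at an unrelated locus).
#' @param polygenic Ratio of background to major effects (default 1e-3).
#' @param seed RNG seed for the whole replicate.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(scenario = c("additive", "dominant", "overdominant",
                                      "backcross-additive",
                                      "neighbor-phenotype"),
                         cross_type = "f2", distance_percentile = 10,
                         pve_nei = 0.5, n = 200, a1 = NULL, major = NULL,
                         major_self = NULL, polygenic = 1e-3, seed = NULL) {
  scenario <- match.arg(scenario)
  cross_type <- normalize_cross_type(cross_type)
  if (scenario %in% c("dominant", "overdominant") && cross_type != "f2") {
    abort("dominance scenarios are defined for F2 crosses only")
  }
  if (scenario == "backcross-additive" && cross_type != "backcross") {
    abort("scenario 'backcross-additive' requires cross_type = 'backcross'")
  }
  if (pve_nei <= 0 || pve_nei >= 1) abort("`pve_nei` must lie in (0, 1)")
  a1 <- a1 %||% if (cross_type == "backcross") 0.28 else 0.56
  d2_ratio <- switch(scenario,
    additive = 0.25, dominant = 1, overdominant = 1.25,
    `backcross-additive` = -1, `neighbor-phenotype` = NA_real_)
  structure(
    list(scenario = scenario, cross_type = cross_type,
         distance_percentile = distance_percentile, pve_nei = pve_nei,
         n = n, a1 = a1, a2 = a1, d2 = a1 * d2_ratio, major = major,
         major_self = major_self, polygenic = polygenic, seed = seed),
    class = "sim_scenario"
  )
}

#' Simulate a neighbor-effect trait on a cross
#'
#' The self component assigns the major additive effect `a1` to one marker and
#' `polygenic * a1` to every other marker, adds standard-normal residuals, and
#' is standardized to mean 0 / variance 1. The neighbor component is the
#' per-individual mean genotype-pair effect over neighbors within the true
#' scale (self codes `(a2, d2, -a2)`, pair effect their product, again with
#' the polygenic background), acting at a marker distinct from the self QTL,
#' and rescaled so that exactly the requested share of the summed trait's
#' variance is attributable to it; the `neighbor-phenotype` scenario instead
#' adds the scaled mean self-phenotype of neighbors.
#'
#' @param cross A [cross_population()] (default: simulated from the scenario).
#' @param smap Spatial map (default: simulated).
#' @param scenario A [sim_scenario()].
#' @return A `sim_result` list: `cross`, `smap`, `y`, `major` (marker name),
#'   `s_true`, `a2`, `d2`, `share_realized`, `scenario`.
#' @export
sim_phenotype <- function(scenario, cross = NULL, smap = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  cross <- cross %||% sim_cross(scenario$cross_type, n = scenario$n)
  smap <- smap %||% sim_spatial(nrow(cross$geno))
  smap <- validate_spatial(smap)
  if (nrow(smap) != nrow(cross$geno)) {
    abort("spatial map and cross disagree on individual count")
  }
  smap$id <- cross$ids
  n <- nrow(cross$geno)
  n_mar <- ncol(cross$geno)
  major <- scenario$major %||% sample.int(n_mar, 1)
  if (major < 1 || major > n_mar) abort("major-marker index out of range")
  # self-QTL and neighbor-QTL loci are decoupled: the major self effect sits
  # at its own marker, the neighbor effect at `major`
  major_self <- scenario$major_self %||%
    sample(setdiff(seq_len(n_mar), major), 1)

  geno <- cross$geno
  if (anyNA(geno)) abort("simulated phenotype requires complete genotypes")

  # self component: additive codes -1/0/1, effect a1 at its major marker,
  # polygenic background elsewhere
  add_code <- c(-1, 0, 1)[geno]
  dim(add_code) <- dim(geno)
  eff <- rep(scenario$polygenic * scenario$a1, n_mar)
  eff[major_self] <- scenario$a1
  y_self <- drop(add_code %*% eff) + stats::rnorm(n)
  y_self <- (y_self - mean(y_self)) / stats::sd(y_self)

  # neighborhood at the true scale
  d <- stats::dist(cbind(smap$x, smap$y))
  s_true <- as.numeric(stats::quantile(as.vector(d),
                                       scenario$distance_percentile / 100))
  A <- as.matrix(d) <= s_true
  diag(A) <- FALSE
  L <- rowSums(A)

  zero_nei <- FALSE
  if (scenario$scenario == "neighbor-phenotype") {
    w <- ifelse(L > 0, drop(A %*% y_self) / pmax(L, 1), 0)
  } else {
    a2 <- scenario$a2
    d2 <- scenario$d2
    w <- numeric(n)
    for (k in seq_len(n_mar)) {
      gk <- c(a2, d2, -a2)[geno[, k]] *
        (if (k == major) 1 else scenario$polygenic)
      w <- w + gk * ifelse(L > 0, drop(A %*% gk) / pmax(L, 1), 0)
    }
    zero_nei <- a2 == 0 && (is.na(d2) || d2 == 0)
  }

  if (zero_nei || stats::sd(w) < 1e-12) {
    if (!zero_nei) {
      abort("neighbor component has no variance; requested share unattainable")
    }
    y <- y_self
    share <- 0
  } else {
    # rescale w so its share of total variance is exactly pve_nei
    phi <- scenario$pve_nei
    vw <- stats::var(w)
    vs <- stats::var(y_self)
    cv <- stats::cov(y_self, w)
    cc <- (2 * phi * cv +
             sqrt(4 * phi^2 * cv^2 + 4 * vw * (1 - phi) * phi * vs)) /
      (2 * vw * (1 - phi))
    y <- y_self + cc * w
    share <- (cc^2 * vw) / stats::var(y)
  }

  structure(
    list(cross = cross, smap = smap, y = y, y_self = y_self,
         major = cross$map$marker[major],
         major_self = cross$map$marker[major_self], s_true = s_true,
         a2 = scenario$a2, d2 = scenario$d2, share_realized = share,
         scenario = scenario),
    class = "sim_result"
  )
}

#' Run the simulation benchmark
#'
#' For each scenario x true-distance percentile x replicate: simulates a
#' cross, spatial map, and neighbor-effect trait; estimates the effective
#' scale by [delta_pve()]; scans neighbor effects at the estimated scale; and
#' records the major-marker `lod_nei` together with the variance-partitioning
#' summaries (PVE_self, PVE_nei, h2 and their net difference).
#'
#' @param scenarios Character vector of scenario names (see [sim_scenario()]).
#' @param cross_type Cross design shared by the scenarios.
#' @param percentiles True-distance percentiles (default 10th-50th).
#' @param reps Replicates per scenario x percentile.
#' @param n Individuals per replicate.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param step Pseudomarker step for [calc_genoprob()] (`Inf`: markers only,
#'   the benchmark default).
#' @return Tibble with one row per replicate: `scenario`, `percentile`,
#'   `rep`, `s_true`, `s_hat`, `s_hat_percentile`, `lod_self_major`,
#'   `lod_nei_major`, `pve_self`, `pve_nei`, `h2`, `net_pve`,
#'   `share_realized`, plus an `error` column for propagated per-rep failures.
#' @export
run_benchmark <- function(scenarios = "additive", cross_type = "f2",
                          percentiles = seq(10, 50, 10), reps = 10,
                          n = 200, seed = 1, step = Inf) {
  if (reps < 1) abort("reps must be >= 1")
  grid <- expand.grid(scenario = scenarios, percentile = percentiles,
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  seeds <- draw_seeds(nrow(grid), seed)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows[[i]] <- tryCatch(
      benchmark_rep(grid$scenario[i], cross_type, grid$percentile[i],
                    grid$rep[i], n, seeds[i], step),
      error = function(e) {
        tibble(scenario = grid$scenario[i], percentile = grid$percentile[i],
               rep = grid$rep[i], s_true = NA_real_, s_hat = NA_real_,
               s_hat_percentile = NA_real_, lod_self_major = NA_real_,
               lod_nei_major = NA_real_, pve_self = NA_real_,
               pve_nei = NA_real_, h2 = NA_real_, net_pve = NA_real_,
               share_realized = NA_real_, error = conditionMessage(e))
      })
  }
  bind_rows(rows)
}

benchmark_rep <- function(scenario, cross_type, percentile, rep_i, n, seed,
                          step) {
  sc <- sim_scenario(scenario, cross_type = cross_type,
                     distance_percentile = percentile, n = n, seed = seed)
  sim <- sim_phenotype(sc)
  gp <- calc_genoprob(sim$cross, step = step)
  scales <- distance_scales(sim$smap, 10)
  prof <- delta_pve(gp, sim$smap, sim$y, scales = scales)
  s_hat <- attr(prof, "s_hat")
  ni <- neighbor_identity(gp, sim$smap, s_hat)
  scan <- suppressWarnings(scan_neighbor(gp, ni, sim$y))
  # the major-effect marker: the neighbor QTL, except in the
  # neighbor-phenotype control where only the self QTL exists
  eval_marker <- if (scenario == "neighbor-phenotype") sim$major_self else sim$major
  at <- match(eval_marker, scan$marker)
  hat_row <- which(prof$s == s_hat)
  g <- glance.pve_profile(prof)
  pve_self <- prof$pve_self[hat_row]
  pve_nei <- prof$pve_nei[hat_row]
  tibble(
    scenario = scenario, percentile = percentile, rep = rep_i,
    s_true = sim$s_true, s_hat = s_hat,
    s_hat_percentile = prof$percentile[hat_row],
    lod_self_major = scan$lod_self[at], lod_nei_major = scan$lod_nei[at],
    pve_self = pve_self, pve_nei = pve_nei, h2 = g$h2,
    net_pve = pve_self + pve_nei - g$h2,
    share_realized = sim$share_realized, error = NA_character_
  )
}
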