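#' Build a genetic map
#'
#' A genetic map is a tibble with one row per marker: chromosome id, marker
#' name, and position in centimorgans. Positions must be non-decreasing within
#' a chromosome and marker names unique genome-wide.
#'
#' @param chr Chromosome id per marker (coerced to character).
#' @param marker Marker names, unique genome-wide.
#' @param pos Positions in cM, non-negative and non-decreasing within
#'   chromosome.
#' @return A tibble of class `genetic_map` with columns `chr`, `marker`, `pos`.
#' @export
genetic_map <- function(chr, marker, pos) {
  map <- tibble(chr = as.character(chr), marker = as.character(marker),
                pos = as.numeric(pos))
  validate_genetic_map(map)
}

validate_genetic_map <- function(map) {
  stopifnot(all(c("chr", "marker", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) {
    abort(paste0("duplicated marker name(s): ",
                 paste(unique(map$marker[duplicated(map$marker)]), collapse = ", ")))
  }
  if (any(!is.finite(map$pos)) || any(map$pos < 0)) {
    abort("marker positions must be finite and non-negative cM values")
  }
  bad <- map |>
    group_by(.data$chr) |>
    summarise(ok = !is.unsorted(.data$pos), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("positions not sorted on chromosome(s): ",
                 paste(bad$chr, collapse = ", ")))
  }
  class(map) <- unique(c("genetic_map", class(map)))
  map
}

#' Insert pseudomarkers into a genetic map
#'
#' Builds the evaluation grid for interval mapping: every observed marker plus
#' evenly spaced pseudomarkers so that no two adjacent grid positions are more
#' than `step` cM apart.
#'
#' @param map A [genetic_map()] tibble.
#' @param step Maximum spacing between adjacent grid positions, in cM. Use
#'   `Inf` to evaluate at observed markers only.
#' @return A tibble (class `position_grid`) with columns `chr`, `marker`
#'   (pseudomarkers named `c<chr>.loc<pos>`), `pos`, `is_marker`, and
#'   `geno_col` (column index in the genotype matrix; `NA` for pseudomarkers).
#' @export
insert_pseudomarkers <- function(map, step = 1) {
  map <- validate_genetic_map(as_tibble(map))
  if (!is.numeric(step) || length(step) != 1 || is.na(step) || step <= 0) {
    abort("`step` must be a single positive number (cM)")
  }
  out <- vector("list", length(unique(map$chr)))
  chrs <- unique(map$chr)
  for (ci in seq_along(chrs)) {
    mc <- map[map$chr == chrs[ci], ]
    rows <- list(tibble(chr = mc$chr, marker = mc$marker, pos = mc$pos,
                        is_marker = TRUE,
                        geno_col = match(mc$marker, map$marker)))
    if (is.finite(step) && nrow(mc) > 1) {
      for (k in seq_len(nrow(mc) - 1)) {
        gap <- mc$pos[k + 1] - mc$pos[k]
        if (gap > step) {
          n_in <- ceiling(gap / step) - 1
          p <- mc$pos[k] + gap * seq_len(n_in) / (n_in + 1)
          rows[[length(rows) + 1]] <- tibble(
            chr = chrs[ci],
            marker = sprintf("c%s.loc%.6g", chrs[ci], p),
            pos = p, is_marker = FALSE, geno_col = NA_integer_
          )
        }
      }
    }
    g <- bind_rows(rows) |> arrange(.data$pos, !.data$is_marker)
    # keep the marker when a pseudomarker would coincide with it
    g <- g[!duplicated(g$pos), ]
    out[[ci]] <- g
  }
  grid <- bind_rows(out)
  class(grid) <- unique(c("position_grid", class(grid)))
  grid
}

#' Estimate a genetic map from observed genotypes
#'
#' Maximum-likelihood estimates of adjacent-pair recombination fractions from
#' two-marker genotype counts, converted to cM via the chosen map function.
#' For selfed RILs the observed recombination fraction is first mapped back to
#' the meiotic fraction through the RIL expansion R = 2r / (1 + 2r).
#'
#' @param cross A [cross_population()].
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @param max_rf Recombination fractions are capped just below 0.5 at this
#'   value before cM conversion, to avoid infinite distances for unlinked
#'   markers (a warning is raised when the cap binds).
#' @return A `genetic_map` tibble with re-estimated positions (each chromosome
#'   starting at 0 cM).
#' @export
estimate_map <- function(cross, map_function = "haldane", max_rf = 0.49) {
  mfs <- get_map_function(map_function)
  map <- cross$map
  geno <- cross$geno
  capped <- FALSE
  pieces <- list()
  for (cc in unique(map$chr)) {
    mc <- map[map$chr == cc, ]
    d <- numeric(max(nrow(mc) - 1, 0))
    if (nrow(mc) >= 2) {
      for (k in seq_len(nrow(mc) - 1)) {
        g1 <- geno[, match(mc$marker[k], colnames(geno))]
        g2 <- geno[, match(mc$marker[k + 1], colnames(geno))]
        keep <- !is.na(g1) & !is.na(g2)
        if (!any(keep)) {
          warn(paste0("no informative pairs for interval ", mc$marker[k], "-",
                      mc$marker[k + 1], "; retaining map distance"))
          d[k] <- mc$pos[k + 1] - mc$pos[k]
          next
        }
        r <- est_rf_pair(g1[keep], g2[keep], cross$cross_type)
        if (r > max_rf) {
          r <- max_rf
          capped <- TRUE
        }
        d[k] <- mfs$imf(r)
      }
    }
    pieces[[cc]] <- tibble(chr = cc, marker = mc$marker,
                           pos = cumsum(c(0, d)))
  }
  if (capped) {
    warn(paste0("one or more recombination fractions capped at ", max_rf,
                " (markers look unlinked)"))
  }
  validate_genetic_map(bind_rows(pieces))
}

# ML recombination fraction for one adjacent marker pair
est_rf_pair <- function(g1, g2, cross_type) {
  if (cross_type == "backcross") {
    return(mean(g1 != g2))
  }
  if (cross_type == "riself") {
    R <- mean(g1 != g2)
    R <- min(R, 0.499999) # observed RF in RILs is < 0.5 at meiotic r < 0.5
    return(R / (2 * (1 - R)))
  }
  # f2: numeric ML over the two-locus genotype table
  counts <- table(factor(g1, levels = 1:3), factor(g2, levels = 1:3))
  negll <- function(r) {
    Tm <- trans_matrix(r, "f2")
    P <- c(0.25, 0.5, 0.25) * Tm
    -sum(counts * log(pmax(P, 1e-300)))
  }
  stats::optimize(negll, interval = c(1e-6, 0.499))$minimum
}
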