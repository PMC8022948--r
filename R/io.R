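# Readers and writers for the cross CSV dialect, spatial maps, and results.

#' Read a cross from CSV
#'
#' The cross CSV dialect: row 1 holds column names (phenotype names and marker
#' names), row 2 chromosome ids (empty cells flag phenotype columns), row 3 cM
#' positions, and subsequent rows one individual each. Genotype codes default
#' to `AA`/`AB`/`BB` with `A`/`H`/`B` accepted as shorthand; `-` and empty
#' cells are missing. A phenotype column named `id` supplies individual ids.
#'
#' @param path File path.
#' @param cross_type Cross design (`"f2"`, `"backcross"`, `"riself"`).
#' @return A [cross_population()]; phenotype columns end up in `$pheno`.
#' @export
read_cross <- function(path, cross_type) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 4) abort(paste0(path, ": expected header rows plus individuals"))
  cn <- trimws(as.character(raw[1, ]))
  chr_row <- trimws(as.character(raw[2, ]))
  pos_row <- trimws(as.character(raw[3, ]))
  is_pheno <- chr_row == "" | is.na(chr_row)
  if (!any(!is_pheno)) abort(paste0(path, ": no marker columns found"))
  body <- raw[-(1:3), , drop = FALSE]

  markers <- cn[!is_pheno]
  if (anyDuplicated(markers)) {
    abort(paste0(path, ": duplicated marker name(s): ",
                 paste(unique(markers[duplicated(markers)]), collapse = ", ")))
  }
  map <- genetic_map(chr = chr_row[!is_pheno], marker = markers,
                     pos = as.numeric(pos_row[!is_pheno]))
  geno <- as.matrix(body[, !is_pheno, drop = FALSE])
  colnames(geno) <- markers

  pheno <- NULL
  ids <- NULL
  if (any(is_pheno)) {
    pheno <- as_tibble(body[, is_pheno, drop = FALSE], .name_repair = "minimal")
    names(pheno) <- cn[is_pheno]
    pheno <- as_tibble(lapply(pheno, function(col) {
      num <- suppressWarnings(as.numeric(col))
      if (all(is.na(num) == (is.na(col) | col == ""))) num else col
    }))
    if ("id" %in% names(pheno)) {
      ids <- as.character(body[, which(is_pheno)[match("id", cn[is_pheno])]])
    }
  }
  cross_population(geno, map, cross_type, pheno = pheno, ids = ids)
}

#' Write a cross to CSV
#'
#' Inverse of [read_cross()]: phenotype columns first (chromosome/position
#' rows empty), then markers with chromosome ids and cM positions.
#'
#' @param cross A [cross_population()].
#' @param path Output path.
#' @param include_id Write the individual ids as an `id` phenotype column.
#' @return `path`, invisibly.
#' @export
write_cross <- function(cross, path, include_id = TRUE) {
  geno_chr <- matrix(GENO_CODES[cross$geno], nrow(cross$geno),
                     ncol(cross$geno))
  geno_chr[is.na(geno_chr)] <- "-"
  ph <- cross$pheno
  if (include_id && (is.null(ph) || !"id" %in% names(ph))) {
    ph <- bind_cols(tibble(id = cross$ids), ph %||% tibble())
  }
  n_ph <- if (is.null(ph)) 0 else ncol(ph)
  header <- rbind(
    c(if (n_ph) names(ph), cross$map$marker),
    c(rep("", n_ph), cross$map$chr),
    c(rep("", n_ph), as.character(cross$map$pos))
  )
  body <- cbind(
    if (n_ph) as.matrix(as_tibble(lapply(ph, as.character))) else NULL,
    geno_chr
  )
  utils::write.table(rbind(header, body), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spatial map from CSV
#'
#' @param path CSV with columns `id`, `x`, `y`.
#' @return Spatial-map tibble.
#' @export
read_spatial <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_spatial(utils::read.csv(path))
}

#' Write a spatial map to CSV
#' @param smap Spatial-map tibble (`id`, `x`, `y`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spatial <- function(smap, path) {
  utils::write.csv(validate_spatial(smap), path, row.names = FALSE)
  invisible(path)
}

#' Write scan results to CSV
#'
#' Columns: chromosome, position, marker name, effect estimates and LOD
#' scores as produced by [scan_self()] / [scan_neighbor()].
#'
#' @param scan A `neiqtl_scan` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}

#' Write permutation thresholds to JSON
#'
#' Records thresholds per alpha together with `n_perm` and the seed, so a run
#' can be reproduced exactly.
#'
#' @param pt A [perm_threshold()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(pt, path) {
  jsonlite::write_json(
    list(n_perm = pt$n_perm, seed = pt$seed, alphas = pt$alphas,
         thresholds = pt$thresholds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a PVE profile to CSV with a JSON sidecar
#'
#' The CSV holds the per-scale profile; `<path>.json` records the selected
#' scale, the marker heritability, and the family.
#'
#' @param profile A [delta_pve()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  jsonlite::write_json(
    list(s_hat = attr(profile, "s_hat"), h2 = attr(profile, "h2"),
         family = attr(profile, "family")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export genotype probabilities to long CSV
#'
#' @param gp A [calc_genoprob()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genoprob <- function(gp, path) {
  utils::write.csv(as.data.frame(tidy.geno_probs(gp)), path, row.names = FALSE)
  invisible(path)
}
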