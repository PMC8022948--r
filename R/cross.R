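#' Assemble a cross population
#'
#' Bundles a genotype matrix, a genetic map, the cross design, and (optionally)
#' phenotypes into one object. Genotypes are stored internally as integers
#' 1/2/3 for AA/AB/BB with `NA` for missing.
#'
#' Cross-design constraints are enforced: a backcross may not contain BB
#' calls (error), and heterozygous calls in a selfed RIL are demoted to
#' missing with a warning (true residual heterozygosity cannot be modelled by
#' the two-state chain).
#'
#' @param geno Individuals x markers matrix of genotype codes. Character
#'   codes `"AA"/"AB"/"BB"` (or `"A"/"H"/"B"`) or integers 1/2/3; missing as
#'   `NA`, `"-"` or `""`.
#' @param map A [genetic_map()]; marker order must match `geno` columns.
#' @param cross_type `"f2"`, `"backcross"`, or `"riself"` (selfed RIL;
#'   aliases such as `"selfed-RIL"` are accepted).
#' @param pheno Optional data frame of phenotypes/covariates, one row per
#'   individual.
#' @param ids Optional individual ids (default: rownames of `geno` or
#'   `ind1...indN`).
#' @return An object of class `cross_pop`.
#' @export
cross_population <- function(geno, map, cross_type, pheno = NULL, ids = NULL) {
  cross_type <- normalize_cross_type(cross_type)
  map <- validate_genetic_map(as_tibble(map))
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map)) {
    abort(sprintf("genotype matrix has %d columns but map has %d markers",
                  ncol(geno), nrow(map)))
  }
  if (!is.null(colnames(geno)) && !identical(colnames(geno), map$marker)) {
    abort("genotype column names do not match map marker order")
  }
  geno <- encode_geno(geno)
  colnames(geno) <- map$marker

  if (cross_type == "backcross" && any(geno == 3L, na.rm = TRUE)) {
    abort("backcross genotypes contain BB calls")
  }
  if (cross_type == "riself" && any(geno == 2L, na.rm = TRUE)) {
    n_het <- sum(geno == 2L, na.rm = TRUE)
    warn(sprintf("selfed RIL: %d heterozygous call(s) set to missing", n_het))
    geno[geno == 2L] <- NA_integer_
  }

  ids <- as.character(ids %||% rownames(geno) %||% paste0("ind", seq_len(nrow(geno))))
  if (length(ids) != nrow(geno)) abort("`ids` length does not match individuals")
  rownames(geno) <- ids
  if (!is.null(pheno)) {
    pheno <- as_tibble(pheno)
    if (nrow(pheno) != nrow(geno)) {
      abort("phenotype table and genotype matrix disagree on individual count")
    }
  }
  structure(
    list(geno = geno, map = map, cross_type = cross_type,
         pheno = pheno, ids = ids),
    class = "cross_pop"
  )
}

# accept character codes, A/H/B shorthand, or integers already in 1:3
encode_geno <- function(geno) {
  if (is.numeric(geno)) {
    g <- geno
    bad <- !(is.na(g) | g %in% 1:3)
    if (any(bad)) abort("numeric genotype codes must be 1, 2, 3 or NA")
    storage.mode(g) <- "integer"
    return(g)
  }
  lookup <- c(AA = 1L, AB = 2L, BB = 3L, A = 1L, H = 2L, B = 3L,
    BA = 2L, `1` = 1L, `2` = 2L, `3` = 3L)
  g <- matrix(NA_integer_, nrow(geno), ncol(geno))
  chr <- trimws(as.character(geno))
  miss <- is.na(chr) | chr %in% c("", "-", "NA", "N")
  known <- chr %in% names(lookup)
  if (any(!miss & !known)) {
    idx <- which(!miss & !known)[1]
    rc <- arrayInd(idx, dim(geno))
    abort(sprintf("unknown genotype code '%s' at row %d, column %d",
                  chr[idx], rc[1], rc[2]))
  }
  g[known] <- lookup[chr[known]]
  dimnames(g) <- dimnames(geno)
  g
}

#' @export
print.cross_pop <- function(x, ...) {
  cat(sprintf("<cross_pop> %s: %d individuals, %d markers on %d chromosome(s)\n",
              x$cross_type, nrow(x$geno), ncol(x$geno),
              length(unique(x$map$chr))))
  if (!is.null(x$pheno)) {
    cat("  phenotypes:", paste(names(x$pheno), collapse = ", "), "\n")
  }
  n_miss <- sum(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * n_miss / length(x$geno)))
  invisible(x)
}
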