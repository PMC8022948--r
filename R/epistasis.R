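# Two-way interaction (epistasis) scan between neighbor QTL effects.

#' Epistasis scan for neighbor QTL effects
#'
#' Tests two-way interactions between a focal position's neighbor identity and
#' every other position's. At each other position the additive-joint model
#' (covariates + fitted self effect + both standardized identities) is
#' compared with the model adding their product; `lod_int` is the log10
#' likelihood ratio. Positions on the focal chromosome within `linked_window`
#' cM of the focal position are reported but flagged `linked`.
#'
#' @inheritParams scan_neighbor
#' @param focal Focal grid position: a marker name or a row index into the
#'   grid.
#' @param linked_window Flagging window in cM (default 1).
#' @return Tibble with `chr`, `pos`, `marker`, `lod_int`, `linked` for every
#'   non-focal position.
#' @export
scan_epistasis <- function(gp, ni, pheno, focal, trait = NULL,
                           covariates = NULL, family = "gaussian",
                           self_scan = NULL, linked_window = 1) {
  stopifnot(inherits(gp, "geno_probs"), inherits(ni, "neighbor_identity"))
  grid <- gp$grid
  if (is.character(focal)) {
    fk <- match(focal, grid$marker)
    if (is.na(fk)) abort(paste0("focal position '", focal, "' not in grid"))
  } else {
    fk <- as.integer(focal)
    if (fk < 1 || fk > nrow(grid)) abort("focal index out of range")
  }
  self_scan <- self_scan %||% scan_self(gp, pheno, trait, covariates, family)
  y <- attr(self_scan, "y")
  X0 <- attr(self_scan, "X0")
  fam <- attr(self_scan, "family")
  self_eff <- attr(self_scan, "self_effect")
  keep <- !is.na(ni$value[, 1])
  ridge_note <- new.env()

  zf <- std_score(ni$value[keep, fk])$z
  others <- setdiff(seq_len(nrow(grid)), fk)
  lod <- rep(NA_real_, length(others))
  for (i in seq_along(others)) {
    k <- others[i]
    zk <- std_score(ni$value[keep, k])$z
    Xb <- cbind(X0[keep, , drop = FALSE], self_eff[keep, fk], zf, zk)
    f0 <- fit_ll(Xb, y[keep], fam, ridge_note)
    f1 <- fit_ll(cbind(Xb, zf * zk), y[keep], fam, ridge_note)
    lod[i] <- max((f1$ll - f0$ll) / log(10), 0)
  }
  tibble(
    chr = grid$chr[others], pos = grid$pos[others],
    marker = grid$marker[others], lod_int = lod,
    linked = grid$chr[others] == grid$chr[fk] &
      abs(grid$pos[others] - grid$pos[fk]) <= linked_window
  )
}
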