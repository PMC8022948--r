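# ggplot2 figures for scans and PVE profiles.

#' LOD-curve plot for a genome scan
#'
#' @param object A `neiqtl_scan` tibble.
#' @param which `"both"` (default, when neighbor LODs are present), `"self"`,
#'   or `"nei"`.
#' @param ... Unused.
#' @return A ggplot object: LOD against genome position, faceted by
#'   chromosome.
#' @export
autoplot.neiqtl_scan <- function(object, which = c("both", "self", "nei"),
                                 ...) {
  which <- match.arg(which)
  has_nei <- "lod_nei" %in% names(object)
  long <- as_tibble(object) |>
    select(dplyr::any_of(c("chr", "pos", "lod_self", "lod_nei"))) |>
    pivot_longer(dplyr::starts_with("lod_"), names_to = "scan",
                 names_prefix = "lod_", values_to = "lod")
  if (which != "both" || !has_nei) {
    long <- filter(long, .data$scan == if (which == "nei") "nei" else "self")
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$lod,
                                     colour = .data$scan)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(. ~ chr, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD", colour = NULL) +
    ggplot2::theme_bw()
}

#' PVE-profile plot across spatial scales
#'
#' @param object A `pve_profile` from [delta_pve()].
#' @param ... Unused.
#' @return A ggplot object: neighbor PVE (or RVE) against the spatial scale,
#'   with the selected effective distance marked.
#' @export
autoplot.pve_profile <- function(object, ...) {
  nei_col <- intersect(c("pve_nei", "rve_nei"), names(object))[1]
  df <- as_tibble(object)
  df$value <- df[[nei_col]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::geom_vline(xintercept = attr(object, "s_hat"), linetype = 2) +
    ggplot2::labs(x = "spatial scale s", y = nei_col) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
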