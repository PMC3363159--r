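#' Manhattan plot of a genome scan
#'
#' Plots `-log10(p)` against cumulative map position, chromosomes in
#' alternating colours, with optional dotted lines for the Bonferroni and
#' permutation significance thresholds (on the raw-p scale).
#'
#' @param scan An `mmra_scan` tibble.
#' @param bonferroni_p,permutation_p Optional raw p-value thresholds drawn
#'   as horizontal dotted lines.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, bonferroni_p = NULL, permutation_p = NULL) {
  df <- dplyr::filter(tibble::as_tibble(scan), !is.na(.data$p_raw))
  offsets <- df |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(len = max(.data$pos_cM), .groups = "drop") |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  df <- dplyr::left_join(df, offsets, by = "chromosome") |>
    dplyr::mutate(x = .data$pos_cM + .data$offset,
                  chromosome = factor(.data$chromosome))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, -log10(.data$p_raw),
                                        colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "cumulative map position (cM)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (!is.null(bonferroni_p)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(bonferroni_p),
                                 linetype = "dotted", colour = "magenta")
  }
  if (!is.null(permutation_p)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(permutation_p),
                                 linetype = "dotted", colour = "black")
  }
  p
}

#' @rdname plot_manhattan
#' @param object An `mmra_scan`.
#' @param ... Passed to [plot_manhattan()].
#' @export
autoplot.mmra_scan <- function(object, ...) plot_manhattan(object, ...)

#' Pairwise D' heatmap in the Haploview colour scheme
#'
#' Red: LOD > 2 and D' = 1; pink shades: LOD > 2, D' < 1; blue: LOD <= 2,
#' D' = 1; white otherwise.
#'
#' @param pairs Tibble from [ld_pairs()].
#' @param snp_order Optional SNP ordering (defaults to appearance order).
#' @return A ggplot object.
#' @export
plot_ld_heatmap <- function(pairs, snp_order = NULL) {
  if (is.null(snp_order)) snp_order <- unique(c(pairs$snp_i, pairs$snp_j))
  df <- pairs |>
    dplyr::mutate(
      i = factor(.data$snp_i, levels = snp_order),
      j = factor(.data$snp_j, levels = snp_order),
      class = dplyr::case_when(
        is.na(.data$d_prime) ~ "degenerate",
        .data$lod > 2 & .data$d_prime >= 0.999 ~ "red",
        .data$lod > 2 ~ "pink",
        .data$d_prime >= 0.999 ~ "blue",
        TRUE ~ "white"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$class,
                                    alpha = .data$d_prime), colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(red = "red", pink = "salmon",
                                          blue = "royalblue", white = "white",
                                          degenerate = "grey90")) +
    ggplot2::scale_alpha_continuous(range = c(0.3, 1), guide = "none") +
    ggplot2::labs(x = NULL, y = NULL, fill = "LD class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Distribution of the permutation maxima
#'
#' @param null A `perm_null`.
#' @param threshold Optional Wald threshold to mark.
#' @return A ggplot object.
#' @export
plot_perm_null <- function(null, threshold = NULL) {
  df <- tibble::tibble(max_wald = null$max_wald)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$max_wald)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "per-permutation maximum Wald statistic", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}
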