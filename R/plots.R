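#' MA-style plot of a differential-expression result
#'
#' Mean log2-CPM against log2 fold change per tissue, DEGs highlighted.
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  dat <- object$table |>
    dplyr::mutate(mean_expr = (.data$mean_trad + .data$mean_alt) / 2)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$mean_expr, y = .data$log2fc, colour = .data$is_deg)
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = paste0("P < ", object$p_threshold)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue)) +
    ggplot2::labs(
      x = "mean log2-CPM", y = paste0("log2FC (", object$orientation, ")")
    ) +
    ggplot2::theme_minimal()
}

#' RIF score landscape
#'
#' RIF1 against RIF2 z-scores with the significance band at the cutoff.
#'
#' @param rif A `rif_result`.
#' @param z_cut Cutoff drawn as reference lines (default 1.96).
#' @return A ggplot.
#' @export
plot_rif <- function(rif, z_cut = 1.96) {
  dat <- tibble::as_tibble(rif)
  p <- ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$rif1_z, y = .data$rif2_z, colour = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(-z_cut, z_cut), linetype = 3) +
    ggplot2::geom_vline(xintercept = c(-z_cut, z_cut), linetype = 3) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(x = "RIF1 z-score", y = "RIF2 z-score") +
    ggplot2::theme_minimal()
  if ("tissue" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$tissue))
  }
  p
}

#' Phenotype connectivity change bar chart
#'
#' Total connections per phenotype under each diet, ordered by change.
#'
#' @param conn A [phenotype_connection_table()].
#' @return A ggplot.
#' @export
plot_phenotype_connectivity <- function(conn) {
  ordered <- rank_phenotypes_by_change(conn)
  dat <- ordered |>
    dplyr::select("phenotype", ALT = "total_alt", TRAD = "total_trad") |>
    tidyr::pivot_longer(-"phenotype", names_to = "diet", values_to = "n") |>
    dplyr::mutate(
      phenotype = factor(.data$phenotype, levels = rev(ordered$phenotype))
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$n, y = .data$phenotype, fill = .data$diet)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "phenotype-anchored connections", y = NULL) +
    ggplot2::theme_minimal()
}
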