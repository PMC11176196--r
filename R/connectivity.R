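#' Per-phenotype connection counts by diet and tissue
#'
#' For each phenotype, counts the incident edges of each diet network broken
#' down by the edge tissue label. Phenotype-phenotype edges have no tissue
#' and are reported in separate `pheno` columns; the per-diet totals and the
#' connectivity change are sums over the tissue cells only. Rows are sorted
#' by grand total (ALT + TRAD), descending.
#'
#' @param net_trad,net_alt `diet_network` objects for the two diets.
#' @return Tibble with one row per phenotype: `alt_<tissue>` and
#'   `trad_<tissue>` cells, `alt_pheno` / `trad_pheno`, `total_alt`,
#'   `total_trad`, `change = |total_alt - total_trad|`.
#' @export
phenotype_connection_table <- function(net_trad, net_alt) {
  traits <- net_trad$nodes$id[net_trad$nodes$kind == "phenotype"]
  tissues <- intersect(
    tissue_levels(),
    unique(c(net_trad$edges$tissue_label, net_alt$edges$tissue_label))
  )
  if (length(tissues) == 0) tissues <- tissue_levels()

  count_one <- function(net, prefix) {
    kind <- stats::setNames(net$nodes$kind, net$nodes$id)
    long <- net$edges |>
      tidyr::pivot_longer(
        c("node_a", "node_b"),
        names_to = NULL, values_to = "node"
      ) |>
      dplyr::filter(kind[.data$node] == "phenotype") |>
      dplyr::count(
        phenotype = .data$node, tissue_label = .data$tissue_label
      )
    cells <- tidyr::expand_grid(
      phenotype = traits, tissue_label = c(tissues, "none")
    ) |>
      dplyr::left_join(long, by = c("phenotype", "tissue_label")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
      tidyr::pivot_wider(
        names_from = "tissue_label", values_from = "n",
        names_prefix = paste0(prefix, "_")
      )
    names(cells)[names(cells) == paste0(prefix, "_none")] <-
      paste0(prefix, "_pheno")
    cells
  }

  alt <- count_one(net_alt, "alt")
  trad <- count_one(net_trad, "trad")
  out <- dplyr::left_join(alt, trad, by = "phenotype")
  alt_cells <- paste0("alt_", tissues)
  trad_cells <- paste0("trad_", tissues)
  out |>
    dplyr::mutate(
      total_alt = rowSums(dplyr::pick(dplyr::all_of(alt_cells))),
      total_trad = rowSums(dplyr::pick(dplyr::all_of(trad_cells))),
      change = abs(.data$total_alt - .data$total_trad)
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$total_alt + .data$total_trad), .data$phenotype
    )
}

#' Rank phenotypes by connectivity change
#'
#' Orders a [phenotype_connection_table()] by the absolute change in total
#' connections between diets, descending; ties are broken alphabetically by
#' phenotype code.
#'
#' @param table A phenotype connectivity table.
#' @return The table reordered.
#' @export
rank_phenotypes_by_change <- function(table) {
  if (nrow(table) == 0) stop("empty phenotype table", call. = FALSE)
  dplyr::arrange(table, dplyr::desc(.data$change), .data$phenotype)
}

#' Differentially connected genes (DCGs)
#'
#' Counts, for every gene variable appearing in either diet network's node
#' set, its incident edges in each network, and flags as differentially
#' connected the genes whose connection count changes by at least `min_diff`
#' and that are differentially expressed in the variable's tissue (a DCG is
#' by construction also a DEG). Sorted by the absolute connectivity
#' difference, descending.
#'
#' Gene connectivity is counted on the full set of PCIT-kept pairs
#' (`edges_all`, including gene-gene pairs) when the networks carry it;
#' phenotype anchoring applies to the exported network edges, not to a
#' gene's connectivity, whose changes are dominated by rewired gene-gene
#' co-expression.
#'
#' @param net_trad,net_alt `diet_network` objects.
#' @param de A `de_result`.
#' @param min_diff Minimum absolute connectivity difference (default 1).
#' @return Tibble: `gene`, `tissue`, `conn_trad`, `conn_alt`, `diff`,
#'   `is_deg`, `is_dcg`.
#' @export
dcg_table <- function(net_trad, net_alt, de, min_diff = 1) {
  stopifnot(inherits(de, "de_result"))
  nodes <- net_trad$nodes
  gene_ids <- nodes$id[nodes$kind == "gene"]
  degree_of <- function(net) {
    e <- net$edges_all %||% net$edges
    tab <- table(c(e$node_a, e$node_b))
    counts <- as.integer(tab[gene_ids])
    counts[is.na(counts)] <- 0L
    counts
  }
  parts <- strsplit(gene_ids, ":", fixed = TRUE)
  out <- tibble::tibble(
    gene = vapply(parts, `[`, character(1), 1),
    tissue = vapply(parts, `[`, character(1), 2),
    conn_trad = degree_of(net_trad),
    conn_alt = degree_of(net_alt)
  ) |>
    dplyr::mutate(diff = abs(.data$conn_trad - .data$conn_alt)) |>
    dplyr::left_join(
      dplyr::select(de$table, "gene", "tissue", "is_deg"),
      by = c("gene", "tissue")
    ) |>
    dplyr::mutate(
      is_deg = dplyr::coalesce(.data$is_deg, FALSE),
      is_dcg = .data$diff >= min_diff & .data$is_deg
    ) |>
    dplyr::arrange(dplyr::desc(.data$diff), .data$gene)
  out
}

#' Differentially expressed and differentially connected regulators (DEDC)
#'
#' Restricts a [dcg_table()] to TFs and COFs flagged as DCGs and joins the
#' per-diet mean expression and DE p-value, mirroring the layout of a
#' regulator differential-connectivity report: tissue, gene, type,
#' expression under each diet, connections under each diet, and the
#' connectivity difference.
#'
#' @param dcg A [dcg_table()] result.
#' @param rif A `rif_result` (with `type`; used as the regulator catalogue),
#'   or any data frame with `regulator` and `type` columns.
#' @param de A `de_result`.
#' @return Tibble: `tissue`, `gene`, `type`, `expr_trad`, `expr_alt`,
#'   `conn_trad`, `conn_alt`, `diff`, `p_value`, sorted by `diff` descending.
#' @export
dedc_regulators <- function(dcg, rif, de) {
  types <- tibble::as_tibble(rif) |>
    dplyr::distinct(gene = .data$regulator, .data$type)
  dcg |>
    dplyr::filter(.data$is_dcg) |>
    dplyr::inner_join(types, by = "gene") |>
    dplyr::left_join(
      dplyr::select(
        de$table, "gene", "tissue",
        expr_trad = "mean_trad", expr_alt = "mean_alt", "p_value"
      ),
      by = c("gene", "tissue")
    ) |>
    dplyr::select(
      "tissue", "gene", "type", "expr_trad", "expr_alt",
      "conn_trad", "conn_alt", "diff", "p_value"
    ) |>
    dplyr::arrange(dplyr::desc(.data$diff), .data$gene)
}

#' Percent difference between diet least-squares means
#'
#' Signed percent difference of the alternative-diet mean relative to the
#' traditional-diet baseline:
#' `100 * (lsmean_alt - lsmean_trad) / lsmean_trad`.
#'
#' @param lsmean_trad Baseline (traditional diet) mean, must be positive.
#' @param lsmean_alt Alternative-diet mean.
#' @return Signed percentage (vectorized).
#' @examples
#' percent_diet_difference(8.00, 9.77) # +22.1
#' @export
percent_diet_difference <- function(lsmean_trad, lsmean_alt) {
  if (any(!(lsmean_trad > 0))) {
    stop("baseline mean must be positive", call. = FALSE)
  }
  100 * (lsmean_alt - lsmean_trad) / lsmean_trad
}
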