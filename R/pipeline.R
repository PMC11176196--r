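#' Pipeline configuration
#'
#' Bundles every tunable threshold of the workflow with validation. Unknown
#' arguments are rejected.
#'
#' @param de_p DEG p-value cutoff (default 0.01).
#' @param rif_z RIF |z| significance cutoff (default 1.96).
#' @param min_cpm,min_fraction Expression filter (defaults 1 and 0.5).
#' @param min_overlap Minimum pairwise observations for a network
#'   correlation (default 10).
#' @param dcg_min_diff Minimum connectivity difference for a DCG
#'   (default 1).
#' @param prior_count Log-CPM prior count (default 2).
#' @param orientation Fold-change orientation (default `"alt_minus_trad"`).
#' @param correlation Correlation method for networks (default
#'   `"pearson"`).
#' @param seed Integer seed recorded for provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(de_p = 0.01, rif_z = 1.96, min_cpm = 1,
                            min_fraction = 0.5, min_overlap = 10,
                            dcg_min_diff = 1, prior_count = 2,
                            orientation = c("alt_minus_trad", "trad_minus_alt"),
                            correlation = c("pearson", "spearman"),
                            seed = 1L) {
  orientation <- match.arg(orientation)
  correlation <- match.arg(correlation)
  stopifnot(
    de_p > 0, de_p <= 1,
    rif_z > 0,
    min_cpm >= 0,
    min_fraction > 0, min_fraction <= 1,
    min_overlap >= 2,
    dcg_min_diff >= 0,
    prior_count >= 0
  )
  structure(
    list(
      de_p = de_p, rif_z = rif_z, min_cpm = min_cpm,
      min_fraction = min_fraction, min_overlap = min_overlap,
      dcg_min_diff = dcg_min_diff, prior_count = prior_count,
      orientation = orientation, correlation = correlation,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full diet-contrast workflow
#'
#' Chains the stages on a [count_dataset()]: normalization (filter + TMM +
#' log2-CPM), per-tissue differential expression with the analytic FDR
#' table, RIF regulator scoring per tissue, construction of the two
#' diet-specific phenotype-anchored PCIT networks over all tissues jointly,
#' and the connectivity analytics (phenotype connection table, DCGs, DEDC
#' regulators, shared/unique edges). Deterministic given the dataset and
#' configuration.
#'
#' @param dataset A [count_dataset()].
#' @param config A [pipeline_config()].
#' @return A `dietwire_result` list: `expression`, `de`, `rif` (row-bound
#'   across tissues), `variables`, `networks` (list `TRAD`, `ALT`),
#'   `edge_overlap`, `phenotype_connectivity`, `dcg`, `dedc`, `summary`,
#'   `config`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "count_dataset"))
  expr <- normalize_counts(
    dataset,
    min_cpm = config$min_cpm, min_fraction = config$min_fraction,
    prior_count = config$prior_count
  )
  de <- run_de(
    expr,
    p_threshold = config$de_p, orientation = config$orientation
  )
  tissues <- unique(expr$samples$tissue)
  rif <- purrr::map(tissues, function(t) {
    suppressWarnings(
      run_rif(expr, de, dataset$regulators, t, z_cut = config$rif_z)
    )
  }) |>
    purrr::list_rbind()
  class(rif) <- c("rif_result", class(rif))

  vars <- build_variable_set(expr, de, rif, dataset$phenotypes)
  networks <- list(
    TRAD = build_diet_network(
      vars$matrices$TRAD, vars$nodes, "TRAD",
      min_overlap = config$min_overlap, method = config$correlation
    ),
    ALT = build_diet_network(
      vars$matrices$ALT, vars$nodes, "ALT",
      min_overlap = config$min_overlap, method = config$correlation
    )
  )
  overlap <- shared_and_unique_edges(networks$TRAD, networks$ALT)
  conn <- phenotype_connection_table(networks$TRAD, networks$ALT)
  dcg <- dcg_table(networks$TRAD, networks$ALT, de,
    min_diff = config$dcg_min_diff
  )
  dedc <- dedc_regulators(dcg, rif, de)

  summary <- dplyr::bind_rows(
    glance(networks$TRAD), glance(networks$ALT)
  ) |>
    dplyr::mutate(
      n_shared_edges = nrow(overlap$shared),
      n_dcg = sum(dcg$is_dcg),
      n_dedc = nrow(dedc)
    )

  structure(
    list(
      expression = expr, de = de, rif = rif, variables = vars,
      networks = networks, edge_overlap = overlap,
      phenotype_connectivity = conn, dcg = dcg, dedc = dedc,
      summary = summary, config = config
    ),
    class = "dietwire_result"
  )
}

#' @export
print.dietwire_result <- function(x, ...) {
  cat("dietwire_result\n")
  print(x$expression)
  print(x$de)
  print(x$networks$TRAD)
  print(x$networks$ALT)
  cat(
    "shared edges:", nrow(x$edge_overlap$shared),
    "| DCGs:", sum(x$dcg$is_dcg),
    "| DEDC regulators:", nrow(x$dedc), "\n"
  )
  invisible(x)
}

#' Write every stage output of a pipeline run to a directory
#'
#' Emits the normalized expression TSV, a normalization report JSON, the DE
#' and FDR tables, the RIF table, per-diet edge and node-attribute TSVs
#' (loadable by standard graph viewers), shared/unique edge TSVs, the
#' phenotype connectivity, DCG and DEDC tables, and a run summary JSON that
#' records the effective thresholds.
#'
#' @param result A `dietwire_result` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  stopifnot(inherits(result, "dietwire_result"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  expr <- result$expression
  write_table_tsv(
    tibble::as_tibble(expr$values, rownames = "gene"),
    file.path(outdir, "expression_log2cpm.tsv")
  )
  jsonlite::write_json(
    list(
      lib_sizes = as.list(expr$lib_sizes),
      tmm_factors = as.list(expr$tmm_factors),
      n_retained = length(expr$retained_genes)
    ),
    file.path(outdir, "normalization_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_table_tsv(result$de$table, file.path(outdir, "de_table.tsv"))
  write_table_tsv(result$de$fdr_table, file.path(outdir, "fdr_table.tsv"))
  write_table_tsv(
    tibble::as_tibble(result$rif), file.path(outdir, "rif_table.tsv")
  )
  write_table_tsv(
    result$variables$nodes, file.path(outdir, "node_attributes.tsv")
  )
  for (d in names(result$networks)) {
    write_table_tsv(
      result$networks[[d]]$edges,
      file.path(outdir, paste0("edges_", tolower(d), ".tsv"))
    )
  }
  write_table_tsv(
    result$edge_overlap$shared, file.path(outdir, "edges_shared.tsv")
  )
  write_table_tsv(
    result$phenotype_connectivity,
    file.path(outdir, "phenotype_connectivity.tsv")
  )
  write_table_tsv(result$dcg, file.path(outdir, "dcg_table.tsv"))
  write_table_tsv(result$dedc, file.path(outdir, "dedc_table.tsv"))
  jsonlite::write_json(
    list(
      thresholds = unclass(result$config),
      summary = result$summary
    ),
    file.path(outdir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(outdir)
}
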