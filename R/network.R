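#' Tissue of maximum expression for a gene
#'
#' The tissue whose samples have the highest mean log2-CPM for the gene.
#' Exact ties are broken by the fixed tissue order liver < muscle < rumen.
#'
#' @param expr An `expression_matrix`.
#' @param gene Gene ID (must be retained in at least one tissue).
#' @return Tissue label.
#' @export
assign_max_expression_tissue <- function(expr, gene) {
  means <- max_expression_tissue_table(expr)
  hit <- means$max_expression_tissue[means$gene == gene]
  if (length(hit) == 0) stop("gene not retained: ", gene, call. = FALSE)
  hit
}

# Per-gene tissue of maximum mean expression, vectorized.
max_expression_tissue_table <- function(expr) {
  tissues <- intersect(tissue_levels(), unique(expr$samples$tissue))
  means <- vapply(tissues, function(t) {
    rowMeans(
      expr$values[, expr$samples$sample_id[expr$samples$tissue == t],
        drop = FALSE
      ]
    )
  }, numeric(nrow(expr$values)))
  if (!is.matrix(means)) means <- matrix(means, nrow = 1)
  # max.col with ties.method = "first" respects the liver < muscle < rumen
  # order because columns follow tissue_levels()
  pick <- max.col(means, ties.method = "first")
  tibble::tibble(
    gene = rownames(expr$values),
    max_expression_tissue = tissues[pick]
  )
}

variable_id <- function(gene, tissue) paste(gene, tissue, sep = ":")

#' Assemble the network variable set and per-diet data matrices
#'
#' The node set for the diet-specific networks: one variable per
#' (informative gene, tissue) pair — informative meaning differentially
#' expressed in that tissue or a significant regulator in that tissue — plus
#' one variable per phenotype. For each diet an animals x variables matrix is
#' built over that diet's animals: gene variables take the animal's log2-CPM
#' in the tissue (NA when the tissue sample is missing), phenotype variables
#' the animal's trait value.
#'
#' @param expr An `expression_matrix`.
#' @param de A `de_result` covering the tissues of interest.
#' @param rif A `rif_result` (or row-bound results across tissues, with a
#'   `tissue` column), or `NULL` for none.
#' @param phenotypes Data frame with `animal_id` plus the trait columns.
#' @return List with `nodes` (tibble: `id`, `kind`, `tissue`,
#'   `regulator_type`, `max_expression_tissue`), `matrices` (named list
#'   `TRAD` / `ALT` of animals x variables matrices) and `animals` (named
#'   list of animal IDs per diet).
#' @export
build_variable_set <- function(expr, de, rif = NULL, phenotypes) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(de, "de_result"))
  phenotypes <- tibble::as_tibble(phenotypes)
  traits <- intersect(trait_codes(), names(phenotypes))

  deg <- de$table |>
    dplyr::filter(.data$is_deg) |>
    dplyr::select("gene", "tissue")
  sig_reg <- if (!is.null(rif) && nrow(rif) > 0) {
    rif |>
      tibble::as_tibble() |>
      dplyr::filter(.data$significant) |>
      dplyr::select(gene = "regulator", "tissue", regulator_type = "type")
  } else {
    tibble::tibble(
      gene = character(), tissue = character(), regulator_type = character()
    )
  }
  reg_types <- dplyr::distinct(
    sig_reg, .data$gene, .data$tissue, .data$regulator_type
  )
  informative <- dplyr::bind_rows(
    deg, dplyr::select(sig_reg, "gene", "tissue")
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$tissue, .data$gene)

  max_tissue <- max_expression_tissue_table(expr)
  gene_nodes <- informative |>
    dplyr::left_join(reg_types, by = c("gene", "tissue")) |>
    dplyr::left_join(max_tissue, by = "gene") |>
    dplyr::mutate(
      id = variable_id(.data$gene, .data$tissue),
      kind = "gene",
      regulator_type = dplyr::coalesce(.data$regulator_type, "none")
    ) |>
    dplyr::select(
      "id", "kind", "tissue", "regulator_type", "max_expression_tissue"
    )
  pheno_nodes <- tibble::tibble(
    id = traits, kind = "phenotype", tissue = "none",
    regulator_type = "none", max_expression_tissue = "none"
  )
  nodes <- dplyr::bind_rows(gene_nodes, pheno_nodes)

  meta <- expr$samples
  dropped <- setdiff(phenotypes$animal_id, meta$animal_id)
  if (length(dropped) > 0) {
    warning(
      "animals with no tissue samples dropped: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  animals_by_diet <- list()
  matrices <- list()
  for (d in diet_levels()) {
    diet_meta <- meta[meta$diet == d, ]
    animals <- sort(unique(diet_meta$animal_id))
    m <- matrix(NA_real_, length(animals), nrow(nodes),
      dimnames = list(animals, nodes$id)
    )
    if (nrow(informative) > 0) {
      for (t in unique(informative$tissue)) {
        sub <- diet_meta[diet_meta$tissue == t, ]
        genes_t <- informative$gene[informative$tissue == t]
        ids_t <- variable_id(genes_t, t)
        m[sub$animal_id, ids_t] <-
          t(expr$values[genes_t, sub$sample_id, drop = FALSE])
      }
    }
    ph <- phenotypes[match(animals, phenotypes$animal_id), traits,
      drop = FALSE
    ]
    m[, traits] <- as.matrix(ph)
    matrices[[d]] <- m
    animals_by_diet[[d]] <- animals
  }
  list(nodes = nodes, matrices = matrices, animals = animals_by_diet)
}

#' Build one diet-specific phenotype-anchored network
#'
#' Pairwise correlations over the diet's animals x variables matrix, PCIT
#' significance via [pcit_adjacency()], then anchoring: only kept pairs with
#' at least one phenotype endpoint become edges. Each edge carries the signed
#' correlation, its sign, and a tissue label (the gene variable's tissue;
#' `"none"` for phenotype-phenotype edges).
#'
#' @param diet_matrix Animals x variables matrix for one diet (from
#'   [build_variable_set()]).
#' @param nodes Node table from [build_variable_set()].
#' @param diet Diet label (`"TRAD"` or `"ALT"`).
#' @param min_overlap Minimum pairwise complete observations (default 10).
#' @param method Correlation method (default `"pearson"`).
#' @return A `diet_network`: list with `diet`, `nodes`, `edges` (the
#'   phenotype-anchored edge tibble: `node_a`, `node_b`, `r`, `sign`,
#'   `tissue_label`, `diet`) and `edges_all` (every PCIT-kept pair including
#'   gene-gene pairs, same columns; the basis for gene connectivity counts).
#' @export
build_diet_network <- function(diet_matrix, nodes, diet,
                               min_overlap = 10,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(colnames(diet_matrix) == nodes$id))
  cc <- correlate_variables(diet_matrix, method = method)
  adj <- pcit_adjacency(cc$r, n_obs = cc$n_obs, min_overlap = min_overlap)
  kind <- stats::setNames(nodes$kind, nodes$id)
  tissue <- stats::setNames(nodes$tissue, nodes$id)
  edges_all <- tidy(adj) |>
    dplyr::mutate(
      tissue_label = dplyr::case_when(
        kind[.data$var_a] == "gene" ~ tissue[.data$var_a],
        kind[.data$var_b] == "gene" ~ tissue[.data$var_b],
        TRUE ~ "none"
      ),
      sign = ifelse(.data$r >= 0, "+", "-"),
      diet = diet
    ) |>
    dplyr::select(
      node_a = "var_a", node_b = "var_b", "r", "sign", "tissue_label", "diet"
    )
  edges <- edges_all |>
    dplyr::filter(
      kind[.data$node_a] == "phenotype" | kind[.data$node_b] == "phenotype"
    )
  structure(
    list(diet = diet, nodes = nodes, edges = edges, edges_all = edges_all),
    class = "diet_network"
  )
}

#' @export
print.diet_network <- function(x, ...) {
  cat(
    "diet_network (", x$diet, "): ", nrow(x$nodes), " candidate nodes, ",
    nrow(x$edges), " phenotype-anchored edges\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a diet network into its edge table
#'
#' @param x A `diet_network`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.diet_network <- function(x, ...) x$edges

#' One-row summary of a diet network
#'
#' @param x A `diet_network`.
#' @param ... Unused.
#' @return Tibble with connected-node count, edge count and density (%).
#' @export
glance.diet_network <- function(x, ...) {
  n_nodes <- length(unique(c(x$edges$node_a, x$edges$node_b)))
  tibble::tibble(
    diet = x$diet,
    n_nodes = n_nodes,
    n_edges = nrow(x$edges),
    density_pct = if (n_nodes >= 2) {
      network_density(n_nodes, nrow(x$edges))
    } else {
      NA_real_
    }
  )
}

#' Network density as a percentage of possible edges
#'
#' `100 * n_edges / (n_nodes * (n_nodes - 1) / 2)` for an undirected simple
#' graph.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param n_edges Number of edges (at most `choose(n_nodes, 2)`).
#' @return Percentage in `[0, 100]`.
#' @examples
#' network_density(835, 1813) # ~0.52
#' @export
network_density <- function(n_nodes, n_edges) {
  if (any(n_nodes < 2)) stop("need at least 2 nodes", call. = FALSE)
  possible <- n_nodes * (n_nodes - 1) / 2
  if (any(n_edges > possible) || any(n_edges < 0)) {
    stop("edge count outside [0, n(n-1)/2]", call. = FALSE)
  }
  100 * n_edges / possible
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

#' Shared and diet-unique edges between two networks
#'
#' Unordered node pairs present in both networks are shared and tagged by
#' sign concordance: `same_sign`, `alt_neg_trad_pos` (negative in ALT,
#' positive in TRAD) or `alt_pos_trad_neg`. The remaining edges are unique to
#' one network.
#'
#' @param net_a,net_b Two `diet_network` objects (conventionally TRAD and
#'   ALT, in that order).
#' @return List with `shared` (tibble: `node_a`, `node_b`, `r_a`, `r_b`,
#'   `concordance`), `unique_a` and `unique_b` (edge tibbles).
#' @export
shared_and_unique_edges <- function(net_a, net_b) {
  ea <- net_a$edges |>
    dplyr::mutate(key = edge_key(.data$node_a, .data$node_b))
  eb <- net_b$edges |>
    dplyr::mutate(key = edge_key(.data$node_a, .data$node_b))
  shared_keys <- intersect(ea$key, eb$key)
  shared <- dplyr::inner_join(
    dplyr::select(ea, "key", "node_a", "node_b", r_a = "r"),
    dplyr::select(eb, "key", r_b = "r"),
    by = "key"
  ) |>
    dplyr::mutate(
      concordance = dplyr::case_when(
        sign(.data$r_a) == sign(.data$r_b) ~ "same_sign",
        .data$r_b < 0 ~ "alt_neg_trad_pos",
        TRUE ~ "alt_pos_trad_neg"
      )
    ) |>
    dplyr::select("node_a", "node_b", "r_a", "r_b", "concordance")
  list(
    shared = shared,
    unique_a = dplyr::select(
      dplyr::filter(ea, !.data$key %in% shared_keys), -"key"
    ),
    unique_b = dplyr::select(
      dplyr::filter(eb, !.data$key %in% shared_keys), -"key"
    )
  )
}
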