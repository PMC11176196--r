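# Small hand-built networks used across the network/connectivity tests.
make_nodes <- function(genes, tissues, traits) {
  dplyr::bind_rows(
    tibble::tibble(
      id = paste(genes, tissues, sep = ":"), kind = "gene",
      tissue = tissues, regulator_type = "none",
      max_expression_tissue = tissues
    ),
    tibble::tibble(
      id = traits, kind = "phenotype", tissue = "none",
      regulator_type = "none", max_expression_tissue = "none"
    )
  )
}

make_net <- function(diet, nodes, edges) {
  tissue <- stats::setNames(nodes$tissue, nodes$id)
  kind <- stats::setNames(nodes$kind, nodes$id)
  edges <- tibble::as_tibble(edges)
  edges$sign <- ifelse(edges$r >= 0, "+", "-")
  edges$tissue_label <- dplyr::case_when(
    kind[edges$node_a] == "gene" ~ tissue[edges$node_a],
    kind[edges$node_b] == "gene" ~ tissue[edges$node_b],
    TRUE ~ "none"
  )
  edges$diet <- diet
  structure(list(diet = diet, nodes = nodes, edges = edges),
    class = "diet_network"
  )
}
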