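test_that("network density matches direct arithmetic", {
  expect_equal(network_density(835, 1813), 0.52, tolerance = 0.01)
  expect_equal(network_density(525, 998), 0.72, tolerance = 0.01)
  expect_equal(network_density(10, 45), 100)
  expect_error(network_density(1, 0), "at least 2")
  expect_error(network_density(4, 10), "outside")
})

test_that("variable set is the union of informative genes per tissue plus traits", {
  sim <- simulate_counts(small_config(61))
  res_expr <- normalize_counts(sim$dataset)
  de <- run_de(res_expr)
  rif <- purrr::list_rbind(purrr::map(
    tissue_levels(),
    function(t) {
      suppressWarnings(run_rif(res_expr, de, sim$dataset$regulators, t))
    }
  ))
  class(rif) <- c("rif_result", class(rif))
  vars <- build_variable_set(res_expr, de, rif, sim$dataset$phenotypes)

  # enumeration oracle
  expected <- 0L
  for (t in tissue_levels()) {
    degs <- de$table$gene[de$table$tissue == t & de$table$is_deg]
    sigs <- rif$regulator[rif$tissue == t & rif$significant]
    expected <- expected + length(union(degs, sigs))
  }
  gene_nodes <- vars$nodes[vars$nodes$kind == "gene", ]
  expect_identical(nrow(gene_nodes), expected)
  expect_identical(
    sum(vars$nodes$kind == "phenotype"), length(trait_codes())
  )
  # a gene informative in two tissues appears as two variables
  dup <- table(sub(":.*", "", gene_nodes$id))
  if (any(dup > 1)) {
    g <- names(dup)[dup > 1][1]
    ids <- gene_nodes$id[sub(":.*", "", gene_nodes$id) == g]
    expect_gt(length(unique(sub(".*:", "", ids))), 1)
  }
  # per-diet matrices align animals x variables
  expect_identical(colnames(vars$matrices$TRAD), vars$nodes$id)
  expect_identical(
    nrow(vars$matrices$ALT), as.integer(small_config(61)$n_animals_per_diet)
  )
})

test_that("with no DEGs or significant regulators only phenotypes remain", {
  sim <- simulate_counts(
    small_config(62, n_de_per_tissue = 0, n_rewired_regulators = 0)
  )
  expr <- normalize_counts(sim$dataset)
  de <- run_de(expr, p_threshold = 1e-12) # essentially nothing passes
  vars <- build_variable_set(expr, de, NULL, sim$dataset$phenotypes)
  expect_true(all(vars$nodes$kind == "phenotype"))
})

test_that("diet networks are phenotype-anchored with labeled, signed edges", {
  sim <- simulate_counts(small_config(63))
  res <- run_pipeline(sim$dataset)
  for (net in res$networks) {
    kind <- stats::setNames(net$nodes$kind, net$nodes$id)
    expect_true(all(
      kind[net$edges$node_a] == "phenotype" |
        kind[net$edges$node_b] == "phenotype"
    ))
    # no self edges, no duplicate unordered pairs
    expect_false(any(net$edges$node_a == net$edges$node_b))
    keys <- paste(
      pmin(net$edges$node_a, net$edges$node_b),
      pmax(net$edges$node_a, net$edges$node_b)
    )
    expect_false(any(duplicated(keys)))
    expect_identical(net$edges$sign, ifelse(net$edges$r >= 0, "+", "-"))
  }
})

test_that("a phenotype copying a gene variable connects in both diets", {
  sim <- simulate_counts(small_config(64))
  expr <- normalize_counts(sim$dataset)
  de <- run_de(expr)
  vars <- build_variable_set(expr, de, NULL, sim$dataset$phenotypes)
  # overwrite one trait with a noise-free copy of a gene variable
  gene_id <- vars$nodes$id[vars$nodes$kind == "gene"][1]
  for (d in c("TRAD", "ALT")) {
    vars$matrices[[d]][, "REA"] <- vars$matrices[[d]][, gene_id]
  }
  for (d in c("TRAD", "ALT")) {
    net <- build_diet_network(vars$matrices[[d]], vars$nodes, d)
    hit <- (net$edges$node_a == gene_id & net$edges$node_b == "REA") |
      (net$edges$node_b == gene_id & net$edges$node_a == "REA")
    expect_true(any(hit))
  }
})

test_that("maximum-expression tissue is the argmax with the documented tie-break", {
  sim <- simulate_counts(small_config(65))
  expr <- normalize_counts(sim$dataset)
  g <- expr$retained_genes[1]
  means <- vapply(tissue_levels(), function(t) {
    mean(expr$values[
      g, expr$samples$sample_id[expr$samples$tissue == t]
    ])
  }, numeric(1))
  expect_identical(
    assign_max_expression_tissue(expr, g),
    names(means)[which.max(means)]
  )
  expect_error(assign_max_expression_tissue(expr, "NOPE"), "not retained")
  # tie-break: liver < muscle < rumen with max.col(ties.method = "first")
  fake <- expr
  fake$values <- matrix(5, 1, ncol(expr$values),
    dimnames = list("TIE", colnames(expr$values))
  )
  expect_identical(assign_max_expression_tissue(fake, "TIE"), "liver")
})

test_that("shared and unique edge sets partition both networks", {
  nodes <- make_nodes(
    paste0("g", 1:4), rep("liver", 4), c("ME", "CY")
  )
  e_trad <- tibble::tibble(
    node_a = c("g1:liver", "g2:liver", "g3:liver", "ME"),
    node_b = c("ME", "ME", "CY", "CY"),
    r = c(0.8, -0.5, 0.6, 0.4)
  )
  e_alt <- tibble::tibble(
    node_a = c("g1:liver", "g2:liver", "g4:liver"),
    node_b = c("ME", "ME", "CY"),
    r = c(0.7, 0.55, -0.3)
  )
  net_t <- make_net("TRAD", nodes, e_trad)
  net_a <- make_net("ALT", nodes, e_alt)
  out <- shared_and_unique_edges(net_t, net_a)
  expect_equal(nrow(out$shared), 2)
  expect_equal(nrow(out$unique_a), 2)
  expect_equal(nrow(out$unique_b), 1)
  # exactly one discordant shared edge, with the right class
  disc <- out$shared[out$shared$concordance != "same_sign", ]
  expect_equal(nrow(disc), 1)
  expect_identical(disc$node_a, "g2:liver")
  expect_identical(disc$concordance, "alt_pos_trad_neg")
  # set identities: shared + unique reconstruct each network
  key <- function(df) {
    sort(paste(pmin(df$node_a, df$node_b), pmax(df$node_a, df$node_b)))
  }
  expect_identical(
    sort(c(key(out$shared), key(out$unique_a))), key(net_t$edges)
  )
  expect_identical(
    sort(c(key(out$shared), key(out$unique_b))), key(net_a$edges)
  )
  # identical networks: all shared, same sign
  self <- shared_and_unique_edges(net_t, net_t)
  expect_equal(nrow(self$unique_a), 0)
  expect_true(all(self$shared$concordance == "same_sign"))
  # disjoint networks: nothing shared
  disj <- shared_and_unique_edges(
    make_net("TRAD", nodes, e_trad[1:2, ]),
    make_net("ALT", nodes, e_alt[3, ])
  )
  expect_equal(nrow(disj$shared), 0)
})
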