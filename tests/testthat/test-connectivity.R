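test_that("phenotype connection counts and totals follow the edge lists", {
  nodes <- make_nodes(
    paste0("g", 1:5),
    c("liver", "liver", "muscle", "rumen", "rumen"),
    c("ME", "CY")
  )
  net_trad <- make_net("TRAD", nodes, tibble::tibble(
    node_a = c("g1:liver", "g2:liver", "g3:muscle", "ME"),
    node_b = c("ME", "ME", "CY", "CY"),
    r = c(0.9, 0.8, -0.7, 0.5)
  ))
  net_alt <- make_net("ALT", nodes, tibble::tibble(
    node_a = c("g4:rumen", "g5:rumen", "g1:liver"),
    node_b = c("ME", "ME", "CY"),
    r = c(0.6, 0.6, 0.4)
  ))
  tab <- phenotype_connection_table(net_trad, net_alt)
  me <- tab[tab$phenotype == "ME", ]
  expect_equal(me$trad_liver, 2L)
  expect_equal(me$alt_rumen, 2L)
  expect_equal(me$total_trad, 2)
  expect_equal(me$total_alt, 2)
  expect_equal(me$change, 0)
  cy <- tab[tab$phenotype == "CY", ]
  expect_equal(cy$trad_muscle, 1L)
  expect_equal(cy$alt_liver, 1L)
  # the phenotype-phenotype edge sits in the pheno column, not the totals
  expect_equal(cy$trad_pheno, 1L)
  expect_equal(me$trad_pheno, 1L)
  expect_equal(cy$total_trad, 1)
  expect_equal(cy$change, 0)
  # empty networks give an all-zero table
  empty <- make_net("ALT", nodes, tibble::tibble(
    node_a = character(), node_b = character(), r = numeric()
  ))
  tab0 <- phenotype_connection_table(
    make_net("TRAD", nodes, tibble::tibble(
      node_a = character(), node_b = character(), r = numeric()
    )),
    empty
  )
  expect_true(all(tab0$total_alt == 0 & tab0$total_trad == 0))
})

test_that("connectivity-change arithmetic reproduces printed-style extremes", {
  # cells as printed in a phenotype-connections report: (liver, muscle,
  # rumen) per diet
  cy_alt <- c(75, 27, 16)
  cy_trad <- c(114, 132, 14)
  me_alt <- c(20, 23, 26)
  me_trad <- c(32, 24, 6)
  expect_equal(abs(sum(cy_alt) - sum(cy_trad)), 142)
  tab <- tibble::tibble(
    phenotype = c("CY", "ME", "REA"),
    total_alt = c(sum(cy_alt), sum(me_alt), 100),
    total_trad = c(sum(cy_trad), sum(me_trad), 80),
    change = abs(total_alt - total_trad)
  )
  expect_equal(tab$change[tab$phenotype == "ME"], 7)
  ranked <- rank_phenotypes_by_change(tab)
  expect_identical(ranked$phenotype[1], "CY")
  expect_identical(ranked$phenotype[nrow(ranked)], "ME")
})

test_that("rank_phenotypes_by_change breaks ties alphabetically", {
  tab <- tibble::tibble(
    phenotype = c("ME", "CY", "BW1"),
    total_alt = c(5, 5, 5), total_trad = c(2, 2, 2),
    change = c(3, 3, 3)
  )
  expect_identical(
    rank_phenotypes_by_change(tab)$phenotype, c("BW1", "CY", "ME")
  )
  single <- tab[1, ]
  expect_identical(rank_phenotypes_by_change(single)$phenotype, "ME")
  expect_error(rank_phenotypes_by_change(tab[0, ]), "empty")
})

test_that("DCG counting, the DEG constraint, and diff arithmetic hold", {
  nodes <- make_nodes(
    c("BASP1", "g2", "g3"), c("rumen", "liver", "liver"), c("ME", "CY")
  )
  # BASP1-style printed counts: 57 TRAD vs 366 ALT -> diff 309
  e_trad <- tibble::tibble(
    node_a = rep("BASP1:rumen", 57), node_b = rep("ME", 57), r = 0.5
  )
  e_alt <- tibble::tibble(
    node_a = rep("BASP1:rumen", 366), node_b = rep("ME", 366), r = 0.5
  )
  net_t <- make_net("TRAD", nodes, e_trad)
  net_a <- make_net("ALT", nodes, e_alt)
  de <- structure(
    list(
      table = tibble::tibble(
        gene = c("BASP1", "g2", "g3"),
        tissue = c("rumen", "liver", "liver"),
        mean_trad = c(3.39, 1, 1), mean_alt = c(3.40, 1, 1),
        log2fc = 0, t_stat = 0,
        p_value = c(0.001, 0.5, 0.002),
        is_deg = c(TRUE, FALSE, TRUE)
      ),
      p_threshold = 0.01
    ),
    class = "de_result"
  )
  dcg <- dcg_table(net_t, net_a, de)
  basp <- dcg[dcg$gene == "BASP1", ]
  expect_equal(basp$diff, 309L)
  expect_true(basp$is_dcg)
  # absent gene: zero connections, not a DCG
  g3 <- dcg[dcg$gene == "g3", ]
  expect_equal(g3$conn_trad + g3$conn_alt, 0L)
  expect_false(g3$is_dcg)
  # a non-DEG can never be a DCG regardless of diff
  expect_false(any(dcg$is_dcg & !dcg$is_deg))
  # diet swap leaves diff invariant
  swapped <- dcg_table(net_a, net_t, de)
  expect_equal(
    swapped$diff[match(dcg$gene, swapped$gene)], dcg$diff
  )
})

test_that("DEDC restricts DCGs to regulators with the documented columns", {
  nodes <- make_nodes(
    c("MEOX1", "g2"), c("liver", "liver"), c("ME", "CY")
  )
  e_trad <- tibble::tibble(
    node_a = rep("MEOX1:liver", 25), node_b = rep("CY", 25), r = 0.4
  )
  e_alt <- tibble::tibble(
    node_a = rep("MEOX1:liver", 100), node_b = rep("CY", 100), r = 0.4
  )
  de <- structure(
    list(
      table = tibble::tibble(
        gene = c("MEOX1", "g2"), tissue = "liver",
        mean_trad = c(-2.27, 0), mean_alt = c(-1.77, 0),
        log2fc = 0.5, t_stat = 1,
        p_value = c(0.0007, 0.9), is_deg = c(TRUE, FALSE)
      ),
      p_threshold = 0.01
    ),
    class = "de_result"
  )
  dcg <- dcg_table(
    make_net("TRAD", nodes, e_trad), make_net("ALT", nodes, e_alt), de
  )
  rif <- tibble::tibble(regulator = "MEOX1", type = "TF")
  dedc <- dedc_regulators(dcg, rif, de)
  expect_equal(nrow(dedc), 1)
  expect_equal(dedc$diff, 75L)
  expect_identical(dedc$tissue, "liver")
  expect_identical(
    names(dedc),
    c(
      "tissue", "gene", "type", "expr_trad", "expr_alt",
      "conn_trad", "conn_alt", "diff", "p_value"
    )
  )
  # no regulators among the DCGs -> empty table
  none <- dedc_regulators(dcg, tibble::tibble(
    regulator = "g2", type = "COF"
  ), de)
  expect_equal(nrow(none), 0)
})

test_that("percent diet differences follow the TRAD-baseline formula", {
  expect_equal(percent_diet_difference(8.00, 9.77), 22.1, tolerance = 0.05)
  expect_equal(percent_diet_difference(3.59, 4.72), 31.5, tolerance = 0.05)
  expect_equal(percent_diet_difference(5, 5), 0)
  expect_error(percent_diet_difference(0, 5), "positive")
})

test_that("phenotype table cells conserve the phenotype-incident edge counts", {
  sim <- simulate_counts(small_config(71))
  res <- run_pipeline(sim$dataset)
  tab <- res$phenotype_connectivity
  for (d in c("TRAD", "ALT")) {
    net <- res$networks[[d]]
    kind <- stats::setNames(net$nodes$kind, net$nodes$id)
    incid <- sum(
      (kind[net$edges$node_a] == "phenotype") +
        (kind[net$edges$node_b] == "phenotype")
    )
    cols <- grep(paste0("^", tolower(d), "_"), names(tab), value = TRUE)
    expect_equal(sum(tab[cols]), incid)
  }
})
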