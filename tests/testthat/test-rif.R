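test_that("a regulator with no wiring or abundance change scores zero", {
  withr::with_seed(41, {
    reg <- rnorm(6)
    de1 <- matrix(rnorm(12), 2, 6)
    # identical regulator vector and identical DE means across conditions
    expr1 <- rbind(R = reg, D1 = de1[1, ], D2 = de1[2, ])
    res <- suppressWarnings(rif_scores(expr1, expr1, c("D1", "D2"), "R"))
    expect_equal(res$rif1_raw, 0)
    expect_equal(res$rif2_raw, 0)
  })
})

test_that("RIF1/RIF2 match a hand-executed computation", {
  # 1 regulator, 2 DE genes, 4 samples per condition, hand-chosen values
  trad <- rbind(
    R = c(1, 2, 3, 4),
    D1 = c(2, 2.5, 3.5, 4),
    D2 = c(5, 4, 3, 2)
  )
  alt <- rbind(
    R = c(2, 2, 1, 3),
    D1 = c(6, 5, 7, 6),
    D2 = c(1, 1.5, 0.5, 1)
  )
  res <- suppressWarnings(rif_scores(trad, alt, c("D1", "D2"), "R"))

  # step-by-step arithmetic, scalar calls only
  expected <- local({
    e1 <- c(mean(trad["D1", ]), mean(trad["D2", ]))
    e2 <- c(mean(alt["D1", ]), mean(alt["D2", ]))
    a <- (e1 + e2) / 2
    d <- e1 - e2
    pif <- a * d
    r1 <- c(cor(trad["R", ], trad["D1", ]), cor(trad["R", ], trad["D2", ]))
    r2 <- c(cor(alt["R", ], alt["D1", ]), cor(alt["R", ], alt["D2", ]))
    dw <- r1 - r2
    list(
      rif1 = mean(pif * dw^2),
      rif2 = mean((e1 * r1)^2 - (e2 * r2)^2)
    )
  })
  expect_equal(res$rif1_raw, expected$rif1)
  expect_equal(res$rif2_raw, expected$rif2)
  expect_equal(res$n_de_used, 2L)
})

test_that("condition exchange negates RIF2 and flips RIF1 through PIF", {
  withr::with_seed(42, {
    genes <- c(paste0("R", 1:3), paste0("D", 1:5))
    trad <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(genes, NULL))
    alt <- matrix(rnorm(8 * 10, 0.5), 8, 10, dimnames = list(genes, NULL))
    fwd <- rif_scores(trad, alt, paste0("D", 1:5), paste0("R", 1:3))
    swp <- rif_scores(alt, trad, paste0("D", 1:5), paste0("R", 1:3))
    expect_equal(swp$rif2_raw, -fwd$rif2_raw)
    # PIF_j flips sign while DW^2 is invariant, so RIF1 negates
    expect_equal(swp$rif1_raw, -fwd$rif1_raw)
  })
})

test_that("z-scores have mean 0 and sd 1 and shift-invariant selections", {
  sim <- simulate_counts(small_config(43))
  expr <- normalize_counts(sim$dataset)
  de <- run_de(expr)
  rif <- suppressWarnings(
    run_rif(expr, de, sim$dataset$regulators, "liver")
  )
  expect_equal(mean(rif$rif1_z), 0, tolerance = 1e-8)
  expect_equal(sd(rif$rif1_z), 1, tolerance = 1e-8)
  expect_equal(mean(rif$rif2_z), 0, tolerance = 1e-8)
  expect_equal(sd(rif$rif2_z), 1, tolerance = 1e-8)

  shifted <- rif
  shifted$rif1_raw <- shifted$rif1_raw + 100
  z <- (shifted$rif1_raw - mean(shifted$rif1_raw)) / sd(shifted$rif1_raw)
  expect_equal(z, rif$rif1_z, tolerance = 1e-8)
})

test_that("a regulator that is also a DEG is excluded from its own targets", {
  withr::with_seed(44, {
    genes <- c("RA", "D1", "D2")
    trad <- matrix(rnorm(18), 3, 6, dimnames = list(genes, NULL))
    alt <- matrix(rnorm(18, 1), 3, 6, dimnames = list(genes, NULL))
    res <- suppressWarnings(
      rif_scores(trad, alt, de_genes = c("RA", "D1", "D2"), regulators = "RA")
    )
    expect_equal(res$n_de_used, 2L)
  })
})

test_that("significance selection is inclusive at the z cutoff", {
  rif <- tibble::tibble(
    regulator = c("a", "b", "c"),
    type = "TF",
    rif1_raw = c(0, 0, 0), rif2_raw = c(0, 0, 0),
    rif1_z = c(1.96, 1.9599, -2.5),
    rif2_z = c(0, 0, 0),
    significant = abs(c(1.96, 1.9599, -2.5)) >= 1.96,
    n_de_used = 2L
  )
  class(rif) <- c("rif_result", class(rif))
  sel <- select_key_regulators(rif)
  expect_identical(sel, c("c", "a")) # ordered by |z| descending
})

test_that("constant raw scores give an empty selection with a warning", {
  withr::with_seed(45, {
    genes <- c("R1", "R2", "D1", "D2")
    trad <- matrix(rnorm(24), 4, 6, dimnames = list(genes, NULL))
    # both regulators identical -> identical raw scores -> sd 0
    trad["R2", ] <- trad["R1", ]
    alt <- trad + matrix(rnorm(24, sd = 0.0), 4, 6)
    expect_warning(
      expect_warning( # one warning per z-scored metric
        res <- rif_scores(trad, alt, c("D1", "D2"), c("R1", "R2")),
        "z-scores undefined"
      ),
      "z-scores undefined"
    )
    expect_false(any(res$significant))
    expect_length(select_key_regulators(res), 0)
  })
})

test_that("rewired regulators stand out from the background", {
  sim <- simulate_counts(small_config(46))
  expr <- normalize_counts(sim$dataset)
  de <- run_de(expr)
  rw <- sim$truth$rewired_regulators
  zs <- purrr::map(unique(rw$tissue), function(t) {
    rif <- suppressWarnings(
      run_rif(expr, de, sim$dataset$regulators, t)
    )
    rw_t <- rw$regulator[rw$tissue == t]
    list(
      rewired = abs(rif$rif1_z[rif$regulator %in% rw_t]),
      background = abs(rif$rif1_z[!rif$regulator %in% rw_t])
    )
  })
  expect_gt(
    mean(unlist(purrr::map(zs, "rewired"))),
    mean(unlist(purrr::map(zs, "background")))
  )
})
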