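#' Default trait distribution used by the simulator
#'
#' Per-diet means and population standard deviations for the 14 traits,
#' emulating a 52-bull two-diet feedlot contrast (traditional corn-grain
#' versus by-product alternative diet): group means follow the adjusted
#' (least-squares) means of such a design, spreads the descriptive standard
#' deviations.
#'
#' @return Tibble with columns `phenotype`, `mean_trad`, `mean_alt`, `sd`.
#' @export
trait_distributions <- function() {
  tibble::tibble(
    phenotype = trait_codes(),
    mean_trad = c(
      1.78, 1.40, 1.56, 328.96, 451.71, 476.94,
      7.65, 8.00, 7.84, 178.86, 260.62, 54.67, 68.29, 3.59
    ),
    mean_alt = c(
      1.71, 1.59, 1.65, 322.54, 452.66, 479.43,
      6.75, 9.77, 8.24, 161.26, 266.77, 55.61, 70.67, 4.72
    ),
    sd = c(
      0.33, 0.41, 0.25, 34.60, 41.24, 39.74,
      1.99, 1.89, 1.69, 27.67, 23.52, 1.50, 7.99, 1.50
    )
  )
}

#' Default phenotype driver specifications
#'
#' Three diet-gated driven phenotypes: methane emission driven from rumen
#' expression under the alternative diet, carcass yield from muscle under the
#' traditional diet, and finishing dry matter intake from liver under the
#' alternative diet; two driver genes each, equal weights, with Gaussian
#' noise at half the latent signal's scale. The remaining 11 traits are pure
#' noise around their trait distribution.
#'
#' @return List of specs, each a list with `phenotype`, `tissue`,
#'   `gated_diet`, `n_drivers`, `weights`, `noise_sd`.
#' @export
default_phenotype_specs <- function() {
  list(
    list(
      phenotype = "ME", tissue = "rumen", gated_diet = "ALT",
      n_drivers = 2, weights = c(1, 1), noise_sd = 0.5
    ),
    list(
      phenotype = "CY", tissue = "muscle", gated_diet = "TRAD",
      n_drivers = 2, weights = c(1, 1), noise_sd = 0.5
    ),
    list(
      phenotype = "DMI_F", tissue = "liver", gated_diet = "ALT",
      n_drivers = 2, weights = c(1, 1), noise_sd = 0.5
    )
  )
}

#' Configuration for the synthetic multi-tissue count simulator
#'
#' Defaults emulate the feedlot design the pipeline targets: 52 animals split
#' 26/26 between a traditional (TRAD) and an alternative (ALT) diet, liver /
#' muscle / rumen sampled per animal with two muscle and one rumen sample
#' missing (52/50/51 samples), log-normal library sizes around 40 million
#' reads, negative-binomial counts (variance mu + phi mu^2), a configurable
#' block of differentially expressed genes per tissue, diet-gated rewired
#' regulators, and phenotypes that are noisy linear combinations of latent
#' driver-gene signals.
#'
#' @param n_animals_per_diet Animals per diet arm (default 26).
#' @param tissues Tissue labels (default liver, muscle, rumen).
#' @param missing_samples Named list mapping tissue to animal IDs whose
#'   sample of that tissue is absent. Default drops two muscle and one rumen
#'   sample.
#' @param n_genes Number of simulated genes (default 2000).
#' @param n_de_per_tissue Differentially expressed genes injected per tissue
#'   (default 100), half up- and half down-regulated under ALT.
#' @param de_log2fc_range Magnitude bounds for injected log2 fold changes
#'   (default `c(1, 2)`).
#' @param n_regulators Regulators (TFs/COFs) in the catalogue (default 100).
#' @param n_rewired_regulators Regulators given a diet-gated latent factor
#'   shared with a block of target genes (default 10).
#' @param n_targets_per_regulator Target genes per rewired regulator
#'   (default 8).
#' @param regulator_beta Loading of regulator and targets on the shared
#'   factor (default 1).
#' @param driver_beta Loading of driver genes on their phenotype latent
#'   (default 1).
#' @param phenotype_specs Driver specifications, see
#'   [default_phenotype_specs()].
#' @param nb_dispersion Negative-binomial dispersion phi (default 0.1);
#'   0 gives Poisson counts.
#' @param frac_expressed Fraction of genes drawn from the expressed
#'   baseline component (default 0.55); the rest are near-silent and are
#'   expected to fail the CPM filter, emulating the large unexpressed
#'   portion of an annotated transcriptome. DE genes, regulators and
#'   drivers are always drawn from the expressed component.
#' @param mean_log_expression,sd_log_expression Mean and spread of baseline
#'   log2 expression across expressed genes (defaults 5 and 2, latent
#'   log2 scale).
#' @param silent_log_expression Baseline log2 expression of the silent
#'   component (default -4).
#' @param tissue_effect_sd Spread of per-gene tissue offsets (default 0.5).
#' @param lib_size_mean,lib_size_cv Log-normal library-size location
#'   (default 4e7 reads) and coefficient of variation (default 0.15).
#' @param seed Integer seed fixing all randomness.
#' @return A validated `simulation_config` object (a list).
#' @export
simulation_config <- function(n_animals_per_diet = 26,
                              tissues = tissue_levels(),
                              missing_samples = NULL,
                              n_genes = 2000,
                              n_de_per_tissue = 100,
                              de_log2fc_range = c(1, 2),
                              n_regulators = 100,
                              n_rewired_regulators = 10,
                              n_targets_per_regulator = 8,
                              regulator_beta = 1,
                              driver_beta = 1,
                              phenotype_specs = default_phenotype_specs(),
                              nb_dispersion = 0.1,
                              frac_expressed = 0.55,
                              mean_log_expression = 5,
                              sd_log_expression = 2,
                              silent_log_expression = -4,
                              tissue_effect_sd = 0.5,
                              lib_size_mean = 4e7,
                              lib_size_cv = 0.15,
                              seed = 1L) {
  cfg <- as.list(environment())
  check_pos_int <- function(value, field) {
    if (length(value) != 1 || !is.finite(value) || value < 1 ||
      value != round(value)) {
      stop("invalid `", field, "`: must be a positive integer", call. = FALSE)
    }
  }
  check_pos_int(cfg$n_animals_per_diet, "n_animals_per_diet")
  check_pos_int(cfg$n_genes, "n_genes")
  for (field in c(
    "n_de_per_tissue", "n_regulators", "n_rewired_regulators",
    "n_targets_per_regulator"
  )) {
    value <- cfg[[field]]
    if (length(value) != 1 || !is.finite(value) || value < 0 ||
      value != round(value)) {
      stop("invalid `", field, "`: must be a non-negative integer",
        call. = FALSE
      )
    }
  }
  if (cfg$n_de_per_tissue > cfg$n_genes) {
    stop("invalid `n_de_per_tissue`: exceeds `n_genes`", call. = FALSE)
  }
  if (cfg$n_rewired_regulators > cfg$n_regulators) {
    stop("invalid `n_rewired_regulators`: exceeds `n_regulators`",
      call. = FALSE
    )
  }
  if (length(cfg$de_log2fc_range) != 2 ||
    any(!is.finite(cfg$de_log2fc_range)) ||
    any(cfg$de_log2fc_range < 0) || diff(cfg$de_log2fc_range) < 0) {
    stop("invalid `de_log2fc_range`: need non-decreasing magnitude bounds",
      call. = FALSE
    )
  }
  if (length(cfg$nb_dispersion) != 1 || !is.finite(cfg$nb_dispersion) ||
    cfg$nb_dispersion < 0) {
    stop("invalid `nb_dispersion`: must be a non-negative real",
      call. = FALSE
    )
  }
  if (!(cfg$frac_expressed > 0 && cfg$frac_expressed <= 1)) {
    stop("invalid `frac_expressed`: must be in (0, 1]", call. = FALSE)
  }
  if (!all(cfg$tissues %in% tissue_levels()) || length(cfg$tissues) < 1) {
    stop("invalid `tissues`", call. = FALSE)
  }
  if (is.null(cfg$missing_samples)) {
    cfg$missing_samples <- default_missing_samples(cfg)
  }
  if (!all(names(cfg$missing_samples) %in% cfg$tissues)) {
    stop("invalid `missing_samples`: unknown tissue", call. = FALSE)
  }
  for (sp in cfg$phenotype_specs) {
    if (!sp$phenotype %in% trait_codes()) {
      stop("invalid `phenotype_specs`: unknown trait ", sp$phenotype,
        call. = FALSE
      )
    }
    if (!sp$tissue %in% cfg$tissues || !sp$gated_diet %in% diet_levels()) {
      stop("invalid `phenotype_specs` for ", sp$phenotype, call. = FALSE)
    }
    if (length(sp$weights) != sp$n_drivers || any(!is.finite(sp$weights))) {
      stop("invalid `phenotype_specs` weights for ", sp$phenotype,
        call. = FALSE
      )
    }
    if (!is.finite(sp$noise_sd) || sp$noise_sd < 0) {
      stop("invalid `phenotype_specs` noise_sd for ", sp$phenotype,
        call. = FALSE
      )
    }
  }
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    stop("invalid `seed`", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "simulation_config")
}

# Two muscle samples (one per diet) and one rumen sample absent, echoing a
# 52/50/51 sample layout.
default_missing_samples <- function(cfg) {
  n <- 2 * cfg$n_animals_per_diet
  ids <- animal_ids(n)
  out <- list()
  if ("muscle" %in% cfg$tissues && n >= 2) {
    out$muscle <- c(ids[min(5, n)], ids[min(cfg$n_animals_per_diet + 5, n)])
  }
  if ("rumen" %in% cfg$tissues && n >= 1) {
    out$rumen <- ids[min(cfg$n_animals_per_diet + 14, n)]
  }
  out
}

animal_ids <- function(n) sprintf("A%02d", seq_len(n))

#' Simulate a multi-tissue count dataset with known ground truth
#'
#' Draws negative-binomial counts from a latent log2-expression model:
#' per-gene baselines plus per-tissue offsets, diet effects for injected DE
#' genes (shifted in the ALT arm only), diet-gated shared latent factors
#' linking each rewired regulator to a block of same-direction DE targets,
#' and, per driven phenotype, one diet-gated latent signal on which the
#' phenotype's driver genes load with their configured weights (a
#' co-regulated driver block). Phenotypes are the latent signal plus
#' Gaussian noise, placed on each trait's natural scale. All randomness is governed by
#' `config$seed`; the same seed reproduces the output exactly.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (a [count_dataset()]) and `truth` (a
#'   `ground_truth` list with `de_genes`, `rewired_regulators`,
#'   `phenotype_drivers`).
#' @export
simulate_counts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(cfg) {
  n_animals <- 2L * cfg$n_animals_per_diet
  animals <- animal_ids(n_animals)
  diets <- rep(diet_levels(), each = cfg$n_animals_per_diet)
  names(diets) <- animals
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  # Baseline architecture: expressed/silent mixture
  expressed <- stats::runif(cfg$n_genes) < cfg$frac_expressed
  if (sum(expressed) < cfg$n_de_per_tissue) {
    stop("too few expressed genes to place the requested DE genes",
      call. = FALSE
    )
  }
  base <- ifelse(
    expressed,
    stats::rnorm(cfg$n_genes, cfg$mean_log_expression, cfg$sd_log_expression),
    stats::rnorm(cfg$n_genes, cfg$silent_log_expression, 1)
  )
  toff <- matrix(
    stats::rnorm(cfg$n_genes * length(cfg$tissues), 0, cfg$tissue_effect_sd),
    nrow = cfg$n_genes,
    dimnames = list(genes, cfg$tissues)
  )

  # Injected DE genes per tissue: half up-, half down-regulated under ALT
  de_genes <- purrr::map(cfg$tissues, function(t) {
    if (cfg$n_de_per_tissue == 0) {
      return(tibble::tibble(
        gene = character(), tissue = character(), log2fc = numeric()
      ))
    }
    g <- sample(genes[expressed], cfg$n_de_per_tissue)
    n_up <- ceiling(cfg$n_de_per_tissue / 2)
    sign <- c(rep(1, n_up), rep(-1, cfg$n_de_per_tissue - n_up))
    mag <- stats::runif(
      cfg$n_de_per_tissue, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2]
    )
    tibble::tibble(gene = g, tissue = t, log2fc = sign * mag)
  }) |>
    purrr::list_rbind()

  up_pool <- split(
    de_genes$gene[de_genes$log2fc > 0], de_genes$tissue[de_genes$log2fc > 0]
  )
  down_pool <- split(
    de_genes$gene[de_genes$log2fc < 0], de_genes$tissue[de_genes$log2fc < 0]
  )
  free_pool <- setdiff(genes[expressed], de_genes$gene)
  take <- function(pool_tissue, k) {
    # prefer up-regulated DE genes of the tissue, fall back to unused genes
    pool <- up_pool[[pool_tissue]]
    if (is.null(pool) || length(pool) < k) {
      picked <- free_pool[seq_len(k)]
      free_pool <<- setdiff(free_pool, picked)
      return(picked)
    }
    picked <- pool[seq_len(k)]
    up_pool[[pool_tissue]] <<- setdiff(pool, picked)
    picked
  }

  # Rewired regulators: a diet-gated factor shared with a target block
  rewired <- NULL
  if (cfg$n_rewired_regulators > 0) {
    rew_tissue <- rep_len(cfg$tissues, cfg$n_rewired_regulators)
    rew_diet <- rep_len(diet_levels(), cfg$n_rewired_regulators)
    rew_gene <- character(cfg$n_rewired_regulators)
    rew_targets <- vector("list", cfg$n_rewired_regulators)
    for (i in seq_len(cfg$n_rewired_regulators)) {
      rew_gene[i] <- take(rew_tissue[i], 1)
      rew_targets[[i]] <- take(rew_tissue[i], cfg$n_targets_per_regulator)
    }
    rewired <- tibble::tibble(
      regulator = rew_gene, tissue = rew_tissue, gated_diet = rew_diet,
      targets = rew_targets
    )
  }

  # Phenotype drivers, preferentially down-regulated DE genes of the tissue
  drivers <- purrr::map(cfg$phenotype_specs, function(sp) {
    pool <- down_pool[[sp$tissue]]
    if (is.null(pool) || length(pool) < sp$n_drivers) {
      g <- free_pool[seq_len(sp$n_drivers)]
      free_pool <<- setdiff(free_pool, g)
    } else {
      g <- pool[seq_len(sp$n_drivers)]
      down_pool[[sp$tissue]] <<- setdiff(pool, g)
    }
    tibble::tibble(
      phenotype = sp$phenotype, gene = g, tissue = sp$tissue,
      gated_diet = sp$gated_diet, weight = sp$weights,
      noise_sd = sp$noise_sd
    )
  }) |>
    purrr::list_rbind()
  if (is.null(drivers)) {
    drivers <- tibble::tibble(
      phenotype = character(), gene = character(), tissue = character(),
      gated_diet = character(), weight = numeric(), noise_sd = numeric()
    )
  }

  # Latent per-animal signals
  reg_factor <- if (!is.null(rewired) && nrow(rewired) > 0) {
    matrix(stats::rnorm(nrow(rewired) * n_animals), nrow(rewired), n_animals,
      dimnames = list(rewired$regulator, animals)
    )
  }
  # one latent signal per driven phenotype; its drivers form a co-regulated
  # block loading on it
  driven_traits <- unique(drivers$phenotype)
  driver_latent <- if (length(driven_traits) > 0) {
    matrix(
      stats::rnorm(length(driven_traits) * n_animals),
      length(driven_traits), n_animals,
      dimnames = list(driven_traits, animals)
    )
  }

  # Sample table and library sizes
  samples <- purrr::map(cfg$tissues, function(t) {
    keep <- setdiff(animals, cfg$missing_samples[[t]])
    tibble::tibble(
      sample_id = paste(keep, t, sep = "_"),
      animal_id = keep, tissue = t, diet = unname(diets[keep])
    )
  }) |>
    purrr::list_rbind()
  lib_sizes <- stats::rlnorm(
    nrow(samples), log(cfg$lib_size_mean), cfg$lib_size_cv
  )
  names(lib_sizes) <- samples$sample_id

  # Latent log2 expression per tissue, then NB counts
  counts <- matrix(0L, cfg$n_genes, nrow(samples),
    dimnames = list(genes, samples$sample_id)
  )
  for (t in cfg$tissues) {
    sub <- samples[samples$tissue == t, ]
    x <- matrix(base + toff[, t], cfg$n_genes, nrow(sub),
      dimnames = list(genes, sub$sample_id)
    )
    de_t <- de_genes[de_genes$tissue == t, ]
    alt_cols <- sub$diet == "ALT"
    if (nrow(de_t) > 0 && any(alt_cols)) {
      x[de_t$gene, alt_cols] <- x[de_t$gene, alt_cols] + de_t$log2fc
    }
    if (!is.null(rewired)) {
      for (i in which(rewired$tissue == t)) {
        gated_cols <- sub$diet == rewired$gated_diet[i]
        if (!any(gated_cols)) next
        f <- reg_factor[i, sub$animal_id[gated_cols]]
        members <- c(rewired$regulator[i], rewired$targets[[i]])
        x[members, gated_cols] <- x[members, gated_cols] +
          cfg$regulator_beta * rep(f, each = length(members))
      }
    }
    if (nrow(drivers) > 0) {
      for (i in which(drivers$tissue == t)) {
        gated_cols <- sub$diet == drivers$gated_diet[i]
        if (!any(gated_cols)) next
        z <- driver_latent[drivers$phenotype[i], sub$animal_id[gated_cols]]
        x[drivers$gene[i], gated_cols] <- x[drivers$gene[i], gated_cols] +
          cfg$driver_beta * drivers$weight[i] * z
      }
    }
    mu <- 2^x * rep(lib_sizes[sub$sample_id] / 1e6, each = cfg$n_genes)
    drawn <- if (cfg$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    counts[, sub$sample_id] <- matrix(drawn, cfg$n_genes, nrow(sub))
  }
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"

  # Phenotypes: trait-scale mean per diet + sd * (latent combination + noise)
  dist <- trait_distributions()
  phen <- tibble::tibble(animal_id = animals, diet = unname(diets))
  for (k in seq_len(nrow(dist))) {
    trait <- dist$phenotype[k]
    mu <- ifelse(phen$diet == "TRAD", dist$mean_trad[k], dist$mean_alt[k])
    rows <- which(drivers$phenotype == trait)
    if (length(rows) > 0) {
      u <- driver_latent[trait, ]
      noise_sd <- drivers$noise_sd[rows[1]]
      e <- stats::rnorm(n_animals)
      std <- (u + noise_sd * e) / sqrt(1 + noise_sd^2)
    } else {
      std <- stats::rnorm(n_animals)
    }
    phen[[trait]] <- mu + dist$sd[k] * std
  }
  phen$diet <- NULL

  # Regulator catalogue: rewired ones first, background from non-DE genes
  reg_ids <- character(0)
  if (!is.null(rewired)) reg_ids <- rewired$regulator
  n_bg <- cfg$n_regulators - length(reg_ids)
  if (n_bg > 0) {
    bg <- free_pool[seq_len(min(n_bg, length(free_pool)))]
    reg_ids <- c(reg_ids, bg)
  }
  regulators <- tibble::tibble(
    regulator = reg_ids,
    type = ifelse(seq_along(reg_ids) %% 3 == 0, "COF", "TF")
  )

  dataset <- count_dataset(counts, samples, phen, regulators)
  truth <- structure(
    list(
      de_genes = de_genes,
      rewired_regulators = rewired %||% tibble::tibble(
        regulator = character(), tissue = character(),
        gated_diet = character(), targets = list()
      ),
      phenotype_drivers = drivers,
      seed = cfg$seed
    ),
    class = "ground_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(
    "simulation_config:", 2 * x$n_animals_per_diet, "animals,",
    length(x$tissues), "tissues,", x$n_genes, "genes,",
    x$n_de_per_tissue, "DE/tissue,", x$n_rewired_regulators,
    "rewired regulators, seed", x$seed, "\n"
  )
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(
    "ground_truth:", nrow(x$de_genes), "DE gene injections,",
    nrow(x$rewired_regulators), "rewired regulators,",
    nrow(x$phenotype_drivers), "phenotype drivers\n"
  )
  invisible(x)
}
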