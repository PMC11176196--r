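#' Regulatory impact factor scores (RIF1 and RIF2)
#'
#' Scores each candidate regulator for differential regulatory impact
#' between two conditions against a set of differentially expressed target
#' genes. For DE gene j, with `e1_j`, `e2_j` its mean log2-CPM in condition 1
#' (TRAD) and condition 2 (ALT), `a_j = (e1_j + e2_j) / 2`,
#' `d_j = e1_j - e2_j` and phenotype impact factor `PIF_j = a_j * d_j`. With
#' `r1_ij`, `r2_ij` the regulator-target Pearson correlations within each
#' condition and differential wiring `DW_ij = r1_ij - r2_ij`:
#' \deqn{RIF1_i = \frac{1}{n_{de}} \sum_j PIF_j \, DW_{ij}^2}
#' \deqn{RIF2_i = \frac{1}{n_{de}} \sum_j (e1_j r1_{ij})^2 - (e2_j r2_{ij})^2}
#' Raw scores are z-scored across regulators (separately per metric) and a
#' regulator is significant when either |z| reaches `z_cut`.
#'
#' A regulator that is itself a DE gene is excluded from its own target sum.
#' A regulator with zero variance in either condition gets all its
#' correlations in that condition set to 0, with a warning.
#'
#' @param expr_trad,expr_alt Log2-CPM matrices, genes x samples, for the
#'   TRAD and ALT condition respectively (same genes; >= 3 samples each).
#' @param de_genes Character vector of DE target gene IDs (rows of the
#'   matrices).
#' @param regulators Character vector of regulator gene IDs, or a data frame
#'   with columns `regulator` and `type`.
#' @param z_cut Significance cutoff on |z| (default 1.96, inclusive).
#' @return A `rif_result` tibble: `regulator`, `type`, `rif1_raw`,
#'   `rif2_raw`, `rif1_z`, `rif2_z`, `significant`, `n_de_used`.
#' @export
rif_scores <- function(expr_trad, expr_alt, de_genes, regulators,
                       z_cut = 1.96) {
  reg_type <- NULL
  if (is.data.frame(regulators)) {
    reg_type <- regulators$type
    regulators <- regulators$regulator
  }
  expr_trad <- as.matrix(expr_trad)
  expr_alt <- as.matrix(expr_alt)
  if (ncol(expr_trad) < 3 || ncol(expr_alt) < 3) {
    stop("each condition needs at least 3 samples", call. = FALSE)
  }
  if (!all(de_genes %in% rownames(expr_trad)) ||
    !all(regulators %in% rownames(expr_trad))) {
    stop("de_genes and regulators must be rows of the expression matrices",
      call. = FALSE
    )
  }
  if (length(de_genes) == 0) {
    stop("no DE target genes supplied (n_de = 0)", call. = FALSE)
  }

  e1 <- rowMeans(expr_trad[de_genes, , drop = FALSE])
  e2 <- rowMeans(expr_alt[de_genes, , drop = FALSE])
  a <- (e1 + e2) / 2
  d <- e1 - e2
  pif <- a * d

  cor_cond <- function(expr) {
    x <- t(expr[regulators, , drop = FALSE])
    y <- t(expr[de_genes, , drop = FALSE])
    zero_var <- apply(x, 2, stats::sd) == 0
    suppressWarnings(r <- stats::cor(x, y))
    if (any(zero_var)) {
      warning(
        "zero-variance regulator(s): correlations set to 0: ",
        paste(regulators[zero_var], collapse = ", "),
        call. = FALSE
      )
    }
    r[!is.finite(r)] <- 0
    r
  }
  r1 <- cor_cond(expr_trad)
  r2 <- cor_cond(expr_alt)
  dw <- r1 - r2

  # exclude a regulator's own row from its target sum
  use <- matrix(TRUE, length(regulators), length(de_genes),
    dimnames = list(regulators, de_genes)
  )
  self <- intersect(regulators, de_genes)
  for (g in self) use[g, g] <- FALSE
  n_used <- rowSums(use)
  if (any(n_used == 0)) {
    stop("a regulator has no usable DE targets (n_de = 0)", call. = FALSE)
  }

  rif1 <- rowSums(use * dw^2 * rep(pif, each = length(regulators))) / n_used
  term2 <- sweep(r1^2, 2, e1^2, "*") - sweep(r2^2, 2, e2^2, "*")
  rif2 <- rowSums(use * term2) / n_used

  zscore <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("constant raw RIF scores: z-scores undefined", call. = FALSE)
      return(rep(NA_real_, length(v)))
    }
    (v - mean(v)) / s
  }
  z1 <- zscore(rif1)
  z2 <- zscore(rif2)
  sig <- (abs(z1) >= z_cut) | (abs(z2) >= z_cut)
  sig[is.na(sig)] <- FALSE

  out <- tibble::tibble(
    regulator = regulators,
    type = if (is.null(reg_type)) NA_character_ else reg_type,
    rif1_raw = unname(rif1),
    rif2_raw = unname(rif2),
    rif1_z = unname(z1),
    rif2_z = unname(z2),
    significant = unname(sig),
    n_de_used = unname(n_used)
  )
  class(out) <- c("rif_result", class(out))
  out
}

#' Run RIF scoring for a tissue from pipeline objects
#'
#' Splits the tissue's log2-CPM samples by diet, takes the tissue's DEGs from
#' a [run_de()] result as targets and the catalogued TFs/COFs present in the
#' expression matrix as the scored set, and calls [rif_scores()].
#'
#' @param expr An `expression_matrix`.
#' @param de A `de_result`.
#' @param regulators Data frame with `regulator` and `type` columns.
#' @param tissue Tissue label.
#' @param z_cut Significance cutoff (default 1.96).
#' @return A `rif_result` tibble with a `tissue` column.
#' @export
run_rif <- function(expr, de, regulators, tissue, z_cut = 1.96) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(de, "de_result"))
  meta <- expr$samples[expr$samples$tissue == tissue, ]
  if (nrow(meta) == 0) stop("tissue absent: ", tissue, call. = FALSE)
  trad <- expr$values[, meta$sample_id[meta$diet == "TRAD"], drop = FALSE]
  alt <- expr$values[, meta$sample_id[meta$diet == "ALT"], drop = FALSE]
  degs <- de$table$gene[de$table$tissue == tissue & de$table$is_deg]
  regs <- regulators[regulators$regulator %in% rownames(expr$values), ]
  res <- rif_scores(trad, alt, degs, regs, z_cut = z_cut)
  res$tissue <- tissue
  res
}

#' Select significant key regulators
#'
#' Regulators flagged significant by [rif_scores()], ordered by the larger
#' of |RIF1 z| and |RIF2 z| (descending), ties broken by regulator ID.
#'
#' @param rif A `rif_result` tibble.
#' @return Character vector of regulator IDs.
#' @export
select_key_regulators <- function(rif) {
  if (nrow(rif) == 0) stop("empty RIF result", call. = FALSE)
  sel <- rif |>
    dplyr::filter(.data$significant) |>
    dplyr::mutate(
      max_z = pmax(abs(.data$rif1_z), abs(.data$rif2_z), na.rm = TRUE)
    ) |>
    dplyr::arrange(dplyr::desc(.data$max_z), .data$regulator)
  sel$regulator
}

#' Tidy a RIF result
#'
#' @param x A `rif_result`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.rif_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rif_result")
  out
}

#' One-row summary of a RIF result
#'
#' @param x A `rif_result`.
#' @param ... Unused.
#' @return Tibble with regulator counts and the significant fraction.
#' @export
glance.rif_result <- function(x, ...) {
  tibble::tibble(
    n_regulators = nrow(x),
    n_significant = sum(x$significant),
    prop_significant = mean(x$significant)
  )
}
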