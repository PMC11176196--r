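#' Equal-variance two-sample t-test
#'
#' Student's t with pooled variance and `n_a + n_b - 2` degrees of freedom,
#' two-sided p-value. Zero pooled variance is flagged and reported as
#' `t = 0, p = 1` rather than an error, so constant genes fall through a
#' screen harmlessly.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @param welch Use Welch's unequal-variance form instead of the pooled
#'   (Student) form (default `FALSE`).
#' @return List with `t`, `p`, `df` and `zero_variance`.
#' @export
student_t <- function(group_a, group_b, welch = FALSE) {
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  v_a <- stats::var(group_a)
  v_b <- stats::var(group_b)
  if (welch) {
    se2 <- v_a / n_a + v_b / n_b
    if (!is.finite(se2) || se2 <= 0) {
      return(list(t = 0, p = 1, df = n_a + n_b - 2, zero_variance = TRUE))
    }
    df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
    t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
    return(list(
      t = t, p = 2 * stats::pt(-abs(t), df), df = df, zero_variance = FALSE
    ))
  }
  df <- n_a + n_b - 2
  pooled <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / df
  if (!is.finite(pooled) || pooled <= 0) {
    return(list(t = 0, p = 1, df = df, zero_variance = TRUE))
  }
  t <- (mean(group_a) - mean(group_b)) / sqrt(pooled * (1 / n_a + 1 / n_b))
  list(
    t = t, p = 2 * stats::pt(-abs(t), df), df = df, zero_variance = FALSE
  )
}

# Row-wise t-test of two genes-x-samples matrices (same genes).
row_student_t <- function(mat_a, mat_b, welch = FALSE) {
  n_a <- ncol(mat_a)
  n_b <- ncol(mat_b)
  mean_a <- rowMeans(mat_a)
  mean_b <- rowMeans(mat_b)
  ss_a <- rowSums((mat_a - mean_a)^2)
  ss_b <- rowSums((mat_b - mean_b)^2)
  if (welch) {
    va <- ss_a / (n_a - 1)
    vb <- ss_b / (n_b - 1)
    se2 <- va / n_a + vb / n_b
    df <- se2^2 / ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
    t <- ifelse(se2 > 0, (mean_a - mean_b) / sqrt(se2), 0)
    p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1)
    return(list(mean_a = mean_a, mean_b = mean_b, t = t, p = p))
  }
  df <- n_a + n_b - 2
  pooled <- (ss_a + ss_b) / df
  se <- sqrt(pooled * (1 / n_a + 1 / n_b))
  t <- ifelse(pooled > 0, (mean_a - mean_b) / se, 0)
  p <- ifelse(pooled > 0, 2 * stats::pt(-abs(t), df), 1)
  list(mean_a = mean_a, mean_b = mean_b, t = t, p = p)
}

#' Analytic false discovery rate at a p-value threshold
#'
#' `FDR = P (1 - N_DE / T) / ((N_DE / T) (1 - P))`, where `P` is the tested
#' p-value threshold, `N_DE` the number of genes significant at that
#' threshold, and `T` the total number of genes tested; the result is clipped
#' to `[0, 1]`. With `n_de = 0` the rate is not estimable and `NA` is
#' returned with a warning.
#'
#' @param p P-value threshold, in `(0, 1)`.
#' @param n_de Number of significant genes at `p` (vectorized with `p`).
#' @param t_total Total number of genes tested.
#' @return FDR value(s) in `[0, 1]`, proportion scale.
#' @examples
#' analytic_fdr(0.01, 487, 14776) # ~0.296
#' @export
analytic_fdr <- function(p, n_de, t_total) {
  if (any(p <= 0 | p >= 1)) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(n_de > t_total)) {
    stop("`n_de` cannot exceed `t_total`", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  est <- n_de > 0
  if (any(!est)) {
    warning("FDR not estimable where n_de = 0", call. = FALSE)
  }
  frac <- n_de[est] / t_total
  out[est] <- pmin(1, pmax(0, (p[est] * (1 - frac)) / (frac * (1 - p[est]))))
  out
}

#' Default p-value thresholds for the FDR table
#'
#' @return Numeric vector of eight decreasing thresholds.
#' @export
fdr_table_thresholds <- function() {
  c(0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001, 0.00005, 0.00001)
}

#' Per-tissue two-group differential expression
#'
#' For every retained gene in the requested tissue(s), computes the group
#' mean log2-CPM under each diet, the log2 fold change (oriented ALT - TRAD
#' by default, so positive = higher under the alternative diet), the pooled
#' two-sample t statistic and two-sided p-value, and flags genes below the
#' p-value threshold as differentially expressed. A threshold-to-FDR table
#' over `thresholds` is attached per tissue using [analytic_fdr()].
#'
#' @param expr An `expression_matrix` from [normalize_counts()].
#' @param tissue Tissue label(s) to test; default all tissues present.
#' @param p_threshold DEG p-value cutoff (default 0.01).
#' @param thresholds Thresholds for the FDR table
#'   (default [fdr_table_thresholds()]).
#' @param orientation `"alt_minus_trad"` (default) or `"trad_minus_alt"`.
#' @param welch Use Welch's unequal-variance t instead of the pooled form
#'   (default `FALSE`).
#' @return A `de_result` object: list with `table` (tibble gene / tissue /
#'   mean_trad / mean_alt / log2fc / t_stat / p_value / is_deg), `fdr_table`
#'   (tibble tissue / p_threshold / n_de / fdr), `p_threshold`, `orientation`,
#'   `n_genes_tested`.
#' @export
run_de <- function(expr, tissue = NULL, p_threshold = 0.01,
                   thresholds = fdr_table_thresholds(),
                   orientation = c("alt_minus_trad", "trad_minus_alt"),
                   welch = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  orientation <- match.arg(orientation)
  tissues_present <- unique(expr$samples$tissue)
  if (is.null(tissue)) tissue <- tissues_present
  missing_t <- setdiff(tissue, tissues_present)
  if (length(missing_t) > 0) {
    stop("tissue absent from the dataset: ",
      paste(missing_t, collapse = ", "),
      call. = FALSE
    )
  }
  per_tissue <- purrr::map(tissue, function(t) {
    meta <- expr$samples[expr$samples$tissue == t, ]
    trad <- meta$sample_id[meta$diet == "TRAD"]
    alt <- meta$sample_id[meta$diet == "ALT"]
    if (length(trad) < 2 || length(alt) < 2) {
      stop("both diets need >= 2 samples in tissue ", t, call. = FALSE)
    }
    tt <- row_student_t(
      expr$values[, trad, drop = FALSE],
      expr$values[, alt, drop = FALSE],
      welch = welch
    )
    lfc <- tt$mean_b - tt$mean_a
    if (orientation == "trad_minus_alt") lfc <- -lfc
    tab <- tibble::tibble(
      gene = rownames(expr$values),
      tissue = t,
      mean_trad = unname(tt$mean_a),
      mean_alt = unname(tt$mean_b),
      log2fc = unname(lfc),
      t_stat = unname(tt$t),
      p_value = unname(tt$p),
      is_deg = unname(tt$p < p_threshold)
    )
    n_de <- vapply(thresholds, function(th) sum(tab$p_value < th), integer(1))
    fdr <- suppressWarnings(
      analytic_fdr(thresholds, n_de, nrow(tab))
    )
    list(
      table = tab,
      fdr_table = tibble::tibble(
        tissue = t, p_threshold = thresholds, n_de = n_de, fdr = fdr
      )
    )
  })
  structure(
    list(
      table = purrr::list_rbind(purrr::map(per_tissue, "table")),
      fdr_table = purrr::list_rbind(purrr::map(per_tissue, "fdr_table")),
      p_threshold = p_threshold,
      orientation = orientation,
      n_genes_tested = nrow(expr$values)
    ),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  counts <- dplyr::count(dplyr::filter(x$table, .data$is_deg), .data$tissue)
  cat(
    "de_result:", x$n_genes_tested, "genes tested per tissue; DEGs at P <",
    x$p_threshold, "(log2FC", x$orientation, "):\n"
  )
  print(as.data.frame(counts), row.names = FALSE)
  invisible(x)
}

#' Tidy a differential-expression result
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return The per-(gene, tissue) results tibble.
#' @export
tidy.de_result <- function(x, ...) x$table

#' One-row-per-tissue summary of a differential-expression result
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return Tibble with DEG counts and the analytic FDR at the configured
#'   threshold.
#' @export
glance.de_result <- function(x, ...) {
  x$table |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_deg = sum(.data$is_deg),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_threshold = x$p_threshold,
      fdr = suppressWarnings(
        analytic_fdr(
          rep(x$p_threshold, dplyr::n()), .data$n_deg, .data$n_genes
        )
      )
    )
}
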