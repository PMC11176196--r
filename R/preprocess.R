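#' Counts per million
#'
#' Library-size-scaled expression: `count / lib_size * 1e6`. In log mode the
#' values are `log2(CPM + prior)` where the prior count is scaled by relative
#' library size before the log, the convention of the edgeR toolchain this
#' wraps.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @param lib_sizes Per-sample library sizes; defaults to column sums. These
#'   may be effective sizes (raw size x TMM factor).
#' @param log Return log2 values?
#' @param prior_count Prior count added (library-size scaled) before the log;
#'   only used when `log = TRUE`.
#' @return Numeric matrix of (log2-)CPM values with the input dimnames.
#' @export
compute_cpm <- function(counts, lib_sizes = colSums(counts), log = FALSE,
                        prior_count = 2) {
  counts <- as.matrix(counts)
  if (length(lib_sizes) != ncol(counts)) {
    stop("`lib_sizes` must have one entry per sample", call. = FALSE)
  }
  bad <- which(!(lib_sizes > 0))
  if (length(bad) > 0) {
    nm <- colnames(counts)[bad[1]]
    if (is.null(nm)) nm <- paste0("sample ", bad[1])
    stop("non-positive library size for ", nm, call. = FALSE)
  }
  edgeR::cpm(counts, lib.size = lib_sizes, log = log, prior.count = prior_count)
}

#' Expression filter on CPM
#'
#' Retains a gene when its CPM is at least `min_cpm` in at least
#' `ceiling(min_fraction * n_samples)` samples, evaluated jointly across all
#' samples (all tissues together). The boundary is inclusive: a gene at
#' exactly 1 CPM in exactly half of the samples is retained.
#'
#' @param cpm CPM matrix (not logged), genes x samples, with gene rownames.
#' @param min_cpm Minimum CPM (default 1).
#' @param min_fraction Minimum fraction of samples meeting `min_cpm`,
#'   in `(0, 1]` (default 0.5).
#' @return Character vector of retained gene IDs, in input order.
#' @export
filter_low_expression <- function(cpm, min_cpm = 1, min_fraction = 0.5) {
  cpm <- as.matrix(cpm)
  if (nrow(cpm) == 0 || ncol(cpm) == 0) {
    stop("empty CPM matrix", call. = FALSE)
  }
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop("`min_fraction` must be in (0, 1]", call. = FALSE)
  }
  need <- ceiling(min_fraction * ncol(cpm))
  ok <- rowSums(cpm >= min_cpm) >= need
  genes <- rownames(cpm)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(cpm)))
  genes[ok]
}

#' Trimmed mean of M-values normalization factors
#'
#' TMM scaling factors relative to a reference sample (the sample whose
#' upper-quartile CPM is closest to the mean upper quartile, ties to the
#' lowest index). Gene-wise log-ratios (M) and mean log abundances (A) over
#' genes positive in both samples are doubly trimmed by `trim_m` and
#' `trim_a`, and the factor is 2 to the precision-weighted mean of the
#' surviving M values. Factors are rescaled to geometric mean 1.
#'
#' Computed through `edgeR::calcNormFactors(method = "TMM")`; a sample with
#' no usable genes falls back to factor 1 with a warning.
#'
#' @param counts Count matrix, genes x samples (at least 2 samples, each with
#'   a positive total).
#' @param lib_sizes Library sizes; defaults to column sums.
#' @param trim_m Two-sided trim fraction on M values (default 0.30).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts), trim_m = 0.30,
                        trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) {
    stop("TMM needs at least 2 samples", call. = FALSE)
  }
  if (any(!(colSums(counts) > 0))) {
    stop("every sample needs a positive count total", call. = FALSE)
  }
  f <- edgeR::calcNormFactors(
    counts,
    lib.size = lib_sizes, method = "TMM",
    logratioTrim = trim_m, sumTrim = trim_a
  )
  if (any(!is.finite(f))) {
    warning("no usable genes for some samples; factor set to 1", call. = FALSE)
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  names(f) <- colnames(counts)
  f
}

#' Filter and TMM-normalize a count dataset
#'
#' The preprocessing pipeline applied jointly across all tissues: raw-library
#' CPM, expression filter (`min_cpm` in at least `min_fraction` of samples),
#' TMM factors on the filtered counts, then log2-CPM using effective library
#' sizes (raw size x TMM factor).
#'
#' @param dataset A `count_dataset` (see [count_dataset()]).
#' @param min_cpm,min_fraction Expression filter parameters (defaults 1, 0.5).
#' @param prior_count Prior count for the log transform (default 2).
#' @return An `expression_matrix` object: list with `values` (log2-CPM,
#'   retained genes x samples), `lib_sizes`, `tmm_factors`, `retained_genes`,
#'   and the sample metadata tibble `samples`.
#' @export
normalize_counts <- function(dataset, min_cpm = 1, min_fraction = 0.5,
                             prior_count = 2) {
  stopifnot(inherits(dataset, "count_dataset"))
  counts <- dataset$counts
  lib_sizes <- colSums(counts)
  cpm_raw <- compute_cpm(counts, lib_sizes)
  retained <- filter_low_expression(cpm_raw, min_cpm, min_fraction)
  if (length(retained) == 0) {
    stop("no genes retained by the expression filter", call. = FALSE)
  }
  filtered <- counts[retained, , drop = FALSE]
  f <- tmm_factors(filtered, lib_sizes = lib_sizes)
  eff <- lib_sizes * f
  values <- compute_cpm(filtered, eff, log = TRUE, prior_count = prior_count)
  structure(
    list(
      values = values,
      lib_sizes = lib_sizes,
      tmm_factors = f,
      retained_genes = retained,
      samples = dataset$samples
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(
    "expression_matrix:", length(x$retained_genes), "retained genes x",
    ncol(x$values), "samples (log2-CPM, TMM-normalized)\n"
  )
  invisible(x)
}

#' Tidy an expression matrix into long form
#'
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `sample_id`, `log2cpm` joined with the
#'   sample metadata (`animal_id`, `tissue`, `diet`).
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "log2cpm") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' One-row summary of an expression matrix
#'
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return Tibble with retained-gene and sample counts and the library-size
#'   range.
#' @export
glance.expression_matrix <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$retained_genes),
    n_samples = ncol(x$values),
    min_lib_size = min(x$lib_sizes),
    max_lib_size = max(x$lib_sizes)
  )
}
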