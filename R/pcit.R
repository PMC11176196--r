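#' First-order partial correlation
#'
#' Correlation between two variables after removing the linear effect of a
#' third: `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`.
#'
#' When the denominator falls below `guard` the trio is degenerate (one of
#' the conditioning correlations is essentially +/-1) and `NA` is returned;
#' degenerate trios provide no edge-elimination evidence in [pcit_adjacency()].
#'
#' @param r_xy,r_xz,r_yz Pairwise Pearson correlations, each in `[-1, 1]`.
#' @param guard Positive tolerance below which the denominator is treated as
#'   degenerate.
#' @return The partial correlation of x and y given z, or `NA` for a
#'   degenerate trio.
#' @examples
#' partial_correlation(0.8, 0.5, 0.5) # (0.8 - 0.25) / 0.75
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz, guard = 1e-12) {
  stopifnot(length(r_xy) == 1, length(r_xz) == 1, length(r_yz) == 1)
  vals <- c(r_xy, r_xz, r_yz)
  if (any(!is.finite(vals)) || any(abs(vals) > 1)) {
    stop("correlations must be finite and in [-1, 1]", call. = FALSE)
  }
  denom <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (denom < guard) {
    return(NA_real_)
  }
  (r_xy - r_xz * r_yz) / denom
}

#' PCIT significance decision for all pairwise correlations
#'
#' Implements the partial correlation and information theory (PCIT)
#' algorithm: for every trio of variables the three first-order partial
#' correlations are computed and averaged into a data-driven tolerance
#' `eps = mean(partial / direct)`; the pair (x, y) is eliminated when, for at
#' least one third variable z, `|r_xy| < |eps * r_xz|` and
#' `|r_xy| < |eps * r_yz|`. Pairs never eliminated by any trio are kept.
#' With only two variables the single pair is kept (no trio evidence).
#'
#' Pairs whose correlation was computed on fewer than `min_overlap`
#' observations (per `n_obs`) are marked unavailable: they are never kept and
#' never contribute trio evidence.
#'
#' @param r Square symmetric correlation matrix with unit diagonal; row and
#'   column names label the variables.
#' @param n_obs Optional matrix of pairwise observation counts matching `r`.
#' @param min_overlap Minimum pairwise observation count for a correlation to
#'   be usable (default 10).
#' @param guard Degeneracy guard forwarded to the trio computations.
#' @return An object of class `pcit_adjacency`: list with `keep` (symmetric
#'   logical matrix, diagonal `FALSE`) and `r_kept` (matrix of signed weights,
#'   0 where not kept). Use [tidy.pcit_adjacency()] for a sparse edge table.
#' @seealso [partial_correlation()]
#' @export
pcit_adjacency <- function(r, n_obs = NULL, min_overlap = 10, guard = 1e-12) {
  r <- as.matrix(r)
  n <- nrow(r)
  if (n < 2 || ncol(r) != n) {
    stop("`r` must be a square matrix with at least 2 variables", call. = FALSE)
  }
  labels <- rownames(r)
  if (is.null(labels)) {
    labels <- paste0("V", seq_len(n))
    dimnames(r) <- list(labels, labels)
  }
  valid <- matrix(TRUE, n, n)
  if (!is.null(n_obs)) {
    n_obs <- as.matrix(n_obs)
    stopifnot(all(dim(n_obs) == dim(r)))
    valid <- n_obs >= min_overlap
  }
  bad <- which(!is.finite(r) & valid, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad) > 0) {
    stop(
      "non-finite correlation for pair ",
      labels[bad[1, 1]], " -- ", labels[bad[1, 2]],
      call. = FALSE
    )
  }
  if (max(abs(r[valid & is.finite(r)])) > 1 + 1e-8) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  r_safe <- r
  r_safe[!valid] <- 0 # never read for invalid pairs, but keep finite for C++
  keep <- pcit_keep_cpp(r_safe, valid, guard)
  dimnames(keep) <- dimnames(r)
  r_kept <- ifelse(keep, r, 0)
  diag(r_kept) <- 0
  structure(
    list(keep = keep, r_kept = r_kept, n_vars = n),
    class = "pcit_adjacency"
  )
}

#' Pairwise correlations with an overlap floor
#'
#' Pearson (or Spearman) correlations over the columns of a samples-by-
#' variables matrix using pairwise-complete observations, together with the
#' pairwise observation counts needed by [pcit_adjacency()]'s overlap rule.
#' Zero-variance pairs yield a correlation of 0 with a warning rather than
#' `NA`, so downstream trio arithmetic stays finite.
#'
#' @param x Numeric matrix, rows = observations (animals), columns =
#'   variables; `NA`s allowed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r` (correlation matrix, unit diagonal) and `n_obs`
#'   (pairwise complete-observation counts).
#' @export
correlate_variables <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  suppressWarnings(
    r <- stats::cor(x, use = "pairwise.complete.obs", method = method)
  )
  n_obs <- crossprod(!is.na(x))
  degenerate <- !is.finite(r) & n_obs >= 2
  if (any(degenerate)) {
    warning("zero-variance pairs: correlations set to 0", call. = FALSE)
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  list(r = r, n_obs = n_obs)
}

#' @export
print.pcit_adjacency <- function(x, ...) {
  kept <- sum(x$keep[upper.tri(x$keep)])
  total <- x$n_vars * (x$n_vars - 1) / 2
  cat(
    "PCIT adjacency over", x$n_vars, "variables:",
    kept, "of", total, "pairs kept\n"
  )
  invisible(x)
}

#' Tidy a PCIT adjacency into a sparse edge table
#'
#' @param x A `pcit_adjacency` object.
#' @param ... Unused.
#' @return Tibble with one row per kept unordered pair: `var_a`, `var_b`, `r`.
#' @export
tidy.pcit_adjacency <- function(x, ...) {
  idx <- which(x$keep & upper.tri(x$keep), arr.ind = TRUE)
  labels <- rownames(x$keep)
  tibble::tibble(
    var_a = labels[idx[, 1]],
    var_b = labels[idx[, 2]],
    r = x$r_kept[idx]
  ) |>
    dplyr::arrange(.data$var_a, .data$var_b)
}
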