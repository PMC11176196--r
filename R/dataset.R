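#' Trait codes used throughout the package
#'
#' The 14 feed, methane and production efficiency traits: average daily gain
#' and dry matter intake for the growing (G), finishing (F) and combined (GF)
#' feedlot phases, three body weights, methane emission, hot carcass weight,
#' carcass yield, rib-eye area and subcutaneous fat thickness at the rib-eye.
#'
#' @return Character vector of the 14 trait codes.
#' @export
trait_codes <- function() {
  c(
    "ADG_G", "ADG_F", "ADG_GF", "BW1", "BW2", "BW3",
    "DMI_G", "DMI_F", "DMI_GF", "ME", "HCW", "CY", "REA", "FT_REA"
  )
}

#' Canonical tissue and diet labels
#'
#' @return Character vector.
#' @rdname labels
#' @export
tissue_levels <- function() c("liver", "muscle", "rumen")

#' @rdname labels
#' @export
diet_levels <- function() c("TRAD", "ALT")

#' Bundle counts, sample metadata, phenotypes and regulators
#'
#' The single input object of the pipeline: a gene x sample count matrix,
#' per-sample metadata (animal, tissue, diet), per-animal phenotypes and the
#' candidate regulator catalogue (transcription factors and cofactors).
#'
#' @param counts Integer matrix, genes x samples, non-negative, with gene
#'   rownames and sample-ID colnames.
#' @param samples Data frame with columns `sample_id`, `animal_id`, `tissue`,
#'   `diet`, one row per counts column.
#' @param phenotypes Data frame with `animal_id` plus the 14 trait columns
#'   (see [trait_codes()]).
#' @param regulators Data frame with columns `regulator` (gene ID) and `type`
#'   (`"TF"` or `"COF"`).
#' @return A validated `count_dataset` object.
#' @export
count_dataset <- function(counts, samples, phenotypes, regulators) {
  counts <- as.matrix(counts)
  samples <- tibble::as_tibble(samples)
  phenotypes <- tibble::as_tibble(phenotypes)
  regulators <- tibble::as_tibble(regulators)

  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs gene rownames and sample colnames", call. = FALSE)
  }
  need <- c("sample_id", "animal_id", "tissue", "diet")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0) {
    stop("sample metadata lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!setequal(samples$sample_id, colnames(counts)) ||
    anyDuplicated(samples$sample_id) > 0) {
    stop("sample metadata must cover every counts column exactly once",
      call. = FALSE
    )
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (!all(samples$tissue %in% tissue_levels())) {
    stop("tissue must be one of: ", paste(tissue_levels(), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(samples$diet %in% diet_levels())) {
    stop("diet must be one of: ", paste(diet_levels(), collapse = ", "),
      call. = FALSE
    )
  }
  missing_traits <- setdiff(trait_codes(), names(phenotypes))
  if (length(missing_traits) > 0) {
    stop("phenotype table lacks trait column(s): ",
      paste(missing_traits, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(c("regulator", "type") %in% names(regulators)) ||
    !all(regulators$type %in% c("TF", "COF"))) {
    stop("regulators needs columns `regulator` and `type` (TF/COF)",
      call. = FALSE
    )
  }
  structure(
    list(
      counts = counts, samples = samples,
      phenotypes = phenotypes, regulators = regulators
    ),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  tab <- table(x$samples$tissue, x$samples$diet)
  cat(
    "count_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
    nrow(x$phenotypes), "animals;", nrow(x$regulators), "regulators\n"
  )
  print(tab)
  invisible(x)
}
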