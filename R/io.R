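#' Read and write the pipeline's tab-separated formats
#'
#' All tables are UTF-8 TSV with a header row (except the regulator list,
#' which is two headerless columns: ID and type). Gene IDs are opaque
#' strings. Readers tolerate Windows and Unix newlines.
#'
#' @param path File path.
#' @param counts Gene x sample count matrix.
#' @param x Data frame to write.
#' @name dietwire_io
NULL

#' @rdname dietwire_io
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname dietwire_io
#' @export
write_counts <- function(counts, path) {
  tab <- tibble::as_tibble(counts, rownames = "gene")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname dietwire_io
#' @export
read_samples <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "animal_id", "tissue", "diet")
  check_header(tab, need, path)
  tab
}

#' @rdname dietwire_io
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_header(tab, c("animal_id", trait_codes()), path)
  tab
}

#' @rdname dietwire_io
#' @export
read_regulators <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_names = c("regulator", "type"),
    show_col_types = FALSE, progress = FALSE
  )
  if (!all(tab$type %in% c("TF", "COF"))) {
    stop("regulator types must be TF or COF in ", path, call. = FALSE)
  }
  tab
}

#' @rdname dietwire_io
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

check_header <- function(tab, need, path) {
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop(
      "header mismatch in ", path, ": expected column(s) ",
      paste(missing_cols, collapse = ", "), "; found ",
      paste(names(tab), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(tab)
}

#' Write a simulated dataset (and its ground truth) as a fixture directory
#'
#' Emits `counts.tsv`, `samples.tsv`, `phenotypes.tsv`, `regulators.txt`
#' (ID TAB type, no header) and `truth.json`.
#'
#' @param sim Output of [simulate_counts()] (list with `dataset`, `truth`),
#'   or a bare `count_dataset`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (inherits(sim, "count_dataset")) sim <- list(dataset = sim, truth = NULL)
  dataset <- sim$dataset
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(dataset$counts, file.path(dir, "counts.tsv"))
  write_table_tsv(dataset$samples, file.path(dir, "samples.tsv"))
  write_table_tsv(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
  readr::write_tsv(dataset$regulators, file.path(dir, "regulators.txt"),
    col_names = FALSE, progress = FALSE
  )
  if (!is.null(sim$truth)) {
    truth <- sim$truth
    json <- list(
      de_genes = split(
        truth$de_genes[c("gene", "log2fc")], truth$de_genes$tissue
      ),
      rewired_regulators = truth$rewired_regulators,
      phenotype_drivers = truth$phenotype_drivers,
      seed = truth$seed
    )
    jsonlite::write_json(
      json, file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(dir)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `dataset` (a [count_dataset()]) and `truth` (parsed
#'   truth JSON, or `NULL` if absent).
#' @export
read_fixture <- function(dir) {
  dataset <- count_dataset(
    counts = read_counts(file.path(dir, "counts.tsv")),
    samples = read_samples(file.path(dir, "samples.tsv")),
    phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv")),
    regulators = read_regulators(file.path(dir, "regulators.txt"))
  )
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  list(dataset = dataset, truth = truth)
}
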