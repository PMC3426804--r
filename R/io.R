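#' Write a simulated experiment to tab-delimited files
#'
#' Serialises an [`expression_experiment`][simulate_experiment] as three
#' TSV files with headers in `dir`: `expression.tsv` (gene_id + one column
#' per sample), `labels.tsv` (sample_id, group) and `truth.tsv` (gene_id,
#' block_id, active, is_de, delta). Numbers are written in round-trip
#' precision, so reading the files back reproduces the values exactly.
#'
#' @param experiment An `expression_experiment`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_experiment_tsv <- function(experiment, dir) {
  if (!inherits(experiment, "expression_experiment")) {
    stop_invalid("`experiment` must be an expression_experiment.")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "labels.tsv", "truth.tsv"))
  write_matrix_tsv(experiment$log2, paths[1L])
  readr::write_tsv(experiment$labels, paths[2L])
  readr::write_tsv(format_doubles(experiment$truth), paths[3L])
  invisible(paths)
}

#' Read a simulated experiment back from tab-delimited files
#'
#' Counterpart of [write_experiment_tsv()]. The truth and label tables are
#' optional on disk; missing ones are returned as `NULL`.
#'
#' @param dir Directory containing `expression.tsv` and optionally
#'   `labels.tsv`, `truth.tsv`.
#' @return A list with `log2` (matrix), `labels`, `truth`.
#' @export
read_experiment_tsv <- function(dir) {
  mat <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  labels <- NULL
  lpath <- file.path(dir, "labels.tsv")
  if (file.exists(lpath)) {
    labels <- read_tsv_exact(lpath)
    labels$group <- factor(labels$group, levels = unique(labels$group))
  }
  truth <- NULL
  tpath <- file.path(dir, "truth.tsv")
  if (file.exists(tpath)) {
    truth <- read_tsv_exact(tpath)
    truth$block_id <- as.integer(truth$block_id)
    truth$active <- as.logical(truth$active)
    truth$is_de <- as.logical(truth$is_de)
    truth$delta <- parse_double_exact(truth$delta)
  }
  list(log2 = mat, labels = labels, truth = truth)
}

#' Write a genes-by-samples matrix as TSV
#'
#' First column `gene_id` (row names), then one column per sample.
#'
#' @param x Numeric matrix with row names.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path) {
  if (!is.matrix(x)) stop_invalid("`x` must be a matrix.")
  ids <- rownames(x) %||% sprintf("g%0*d", max(4L, nchar(nrow(x))), seq_len(nrow(x)))
  df <- dplyr::bind_cols(tibble(gene_id = ids), as_tibble(x, .name_repair = "minimal"))
  readr::write_tsv(format_doubles(df), path)
  invisible(path)
}

# serialise double columns at 17 significant digits so read-back is exact
format_doubles <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- sub("^\\s+", "", formatC(df[[nm]], format = "g", digits = 17))
    }
  }
  df
}

#' Read a genes-by-samples TSV matrix
#'
#' Expects a header row, a first column of unique gene identifiers, and
#' numeric sample columns. Malformed rows are reported with their line
#' numbers; duplicate gene identifiers are an error naming the ids.
#'
#' @param path TSV file.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_exact(path)
  if (ncol(df) < 2L) stop_invalid("matrix file needs a gene_id column plus data columns.")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop_invalid(paste0("duplicate gene id(s): ", paste(dup, collapse = ", ")))
  }
  num <- vapply(df[-1L], parse_double_exact, numeric(nrow(df)))
  mat <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, names(df)[-1L]))
  mat
}

# Read a TSV with every column as character, reporting malformed rows with
# their file line numbers. Numeric columns are converted afterwards with
# base R's exact parser — fast readers can drop the last bit of a double.
read_tsv_exact <- function(path) {
  if (!file.exists(path)) stop_invalid(paste0("file not found: ", path))
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    show_col_types = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop_invalid(paste0(
      "malformed rows in ", path, " (file line",
      if (length(unique(probs$row)) > 1L) "s" else "", " ",
      paste(unique(probs$row), collapse = ", "), ")."
    ))
  }
  df
}

parse_double_exact <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(is.na(x) | x %in% c("NA", "NaN")))
  if (length(bad) > 0L) {
    stop_invalid(paste0("non-numeric value in data row ", bad[1L], ": ", x[bad[1L]]))
  }
  out
}

#' Write a p-value table as TSV
#'
#' @param pset A [`pvalue_set`][gene_ttests] (with or without the `z`
#'   column from [t_to_z()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_pvalues_tsv <- function(pset, path) {
  if (!is.data.frame(pset) || !all(c("gene_id", "t", "df", "p_value") %in% names(pset))) {
    stop_invalid("`pset` must be a pvalue_set table.")
  }
  readr::write_tsv(format_doubles(as_tibble(pset)), path)
  invisible(path)
}
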