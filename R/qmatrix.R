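#' Validate a Q-matrix
#'
#' Checks that a Q-matrix is binary and that every item requires at least one
#' attribute, returning an integer matrix.
#'
#' @param Q matrix or data frame of 0/1 entries, items in rows, attributes in
#'   columns.
#' @return Integer matrix.
#' @export
validate_qmatrix <- function(Q) {
  Q <- check_binary_matrix(Q, "Q-matrix")
  if (any(rowSums(Q) == 0)) {
    stop(sprintf("Q-matrix row %d requires no attributes",
                 which(rowSums(Q) == 0)[1L]), call. = FALSE)
  }
  Q
}

#' Read and write binary matrices as CSV
#'
#' Thin readr wrappers for the package's file formats: Q-matrices (items by
#' attributes), response matrices (persons by items), and attribute matrices
#' (persons by attributes). Files are plain CSV of 0/1 entries with an
#' optional header row; non-binary cells raise an error naming the cell.
#'
#' @param path file path.
#' @param kind one of `"q"`, `"response"`, `"attribute"` — controls
#'   validation and the informative message only.
#' @return For the readers, an integer matrix; writers return `path`
#'   invisibly.
#' @export
read_matrix_csv <- function(path, kind = c("response", "q", "attribute")) {
  kind <- match.arg(kind)
  first <- readr::read_csv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE, progress = FALSE)
  has_header <- !all(vapply(first, function(x) {
    suppressWarnings(!is.na(as.numeric(as.character(x[1])))) &&
      as.character(x[1]) %in% c("0", "1")
  }, logical(1)))
  df <- readr::read_csv(path, col_names = has_header, show_col_types = FALSE,
                        progress = FALSE)
  m <- as.matrix(df)
  what <- c(response = "response matrix", q = "Q-matrix",
            attribute = "attribute matrix")[[kind]]
  m <- check_binary_matrix(m, what)
  if (kind == "q") m <- validate_qmatrix(m)
  dimnames(m) <- NULL
  m
}

#' @rdname read_matrix_csv
#' @param x binary matrix to write.
#' @export
write_matrix_csv <- function(x, path) {
  x <- check_binary_matrix(x, "matrix")
  readr::write_csv(tibble::as_tibble(x, .name_repair = ~ paste0("V", seq_along(.x))),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
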