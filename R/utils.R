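# Internal helpers shared across modules.

# All 2^K attribute profiles, one row per class. Attribute 1 is the least
# significant bit, so class index c (0-based) has alpha_k = bit k-1 of c.
# This ordering is used everywhere a class index appears (sampler, metrics).
profile_grid <- function(K) {
  stopifnot(K >= 1, K <= 20)
  C <- 2L^K
  m <- matrix(0L, C, K)
  for (k in seq_len(K)) {
    m[, k] <- bitwAnd(bitwShiftR(0:(C - 1L), k - 1L), 1L)
  }
  m
}

# Class index (1-based) of each row of a binary attribute matrix.
profile_class <- function(alpha) {
  alpha <- as.matrix(alpha)
  as.integer(alpha %*% 2L^(seq_len(ncol(alpha)) - 1L)) + 1L
}

pattern_labels <- function(Kstar) {
  apply(profile_grid(Kstar), 1L, paste0, collapse = "")
}

check_binary_matrix <- function(x, what = "matrix") {
  x <- as.matrix(x)
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(x))
    stop(sprintf("%s must be binary; found value %s at row %d, column %d",
                 what, format(x[bad[1L]]), rc[1L], rc[2L]), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

check_simplex <- function(tau, tol = 1e-10) {
  if (any(tau < -tol) || abs(sum(tau) - 1) > tol) {
    stop("mixing proportions must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(tau)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
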