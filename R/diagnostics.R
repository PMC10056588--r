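#' Potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic computed on split chains: each chain's
#' retained draws are halved, and the between/within-sequence variance ratio
#' is formed over the resulting `2 * chains` sequences, so within-chain drift
#' also inflates the statistic. Values near 1 indicate convergence; the
#' conventional cutoff used throughout the package is 1.01.
#'
#' @param draws a matrix with one column per chain (retained draws in rows),
#'   or a list of equal-length numeric vectors.
#' @param split halve each chain before computing the diagnostic.
#' @return Scalar PSRF (`>= 1` up to numerical tolerance). For a parameter
#'   with zero variance in every sequence (a structurally fixed parameter),
#'   returns `NA`.
#' @examples
#' psrf(cbind(rnorm(1000), rnorm(1000)))
#' @export
psrf <- function(draws, split = TRUE) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("PSRF needs at least two chains", call. = FALSE)
  if (nrow(draws) < 10L) stop("PSRF needs at least 10 retained draws per chain",
                              call. = FALSE)
  if (split) {
    h <- nrow(draws) %/% 2L
    draws <- cbind(draws[seq_len(h), , drop = FALSE],
                   draws[(nrow(draws) - h + 1L):nrow(draws), , drop = FALSE])
  }
  n <- nrow(draws); m <- ncol(draws)
  means <- colMeans(draws)
  vars <- apply(draws, 2L, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) {
    return(if (B == 0) NA_real_ else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Maximum PSRF over monitored item parameters
#'
#' @param fit a `"dcm_fit"` object.
#' @return Scalar: the largest split-chain PSRF across all non-degenerate
#'   item parameters.
#' @export
max_psrf <- function(fit) {
  td <- tidy(fit)
  max(td$psrf, na.rm = TRUE)
}
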