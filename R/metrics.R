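#' Bias and root mean square error over replications
#'
#' `bias = mean(estimate - truth)` and `rmse = sqrt(mean((estimate -
#' truth)^2))` across replications.
#'
#' @param estimates numeric vector of estimates, one per replication.
#' @param truth true value (scalar, or vector aligned with `estimates`).
#' @return A list with elements `bias` and `rmse`.
#' @examples
#' bias_rmse(c(0.0, 0.2), 0.1)
#' @export
bias_rmse <- function(estimates, truth) {
  if (length(truth) != 1L && length(truth) != length(estimates)) {
    stop("truth must be scalar or match estimates in length", call. = FALSE)
  }
  e <- estimates - truth
  list(bias = mean(e), rmse = sqrt(mean(e^2)))
}

#' Attribute and profile classification accuracy
#'
#' `accr()` returns, per attribute, the fraction of person cells classified
#' correctly; `pccr()` the fraction of persons whose whole profile matches
#' exactly. Replications are handled by row-binding estimated and true
#' matrices. `pccr()` can never exceed any attribute's `accr()`.
#'
#' @param estimated,truth binary matrices of identical shape (persons
#'   by attributes, rows stacked over replications).
#' @return `accr()`: numeric vector of length K; `pccr()`: scalar.
#' @examples
#' a <- matrix(c(1, 0, 1, 1), 2)
#' accr(a, a); pccr(a, a)
#' @export
accr <- function(estimated, truth) {
  estimated <- check_binary_matrix(estimated, "estimated attribute matrix")
  truth <- check_binary_matrix(truth, "true attribute matrix")
  if (!identical(dim(estimated), dim(truth))) {
    stop("attribute matrices have different shapes", call. = FALSE)
  }
  colMeans(estimated == truth)
}

#' @rdname accr
#' @export
pccr <- function(estimated, truth) {
  estimated <- check_binary_matrix(estimated, "estimated attribute matrix")
  truth <- check_binary_matrix(truth, "true attribute matrix")
  if (!identical(dim(estimated), dim(truth))) {
    stop("attribute matrices have different shapes", call. = FALSE)
  }
  mean(rowSums(estimated == truth) == ncol(truth))
}

#' RMSE of attribute-profile proportions
#'
#' For each of the `2^K` profiles, the root mean square error of its
#' estimated population proportion across replications, plus the mean of
#' those per-profile RMSEs.
#'
#' @param estimated matrix of estimated proportion vectors, one replication
#'   per row (a single vector is treated as one replication); rows must lie
#'   on the simplex.
#' @param truth true proportion vector.
#' @param tol simplex tolerance.
#' @return A list with `per_profile` (numeric vector) and `mean` (scalar).
#' @export
profile_proportion_rmse <- function(estimated, truth, tol = 1e-8) {
  if (is.null(dim(estimated))) estimated <- matrix(estimated, nrow = 1L)
  if (ncol(estimated) != length(truth)) {
    stop("proportion vectors have different lengths", call. = FALSE)
  }
  ok <- abs(rowSums(estimated) - 1) < tol & apply(estimated >= -tol, 1L, all) &
    abs(sum(truth) - 1) < tol
  if (!all(ok)) stop("proportions must lie on the simplex", call. = FALSE)
  per <- sqrt(colMeans((estimated - matrix(truth, nrow(estimated),
                                           length(truth), byrow = TRUE))^2))
  list(per_profile = per, mean = mean(per))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_hat)`. The deviance is
#' `-2` times the Bernoulli log-likelihood conditional on the sampled
#' attribute profiles (the convention of general-purpose Gibbs samplers, so
#' attribute classes count toward model complexity). The plug-in deviance
#' `D(theta_hat)` uses posterior-mean item parameters and each person's modal
#' profile. Smaller is better.
#'
#' @param fit a `"dcm_fit"` object, or a list with elements `deviance_draws`
#'   (list of per-chain deviance vectors) and `plugin_deviance` (scalar) for
#'   direct computation from stored quantities.
#' @return A list with `dic`, `pd`, `dbar` (posterior-mean deviance), and
#'   `dhat` (plug-in deviance).
#' @export
dic <- function(fit) {
  dev <- unlist(fit$deviance_draws)
  if (!length(dev)) stop("no retained draws", call. = FALSE)
  dbar <- mean(dev)
  dhat <- if (!is.null(fit$plugin_deviance)) {
    fit$plugin_deviance
  } else {
    params_hat <- posterior_mean_params(fit)
    est <- estimate_attributes(fit)
    -2 * loglik_dcm(fit$Y, fit$Q, params_hat, est$modal, eps = fit$eps)
  }
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Conditional predictive ordinate fit indices
#'
#' The conditional predictive ordinate of each response is estimated by the
#' harmonic mean of its per-draw Bernoulli likelihoods over the retained
#' draws: `CPO_ni = D / sum_d 1 / p_nid`, accumulated during sampling.
#' Item-level `-2LCPO_i = -2 * sum_n log CPO_ni`; the test-level value is
#' their sum. Smaller values indicate better fit. With likelihood clipping at
#' `eps`, every summand is bounded by `1/eps`, so the accumulation cannot
#' overflow.
#'
#' @param fit a `"dcm_fit"` object.
#' @return A list with `test` (scalar), `item` (numeric vector of length I),
#'   and `log_cpo` (N-by-I matrix of log conditional predictive ordinates).
#' @export
lcpo <- function(fit) {
  log_cpo <- log(fit$n_kept) - log(fit$cpo_sum)
  item <- -2 * colSums(log_cpo)
  list(test = sum(item), item = item, log_cpo = log_cpo)
}
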