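#' Classify the operative condensation rule of one item
#'
#' Decision rule on estimated mixing proportions: `tau1 > threshold` means
#' the item is conjunctive; `tau2 > threshold` disjunctive; otherwise, if
#' `tau3` is strictly larger than both `tau1` and `tau2`, the item follows
#' the ratio/compensatory rule; anything else is flagged as coexisting
#' condensation rules. Unidimensional items (Q-row sum 1) are not
#' classifiable — all rules coincide — and get verdict `unidimensional_na`.
#'
#' @param tau_hat length-3 estimated mixing proportions (simplex).
#' @param q binary required-attribute vector of the item.
#' @param threshold cut-point for the conjunctive/disjunctive calls, in
#'   (1/3, 1\].
#' @return A single string: one of `"conjunctive"`, `"disjunctive"`,
#'   `"ratio_compensatory"`, `"coexisting"`, `"unidimensional_na"`.
#' @examples
#' classify_item(c(0.95, 0.03, 0.02), c(1, 1, 0))
#' classify_item(c(0.25, 0.15, 0.60), c(1, 1, 1))
#' @export
classify_item <- function(tau_hat, q, threshold = 0.9) {
  check_simplex(tau_hat, tol = 1e-6)
  if (threshold <= 1 / 3 || threshold > 1) {
    stop("threshold must lie in (1/3, 1]", call. = FALSE)
  }
  if (sum(q == 1) == 1L) return("unidimensional_na")
  if (tau_hat[1L] > threshold) return("conjunctive")
  if (tau_hat[2L] > threshold) return("disjunctive")
  if (tau_hat[3L] > tau_hat[1L] && tau_hat[3L] > tau_hat[2L]) {
    return("ratio_compensatory")
  }
  "coexisting"
}

#' Condensation-rule verdicts for every item of a DINMix fit
#'
#' Applies [classify_item()] to the posterior-mean mixing proportions of each
#' item. Optionally also reports, per item, the posterior probability that
#' each mixing proportion exceeds the threshold (an uncertainty-aware
#' companion to the point-estimate verdict).
#'
#' @param fit a `"dcm_fit"` object fitted with `model = "DINMIX"`, or a
#'   tibble with columns `item`, `tau1`, `tau2`, `tau3` (then `Q` must be
#'   given).
#' @param Q Q-matrix (taken from the fit when available).
#' @param threshold cut-point passed to [classify_item()].
#' @param posterior_probs also compute `pr_tau1`, `pr_tau2`, `pr_tau3`
#'   columns (posterior exceedance probabilities; fits only).
#' @return A tibble: `item`, `tau1..tau3`, `verdict`, `threshold`.
#' @export
classify_rules <- function(fit, Q = NULL, threshold = 0.9,
                           posterior_probs = FALSE) {
  if (inherits(fit, "dcm_fit")) {
    if (fit$model != "DINMIX") {
      stop("rule identification needs a DINMix fit", call. = FALSE)
    }
    Q <- fit$Q
    td <- tidy(fit)
    I <- nrow(Q)
    tau_tbl <- tibble::tibble(
      item = seq_len(I),
      tau1 = td$estimate[match(paste0("tau1[", seq_len(I), "]"), td$term)],
      tau2 = td$estimate[match(paste0("tau2[", seq_len(I), "]"), td$term)],
      tau3 = td$estimate[match(paste0("tau3[", seq_len(I), "]"), td$term)]
    )
  } else {
    if (is.null(Q)) stop("Q must be supplied with a tau table", call. = FALSE)
    tau_tbl <- fit
  }
  tau_tbl$tau3 <- pmax(tau_tbl$tau3, 0)
  out <- tau_tbl
  out$verdict <- vapply(seq_len(nrow(out)), function(i) {
    tau <- c(out$tau1[i], out$tau2[i], out$tau3[i])
    classify_item(tau / sum(tau), Q[out$item[i], ], threshold)
  }, character(1))
  out$threshold <- threshold
  if (posterior_probs && inherits(fit, "dcm_fit")) {
    draws <- do.call(rbind, fit$par_draws)
    for (m in 1:3) {
      out[[paste0("pr_tau", m)]] <- vapply(out$item, function(i) {
        mean(draws[, paste0("tau", m, "[", i, "]")] > threshold)
      }, numeric(1))
    }
  }
  out
}

#' Compare rule verdicts with expert expectations
#'
#' Items whose identified condensation rule disagrees with the rule the test
#' developers intended are flagged for possible revision.
#'
#' @param verdicts tibble from [classify_rules()].
#' @param expected character vector of expected verdicts, aligned with the
#'   items (`"unidimensional_na"` entries are never flagged).
#' @return The verdict tibble with logical columns `expected` and `flagged`;
#'   the number of flagged items is attached as attribute `n_flagged` and
#'   printed by `summary()`-style inspection.
#' @export
revision_report <- function(verdicts, expected) {
  if (nrow(verdicts) != length(expected)) {
    stop("one expected rule per item is required", call. = FALSE)
  }
  out <- verdicts
  out$expected <- expected
  out$flagged <- out$verdict != expected & out$verdict != "unidimensional_na"
  attr(out, "n_flagged") <- sum(out$flagged)
  out
}
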