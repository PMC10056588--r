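#' Plot estimated mixing proportions per item
#'
#' Stacked-bar display of the posterior-mean mixing proportions of a DINMix
#' fit, the standard visual for judging which condensation rule dominates
#' each item.
#'
#' @param object a `"dcm_fit"` object with `model = "DINMIX"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dcm_fit <- function(object, ...) {
  if (object$model == "DINMIX") {
    tbl <- classify_rules(object) |>
      tidyr::pivot_longer(dplyr::all_of(c("tau1", "tau2", "tau3")),
                          names_to = "rule", values_to = "proportion") |>
      dplyr::mutate(rule = dplyr::recode(.data$rule, tau1 = "conjunctive",
                                         tau2 = "disjunctive", tau3 = "ratio"))
    ggplot2::ggplot(tbl, ggplot2::aes(x = factor(.data$item),
                                      y = .data$proportion,
                                      fill = .data$rule)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "item", y = "estimated mixing proportion",
                    fill = "condensation rule") +
      ggplot2::theme_minimal()
  } else {
    td <- tidy(object)
    td <- td[td$std.error > 0, ]
    ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$estimate - 2 * .data$std.error,
        ymax = .data$estimate + 2 * .data$std.error)) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "posterior mean ± 2 sd") +
      ggplot2::theme_minimal()
  }
}

#' Trace plot of retained draws
#'
#' @param fit a `"dcm_fit"` object.
#' @param pars character vector of parameter names (see `tidy(fit)$term`).
#' @return A ggplot object, one facet per parameter, coloured by chain.
#' @export
plot_trace <- function(fit, pars) {
  tbl <- purrr::imap_dfr(fit$par_draws, function(m, ch) {
    d <- tibble::as_tibble(m[, pars, drop = FALSE])
    d$chain <- factor(ch)
    d$iteration <- seq_len(nrow(m))
    tidyr::pivot_longer(d, !dplyr::all_of(c("chain", "iteration")),
                        names_to = "parameter", values_to = "value")
  })
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$iteration, y = .data$value,
                                    colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::theme_minimal()
}
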