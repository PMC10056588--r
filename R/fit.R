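MODEL_CODES <- c(DINA = 0L, DINO = 1L, DINR = 2L, DINMIX = 3L, ACDM = 4L,
                 GDINA = 5L)

#' Fit a cognitive diagnosis model by MCMC
#'
#' Bayesian estimation of DINA, DINO, DINR, DINMix, ACDM, or saturated GDINA
#' by Metropolis-within-Gibbs sampling. Each sweep samples every person's
#' attribute class from its full conditional over the `2^K` classes, samples
#' the class-proportion vector from its conjugate Dirichlet conditional, and
#' updates item parameters by adaptive random-walk Metropolis (conjugate
#' truncated-Beta draws for GDINA pattern probabilities). Priors are flat:
#' uniform on (g, s) truncated to `g < 1 - s`, Dirichlet(1,1,1) on mixing
#' proportions, Dirichlet(1,...,1) on class proportions, Beta(1,1) on GDINA
#' pattern probabilities constrained monotone in the mastery partial order,
#' and uniform on the ACDM constraint polytope with non-negative main
#' effects. Mixing proportions of unidimensional items are fixed at
#' `(1, 0, 0)`.
#'
#' @param Y binary N-by-I response matrix (or data frame).
#' @param Q binary I-by-K Q-matrix.
#' @param model one of `"DINA"`, `"DINO"`, `"DINR"`, `"DINMIX"`, `"ACDM"`,
#'   `"GDINA"` (case-insensitive).
#' @param chains number of chains (at least 2 for convergence diagnostics).
#' @param iter iterations per chain.
#' @param burnin burn-in iterations discarded per chain.
#' @param thin thinning interval for retained draws.
#' @param alpha_thin additional thinning applied to stored attribute-class
#'   draws (estimates use exact accumulators; stored class draws are for
#'   export and cross-checks).
#' @param seed integer seed; chain seeds are derived from it.
#' @param fix_item_params optional item-parameter tibble (as from
#'   [item_params_tbl()]); when supplied, item parameters are held fixed at
#'   these values and only attribute classes and class proportions are
#'   sampled. Intended for validation against enumeration-based posteriors.
#' @param target_accept Metropolis acceptance rate targeted during burn-in
#'   adaptation.
#' @param adapt_every adaptation interval (iterations) during burn-in.
#' @param gs_reps,tau_reps repetitions per sweep of the collapsed
#'   (class-marginalised) guessing/slip and mixing-proportion refreshes.
#'   The defaults favour low autocorrelation; reduce them for quick
#'   model-comparison fits where ranking, not per-parameter precision, is
#'   the goal.
#' @param eps likelihood clipping bound.
#' @return An object of class `"dcm_fit"`; see [tidy.dcm_fit()],
#'   [glance.dcm_fit()], [estimate_attributes()], [dic()], [lcpo()].
#' @export
dcm_fit <- function(Y, Q, model = "DINMIX", chains = 2, iter = 10000,
                    burnin = 5000, thin = 1, alpha_thin = 10, seed = NULL,
                    fix_item_params = NULL, target_accept = 0.3,
                    adapt_every = 50, gs_reps = 20, tau_reps = 3,
                    eps = 1e-12) {
  Y <- check_binary_matrix(Y, "response matrix")
  Q <- validate_qmatrix(Q)
  if (ncol(Y) != nrow(Q)) stop("Y has a column per item; Q a row per item", call. = FALSE)
  model <- toupper(model)
  if (!model %in% names(MODEL_CODES)) {
    stop("unknown model tag: ", model, call. = FALSE)
  }
  if (burnin >= iter) stop("burn-in must be smaller than iter", call. = FALSE)
  if (chains < 1) stop("need at least one chain", call. = FALSE)

  fixed_probs <- NULL
  if (!is.null(fix_item_params)) {
    fixed_probs <- class_probability_matrix(Q, fix_item_params)
  }

  seeds <- derive_seeds(seed, chains)
  runs <- lapply(seq_len(chains), function(ch) {
    with_seed(seeds[[ch]],
      run_dcm_chain(Y, Q, MODEL_CODES[[model]], as.integer(iter),
                    as.integer(burnin), as.integer(thin),
                    as.integer(alpha_thin), fixed_probs, eps,
                    target_accept, as.integer(adapt_every),
                    as.integer(gs_reps), as.integer(tau_reps)))
  })

  K <- ncol(Q)
  nm <- par_names(model, Q)
  par_draws <- lapply(runs, function(r) {
    m <- r$par
    if (ncol(m)) colnames(m) <- nm
    m
  })
  n_kept_total <- sum(vapply(runs, function(r) r$n_kept, numeric(1)))
  cpo_sum <- Reduce(`+`, lapply(runs, `[[`, "cpo_sum"))
  cls_counts <- Reduce(`+`, lapply(runs, `[[`, "cls_counts"))

  fit <- structure(list(
    model = model, Y = Y, Q = Q, K = K,
    chains = chains, iter = iter, burnin = burnin, thin = thin,
    n_kept = n_kept_total,
    par_draws = par_draws,
    pi_draws = lapply(runs, `[[`, "pi"),
    deviance_draws = lapply(runs, `[[`, "deviance"),
    alpha_draws = lapply(runs, `[[`, "alpha"),
    cpo_sum = cpo_sum,
    cls_counts = cls_counts,
    accept_rate = lapply(runs, `[[`, "accept_rate"),
    fixed = !is.null(fix_item_params),
    fix_item_params = fix_item_params,
    eps = eps, seed = seed
  ), class = "dcm_fit")
  fit
}

# Column names of the retained parameter-draw matrices.
par_names <- function(model, Q) {
  I <- nrow(Q)
  if (model %in% c("DINA", "DINO", "DINR", "DINMIX")) {
    c(paste0("g[", seq_len(I), "]"), paste0("s[", seq_len(I), "]"),
      as.vector(t(outer(seq_len(I), 1:3,
                        function(i, m) paste0("tau", m, "[", i, "]")))))
  } else if (model == "ACDM") {
    unlist(lapply(seq_len(I), function(i) {
      Kstar <- sum(Q[i, ])
      c(paste0("d0[", i, "]"), paste0("d", seq_len(Kstar), "[", i, "]"))
    }))
  } else {
    unlist(lapply(seq_len(I), function(i) {
      paste0("p", pattern_labels(sum(Q[i, ])), "[", i, "]")
    }))
  }
}

#' Posterior summary of item parameters
#'
#' One row per monitored item parameter: posterior mean (EAP), posterior
#' standard deviation, and split-chain potential scale reduction factor.
#' Parameters that are structurally fixed (e.g., mixing proportions of
#' unidimensional items) have zero posterior spread and `NA` PSRF.
#'
#' @param x a `"dcm_fit"` object.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `psrf`.
#' @export
tidy.dcm_fit <- function(x, ...) {
  if (x$fixed) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), psrf = numeric()))
  }
  all_draws <- do.call(rbind, x$par_draws)
  tibble::tibble(
    term = colnames(all_draws),
    estimate = colMeans(all_draws),
    std.error = apply(all_draws, 2L, sd),
    psrf = vapply(colnames(all_draws), function(p) {
      psrf(sapply(x$par_draws, function(m) m[, p]))
    }, numeric(1))
  )
}

#' One-line model summary
#'
#' @param x a `"dcm_fit"` object.
#' @param ... unused.
#' @return A one-row tibble: model, dimensions, sampler settings, DIC,
#'   effective parameter count `pD`, test-level -2LCPO, and the maximum PSRF
#'   over item parameters.
#' @export
glance.dcm_fit <- function(x, ...) {
  d <- dic(x)
  l <- lcpo(x)
  tibble::tibble(
    model = x$model, N = nrow(x$Y), I = ncol(x$Y), K = x$K,
    chains = x$chains, iter = x$iter, burnin = x$burnin,
    draws = x$n_kept,
    DIC = d$dic, pD = d$pd, lcpo_test = l$test,
    max_psrf = max_psrf(x)
  )
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("%s fit: N = %d, I = %d, K = %d; %d chains x %d iterations (%d burn-in), %d retained draws\n",
              x$model, nrow(x$Y), ncol(x$Y), x$K, x$chains, x$iter, x$burnin,
              x$n_kept))
  if (!x$fixed) {
    mp <- max_psrf(x)
    cat(sprintf("max split-chain PSRF over item parameters: %.4f\n", mp))
  }
  invisible(x)
}

# Posterior-mean item parameters as an item-parameter table.
posterior_mean_params <- function(fit) {
  if (fit$fixed) return(fit$fix_item_params)
  draws <- do.call(rbind, fit$par_draws)
  est <- colMeans(draws)
  I <- ncol(fit$Y)
  Q <- fit$Q
  if (fit$model %in% c("DINA", "DINO", "DINR", "DINMIX")) {
    par <- lapply(seq_len(I), function(i) {
      tau <- est[paste0("tau", 1:3, "[", i, "]")]
      dinmix_pars(est[paste0("g[", i, "]")], est[paste0("s[", i, "]")],
                  tau / sum(tau))
    })
    item_params_tbl(rep(fit$model, I), par)
  } else if (fit$model == "ACDM") {
    par <- lapply(seq_len(I), function(i) {
      Kstar <- sum(Q[i, ])
      additive_pars(est[paste0("d0[", i, "]")],
                    est[paste0("d", seq_len(Kstar), "[", i, "]")])
    })
    item_params_tbl(rep("ACDM", I), par)
  } else {
    par <- lapply(seq_len(I), function(i) {
      labs <- pattern_labels(sum(Q[i, ]))
      structure(list(probs = unname(est[paste0("p", labs, "[", i, "]")])),
                class = "dcm_pars")
    })
    item_params_tbl(rep("GDINA", I), par)
  }
}

#' Attribute estimates from a fitted model
#'
#' Marginal posterior mastery probabilities per person and attribute, the
#' binary attribute estimates `alpha_hat` (mastery iff the marginal posterior
#' mean is at least 0.5 — ties resolve to mastery), and each person's modal
#' attribute profile (the most frequently sampled class; ties resolve to the
#' lowest class index).
#'
#' @param fit a `"dcm_fit"` object.
#' @return A list with `marginal` (N-by-K numeric), `alpha_hat` (N-by-K
#'   binary), `modal` (N-by-K binary), and `class_probs` (N-by-2^K posterior
#'   class frequencies).
#' @export
estimate_attributes <- function(fit) {
  grid <- profile_grid(fit$K)
  freq <- fit$cls_counts / rowSums(fit$cls_counts)
  marginal <- freq %*% grid
  alpha_hat <- matrix(as.integer(marginal >= 0.5), nrow(marginal))
  modal_cls <- max.col(freq, ties.method = "first")
  modal <- grid[modal_cls, , drop = FALSE]
  list(marginal = marginal, alpha_hat = alpha_hat, modal = modal,
       class_probs = freq)
}

#' Posterior mean class proportions
#'
#' @param fit a `"dcm_fit"` object.
#' @return Numeric vector over the `2^K` attribute classes (ordered with
#'   attribute 1 as the least significant bit).
#' @export
class_proportions <- function(fit) {
  colMeans(do.call(rbind, fit$pi_draws))
}

#' Fit several models to the same data and compare them
#'
#' @param Y,Q response and Q-matrix as in [dcm_fit()].
#' @param models character vector of model tags.
#' @param ... passed to [dcm_fit()].
#' @return A tibble with one row per model: DIC, pD, test-level -2LCPO, and
#'   maximum PSRF, sorted as given.
#' @export
compare_models <- function(Y, Q, models = c("DINA", "DINMIX"), ...) {
  purrr::map_dfr(models, function(m) {
    f <- dcm_fit(Y, Q, model = m, ...)
    glance(f)[, c("model", "DIC", "pD", "lcpo_test", "max_psrf")]
  })
}
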