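#' Latent responses under the three condensation rules
#'
#' A condensation rule maps a respondent's attribute profile `alpha` and an
#' item's required-attribute vector `q` to a latent response:
#' conjunctive (all required attributes mastered), disjunctive (at least one
#' required attribute mastered), or ratio (the fraction of required
#' attributes mastered). Conjunctive and disjunctive latent responses are 0/1;
#' the ratio latent response lies in \[0, 1\].
#'
#' @param alpha binary vector of attribute masteries, or a matrix with one
#'   profile per row.
#' @param q binary vector of required attributes for one item; must contain at
#'   least one 1.
#' @return A numeric latent response (vector if `alpha` is a matrix).
#' @examples
#' latent_conjunctive(c(1, 0, 1), c(1, 0, 1))
#' latent_ratio(c(1, 0, 0), c(1, 1, 1))
#' @export
latent_conjunctive <- function(alpha, q) {
  m <- check_alpha_q(alpha, q)
  req <- which(q == 1)
  as.numeric(rowSums(m[, req, drop = FALSE]) == length(req))
}

#' @rdname latent_conjunctive
#' @export
latent_disjunctive <- function(alpha, q) {
  m <- check_alpha_q(alpha, q)
  req <- which(q == 1)
  as.numeric(rowSums(m[, req, drop = FALSE]) > 0)
}

#' @rdname latent_conjunctive
#' @export
latent_ratio <- function(alpha, q) {
  m <- check_alpha_q(alpha, q)
  req <- which(q == 1)
  rowSums(m[, req, drop = FALSE]) / length(req)
}

check_alpha_q <- function(alpha, q) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1L)
  alpha <- check_binary_matrix(alpha, "attribute profile")
  q <- as.integer(q)
  if (ncol(alpha) != length(q)) {
    stop("attribute profile and q-vector have different lengths", call. = FALSE)
  }
  if (!any(q == 1)) stop("q-vector must require at least one attribute", call. = FALSE)
  if (any(!q %in% c(0L, 1L))) stop("q-vector must be binary", call. = FALSE)
  alpha
}

#' Mixed latent response
#'
#' Convex combination of the conjunctive, disjunctive, and ratio latent
#' responses with item-level mixing proportions `tau = (tau1, tau2, tau3)` on
#' the simplex. Equals 1 when all required attributes are mastered and 0 when
#' none are.
#'
#' @inheritParams latent_conjunctive
#' @param tau length-3 non-negative vector summing to 1, ordered
#'   (conjunctive, disjunctive, ratio).
#' @return Numeric mixed latent response in \[0, 1\].
#' @examples
#' mixed_latent_response(c(1, 0, 0), c(1, 1, 1), c(0.8, 0.1, 0.1))
#' @export
mixed_latent_response <- function(alpha, q, tau) {
  check_simplex(tau)
  tau[1L] * latent_conjunctive(alpha, q) +
    tau[2L] * latent_disjunctive(alpha, q) +
    tau[3L] * latent_ratio(alpha, q)
}

#' Correct-response probability given a latent response
#'
#' The deterministic-input noisy response function
#' `P = g + (1 - s - g) * psi`, where `g` is the guessing probability (correct
#' response with latent response 0) and `s` the slip probability (incorrect
#' response with latent response 1). Monotonicity `g < 1 - s` is enforced.
#'
#' @param g,s guessing and slip probabilities in (0, 1) with `g < 1 - s`.
#' @param psi latent response in \[0, 1\].
#' @return Probability in `[g, 1 - s]`.
#' @examples
#' response_probability(0.1, 0.1, 1 / 3)
#' @export
response_probability <- function(g, s, psi) {
  if (any(g <= 0) || any(g >= 1) || any(s <= 0) || any(s >= 1) || any(g >= 1 - s)) {
    stop("item parameters must satisfy 0 < g < 1 - s < 1", call. = FALSE)
  }
  if (any(psi < 0) || any(psi > 1)) stop("psi must lie in [0, 1]", call. = FALSE)
  g + (1 - s - g) * psi
}

#' DINMix correct-response probability
#'
#' Composition of [mixed_latent_response()] and [response_probability()].
#' With `tau = c(1, 0, 0)`, `c(0, 1, 0)`, or `c(0, 0, 1)` this reduces exactly
#' to the DINA, DINO, or DINR model.
#'
#' @inheritParams mixed_latent_response
#' @inheritParams response_probability
#' @return Probability of a correct response.
#' @examples
#' dinmix_probability(c(1, 0, 0), c(1, 1, 1), g = 0.1, s = 0.1,
#'                    tau = c(0.8, 0.1, 0.1))
#' @export
dinmix_probability <- function(alpha, q, g, s, tau) {
  response_probability(g, s, mixed_latent_response(alpha, q, tau))
}

#' Additive (ACDM / GDINA) correct-response probability
#'
#' Identity-link additive model: intercept, one main effect per required
#' attribute (earned when that attribute is mastered), and optionally one
#' interaction effect per subset of two or more required attributes (earned
#' when the whole subset is mastered). The ACDM is the interaction-free case;
#' with all interactions present the model is the saturated GDINA.
#'
#' Interaction effects are ordered by subset size, then by binary subset mask
#' with the first required attribute as the least significant bit: for a
#' three-attribute item, two-way subsets (1,2), (1,3), (2,3), then the
#' three-way subset.
#'
#' @inheritParams latent_conjunctive
#' @param intercept probability of success with no required attribute mastered.
#' @param main numeric vector of main effects, one per required attribute (in
#'   Q-matrix column order).
#' @param interaction numeric vector of interaction effects (possibly empty).
#' @return Probability of a correct response.
#' @examples
#' additive_probability(c(1, 1, 0), c(1, 1, 0), intercept = 0.1,
#'                      main = c(0.5, 0.3))
#' @export
additive_probability <- function(alpha, q, intercept, main, interaction = numeric(0)) {
  m <- check_alpha_q(alpha, q)
  req <- which(q == 1)
  Kstar <- length(req)
  if (length(main) != Kstar) {
    stop("need one main effect per required attribute", call. = FALSE)
  }
  subsets <- interaction_subsets(Kstar)
  if (length(interaction) == 0L) {
    interaction <- numeric(length(subsets))  # ACDM: no interaction terms
  } else if (length(interaction) != length(subsets)) {
    stop(sprintf("expected %d interaction effects, got %d",
                 length(subsets), length(interaction)), call. = FALSE)
  }
  a <- m[, req, drop = FALSE]
  p <- intercept + as.numeric(a %*% main)
  for (j in seq_along(subsets)) {
    p <- p + interaction[j] * as.numeric(rowSums(a[, subsets[[j]], drop = FALSE]) ==
                                           length(subsets[[j]]))
  }
  if (any(p < -1e-10) || any(p > 1 + 1e-10)) {
    stop("additive parameters imply a pattern probability outside [0, 1]",
         call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

# Subsets of size >= 2 of 1..Kstar, ordered by size then by subset mask with
# attribute 1 as the least significant bit. Empty list for Kstar < 2.
interaction_subsets <- function(Kstar) {
  if (Kstar < 2L) return(list())
  masks <- 0:(2L^Kstar - 1L)
  sizes <- vapply(masks, function(m) sum(bitwAnd(bitwShiftR(m, 0:(Kstar - 1L)), 1L)),
                  numeric(1))
  keep <- masks[sizes >= 2]
  keep <- keep[order(sizes[sizes >= 2], keep)]
  lapply(keep, function(m) which(bitwAnd(bitwShiftR(m, 0:(Kstar - 1L)), 1L) == 1L))
}

#' Per-item parameter constructors
#'
#' Build the per-item parameter object consumed by [pattern_probabilities()],
#' [simulate_responses()], and [loglik_dcm()]. `dinmix_pars()` covers the
#' deterministic-input family (DINA, DINO, DINR, DINMix are distinguished by
#' `tau`); `additive_pars()` covers ACDM (no interactions) and GDINA.
#'
#' @param g,s guessing and slip probabilities, `0 < g < 1 - s < 1`.
#' @param tau length-3 simplex vector of mixing proportions.
#' @param intercept,main,interaction additive-model effects; see
#'   [additive_probability()].
#' @return A list of class `"dcm_pars"`.
#' @export
dinmix_pars <- function(g, s, tau = c(1, 0, 0)) {
  if (g <= 0 || s <= 0 || g >= 1 - s) {
    stop("item parameters must satisfy 0 < g < 1 - s < 1", call. = FALSE)
  }
  check_simplex(tau)
  structure(list(g = g, s = s, tau = as.numeric(tau)), class = "dcm_pars")
}

#' @rdname dinmix_pars
#' @export
additive_pars <- function(intercept, main, interaction = numeric(0)) {
  structure(list(intercept = intercept, main = as.numeric(main),
                 interaction = as.numeric(interaction)), class = "dcm_pars")
}

#' Reduced-pattern correct-response probabilities for one item
#'
#' Enumerates all `2^Kstar` reduced attribute patterns over an item's required
#' attributes and returns the model's correct-response probability for each.
#' Patterns are enumerated in binary order with the first required attribute
#' as the least significant bit, and labelled by their bit strings. Any
#' Q-restricted model in the package can be written this way; for DINMix the
#' whole vector is generated by only four free parameters (g, s, tau1, tau2).
#'
#' @param model one of `"DINA"`, `"DINO"`, `"DINR"`, `"DINMIX"`, `"ACDM"`,
#'   `"GDINA"` (case-insensitive).
#' @param q binary required-attribute vector for the item.
#' @param par a `"dcm_pars"` object from [dinmix_pars()] or [additive_pars()].
#' @return Named numeric vector of length `2^sum(q)`.
#' @examples
#' pattern_probabilities("DINMIX", c(1, 1, 1),
#'                       dinmix_pars(0.1, 0.1, c(0.8, 0.1, 0.1)))
#' @export
pattern_probabilities <- function(model, q, par) {
  model <- toupper(model)
  model <- match.arg(model, c("DINA", "DINO", "DINR", "DINMIX", "ACDM", "GDINA"))
  q <- as.integer(q)
  Kstar <- sum(q == 1)
  if (Kstar < 1) stop("q-vector must require at least one attribute", call. = FALSE)
  red <- profile_grid(Kstar)
  # embed reduced patterns into full-length profiles for the per-profile calls
  alpha <- matrix(0L, nrow(red), length(q))
  alpha[, which(q == 1)] <- red
  if (model == "GDINA" && !is.null(par$probs)) {
    # saturated model given directly by its reduced-pattern probabilities
    if (length(par$probs) != nrow(red)) {
      stop("pattern probability vector has the wrong length", call. = FALSE)
    }
    return(setNames(as.numeric(par$probs), pattern_labels(Kstar)))
  }
  p <- switch(model,
    DINA   = dinmix_probability(alpha, q, par$g, par$s, c(1, 0, 0)),
    DINO   = dinmix_probability(alpha, q, par$g, par$s, c(0, 1, 0)),
    DINR   = dinmix_probability(alpha, q, par$g, par$s, c(0, 0, 1)),
    DINMIX = dinmix_probability(alpha, q, par$g, par$s, par$tau),
    ACDM   = additive_probability(alpha, q, par$intercept, par$main),
    GDINA  = additive_probability(alpha, q, par$intercept, par$main, par$interaction)
  )
  setNames(p, pattern_labels(Kstar))
}

#' Bernoulli log-likelihood of a response matrix
#'
#' Joint log-likelihood of dichotomous responses `Y` given each person's
#' attribute profile, a Q-matrix, and per-item models and parameters.
#' Probabilities are clipped to `[eps, 1 - eps]` before taking logs.
#'
#' @param Y binary N-by-I response matrix.
#' @param Q binary I-by-K Q-matrix.
#' @param item_params tibble with columns `item`, `model`, `par` (a
#'   list-column of `"dcm_pars"`), as produced by the simulators or
#'   [true_params_tbl()].
#' @param alpha binary N-by-K attribute matrix.
#' @param eps clipping bound for probabilities.
#' @return Scalar log-likelihood.
#' @export
loglik_dcm <- function(Y, Q, item_params, alpha, eps = 1e-12) {
  Y <- check_binary_matrix(Y, "response matrix")
  Q <- validate_qmatrix(Q)
  alpha <- check_binary_matrix(alpha, "attribute matrix")
  if (nrow(Y) != nrow(alpha) || ncol(Y) != nrow(Q) || ncol(alpha) != ncol(Q)) {
    stop("Y, Q, and alpha have inconsistent dimensions", call. = FALSE)
  }
  P <- class_probability_matrix(Q, item_params)   # 2^K x I
  cls <- profile_class(alpha)
  ll <- 0
  for (i in seq_len(ncol(Y))) {
    p <- pmin(pmax(P[cls, i], eps), 1 - eps)
    ll <- ll + sum(Y[, i] * log(p) + (1 - Y[, i]) * log1p(-p))
  }
  ll
}

# Full-class probability matrix (2^K rows, I columns): each item's reduced
# pattern probabilities expanded to all attribute classes.
class_probability_matrix <- function(Q, item_params) {
  K <- ncol(Q)
  C <- 2L^K
  grid <- profile_grid(K)
  I <- nrow(Q)
  P <- matrix(NA_real_, C, I)
  for (i in seq_len(I)) {
    q <- Q[i, ]
    red <- pattern_probabilities(item_params$model[[i]], q, item_params$par[[i]])
    idx <- as.integer(grid[, which(q == 1), drop = FALSE] %*%
                        2L^(seq_len(sum(q)) - 1L)) + 1L
    P[, i] <- red[idx]
  }
  P
}
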