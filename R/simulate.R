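# Generators for the two canonical simulation designs and their building
# blocks. All randomness respects an optional `seed` argument; when supplied,
# the global RNG state is restored afterwards, so calls are reproducible in
# isolation without disturbing the caller's stream.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Canonical Q-matrices for the shipped simulation designs
#'
#' Deterministic Q-matrices satisfying the identifiability constraints of the
#' two study designs: at least one K-by-K identity submatrix, every attribute
#' measured at least three times, a unidimensional prefix (the first `I/3`
#' items for `"study1"`, the first 10 items — two stacked identity blocks —
#' for `"study2"`), and a remainder of two- and three-dimensional items. In
#' the `"study2"` design items 11-30 form five blocks of four items with
#' identical q-vectors across blocks, so different response models can be
#' attached to identical attribute requirements.
#'
#' @param I number of items (study1: 15 or 30; study2: 30).
#' @param K number of attributes (5 for the shipped designs).
#' @param design `"study1"` or `"study2"`.
#' @return Binary I-by-K matrix.
#' @export
build_qmatrix <- function(I, K = 5, design = c("study1", "study2")) {
  design <- match.arg(design)
  if (design == "study1") {
    if (I %% 15L != 0L) stop("study1 designs need I divisible by 15", call. = FALSE)
    if (I < 2L * K) stop("study1 designs need I >= 2K", call. = FALSE)
    uni <- I %/% 3L
    rows <- lapply(seq_len(uni), function(i) as.integer(seq_len(K) == ((i - 1L) %% K + 1L)))
    n_multi <- I - uni
    pairs <- lapply(seq_len(K), function(j) {
      a <- j; b <- j %% K + 1L
      as.integer(seq_len(K) %in% c(a, b))
    })
    triples <- lapply(seq_len(K), function(j) {
      idx <- ((j - 1L + 0:2) %% K) + 1L
      as.integer(seq_len(K) %in% idx)
    })
    multi <- vector("list", n_multi)
    half <- n_multi %/% 2L
    for (j in seq_len(half)) multi[[j]] <- pairs[[(j - 1L) %% K + 1L]]
    for (j in seq_len(n_multi - half)) multi[[half + j]] <- triples[[(j - 1L) %% K + 1L]]
    Q <- do.call(rbind, c(rows, multi))
  } else {
    if (I != 6L * K) stop("the study2 design is defined for I = 6K", call. = FALSE)
    ident <- diag(1L, K)
    block <- rbind(
      as.integer(seq_len(K) %in% c(1L, 2L)),
      as.integer(seq_len(K) %in% c(3L, 4L)),
      as.integer(seq_len(K) %in% c(1L, 3L, 5L)),
      as.integer(seq_len(K) %in% c(2L, 4L, 5L))
    )
    Q <- rbind(ident, ident, block, block, block, block, block)
  }
  Q <- validate_qmatrix(Q)
  stopifnot(all(colSums(Q) >= 3L))
  Q
}

#' Draw item quality parameters
#'
#' Draws per-item guessing and slip probabilities by inverse-logit of a
#' bivariate normal with mean `-2.197` (higher quality, mean probability
#' 0.100) or `-1.386` (lower quality, mean probability 0.200), unit variances,
#' and correlation `-0.6`. Pairs violating the monotonicity constraint
#' `g < 1 - s` are redrawn.
#'
#' @param I number of items.
#' @param quality `"higher"` or `"lower"`.
#' @param seed optional integer seed.
#' @return Tibble with columns `g` and `s` (`I` rows).
#' @export
draw_item_quality <- function(I, quality = c("higher", "lower"), seed = NULL) {
  quality <- match.arg(quality)
  mu <- rep(if (quality == "higher") -2.197 else -1.386, 2L)
  Sigma <- matrix(c(1, -0.6, -0.6, 1), 2L)
  with_seed(seed, {
    draw <- function(n) plogis(MASS::mvrnorm(n, mu, Sigma))
    gs <- draw(I)
    if (I == 1L) gs <- matrix(gs, 1L)
    bad <- gs[, 1L] >= 1 - gs[, 2L]
    while (any(bad)) {
      repl <- draw(sum(bad))
      if (sum(bad) == 1L) repl <- matrix(repl, 1L)
      gs[bad, ] <- repl
      bad <- gs[, 1L] >= 1 - gs[, 2L]
    }
    tibble::tibble(g = gs[, 1L], s = gs[, 2L])
  })
}

#' Assign item-level mixing proportions by design block
#'
#' Items `1 .. I/3` are unidimensional and get `tau = (1, 0, 0)` (the
#' conjunctive rule is forced where all rules coincide). Under `"uniform"`
#' mixing the remaining items get `(1/3, 1/3, 1/3)`; under `"skew"` mixing,
#' items `I/3+1 .. 8I/15` get `(0.6, 0.2, 0.2)`, items `8I/15+1 .. 11I/15`
#' get `(0.2, 0.6, 0.2)`, and items `11I/15+1 .. I` get `(0.2, 0.2, 0.6)`.
#'
#' @param I number of items; must be divisible by 15 so the block boundaries
#'   are integers.
#' @param mixing `"uniform"` or `"skew"`.
#' @return List of `I` length-3 numeric vectors.
#' @export
assign_mixing_proportions <- function(I, mixing = c("uniform", "skew")) {
  mixing <- match.arg(mixing)
  if (I %% 15L != 0L) stop("mixing blocks need I divisible by 15", call. = FALSE)
  uni <- I %/% 3L
  tau <- vector("list", I)
  for (i in seq_len(uni)) tau[[i]] <- c(1, 0, 0)
  if (mixing == "uniform") {
    for (i in (uni + 1L):I) tau[[i]] <- c(1, 1, 1) / 3
  } else {
    b1 <- (uni + 1L):(8L * I %/% 15L)
    b2 <- (8L * I %/% 15L + 1L):(11L * I %/% 15L)
    b3 <- (11L * I %/% 15L + 1L):I
    for (i in b1) tau[[i]] <- c(0.6, 0.2, 0.2)
    for (i in b2) tau[[i]] <- c(0.2, 0.6, 0.2)
    for (i in b3) tau[[i]] <- c(0.2, 0.2, 0.6)
  }
  tau
}

#' Draw attribute profiles
#'
#' Under the `"unstructured"` latent structural model each of the `2^K`
#' profiles is equiprobable. Under `"mvn"`, continuous latent traits are drawn
#' from a K-variate normal with zero means, unit variances, and common
#' correlation `rho`, and `alpha_nk = 1` iff `theta_nk >= 0`; marginal mastery
#' probability is 0.5 per attribute and the tetrachoric correlation between
#' attributes is approximately `rho`.
#'
#' @param N number of persons.
#' @param K number of attributes.
#' @param lsm `"unstructured"` or `"mvn"`.
#' @param rho latent correlation for `"mvn"`.
#' @param seed optional integer seed.
#' @return Binary N-by-K matrix.
#' @export
draw_attributes <- function(N, K = 5, lsm = c("unstructured", "mvn"), rho = 0.6,
                            seed = NULL) {
  lsm <- match.arg(lsm)
  with_seed(seed, {
    if (lsm == "unstructured") {
      cls <- sample.int(2L^K, N, replace = TRUE)
      profile_grid(K)[cls, , drop = FALSE]
    } else {
      Sigma <- matrix(rho, K, K); diag(Sigma) <- 1
      theta <- MASS::mvrnorm(N, rep(0, K), Sigma)
      m <- matrix(as.integer(theta >= 0), N, K)
      m
    }
  })
}

#' Build an item-parameter table
#'
#' @param model character vector of per-item model tags.
#' @param par list of `"dcm_pars"` objects, one per item.
#' @return Tibble with columns `item`, `model`, `par`.
#' @export
item_params_tbl <- function(model, par) {
  stopifnot(length(model) == length(par))
  tibble::tibble(item = seq_along(par), model = toupper(model), par = par)
}

#' Simulate dichotomous responses
#'
#' Draws `y_ni ~ Bernoulli(p_ni)` where `p_ni` is each item's model-implied
#' correct-response probability at person `n`'s attribute profile.
#'
#' @param Q binary I-by-K Q-matrix.
#' @param alpha binary N-by-K attribute matrix.
#' @param item_params tibble from [item_params_tbl()] or a shipped design.
#' @param seed optional integer seed; a fixed seed yields a bit-identical
#'   matrix on re-run.
#' @return Binary N-by-I response matrix.
#' @export
simulate_responses <- function(Q, alpha, item_params, seed = NULL) {
  Q <- validate_qmatrix(Q)
  alpha <- check_binary_matrix(alpha, "attribute matrix")
  if (ncol(alpha) != ncol(Q)) stop("alpha and Q column counts differ", call. = FALSE)
  if (nrow(Q) != nrow(item_params)) stop("item_params does not match Q", call. = FALSE)
  P <- class_probability_matrix(Q, item_params)
  cls <- profile_class(alpha)
  with_seed(seed, {
    N <- nrow(alpha); I <- nrow(Q)
    Y <- matrix(0L, N, I)
    for (i in seq_len(I)) Y[, i] <- rbinom(N, 1L, P[cls, i])
    Y
  })
}

#' Fixed item parameters for the six model-comparison test situations
#'
#' Returns the per-item generating models and parameters for one of the six
#' test situations of the model-comparison design. Correct-response
#' probabilities are bounded in `[0.1, 0.9]` throughout: `g = s = 0.1` for the
#' deterministic-input models; for the ACDM, intercept 0.1 with main effects
#' (0.5, 0.3) for two-dimensional and (0.35, 0.25, 0.2) for three-dimensional
#' items; for the GDINA, intercept 0.1 with effects (0.35, 0.25; two-way 0.2)
#' for two-dimensional and (0.15, 0.1, 0.05; two-way 0.05, 0.1, 0.15;
#' three-way 0.2) for three-dimensional items. The first ten (unidimensional)
#' items are always DINA. In situation `"separately"`, items 11-14 are DINA,
#' 15-18 DINO, 19-22 DINR, 23-26 ACDM, and 27-30 GDINA.
#'
#' @param situation one of `"conjunctive"`, `"disjunctive"`, `"ratio"`,
#'   `"compensatory"`, `"fuzzily"`, `"separately"`.
#' @param Q the study2 Q-matrix (defaults to `build_qmatrix(30, 5, "study2")`).
#' @return Tibble with columns `item`, `model`, `par`.
#' @export
study2_item_params <- function(situation = c("conjunctive", "disjunctive", "ratio",
                                             "compensatory", "fuzzily", "separately"),
                               Q = build_qmatrix(30, 5, "study2")) {
  situation <- match.arg(situation)
  I <- nrow(Q)
  dims <- rowSums(Q)
  acdm_par <- function(Kstar) {
    if (Kstar == 2) additive_pars(0.1, c(0.5, 0.3))
    else additive_pars(0.1, c(0.35, 0.25, 0.2))
  }
  gdina_par <- function(Kstar) {
    if (Kstar == 2) additive_pars(0.1, c(0.35, 0.25), 0.2)
    else additive_pars(0.1, c(0.15, 0.1, 0.05), c(0.05, 0.1, 0.15, 0.2))
  }
  det_par <- dinmix_pars(0.1, 0.1)
  model_of <- function(i) {
    if (dims[i] == 1) return("DINA")
    switch(situation,
      conjunctive  = "DINA",
      disjunctive  = "DINO",
      ratio        = "DINR",
      compensatory = "ACDM",
      fuzzily      = "GDINA",
      separately   = c(rep("DINA", 4), rep("DINO", 4), rep("DINR", 4),
                       rep("ACDM", 4), rep("GDINA", 4))[i - 10L]
    )
  }
  model <- vapply(seq_len(I), model_of, character(1))
  par <- lapply(seq_len(I), function(i) {
    switch(model[i],
      ACDM  = acdm_par(dims[i]),
      GDINA = gdina_par(dims[i]),
      det_par
    )
  })
  item_params_tbl(model, par)
}

#' Simulate a dataset from the parameter-recovery design
#'
#' Generates a Q-matrix, item parameters, attribute profiles, and responses
#' under the five-factor recovery design: sample size `N` (500 or 1000), test
#' length `I` (15 or 30), item quality (`g`, `s` drawn on the logit scale, see
#' [draw_item_quality()]), mixing type ([assign_mixing_proportions()]), and
#' latent structural model ([draw_attributes()]). The generating model is
#' DINMix for every item, with `tau` fixed at `(1, 0, 0)` on the
#' unidimensional prefix.
#'
#' @param N sample size.
#' @param I test length (divisible by 15).
#' @param item_quality `"higher"` or `"lower"`.
#' @param mixing `"uniform"` or `"skew"`.
#' @param lsm `"unstructured"` or `"mvn"`.
#' @param K number of attributes.
#' @param seed optional integer master seed; stage substreams are derived
#'   from it deterministically.
#' @return A list of class `"dcm_sim"` with elements `Y`, `Q`, `alpha`,
#'   `item_params`, and `design`.
#' @export
sim_study1 <- function(N = 500, I = 15, item_quality = "higher",
                       mixing = "uniform", lsm = "unstructured", K = 5,
                       seed = NULL) {
  seeds <- derive_seeds(seed, 3L)
  Q <- build_qmatrix(I, K, "study1")
  gs <- draw_item_quality(I, item_quality, seed = seeds[[1L]])
  tau <- assign_mixing_proportions(I, mixing)
  par <- lapply(seq_len(I), function(i) dinmix_pars(gs$g[i], gs$s[i], tau[[i]]))
  item_params <- item_params_tbl(rep("DINMIX", I), par)
  alpha <- draw_attributes(N, K, lsm, seed = seeds[[2L]])
  Y <- simulate_responses(Q, alpha, item_params, seed = seeds[[3L]])
  structure(list(Y = Y, Q = Q, alpha = alpha, item_params = item_params,
                 design = list(study = "study1", N = N, I = I, K = K,
                               item_quality = item_quality, mixing = mixing,
                               lsm = lsm, seed = seed)),
            class = "dcm_sim")
}

#' Simulate a dataset from the model-comparison design
#'
#' Fixed item parameters (see [study2_item_params()]), unstructured attribute
#' profiles, `K = 5`, and the two-identity-block Q-matrix.
#'
#' @param situation test situation tag; see [study2_item_params()].
#' @param N sample size.
#' @param K number of attributes.
#' @param seed optional integer master seed.
#' @return A `"dcm_sim"` list as in [sim_study1()].
#' @export
sim_study2 <- function(situation = "conjunctive", N = 1000, K = 5, seed = NULL) {
  seeds <- derive_seeds(seed, 2L)
  Q <- build_qmatrix(6L * K, K, "study2")
  item_params <- study2_item_params(situation, Q)
  alpha <- draw_attributes(N, K, "unstructured", seed = seeds[[1L]])
  Y <- simulate_responses(Q, alpha, item_params, seed = seeds[[2L]])
  structure(list(Y = Y, Q = Q, alpha = alpha, item_params = item_params,
                 design = list(study = "study2", situation = situation, N = N,
                               I = nrow(Q), K = K, seed = seed)),
            class = "dcm_sim")
}

# Deterministic substream seeds below 2^31 derived from one master seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max, n)))
}

#' True-parameter table of a simulated dataset
#'
#' Flattens a `"dcm_sim"` object's item parameters into a tibble with one row
#' per item: `g`, `s`, `tau1..tau3` for deterministic-input items, additive
#' effects in `delta` list-column form otherwise.
#'
#' @param sim a `"dcm_sim"` object.
#' @return Tibble.
#' @export
true_params_tbl <- function(sim) {
  purrr::map2_dfr(sim$item_params$par, seq_len(nrow(sim$item_params)), function(p, i) {
    if (!is.null(p$g)) {
      tibble::tibble(item = i, model = sim$item_params$model[[i]],
                     g = p$g, s = p$s,
                     tau1 = p$tau[1L], tau2 = p$tau[2L], tau3 = p$tau[3L])
    } else {
      tibble::tibble(item = i, model = sim$item_params$model[[i]],
                     g = p$intercept, s = 1 - (p$intercept + sum(p$main) +
                                                 sum(p$interaction)),
                     tau1 = NA_real_, tau2 = NA_real_, tau3 = NA_real_)
    }
  })
}

#' Write a simulated dataset to CSV files
#'
#' Writes `responses.csv`, `qmatrix.csv`, `attributes.csv`, and
#' `item_params.csv` into `dir`.
#'
#' @param sim a `"dcm_sim"` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_csv(sim$Y, file.path(dir, "responses.csv"))
  write_matrix_csv(sim$Q, file.path(dir, "qmatrix.csv"))
  write_matrix_csv(sim$alpha, file.path(dir, "attributes.csv"))
  readr::write_csv(true_params_tbl(sim), file.path(dir, "item_params.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' @export
print.dcm_sim <- function(x, ...) {
  d <- x$design
  cat(sprintf("Simulated diagnostic dataset (%s): N = %d persons, I = %d items, K = %d attributes\n",
              d$study, nrow(x$Y), ncol(x$Y), ncol(x$Q)))
  invisible(x)
}
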