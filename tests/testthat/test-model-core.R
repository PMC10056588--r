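test_that("condensation-rule latent responses match their definitions", {
  # conjunctive: 1 iff every required attribute mastered
  expect_equal(latent_conjunctive(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(latent_conjunctive(c(1, 0, 0), c(1, 1, 1)), 0)
  expect_equal(latent_conjunctive(c(1, 0, 1), c(1, 0, 1)), 1)
  # disjunctive: 1 iff any required attribute mastered
  expect_equal(latent_disjunctive(c(0, 0, 0), c(1, 1, 1)), 0)
  expect_equal(latent_disjunctive(c(1, 0, 0), c(1, 1, 1)), 1)
  expect_equal(latent_disjunctive(c(0, 1, 0), c(1, 0, 1)), 0)
  # ratio: fraction of required attributes mastered
  expect_equal(latent_ratio(c(1, 0, 0), c(1, 1, 1)), 1 / 3)
  expect_equal(latent_ratio(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(latent_ratio(c(1, 1, 0), c(1, 1, 1)), 2 / 3)

  # brute force over all 8 profiles for q = (1,0,1): conjunctive is 1 only
  # when both required attributes are mastered
  profs <- oracle_profiles(3)
  expect_equal(latent_conjunctive(profs, c(1, 0, 1)),
               as.numeric(profs[, 1] == 1 & profs[, 3] == 1))

  expect_error(latent_conjunctive(c(1, 0), c(1, 1, 1)), "length")
  expect_error(latent_ratio(c(1, 0, 1), c(0, 0, 0)), "at least one")
})

test_that("mixed latent response is the tau-weighted rule combination", {
  expect_equal(mixed_latent_response(c(1, 0, 0), c(1, 1, 1), c(0.8, 0.1, 0.1)),
               0.8 * 0 + 0.1 * 1 + 0.1 / 3)
  expect_equal(mixed_latent_response(c(1, 1, 0), c(1, 1, 1), rep(1, 3) / 3),
               5 / 9)
  expect_equal(mixed_latent_response(c(1, 1, 1), c(1, 1, 1), c(0.2, 0.3, 0.5)), 1)
  expect_equal(mixed_latent_response(c(0, 0, 0), c(1, 1, 1), c(0.2, 0.3, 0.5)), 0)
  expect_error(mixed_latent_response(c(1, 0, 0), c(1, 1, 1), c(0.5, 0.4, 0.4)),
               "sum to 1")
})

test_that("response probability interpolates between g and 1 - s", {
  expect_equal(response_probability(0.1, 0.1, 0), 0.1)
  expect_equal(response_probability(0.1, 0.1, 1), 0.9)
  expect_equal(response_probability(0.2, 0.3, 0.5), 0.45)
  expect_error(response_probability(0.6, 0.5, 0.5), "g < 1 - s")
})

test_that("the mixed-rule worked example reproduces all printed columns", {
  q <- c(1, 1, 1)
  profs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  dina <- dinmix_probability(profs, q, 0.1, 0.1, c(1, 0, 0))
  dino <- dinmix_probability(profs, q, 0.1, 0.1, c(0, 1, 0))
  dinr <- dinmix_probability(profs, q, 0.1, 0.1, c(0, 0, 1))
  mix <- dinmix_probability(profs, q, 0.1, 0.1, c(0.8, 0.1, 0.1))
  expect_equal(round(dina, 3), c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.9))
  expect_equal(round(dino, 3), c(0.1, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9))
  expect_equal(round(dinr, 3), c(0.1, 0.367, 0.367, 0.367, 0.633, 0.633, 0.633, 0.9))
  expect_equal(round(mix, 3), c(0.1, 0.207, 0.207, 0.207, 0.233, 0.233, 0.233, 0.9))
})

test_that("degenerate mixing weights reduce the mixture to each pure model", {
  set.seed(41)
  profs <- oracle_profiles(5)
  for (rep in 1:5) {
    g <- runif(1, 0.01, 0.4)
    s <- runif(1, 0.01, min(0.4, 1 - g) - 0.01)
    q <- as.integer(runif(5) < 0.6)
    if (!any(q == 1)) q[1] <- 1L
    expect_equal(dinmix_probability(profs, q, g, s, c(1, 0, 0)),
                 vapply(seq_len(32), function(r)
                   oracle_detnoisy_p(profs[r, ], q, g, s, c(1, 0, 0)), numeric(1)))
    expect_equal(dinmix_probability(profs, q, g, s, c(0, 1, 0)),
                 g + (1 - s - g) * latent_disjunctive(profs, q))
    expect_equal(dinmix_probability(profs, q, g, s, c(0, 0, 1)),
                 g + (1 - s - g) * latent_ratio(profs, q))
  }
})

test_that("mixture probability is monotone in mastery and bounded by [g, 1-s]", {
  set.seed(42)
  for (rep in 1:10) {
    K <- sample(2:5, 1)
    q <- as.integer(runif(K) < 0.7); if (!any(q == 1)) q[1] <- 1L
    g <- runif(1, 0.01, 0.4); s <- runif(1, 0.01, min(0.5, 1 - g) - 0.01)
    tau <- as.numeric(rmultinom(1, 100, rep(1, 3))) / 100
    profs <- oracle_profiles(K)
    p <- dinmix_probability(profs, q, g, s, tau)
    expect_true(all(p >= g - 1e-12 & p <= 1 - s + 1e-12))
    # flipping any required attribute from 0 to 1 never decreases p
    for (r in seq_len(nrow(profs))) {
      for (k in which(q == 1 & profs[r, ] == 0)) {
        up <- profs[r, ]; up[k] <- 1
        expect_gte(dinmix_probability(up, q, g, s, tau), p[r])
      }
    }
    # corners
    expect_equal(p[which(rowSums(profs[, q == 1, drop = FALSE]) == 0)[1]], g)
    expect_equal(p[which(rowSums(profs[, q == 1, drop = FALSE]) == sum(q))[1]],
                 1 - s)
  }
})

test_that("additive probabilities accumulate mains and interactions", {
  expect_equal(additive_probability(c(1, 1, 0), c(1, 1, 0), 0.1, c(0.5, 0.3)), 0.9)
  expect_equal(
    additive_probability(c(1, 1, 1), c(1, 1, 1), 0.1, c(0.15, 0.1, 0.05),
                         c(0.05, 0.1, 0.15, 0.2)), 0.9)
  expect_equal(additive_probability(c(0, 0, 1), c(1, 1, 0), 0.1, c(0.5, 0.3)), 0.1)
  # mastering only attributes 1 and 3 of a 3-dim item earns that two-way term
  expect_equal(
    additive_probability(c(1, 0, 1), c(1, 1, 1), 0.1, c(0.15, 0.1, 0.05),
                         c(0.05, 0.1, 0.15, 0.2)),
    0.1 + 0.15 + 0.05 + 0.1)
  expect_error(additive_probability(c(1, 1), c(1, 1), 0.5, c(0.5, 0.3)),
               "outside")
})

test_that("pattern probabilities agree with per-profile calls for every model", {
  set.seed(43)
  qs <- list(c(1, 0, 0), c(1, 1, 0), c(0, 1, 1), c(1, 1, 1))
  for (q in qs) {
    Kstar <- sum(q)
    red <- oracle_profiles(Kstar)
    full <- matrix(0L, nrow(red), length(q)); full[, which(q == 1)] <- red
    g <- runif(1, 0.05, 0.3); s <- runif(1, 0.05, 0.3)
    tau <- c(0.5, 0.3, 0.2)
    for (model in c("DINA", "DINO", "DINR", "DINMIX")) {
      p <- pattern_probabilities(model, q, dinmix_pars(g, s, tau))
      tt <- switch(model, DINA = c(1, 0, 0), DINO = c(0, 1, 0),
                   DINR = c(0, 0, 1), DINMIX = tau)
      expect_equal(unname(p), dinmix_probability(full, q, g, s, tt))
    }
    if (Kstar >= 2) {
      main <- runif(Kstar, 0.05, 0.6 / Kstar)
      p <- pattern_probabilities("ACDM", q, additive_pars(0.1, main))
      expect_equal(unname(p), additive_probability(full, q, 0.1, main))
      nint <- 2^Kstar - Kstar - 1
      inter <- runif(nint, 0.01, 0.1 / nint)
      p <- pattern_probabilities("GDINA", q, additive_pars(0.1, main, inter))
      expect_equal(unname(p), additive_probability(full, q, 0.1, main, inter))
    }
  }
  # worked-example column, addressed by pattern label
  p <- pattern_probabilities("DINMIX", c(1, 1, 1),
                             dinmix_pars(0.1, 0.1, c(0.8, 0.1, 0.1)))
  expect_equal(round(p[["000"]], 3), 0.1)
  expect_equal(round(unname(p[c("100", "010", "001")]), 3), rep(0.207, 3))
  expect_equal(round(unname(p[c("110", "101", "011")]), 3), rep(0.233, 3))
  expect_equal(round(p[["111"]], 3), 0.9)
  # DINA: guessing everywhere except full mastery
  pd <- pattern_probabilities("DINA", c(1, 1, 1), dinmix_pars(0.1, 0.1))
  expect_equal(unname(pd), c(rep(0.1, 7), 0.9))
})

test_that("log-likelihood matches a naive double loop", {
  expect_equal(loglik_dcm(matrix(1), matrix(1),
                          item_params_tbl("DINA", list(dinmix_pars(0.5, 0.4))),
                          matrix(0)), log(0.5))
  # worked-example item, y = 1, profile (1,0,0)
  ip <- item_params_tbl("DINMIX", list(dinmix_pars(0.1, 0.1, c(0.8, 0.1, 0.1))))
  ll <- loglik_dcm(matrix(1), matrix(c(1, 1, 1), 1), ip, matrix(c(1, 0, 0), 1))
  expect_equal(ll, log(0.1 + 0.8 * (0.1 + 0.1 / 3)))
  # random 5 x 4 instance against the loop oracle
  set.seed(44)
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 1))
  ip <- item_params_tbl(
    c("DINA", "DINO", "DINMIX", "ACDM"),
    list(dinmix_pars(0.2, 0.1), dinmix_pars(0.1, 0.3),
         dinmix_pars(0.15, 0.2, c(0.5, 0.25, 0.25)),
         additive_pars(0.1, c(0.4, 0.3))))
  alpha <- oracle_profiles(2)[c(1, 2, 3, 4, 2), ]
  Y <- matrix(rbinom(20, 1, 0.5), 5, 4)
  Pni <- matrix(0, 5, 4)
  for (n in 1:5) {
    Pni[n, 1] <- oracle_detnoisy_p(alpha[n, ], Q[1, ], 0.2, 0.1, c(1, 0, 0))
    Pni[n, 2] <- oracle_detnoisy_p(alpha[n, ], Q[2, ], 0.1, 0.3, c(0, 1, 0))
    Pni[n, 3] <- oracle_detnoisy_p(alpha[n, ], Q[3, ], 0.15, 0.2, c(0.5, 0.25, 0.25))
    Pni[n, 4] <- 0.1 + 0.4 * alpha[n, 1] + 0.3 * alpha[n, 2]
  }
  expect_equal(loglik_dcm(Y, Q, ip, alpha), oracle_loglik(Y, Pni))
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(validate_qmatrix(rbind(c(0, 0), c(1, 0))), "requires no attributes")
  expect_error(validate_qmatrix(rbind(c(2, 0), c(1, 0))), "binary")
  expect_error(dinmix_pars(0.6, 0.5), "0 < g < 1 - s")
  expect_error(mixed_latent_response(c(1, 0), c(1, 1), c(0.5, 0.6, -0.1)),
               "sum to 1|non-negative")
})
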