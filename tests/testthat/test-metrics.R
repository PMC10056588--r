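test_that("bias and RMSE follow their definitions", {
  expect_equal(bias_rmse(c(0.2, 0.2), 0.1), list(bias = 0.1, rmse = 0.1))
  expect_equal(bias_rmse(c(0.0, 0.2), 0.1), list(bias = 0.0, rmse = 0.1))
  set.seed(51)
  est <- runif(30); tr <- runif(30)
  out <- bias_rmse(est, tr)
  expect_equal(out$bias, sum(est - tr) / 30)
  expect_equal(out$rmse, sqrt(sum((est - tr)^2) / 30))
  expect_error(bias_rmse(1:3, 1:2), "length")
})

test_that("classification rates match loop oracles and their ordering", {
  set.seed(52)
  a <- matrix(rbinom(500, 1, 0.5), 100, 5)
  b <- matrix(rbinom(500, 1, 0.5), 100, 5)
  expect_equal(accr(a, a), rep(1, 5))
  expect_equal(accr(a, 1 - a), rep(0, 5))
  expect_equal(pccr(a, a), 1)
  # naive counting oracle
  cnt <- numeric(5); whole <- 0
  for (n in 1:100) {
    for (k in 1:5) if (a[n, k] == b[n, k]) cnt[k] <- cnt[k] + 1
    if (all(a[n, ] == b[n, ])) whole <- whole + 1
  }
  expect_equal(accr(a, b), cnt / 100)
  expect_equal(pccr(a, b), whole / 100)
  # exact-profile match implies elementwise match
  expect_lte(pccr(a, b), min(accr(a, b)))
  # one wrong attribute in one of ten persons
  est <- matrix(0L, 10, 3); tru <- est; est[1, 2] <- 1L
  expect_equal(pccr(est, tru), 0.9)
  # invariance under consistent person reordering
  perm <- sample(100)
  expect_equal(accr(a[perm, ], b[perm, ]), accr(a, b))
  expect_equal(pccr(a[perm, ], b[perm, ]), pccr(a, b))
})

test_that("profile-proportion RMSE aggregates over replications and profiles", {
  tr <- rep(1 / 32, 32)
  out <- profile_proportion_rmse(rbind(tr, tr), tr)
  expect_equal(out$per_profile, rep(0, 32))
  est <- tr; est[1] <- est[1] + 0.02; est[2] <- est[2] - 0.02
  out <- profile_proportion_rmse(est, tr)
  expect_equal(out$per_profile[1:2], rep(0.02, 2))
  expect_equal(out$mean, 0.04 / 32)
  # random simplex draws against a direct recomputation
  set.seed(53)
  reps <- t(replicate(4, { x <- rexp(8); x / sum(x) }))
  tr8 <- rep(1 / 8, 8)
  out <- profile_proportion_rmse(reps, tr8)
  direct <- sqrt(colSums((reps - matrix(tr8, 4, 8, byrow = TRUE))^2) / 4)
  expect_equal(out$per_profile, direct)
  expect_error(profile_proportion_rmse(c(0.5, 0.4), c(0.5, 0.5)), "simplex")
})

test_that("DIC reduces to the plug-in deviance at a point-mass posterior", {
  fake <- list(deviance_draws = list(rep(123.4, 50), rep(123.4, 50)),
               plugin_deviance = 123.4)
  out <- dic(fake)
  expect_equal(out$pd, 0)
  expect_equal(out$dic, 123.4)
})

test_that("stored deviance and CPO accumulators match a two-pass recomputation", {
  dat <- tiny_sim(N = 20)
  fit <- dcm_fit(dat$Y, dat$Q, "DINMIX", chains = 1, iter = 150, burnin = 50,
                 alpha_thin = 1, seed = 54)
  m <- fit$par_draws[[1]]
  grid <- oracle_profiles(2)
  dev_r <- numeric(nrow(m))
  cpo_r <- matrix(0, 20, 5)
  for (d in seq_len(nrow(m))) {
    alpha_d <- grid[fit$alpha_draws[[1]][d, ], , drop = FALSE]
    ll <- 0
    for (n in 1:20) for (i in 1:5) {
      tau <- c(m[d, paste0("tau1[", i, "]")], m[d, paste0("tau2[", i, "]")],
               m[d, paste0("tau3[", i, "]")])
      p <- oracle_detnoisy_p(alpha_d[n, ], dat$Q[i, ],
                             m[d, paste0("g[", i, "]")],
                             m[d, paste0("s[", i, "]")], tau)
      p <- min(max(p, 1e-12), 1 - 1e-12)
      lik <- if (dat$Y[n, i] == 1) p else 1 - p
      ll <- ll + log(lik)
      cpo_r[n, i] <- cpo_r[n, i] + 1 / lik
    }
    dev_r[d] <- -2 * ll
  }
  expect_equal(dev_r, as.numeric(fit$deviance_draws[[1]]), tolerance = 1e-10)
  expect_equal(cpo_r, fit$cpo_sum, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("CPO indices use the harmonic-mean identity and are additive", {
  # ten-draw toy posterior for 2 persons x 2 items, built by direct arithmetic
  set.seed(55)
  lik <- array(runif(40, 0.2, 0.9), c(10, 2, 2))
  cpo_sum <- apply(1 / lik, c(2, 3), sum)
  fake <- structure(list(n_kept = 10, cpo_sum = cpo_sum), class = "dcm_fit")
  out <- lcpo(fake)
  harm <- 10 / cpo_sum
  expect_equal(out$log_cpo, log(harm))
  expect_equal(out$item, -2 * colSums(log(harm)))
  expect_equal(out$test, sum(out$item))
  # point mass: CPO equals the single likelihood, -2LCPO equals the deviance
  fake1 <- structure(list(n_kept = 1, cpo_sum = 1 / lik[1, , ]),
                     class = "dcm_fit")
  expect_equal(lcpo(fake1)$test, -2 * sum(log(lik[1, , ])))
})

test_that("DIC and glance cohere on a real fit", {
  dat <- tiny_sim(N = 40)
  fit <- dcm_fit(dat$Y, dat$Q, "DINMIX", chains = 2, iter = 300, burnin = 100,
                 seed = 56)
  out <- dic(fit)
  expect_equal(out$dic, out$dbar + out$pd)
  expect_gt(out$pd, 0)
  gl <- glance(fit)
  expect_equal(gl$DIC, out$dic)
  l <- lcpo(fit)
  expect_equal(sum(l$item), l$test)
  expect_equal(gl$lcpo_test, l$test)
})
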