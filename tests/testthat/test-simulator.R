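test_that("canonical Q-matrices satisfy the stated design constraints", {
  for (I in c(15, 30)) {
    Q <- build_qmatrix(I, 5, "study1")
    expect_equal(dim(Q), c(I, 5))
    expect_true(all(Q %in% 0:1))
    # identity submatrix at the top, unidimensional prefix of length I/3
    expect_equal(Q[1:5, ], diag(1L, 5), ignore_attr = TRUE)
    expect_true(all(rowSums(Q[seq_len(I / 3), , drop = FALSE]) == 1))
    expect_true(all(rowSums(Q[(I / 3 + 1):I, , drop = FALSE]) >= 2))
    expect_true(all(colSums(Q) >= 3))
  }
  Q2 <- build_qmatrix(30, 5, "study2")
  expect_equal(Q2[1:5, ], diag(1L, 5), ignore_attr = TRUE)
  expect_equal(Q2[6:10, ], diag(1L, 5), ignore_attr = TRUE)
  expect_true(all(colSums(Q2) >= 3))
  # the five 4-item model blocks share identical q-vectors
  for (b in 1:4) {
    expect_equal(Q2[10 + 4 * b + 1:4, ], Q2[11:14, ], ignore_attr = TRUE)
  }
  expect_error(build_qmatrix(16, 5, "study1"), "divisible")
})

test_that("item-quality draws respect the logit-scale design", {
  # the design means map to mean guessing/slip probabilities 0.1 and 0.2
  expect_equal(round(plogis(-2.197), 4), 0.1)
  expect_equal(round(plogis(-1.386), 4), 0.2)
  gs <- draw_item_quality(2000, "higher", seed = 5)
  expect_true(all(gs$g < 1 - gs$s))
  # the logit-scale location maps to the median; the mean sits above it
  # because the inverse-logit of a normal is positively skewed here
  expect_lt(abs(median(gs$g) - 0.1), 0.02)
  expect_lt(abs(median(gs$s) - 0.1), 0.02)
  expect_gt(mean(gs$g), median(gs$g))
  # negative correlation on the logit scale survives the redraw rule
  expect_lt(cor(qlogis(gs$g), qlogis(gs$s)), -0.4)
  gs2 <- draw_item_quality(2000, "lower", seed = 6)
  expect_lt(abs(median(gs2$g) - 0.2), 0.03)
  # determinism
  expect_identical(draw_item_quality(10, "higher", seed = 1),
                   draw_item_quality(10, "higher", seed = 1))
})

test_that("mixing-proportion blocks follow the design boundaries", {
  tau <- assign_mixing_proportions(15, "skew")
  expect_true(all(vapply(tau[1:5], identical, logical(1), c(1, 0, 0))))
  expect_true(all(vapply(tau[6:8], identical, logical(1), c(0.6, 0.2, 0.2))))
  expect_true(all(vapply(tau[9:11], identical, logical(1), c(0.2, 0.6, 0.2))))
  expect_true(all(vapply(tau[12:15], identical, logical(1), c(0.2, 0.2, 0.6))))
  tau_u <- assign_mixing_proportions(30, "uniform")
  expect_true(all(vapply(tau_u[11:30], function(t) all(t == 1 / 3), logical(1))))
  expect_true(all(vapply(tau_u, sum, numeric(1)) == 1))
  expect_error(assign_mixing_proportions(16, "uniform"), "divisible")
})

test_that("attribute generators produce the intended latent structure", {
  a <- draw_attributes(20000, 5, "unstructured", seed = 7)
  freq <- tabulate(dinmixr:::profile_class(a), 32) / 20000
  expect_true(all(abs(freq - 1 / 32) < 4 * sqrt((1 / 32) * (31 / 32) / 20000)))
  m <- draw_attributes(20000, 5, "mvn", rho = 0.6, seed = 8)
  expect_true(all(abs(colMeans(m) - 0.5) < 0.02))
  # closed-form tetrachoric estimate for zero thresholds:
  # rho = sin(2 * pi * (p11 - 1/4))
  p11 <- mean(m[, 1] == 1 & m[, 2] == 1)
  expect_lt(abs(sin(2 * pi * (p11 - 0.25)) - 0.6), 0.05)
})

test_that("simulated responses have the model-implied item means", {
  # all-masters answering a DINA item: mean ~ 1 - s
  Q <- matrix(c(1, 1), 1, 2)
  ip <- item_params_tbl("DINA", list(dinmix_pars(0.1, 0.1)))
  alpha <- matrix(1L, 4000, 2)
  Y <- simulate_responses(Q, alpha, ip, seed = 9)
  expect_lt(abs(mean(Y) - 0.9), 0.02)
  # worked-example item under uniform profiles: mean of its probability
  # column, (0.1 + 3 * 31/150 + 3 * 7/30 + 0.9) / 8 = 0.29
  Q3 <- matrix(c(1, 1, 1), 1, 3)
  ip3 <- item_params_tbl("DINMIX", list(dinmix_pars(0.1, 0.1, c(0.8, 0.1, 0.1))))
  alpha3 <- draw_attributes(20000, 3, "unstructured", seed = 10)
  Y3 <- simulate_responses(Q3, alpha3, ip3, seed = 11)
  expect_lt(abs(mean(Y3) - 0.29), 0.01)
  # determinism: same seed, bit-identical output
  s1 <- sim_study1(N = 50, I = 15, seed = 3)
  s2 <- sim_study1(N = 50, I = 15, seed = 3)
  expect_identical(s1$Y, s2$Y)
  expect_identical(s1$alpha, s2$alpha)
})

test_that("fixed model-comparison parameter sets match the printed values", {
  Q <- build_qmatrix(30, 5, "study2")
  dims <- rowSums(Q)
  comp <- study2_item_params("compensatory", Q)
  i3 <- which(dims == 3)[1]
  expect_equal(comp$par[[i3]]$main, c(0.35, 0.25, 0.2))
  i2 <- which(dims == 2)[1]
  expect_equal(comp$par[[i2]]$main, c(0.5, 0.3))
  fuz <- study2_item_params("fuzzily", Q)
  expect_equal(fuz$par[[i2]]$main, c(0.35, 0.25))
  expect_equal(fuz$par[[i2]]$interaction, 0.2)
  expect_equal(fuz$par[[i3]]$main, c(0.15, 0.1, 0.05))
  expect_equal(fuz$par[[i3]]$interaction, c(0.05, 0.1, 0.15, 0.2))
  sep <- study2_item_params("separately", Q)
  expect_equal(sep$model[11:30],
               rep(c("DINA", "DINO", "DINR", "ACDM", "GDINA"), each = 4))
  expect_true(all(sep$model[1:10] == "DINA"))
  # every item's full-mastery probability is 0.9, no-mastery probability 0.1
  for (situation in c("conjunctive", "disjunctive", "ratio", "compensatory",
                      "fuzzily", "separately")) {
    ip <- study2_item_params(situation, Q)
    for (i in seq_len(30)) {
      p <- pattern_probabilities(ip$model[i], Q[i, ], ip$par[[i]])
      expect_equal(unname(p[1]), 0.1)
      expect_equal(unname(p[length(p)]), 0.9)
    }
  }
})

test_that("datasets round-trip through the CSV writers and readers", {
  sim <- sim_study1(N = 25, I = 15, seed = 12)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  expect_identical(read_matrix_csv(file.path(dir, "responses.csv"), "response"),
                   sim$Y)
  expect_identical(read_matrix_csv(file.path(dir, "qmatrix.csv"), "q"), sim$Q)
  expect_identical(read_matrix_csv(file.path(dir, "attributes.csv"), "attribute"),
                   sim$alpha)
  # a non-binary cell is reported with its location
  bad <- file.path(dir, "bad.csv")
  writeLines(c("0,1", "2,0"), bad)
  expect_error(read_matrix_csv(bad, "response"), "row 2, column 1")
})
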