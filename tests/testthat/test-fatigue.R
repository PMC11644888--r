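test_that("FSAS totals span 10 to 50 and reject invalid forms", {
  expect_equal(score_fsas(rep(1, 10)), 10)
  expect_equal(score_fsas(rep(5, 10)), 50)
  expect_equal(score_fsas(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)), 30)

  # one form per row
  m <- rbind(rep(1, 10), rep(5, 10))
  expect_equal(score_fsas(m), c(10, 50))

  # optional reverse scoring flips items 4 and 10
  expect_equal(score_fsas(rep(1, 10), reverse_items = TRUE), 8 + 2 * 5)

  expect_error(score_fsas(rep(6, 10)), "1..5")
  expect_error(score_fsas(rep(1, 9)), "exactly 10")
  expect_error(score_fsas(c(rep(1, 9), 2.5)), "integers")
})

test_that("relative-error accuracy follows its closed form", {
  expect_equal(fatigue_accuracy(c(20, 30), c(20, 30)), 100)
  expect_equal(fatigue_accuracy(11, 10), 90)
  expect_equal(fatigue_accuracy(20, 10), 0)
  expect_equal(fatigue_accuracy(30, 10), -100)

  # scale consistency: common positive rescaling changes nothing
  p <- c(12, 28, 41)
  f <- c(15, 25, 40)
  expect_equal(fatigue_accuracy(p, f), fatigue_accuracy(3.7 * p, 3.7 * f))

  # the signed variant lets errors cancel
  expect_equal(fatigue_accuracy(c(11, 9), c(10, 10), signed = TRUE), 100)
  expect_lt(fatigue_accuracy(c(11, 9), c(10, 10)), 100)

  expect_error(fatigue_accuracy(1, 0), "positive")
  expect_error(fatigue_accuracy(c(1, 2), 1), "equal")
})

test_that("the network recovers a noiseless monotone mapping", {
  d <- generate_feature_dataset(2000,
    coefs = c(intercept = 10, closing = 80, opening = 0, idle = 0),
    noise_sd = 0, seed = 13
  )
  ev <- evaluate_fatigue(d, seed = 17)
  expect_gte(ev$accuracy, 99)
  # on training points of the noiseless regime, within 2 scale points
  pred <- predict(ev$network, d)
  expect_lt(max(abs(pred - d$scale)), 2)
  expect_true(all(pred >= 10 & pred <= 50))
})

test_that("training is deterministic and insensitive to sample order", {
  d <- generate_feature_dataset(200, noise_sd = 0.5, seed = 23)
  n1 <- fit_fatigue_network(d, iterations = 400, seed = 9)
  n2 <- fit_fatigue_network(d, iterations = 400, seed = 9)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$loss, n2$loss)

  # full-batch gradients do not depend on row order
  perm <- withr::with_seed(1, sample(nrow(d)))
  n3 <- fit_fatigue_network(d[perm, ], iterations = 400, seed = 9)
  probe <- generate_feature_dataset(50, seed = 99)
  expect_lt(max(abs(predict(n1, probe) - predict(n3, probe))), 1e-6)
})

test_that("the loss trajectory descends and stabilizes", {
  d <- generate_feature_dataset(1500, seed = 29)
  net <- fit_fatigue_network(d, iterations = 1600, seed = 31)
  expect_lt(net$loss[1500], net$loss[100])
  # plateau: little relative improvement over the last stretch
  expect_lt(
    (net$loss[1500] - net$loss[1600]) / net$loss[1500],
    0.05
  )
})

test_that("tidy and glance summarise the 3-5-1 architecture", {
  d <- generate_feature_dataset(100, seed = 37)
  net <- fit_fatigue_network(d, iterations = 50, seed = 1)
  td <- tidy(net)
  expect_identical(nrow(td), 5L * 4L + 6L) # (3 weights + bias) x 5, 5 + bias
  expect_setequal(unique(td$layer), c("hidden", "output"))
  g <- glance(net)
  expect_identical(g$iterations, 50)
  expect_identical(g$n_train, 100L)
  expect_warning(
    fit_fatigue_network(
      dplyr::mutate(d, idle_s = 1),
      iterations = 10, seed = 1
    ),
    "constant"
  )
})

test_that("an established MLP fit agrees on the noiseless recovery task", {
  skip_if_not_installed("nnet")
  d <- generate_feature_dataset(2000,
    coefs = c(intercept = 10, closing = 80, opening = 0, idle = 0),
    noise_sd = 0, seed = 13
  )
  X <- scale(as.matrix(d[c("closing_s", "opening_s", "idle_s")]))
  y01 <- (d$scale - 10) / 40
  ref <- withr::with_seed(
    1,
    nnet::nnet(X, y01, size = 5, linout = TRUE, trace = FALSE, maxit = 500)
  )
  acc_ref <- fatigue_accuracy(pmin(pmax(predict(ref, X), 0), 1) * 40 + 10, d$scale)
  ours <- evaluate_fatigue(d, seed = 17)
  expect_gte(acc_ref, 99)
  expect_lt(abs(acc_ref - ours$accuracy), 2)
})
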