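test_that("squared-exponential covariance matches hand-computed values", {
  K <- sq_exp_cov(c(0, sqrt(2)), c(0, sqrt(2)), theta1 = 1, length_scale = 1,
                  noise_var = 0.25, add_noise_diag = TRUE)
  expect_equal(K[1, 1], 1.25)                 # theta1 + sigma_n^2 at zero distance
  expect_equal(K[1, 2], exp(-1))              # |dx| = sqrt(2), l = 1
  expect_equal(K, t(K))
  expect_lt(sq_exp_cov(0, 1e6, 2, 5.4)[1, 1], 1e-300)
  expect_error(sq_exp_cov(0, 0, theta1 = -1, length_scale = 1),
               class = "prosthermal_validation_error")
})

test_that("covariance of arbitrary inputs is positive definite after jitter", {
  set.seed(3)
  for (i in 1:5) {
    x <- c(runif(40, 0, 10), runif(10, 0, 10))
    x[41:50] <- x[1:10]                       # exact duplicates
    K <- sq_exp_cov(x, x, theta1 = 2, length_scale = 5.4)
    ch <- prosthermal:::chol_with_jitter(K)
    expect_true(all(diag(ch$L) > 0))
    expect_lte(ch$jitter, 1e-6)
  }
})

test_that("log marginal likelihood matches closed form and a dense-solve oracle", {
  # single observation at zero with unit total variance: -log(2*pi)/2
  st <- prosthermal:::gp_objective(c(log(0.5), log(0.5)), x = 0, yc = 0,
                                   length_scale = 1, want_grad = FALSE)
  expect_equal(st$lml, -0.5 * log(2 * pi), tolerance = 1e-8)

  set.seed(9)
  x <- runif(20, 0, 10)
  y <- sin(x) + rnorm(20, 0, 0.1)
  yc <- y - mean(y)
  theta1 <- 1.3; nv <- 0.04
  st <- prosthermal:::gp_objective(c(log(theta1), log(nv)), x, yc, 2,
                                   want_grad = FALSE)
  K <- sq_exp_cov(x, x, theta1, 2, nv, add_noise_diag = TRUE) +
    diag(st$jitter, 20)
  lml_dense <- -0.5 * drop(yc %*% solve(K, yc)) -
    0.5 * determinant(K)$modulus[1] - 10 * log(2 * pi)
  expect_equal(st$lml, lml_dense, tolerance = 1e-8)
})

test_that("inflating the noise on near-noiseless data lowers the evidence", {
  x <- seq(0, 10, length.out = 30)
  y <- sin(x / 3)
  yc <- y - mean(y)
  lml1 <- prosthermal:::gp_objective(c(0, log(1)), x, yc, 2,
                                     want_grad = FALSE)$lml
  lml2 <- prosthermal:::gp_objective(c(0, log(4)), x, yc, 2,
                                     want_grad = FALSE)$lml
  expect_lt(lml2, lml1)
})

test_that("fitting clamps the length scale and never worsens the evidence", {
  set.seed(21)
  x <- runif(120, 24, 32)
  y <- smooth_fn(x) + rnorm(120, 0, 0.1)
  fit <- gp_fit(tibble::tibble(x = x, y = y), "x", "y", length_scale = 5.4)
  expect_identical(fit$hyper$length_scale, 5.4)
  expect_gte(fit$log_marginal_likelihood, fit$log_marginal_likelihood_init)
  expect_equal(fit$mean_offset, mean(y))

  expect_error(gp_fit(tibble::tibble(x = rep(1, 10), y = rnorm(10)),
                      "x", "y", length_scale = 5.4),
               class = "prosthermal_validation_error")
  expect_error(gp_fit(tibble::tibble(x = 1, y = 2), "x", "y", 5.4),
               class = "prosthermal_validation_error")
})

test_that("fitted noise recovers the generating noise level", {
  set.seed(5)
  x <- runif(300, 24, 32)
  y <- smooth_fn(x) + rnorm(300, 0, 0.1)
  fit <- gp_fit(tibble::tibble(x = x, y = y), "x", "y", length_scale = 5.4)
  expect_gte(sqrt(fit$hyper$noise_var), 0.05)
  expect_lte(sqrt(fit$hyper$noise_var), 0.2)
})

test_that("posterior mean and variance equal a dense-inverse oracle", {
  set.seed(7)
  x <- runif(30, 0, 10)
  y <- sin(x) + rnorm(30, 0, 0.1)
  fit <- gp_fit(tibble::tibble(x = x, y = y), "x", "y", length_scale = 1.5)
  h <- fit$hyper
  xs <- seq(-1, 11, length.out = 60)
  K <- sq_exp_cov(x, x, h$theta1, h$length_scale, h$noise_var,
                  add_noise_diag = TRUE) + diag(fit$jitter, 30)
  Ks <- sq_exp_cov(x, xs, h$theta1, h$length_scale)
  mu <- drop(crossprod(Ks, solve(K, y - fit$mean_offset))) + fit$mean_offset
  va <- h$theta1 + h$noise_var - colSums(Ks * solve(K, Ks))
  pr <- predict(fit, xs)
  expect_equal(pr$mean, mu, tolerance = 1e-8)
  expect_equal(pr$variance, va, tolerance = 1e-8)
  # posterior never exceeds the prior variance
  expect_true(all(pr$variance <= h$theta1 + h$noise_var + 1e-12))
  expect_equal(pr$ci95_high - pr$mean, qnorm(0.975) * sqrt(pr$variance))
})

test_that("predictions interpolate training data and revert to the prior far away", {
  x <- seq(0, 10, length.out = 25)
  y <- sin(x)
  m <- prosthermal:::gp_model_from_hyper(x, y, theta1 = 1, length_scale = 1.5,
                                         noise_var = 1e-8)
  at_train <- predict(m, x[7])
  expect_lt(abs(at_train$mean - y[7]), 1e-3)

  far <- predict(m, 1e4)
  expect_lt(abs(far$mean - m$mean_offset), 1e-10)
  expect_equal(far$variance, 1 + 1e-8, tolerance = 1e-10)
})

test_that("evaluation metrics are computed per the definitions", {
  pr <- tibble::tibble(mean = c(30, 31, 32), variance = 0.04,
                       ci95_low = c(30, 31, 32) - 0.392,
                       ci95_high = c(30, 31, 32) + 0.392)
  same <- gp_evaluate(pr, c(30, 31, 32))
  expect_equal(same$max_abs_err, 0)
  expect_equal(same$rmse, 0)
  expect_equal(same$ci95_coverage, 1)

  off <- gp_evaluate(pr, c(30.1, 31.5, 32))
  expect_equal(off$max_abs_err, 0.5)
  expect_equal(off$rmse, sqrt(mean(c(0.1, 0.5, 0)^2)))
  expect_equal(off$ci95_coverage, 2 / 3)
  expect_error(gp_evaluate(pr, 1:4), class = "prosthermal_validation_error")
})

test_that("gp_fit supports broom-style accessors and plotting", {
  set.seed(2)
  x <- runif(60, 24, 32)
  y <- smooth_fn(x) + rnorm(60, 0, 0.1)
  fit <- gp_fit(tibble::tibble(x = x, y = y), "x", "y", length_scale = 5.4)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "length_scale"], 5.4)
  expect_true(td$fixed[td$term == "length_scale"])
  gl <- glance(fit)
  expect_equal(gl$nobs, 60)
  expect_s3_class(autoplot(fit), "ggplot")
})
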