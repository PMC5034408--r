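#' Squared-exponential covariance
#'
#' The kernel used throughout the skin-temperature model:
#' `C(x_i, x_j) = theta1 * exp(-(x_i - x_j)^2 / (2 l^2))`, optionally plus
#' observation noise `noise_var` on the diagonal (the Kronecker delta term,
#' applied only when the two input sets are the same points). The length
#' scale `l` is the kernel width: in this method it is fixed to the
#' prosthesis stack's thermal time constant in minutes rather than fitted.
#'
#' @param x_a,x_b Numeric input vectors (liner temperatures, degrees C).
#' @param theta1 Signal variance (> 0).
#' @param length_scale Kernel width (> 0).
#' @param noise_var Observation noise variance (>= 0).
#' @param add_noise_diag Add `noise_var` to the diagonal; only meaningful
#'   when `x_a` and `x_b` are the same points.
#' @return A `length(x_a)` by `length(x_b)` covariance matrix.
#' @export
#' @examples
#' sq_exp_cov(c(0, sqrt(2)), c(0, sqrt(2)), theta1 = 1, length_scale = 1,
#'            noise_var = 0)
sq_exp_cov <- function(x_a, x_b, theta1, length_scale, noise_var = 0,
                       add_noise_diag = FALSE) {
  if (theta1 <= 0 || length_scale <= 0 || noise_var < 0) {
    abort("require theta1 > 0, length_scale > 0, noise_var >= 0",
          class = "prosthermal_validation_error")
  }
  d <- outer(x_a, x_b, "-")
  K <- theta1 * exp(-d^2 / (2 * length_scale^2))
  if (add_noise_diag) {
    if (length(x_a) != length(x_b)) {
      abort("add_noise_diag requires square covariance of one input set",
            class = "prosthermal_validation_error")
    }
    K <- K + diag(noise_var, length(x_a))
  }
  K
}

# Cholesky with jitter escalation 1e-10 -> 1e-6; beyond that the smallest
# eigenvalue is reported so the caller can see how non-PD the matrix is.
chol_with_jitter <- function(K, jitter0 = 1e-10, jitter_max = 1e-6) {
  jit <- jitter0
  repeat {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    if (jit >= jitter_max) {
      ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
      abort(sprintf(
        "covariance matrix is not positive definite even with jitter %.1e (smallest eigenvalue %.3e)",
        jit, ev), class = "prosthermal_numerical_error")
    }
    jit <- min(jit * 100, jitter_max)
  }
}

# lml and its gradient wrt (log theta1, log noise_var) at fixed length scale.
gp_objective <- function(par, x, yc, length_scale, want_grad = TRUE) {
  theta1 <- exp(par[1])
  noise_var <- exp(par[2])
  n <- length(x)
  Kf <- sq_exp_cov(x, x, theta1, length_scale, 0)
  K <- Kf + diag(noise_var, n)
  ch <- chol_with_jitter(K)
  L <- ch$L
  alpha <- chol_solve(L, yc)   # K^{-1} yc via two triangular solves
  lml <- -0.5 * sum(yc * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  out <- list(lml = lml, L = L, alpha = alpha, jitter = ch$jitter)
  if (want_grad) {
    Kinv <- chol2inv(L)
    W <- tcrossprod(alpha) - Kinv       # alpha alpha' - K^{-1}
    out$grad <- c(0.5 * sum(W * Kf),    # d lml / d log theta1
                  0.5 * sum(diag(W)) * noise_var)
  }
  out
}

chol_solve <- function(L, b) backsolve(L, backsolve(L, b, transpose = TRUE))

#' Fit a Gaussian-process skin-temperature model
#'
#' Gaussian-process regression of skin temperature on liner temperature
#' with the squared-exponential covariance of [sq_exp_cov()]. The length
#' scale is not fitted: it is clamped to a physical value, the thermal time
#' constant (minutes) of the liner+socket stack in use, which encodes how
#' sluggishly the liner tracks the limb. The remaining hyperparameters
#' (signal variance `theta1` and noise variance `noise_var`) are chosen by
#' maximising the log marginal likelihood with a quasi-Newton optimiser on
#' the log scale, which needs fewer iterations than a full three-parameter
#' search. Targets are centred on their mean before fitting and the offset
#' is added back at prediction.
#'
#' @param data Data frame holding the training pairs.
#' @param input,target Column names (strings) of the input (liner
#'   temperature) and target (skin temperature) channels.
#' @param length_scale Fixed kernel length scale; use the stack's
#'   `combo_tau_min` (e.g. 5.4 for a polyurethane liner with a
#'   thermosetting socket, 6.7 for Pe-lite with thermoplastic).
#' @param theta1_init,noise_sd_init Optimiser starting values (degrees C
#'   scale for `noise_sd_init`).
#' @param max_iter Maximum quasi-Newton iterations.
#' @return An object of class `gp_fit` with elements `hyper`
#'   (`theta1`, `length_scale`, `noise_var`), `mean_offset`,
#'   `log_marginal_likelihood`, `log_marginal_likelihood_init`, the
#'   training data and the Cholesky factorisation reused by [predict()].
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
gp_fit <- function(data, input, target, length_scale,
                   theta1_init = 1, noise_sd_init = 0.1, max_iter = 200) {
  stopifnot(is.data.frame(data))
  x <- data[[input]]
  y <- data[[target]]
  if (is.null(x) || is.null(y)) {
    abort("input/target columns not found in `data`",
          class = "prosthermal_validation_error")
  }
  if (length(x) < 2) {
    abort("need at least 2 training pairs", class = "prosthermal_validation_error")
  }
  if (!is.numeric(length_scale) || length_scale <= 0) {
    abort("length_scale must be positive", class = "prosthermal_validation_error")
  }
  if (sd(x) == 0) {
    abort("training inputs are constant; the model cannot be identified",
          class = "prosthermal_validation_error")
  }
  offset <- mean(y)
  yc <- y - offset

  par0 <- c(log(theta1_init), log(noise_sd_init^2))
  obj0 <- gp_objective(par0, x, yc, length_scale, want_grad = FALSE)

  fn <- function(p) -gp_objective(p, x, yc, length_scale, want_grad = FALSE)$lml
  gr <- function(p) -gp_objective(p, x, yc, length_scale)$grad
  opt <- tryCatch(
    optim(par0, fn, gr, method = "L-BFGS-B",
          lower = c(-15, log(1e-10)), upper = c(15, 10),
          control = list(maxit = max_iter, factr = 1e4, pgtol = 1e-6)),
    error = function(e) {
      abort(paste0("hyperparameter optimisation failed: ", conditionMessage(e)),
            class = "prosthermal_numerical_error")
    })
  # evidence must not decrease relative to the starting point
  par <- if (-opt$value >= obj0$lml) opt$par else par0
  final <- gp_objective(par, x, yc, length_scale, want_grad = FALSE)

  structure(list(
    train_x = x, train_y = y,
    input = input, target = target,
    hyper = list(theta1 = exp(par[1]), length_scale = length_scale,
                 noise_var = exp(par[2])),
    mean_offset = offset,
    L = final$L, alpha = final$alpha, jitter = final$jitter,
    log_marginal_likelihood = final$lml,
    log_marginal_likelihood_init = obj0$lml,
    convergence = opt$convergence, optim_message = opt$message,
    n_evals = unname(opt$counts[1])), class = "gp_fit")
}

# Build a gp_fit with prescribed hyperparameters (no optimisation):
# recomputes the factorisation, alpha and evidence. Backbone of
# read_model() and of oracle comparisons at pinned hyperparameters.
gp_model_from_hyper <- function(x, y, theta1, length_scale, noise_var,
                                input = "x", target = "y",
                                mean_offset = mean(y)) {
  yc <- y - mean_offset
  state <- gp_objective(c(log(theta1), log(noise_var)), x, yc, length_scale,
                        want_grad = FALSE)
  structure(list(
    train_x = x, train_y = y, input = input, target = target,
    hyper = list(theta1 = theta1, length_scale = length_scale,
                 noise_var = noise_var),
    mean_offset = mean_offset,
    L = state$L, alpha = state$alpha, jitter = state$jitter,
    log_marginal_likelihood = state$lml,
    log_marginal_likelihood_init = state$lml,
    convergence = 0L, optim_message = "fixed hyperparameters",
    n_evals = 0L), class = "gp_fit")
}

#' Log marginal likelihood of a fitted GP
#'
#' The model evidence `-1/2 y' C_N^{-1} y - 1/2 log|C_N| - N/2 log(2 pi)`
#' evaluated on the centred targets via the stored Cholesky factorisation.
#'
#' @param model A [gp_fit()] object.
#' @return A scalar.
#' @export
log_marginal_likelihood <- function(model) {
  stopifnot(inherits(model, "gp_fit"))
  model$log_marginal_likelihood
}

#' Predict skin temperature with 95% intervals
#'
#' GP posterior at new liner temperatures: mean
#' `k*' C_N^{-1} (y - offset) + offset` and predictive variance
#' `(theta1 + noise_var) - k*' C_N^{-1} k*` per test point (the variance of
#' a new noisy observation, so ~95% of held-out samples should fall inside
#' the band). The 95% band is mean +/- 1.96 sqrt(variance).
#'
#' @param object A [gp_fit()].
#' @param newdata Data frame containing the input column, or a bare
#'   numeric vector of liner temperatures.
#' @param ... Unused.
#' @return A tibble of class `gp_prediction` with columns `.input`, `mean`,
#'   `variance`, `ci95_low`, `ci95_high`.
#' @export
predict.gp_fit <- function(object, newdata, ...) {
  xs <- if (is.data.frame(newdata)) newdata[[object$input]] else as.numeric(newdata)
  if (is.null(xs)) {
    abort(sprintf("newdata has no column '%s'", object$input),
          class = "prosthermal_validation_error")
  }
  h <- object$hyper
  Ks <- sq_exp_cov(object$train_x, xs, h$theta1, h$length_scale, 0)
  mu <- drop(crossprod(Ks, object$alpha)) + object$mean_offset
  v <- backsolve(object$L, Ks, transpose = TRUE)
  var <- pmax(h$theta1 + h$noise_var - colSums(v^2), 0)
  half <- qnorm(0.975) * sqrt(var)
  out <- tibble::tibble(.input = xs, mean = mu, variance = var,
                        ci95_low = mu - half, ci95_high = mu + half)
  class(out) <- c("gp_prediction", class(out))
  out
}

#' Prediction accuracy metrics
#'
#' @param pred A `gp_prediction` tibble from [predict.gp_fit()].
#' @param actual Observed skin temperatures, same length as `pred`.
#' @return A one-row tibble with `max_abs_err` and `rmse` (degrees C) and
#'   `ci95_coverage` (fraction of `actual` inside the 95% band).
#' @export
gp_evaluate <- function(pred, actual) {
  if (nrow(pred) != length(actual)) {
    abort(sprintf("prediction (%d) and actual (%d) lengths differ",
                  nrow(pred), length(actual)),
          class = "prosthermal_validation_error")
  }
  err <- pred$mean - actual
  tibble::tibble(
    max_abs_err = max(abs(err)),
    rmse = sqrt(mean(err^2)),
    ci95_coverage = mean(actual >= pred$ci95_low & actual <= pred$ci95_high))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "<gp_fit: %s ~ %s, n = %d>\n  theta1     = %.4g degC^2\n  length     = %.4g (fixed)\n  noise sd   = %.4g degC\n  offset     = %.3f degC\n  log evidence = %.3f (init %.3f, %d evaluations)\n",
    x$target, x$input, length(x$train_x), x$hyper$theta1,
    x$hyper$length_scale, sqrt(x$hyper$noise_var), x$mean_offset,
    x$log_marginal_likelihood, x$log_marginal_likelihood_init, x$n_evals))
  invisible(x)
}

#' @export
tidy.gp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("theta1", "length_scale", "noise_var"),
    estimate = c(x$hyper$theta1, x$hyper$length_scale, x$hyper$noise_var),
    fixed = c(FALSE, TRUE, FALSE))
}

#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_marginal_likelihood,
                 logLik_init = x$log_marginal_likelihood_init,
                 nobs = length(x$train_x),
                 convergence = x$convergence,
                 mean_offset = x$mean_offset,
                 jitter = x$jitter)
}

#' @export
autoplot.gp_fit <- function(object, ...) {
  xr <- range(object$train_x)
  grid <- seq(xr[1] - diff(xr) * 0.05, xr[2] + diff(xr) * 0.05, length.out = 200)
  pr <- predict(object, grid)
  train <- tibble::tibble(x = object$train_x, y = object$train_y)
  ggplot2::ggplot(pr, ggplot2::aes(.data$.input)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci95_low,
                                      ymax = .data$ci95_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::geom_point(data = train, ggplot2::aes(.data$x, .data$y),
                        alpha = 0.3, size = 0.7) +
    ggplot2::labs(x = sprintf("%s [°C]", object$input),
                  y = sprintf("%s [°C]", object$target),
                  title = "GP posterior with 95% predictive band")
}
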