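# Offset LASSO and componentwise boosting: penalty boundary, MLE limits,
# invariances, tuning determinism, and null-signal behaviour.

lowdim_with_offset <- function(seed, n = 50, p = 2) {
  d <- random_lowdim(seed, n = n, q = p)
  withr::with_seed(seed + 5000, d$offset <- rnorm(n) * 0.5)
  d
}

test_that("at lambda >= lambda_max the solution is exactly zero", {
  d <- lowdim_with_offset(1, n = 80, p = 12)
  lmax <- lasso_lambda_max(d$X, d$time, d$event, d$offset)
  path <- lasso_path_offset(d$X, d$time, d$event, d$offset,
                            lambdas = c(2 * lmax, lmax))
  expect_true(all(path$beta == 0))
  expect_equal(path$n_selected, c(0, 0), ignore_attr = TRUE)
  expect_error(lasso_path_offset(d$X, d$time, d$event, d$offset,
                                 lambdas = c(1, 2)), "descending")
})

test_that("the unpenalized end of the path matches the offset Cox MLE", {
  d <- lowdim_with_offset(2, n = 50, p = 2)
  lmax <- lasso_lambda_max(d$X, d$time, d$event, d$offset)
  path <- lasso_path_offset(d$X, d$time, d$event, d$offset,
                            lambdas = c(lmax, 0))
  mle <- fit_cox(d$X, d$time, d$event, offset = d$offset)
  expect_lt(max(abs(path$beta[, 2] - mle$coefficients)), 1e-4)
})

test_that("the path is invariant to constant offset shifts", {
  d <- lowdim_with_offset(3, n = 60, p = 8)
  lmax <- lasso_lambda_max(d$X, d$time, d$event, d$offset)
  grid <- exp(seq(log(lmax), log(0.05 * lmax), length.out = 12))
  p1 <- lasso_path_offset(d$X, d$time, d$event, d$offset, grid)
  p2 <- lasso_path_offset(d$X, d$time, d$event, d$offset + 11.3, grid)
  expect_equal(p1$beta, p2$beta, tolerance = 1e-6)
  expect_equal(lasso_lambda_max(d$X, d$time, d$event, d$offset + 11.3), lmax,
               tolerance = 1e-10)
})

test_that("the path agrees with glmnet along a shared grid", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("survival")
  d <- lowdim_with_offset(4, n = 120, p = 30)
  lmax <- lasso_lambda_max(d$X, d$time, d$event, d$offset)
  grid <- exp(seq(log(lmax), log(0.05 * lmax), length.out = 30))
  mine <- lasso_path_offset(d$X, d$time, d$event, d$offset, grid)
  ref <- glmnet::glmnet(d$X, survival::Surv(d$time, d$event), family = "cox",
                        offset = d$offset, lambda = grid, thresh = 1e-10)
  expect_lt(max(abs(mine$beta - as.matrix(coef(ref)))), 1e-3)
})

test_that("original-scale coefficients are equivariant to feature rescaling", {
  d <- lowdim_with_offset(5, n = 60, p = 2)
  lmax <- lasso_lambda_max(d$X, d$time, d$event, d$offset)
  p1 <- lasso_path_offset(d$X, d$time, d$event, d$offset, c(lmax, 0))
  X2 <- d$X; X2[, 1] <- X2[, 1] * 10
  p2 <- lasso_path_offset(X2, d$time, d$event, d$offset, c(lmax, 0))
  expect_equal(p2$beta[1, 2] * 10, p1$beta[1, 2], tolerance = 1e-3)
  expect_equal(p2$beta[2, 2], p1$beta[2, 2], tolerance = 1e-3)
})

test_that("cross-validated penalty selection is deterministic and respects the grid", {
  d <- lowdim_with_offset(6, n = 80, p = 15)
  cfg <- selector_config("lasso", cv_folds = 5, lambda_grid_size = 20)
  cv1 <- cv_lambda(d$X, d$time, d$event, d$offset, cfg, seed = 42)
  cv2 <- cv_lambda(d$X, d$time, d$event, d$offset, cfg, seed = 42)
  expect_equal(cv1$lambda, cv2$lambda)
  expect_equal(cv1$cvm, cv2$cvm)
  expect_true(cv1$lambda %in% cv1$grid)
  # a one-point grid can only return that point
  cfg1 <- selector_config("lasso", cv_folds = 5, lambda_grid_size = 1)
  cv3 <- cv_lambda(d$X, d$time, d$event, d$offset, cfg1, seed = 1)
  expect_equal(cv3$lambda, cv3$grid[1])
})

test_that("with pure-noise omics and an informative offset the LASSO stays empty", {
  empty <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    withr::with_seed(3000 + s, {
      n <- 200L; p <- 500L
      z <- rnorm(n)                       # strong clinical signal
      tm <- rexp(n, 0.1 * exp(0.8 * z))
      cn <- rexp(n, 0.08)
      time <- pmin(tm, cn); ev <- as.integer(tm <= cn)
      X <- matrix(rnorm(n * p), n, p)
      off <- 0.8 * z                       # the true predictor as offset
      cv <- cv_lambda(X, time, ev, off, selector_config("lasso"), seed = s)
      if (sum(cv$path$beta[, cv$index] != 0) == 0L) empty <- empty + 1L
    })
  }
  expect_gte(empty / n_runs, 0.7)
})

test_that("boosting at mstop 0 changes nothing and its loglik path ascends", {
  d <- lowdim_with_offset(7, n = 70, p = 10)
  path <- boost_offset(d$X, d$time, d$event, d$offset, mstop = 0)
  expect_true(all(boost_coef(path, 0) == 0))
  path2 <- boost_offset(d$X, d$time, d$event, d$offset, mstop = 80)
  expect_true(all(diff(path2$loglik) >= -1e-10))
  expect_error(boost_offset(d$X, d$time, d$event, d$offset, mstop = -1))
})

test_that("single-covariate boosting converges to the offset Cox MLE", {
  d <- lowdim_with_offset(8, n = 100, p = 1)
  cfg <- selector_config("boosting", step_size = 0.1, mstop_max = 5000)
  path <- boost_offset(d$X, d$time, d$event, d$offset, cfg, mstop = 5000)
  mle <- fit_cox(d$X, d$time, d$event, offset = d$offset)
  expect_lt(abs(boost_coef(path, 5000) - mle$coefficients), 1e-3)
})

test_that("bootstrap stopping is deterministic, in range, and conservative under noise", {
  d <- lowdim_with_offset(9, n = 80, p = 20)
  cfg <- selector_config("boosting", n_bootstrap = 10, mstop_max = 40)
  b1 <- bootstrap_mstop(d$X, d$time, d$event, d$offset, cfg, seed = 7)
  b2 <- bootstrap_mstop(d$X, d$time, d$event, d$offset, cfg, seed = 7)
  expect_identical(b1$mstop, b2$mstop)
  expect_gte(b1$mstop, 0L)
  expect_lte(b1$mstop, 40L)
  expect_length(b1$risk, 41L)

  # pure-noise omics with an informative offset: (almost) nothing selected
  quiet <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    withr::with_seed(4000 + s, {
      n <- 150L; p <- 200L
      z <- rnorm(n)
      tm <- rexp(n, 0.1 * exp(0.8 * z))
      cn <- rexp(n, 0.08)
      time <- pmin(tm, cn); ev <- as.integer(tm <= cn)
      X <- matrix(rnorm(n * p), n, p)
      bm <- bootstrap_mstop(X, time, ev, 0.8 * z,
                            selector_config("boosting"), seed = s)
      if (bm$mstop == 0L) {
        quiet <- quiet + 1L
      } else {
        path <- boost_offset(X, time, ev, 0.8 * z, mstop = bm$mstop)
        if (sum(boost_coef(path) != 0) == 0L) quiet <- quiet + 1L
      }
    })
  }
  expect_gte(quiet / n_runs, 0.7)
})

test_that("base-learner ties break to the lowest column index", {
  d <- lowdim_with_offset(10, n = 60, p = 1)
  X <- cbind(a = d$X[, 1], b = d$X[, 1])  # identical columns
  path <- boost_offset(X, d$time, d$event, d$offset, mstop = 10)
  expect_true(all(path$selected == 1L))
})
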