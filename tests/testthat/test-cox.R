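# Partial-likelihood machinery: closed forms, invariances, and agreement
# with independent maximisers.

test_that("partial log-likelihood matches closed forms and hand enumeration", {
  # null predictor, no ties: -(ln 3 + ln 2 + ln 1)
  expect_equal(cox_partial_loglik(0, c(1, 2, 3), c(1, 1, 1)), -log(6))

  # 5 patients with tied event times: direct Breslow evaluation by hand.
  # times 2,2,3 are events; 1 censored at 1; 4 censored at 4.
  time <- c(1, 2, 2, 3, 4)
  event <- c(0, 1, 1, 1, 0)
  eta <- c(0.3, -0.2, 0.1, 0.5, -0.4)
  ee <- exp(eta)
  # risk set at t=2: patients 2..5; at t=3: 4,5
  by_hand <- eta[2] + eta[3] - 2 * log(sum(ee[2:5])) + eta[4] - log(sum(ee[4:5]))
  expect_equal(cox_partial_loglik(eta, time, event), by_hand)
})

test_that("partial log-likelihood is invariant to constant shifts", {
  d <- random_lowdim(3, n = 40)
  eta <- drop(d$X %*% c(0.4, -0.2, 0.1))
  ll <- cox_partial_loglik(eta, d$time, d$event)
  for (c0 in c(-5, 1e3, 0.017)) {
    expect_equal(cox_partial_loglik(eta + c0, d$time, d$event), ll)
  }
  expect_error(cox_partial_loglik(eta, d$time, rep(0, 40)), "event")
})

test_that("fit_cox matches a brute-force grid maximizer on a small dataset", {
  d <- random_lowdim(17, n = 20, q = 2)
  fit <- fit_cox(d$X, d$time, d$event)
  # independent oracle: nested grid search over the coefficient plane
  obj <- function(b1, b2) {
    cox_partial_loglik(drop(d$X %*% c(b1, b2)), d$time, d$event)
  }
  ctr <- c(0, 0); width <- 3
  for (stage in 1:4) {
    g1 <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
    g2 <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
    vals <- outer(g1, g2, Vectorize(obj))
    best <- arrayInd(which.max(vals), dim(vals))
    ctr <- c(g1[best[1]], g2[best[2]])
    width <- width / 10
  }
  expect_lt(max(abs(fit$coefficients - ctr)), 1e-4)
})

test_that("fit_cox agrees with survival::coxph on random datasets", {
  skip_if_not_installed("survival")
  worst <- 0
  for (s in 1:50) {
    d <- random_lowdim(s, n = 50 + (s %% 3) * 20, q = 2 + s %% 3,
                       tie_prone = s %% 2 == 0)
    if (sum(d$event) < 3) next
    fit <- fit_cox(d$X, d$time, d$event)
    ref <- survival::coxph(survival::Surv(d$time, d$event) ~ d$X,
                           ties = "breslow",
                           control = survival::coxph.control(eps = 1e-10,
                                                             iter.max = 50))
    worst <- max(worst, max(abs(fit$coefficients - unname(coef(ref)))))
  }
  expect_lt(worst, 1e-6)
})

test_that("fit_cox rejects non-identifiable designs and is offset-shift invariant", {
  d <- random_lowdim(5, n = 30, q = 2)
  expect_error(fit_cox(cbind(d$X, const = 1), d$time, d$event), "constant")
  expect_error(fit_cox(cbind(d$X, d$X[, 1] * 2), d$time, d$event), "rank")
  off <- rnorm(30)
  f1 <- fit_cox(d$X, d$time, d$event, offset = off)
  f2 <- fit_cox(d$X, d$time, d$event, offset = off + 7.3)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("Breslow baseline matches closed forms and is a valid cumulative hazard", {
  # null model, distinct event times: Nelson-Aalen jumps 1/3, 1/2, 1
  bh <- breslow_cumhaz(c(1, 2, 3), c(1, 1, 1), 0)
  expect_equal(cumhaz_at(bh, c(0, 1, 2, 3, 10)),
               c(0, 1/3, 1/3 + 1/2, 1/3 + 1/2 + 1, 1/3 + 1/2 + 1))
  # tied events: times (1,1,2), all events, eta = 0 -> jump at 1 is 2/3
  bh2 <- breslow_cumhaz(c(1, 1, 2), c(1, 1, 1), 0)
  expect_equal(cumhaz_at(bh2, 1), 2/3)
  # nondecreasing from 0 on a random fit
  d <- random_lowdim(9, n = 50)
  fit <- fit_cox(d$X, d$time, d$event)
  tt <- seq(0, max(d$time), length.out = 50)
  H <- cumhaz_at(fit$baseline, tt)
  expect_equal(H[1], 0)
  expect_true(all(diff(H) >= 0))
})

test_that("Kaplan-Meier matches the product-limit closed form and survfit", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km_survival(km, c(1, 3, 4)), c(3/4, 3/8, 0))
  # no events -> survival identically 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_survival(km0, c(0.5, 2, 5)), c(1, 1, 1))
  skip_if_not_installed("survival")
  worst <- 0
  for (s in 1:50) {
    d <- random_lowdim(100 + s, n = 40, tie_prone = s %% 2 == 0)
    km <- kaplan_meier(d$time, d$event)
    sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
    worst <- max(worst, max(abs(km_survival(km, sf$time) - sf$surv)))
  }
  expect_lt(worst, 1e-12)
})

test_that("left limits of the censoring curve are the value just before t", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_survival(km, 2, left = TRUE), km_survival(km, 1))
  expect_equal(km_survival(km, 1, left = TRUE), 1)
})

test_that("predicted survival curves are valid and the null model replays KM", {
  d <- random_lowdim(21, n = 50, q = 2)
  fit <- fit_cox(d$X, d$time, d$event)
  tt <- c(0, sort(runif(20, 0, max(d$time))))
  S <- predict_survival(fit, d$X[1:7, ], tt)
  expect_equal(unname(S[, 1]), rep(1, 7))                 # S(0|x) = 1
  expect_true(all(S > 0 & S <= 1))
  expect_true(all(apply(S, 1, function(r) all(diff(r) <= 1e-12))))
  # monotonicity across random refits (property over models)
  for (s in 1:5) {
    dd <- random_lowdim(30 + s, n = 40, q = 2)
    f2 <- fit_cox(dd$X, dd$time, dd$event)
    S2 <- predict_survival(f2, dd$X, sort(runif(15, 0, max(dd$time))))
    expect_true(all(apply(S2, 1, function(r) all(diff(r) <= 1e-12))))
  }
  # null model: every row is the training KM curve
  null <- fit_km_null(d$time, d$event)
  Sn <- predict_survival(null, d$X[1:4, ], tt)
  expect_equal(Sn, matrix(rep(km_survival(null$km, tt), each = 4), nrow = 4))
  expect_error(predict_survival(fit, d$X, c(-1, 2)), "negative")
})

test_that("score is numerically zero and information positive definite at the optimum", {
  d <- random_lowdim(77, n = 80, q = 3)
  fit <- fit_cox(d$X, d$time, d$event)
  eps <- 1e-5
  for (j in 1:3) {
    b <- fit$coefficients
    bp <- b; bp[j] <- bp[j] + eps
    bm <- b; bm[j] <- bm[j] - eps
    deriv <- (cox_partial_loglik(drop(d$X %*% bp), d$time, d$event) -
                cox_partial_loglik(drop(d$X %*% bm), d$time, d$event)) / (2 * eps)
    expect_lt(abs(deriv), 1e-3)
    # concavity along each axis
    curv <- (cox_partial_loglik(drop(d$X %*% bp), d$time, d$event) -
               2 * fit$meta$loglik +
               cox_partial_loglik(drop(d$X %*% bm), d$time, d$event)) / eps^2
    expect_lt(curv, 0)
  }
})
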