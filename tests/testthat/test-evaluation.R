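# IPCW concordance and Brier/IBS: closed forms, brute-force pair oracles,
# and the no-censoring reductions.

# independent oracle: exhaustive weighted pair enumeration, written directly
# from the definition (double loop, no shared code with the implementation)
cindex_bruteforce <- function(risk, time, event, tau, G) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] > tau) next
    w <- 1 / km_survival(G, time[i], left = TRUE)^2
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + w
      if (risk[i] > risk[j]) num <- num + w
      else if (risk[i] == risk[j]) num <- num + w / 2
    }
  }
  num / den
}

test_that("perfect ranking gives concordance 1 and constant risk the convention value", {
  expect_equal(cindex_ipcw(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(cindex_ipcw(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0.0)
  expect_equal(cindex_ipcw(rep(2, 5), c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 0)), 0.5)
  expect_equal(cindex_ipcw(rep(0, 4), c(1, 2, 3, 4), c(1, 1, 1, 1),
                           constant_risk_value = 0.4), 0.4)
})

test_that("the IPCW concordance equals exhaustive weighted pair enumeration", {
  # 6-patient censored toy, evaluated against the double-loop oracle
  time <- c(2, 5, 3, 8, 6, 4)
  event <- c(1, 0, 1, 1, 0, 1)
  risk <- c(1.2, -0.5, 0.8, -1.0, 0.3, 0.8)  # includes a risk tie
  G <- kaplan_meier(time, 1 - event)
  tau <- max(time[event == 1])
  expect_equal(cindex_ipcw(risk, time, event, tau, G),
               cindex_bruteforce(risk, time, event, tau, G))
  # and on random censored datasets
  for (s in 1:10) {
    d <- random_lowdim(600 + s, n = 25)
    risk <- withr::with_seed(s, rnorm(25))
    G <- kaplan_meier(d$time, 1 - d$event)
    tau <- max(d$time[d$event == 1])
    expect_equal(cindex_ipcw(risk, d$time, d$event, tau, G),
                 cindex_bruteforce(risk, d$time, d$event, tau, G))
  }
})

test_that("without censoring the IPCW concordance is Harrell's C", {
  skip_if_not_installed("survival")
  worst <- 0
  for (s in 1:50) {
    withr::with_seed(700 + s, {
      n <- 40
      time <- rexp(n); event <- rep(1L, n)
      risk <- rnorm(n)
    })
    mine <- cindex_ipcw(risk, time, event)
    ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                                 reverse = TRUE)$concordance
    worst <- max(worst, abs(mine - ref))
  }
  expect_lt(worst, 1e-12)
})

test_that("concordance is a rank statistic and flips under sign reversal", {
  d <- random_lowdim(55, n = 30)
  risk <- withr::with_seed(5, rnorm(30))
  c1 <- cindex_ipcw(risk, d$time, d$event)
  expect_equal(cindex_ipcw(exp(2 * risk), d$time, d$event), c1)  # monotone map
  expect_equal(cindex_ipcw(-risk, d$time, d$event), 1 - c1)      # no risk ties
})

test_that("Brier score matches closed forms without censoring", {
  withr::with_seed(77, { time <- runif(10, 1, 10); event <- rep(1L, 10) })
  # oracle predictions: S(t|x) = 1(t_i > t) -> score 0
  t0 <- 5
  expect_equal(brier_score(t0, as.numeric(time > t0), time, event), 0)
  # constant 1/2 prediction -> 0.25
  expect_equal(brier_score(t0, rep(0.5, 10), time, event), 0.25)
})

test_that("the IPCW Brier score equals a term-by-term hand evaluation", {
  # 8-patient censored toy
  time <- c(1, 3, 4, 4, 6, 7, 9, 10)
  event <- c(1, 0, 1, 1, 0, 1, 0, 1)
  sprob <- c(0.9, 0.8, 0.55, 0.6, 0.5, 0.45, 0.3, 0.2)
  t0 <- 5
  G <- kaplan_meier(time, 1 - event)
  # by hand: events before t weight 1/G(t_i-); survivors weight 1/G(t)
  terms <- numeric(8)
  for (i in 1:8) {
    if (time[i] <= t0 && event[i] == 1) {
      terms[i] <- sprob[i]^2 / km_survival(G, time[i], left = TRUE)
    } else if (time[i] > t0) {
      terms[i] <- (1 - sprob[i])^2 / km_survival(G, t0)
    }
  }
  expect_equal(brier_score(t0, sprob, time, event, G), mean(terms))
})

test_that("IBS normalizes a constant Brier curve to itself and is quadrature-stable", {
  time <- c(2, 4, 6, 8); event <- c(1, 1, 1, 1)
  # a model predicting constant 1/2 everywhere: Brier = 0.25 at every t < min(time)
  grid <- c(0, 1, 1.5)
  S <- matrix(0.5, 4, 3)
  ib <- integrated_brier(S, time, event, grid = grid, tau = 1.9)
  expect_equal(ib$ibs, 0.25)
  # refining the grid barely moves the integral for a smooth model
  d <- random_lowdim(91, n = 60, q = 2)
  fit <- fit_cox(d$X, d$time, d$event)
  tau <- max(d$time[d$event == 1]) * 0.9
  g1 <- seq(0, tau, length.out = 30)
  g2 <- seq(0, tau, length.out = 300)
  i1 <- integrated_brier(predict_survival(fit, d$X, g1), d$time, d$event,
                         grid = g1, tau = tau)$ibs
  i2 <- integrated_brier(predict_survival(fit, d$X, g2), d$time, d$event,
                         grid = g2, tau = tau)$ibs
  expect_lt(abs(i1 - i2), 1e-3)
  # the KM null model has a nonnegative IBS
  km <- fit_km_null(d$time, d$event)
  Sn <- predict_survival(km, d$X, g1)
  expect_gte(integrated_brier(Sn, d$time, d$event, grid = g1, tau = tau)$ibs, 0)
})

test_that("added-value sign conventions favour the better model", {
  clin <- tibble::tibble(level = "M2", cindex = 0.70, ibs = 0.20)
  comb <- tibble::tibble(level = "M2", cindex = 0.65, ibs = 0.18)
  expect_equal(added_value(clin, comb, "ibs"), 0.02)     # omics lowered IBS
  expect_equal(added_value(clin, comb, "cindex"), -0.05) # omics hurt ranking
  expect_equal(added_value(clin, clin, "cindex"), 0)
  expect_equal(added_value(clin, clin, "ibs"), 0)
  comb$level <- "M3"
  expect_error(added_value(clin, comb, "cindex"), "same clinical level")
})
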