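# Shared fixtures, built in code at test time.

# Small random low-dimensional survival dataset for oracle comparisons.
random_lowdim <- function(seed, n = 60, q = 3, tie_prone = FALSE) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * q), n, q)
    colnames(X) <- paste0("x", seq_len(q))
    b <- seq(-0.5, 0.5, length.out = q)
    tm <- rexp(n, rate = 0.1 * exp(drop(X %*% b)))
    cn <- rexp(n, rate = 0.08)
    time <- pmin(tm, cn)
    if (tie_prone) time <- ceiling(time)  # force tied times
    list(X = X, time = time, event = as.integer(tm <= cn))
  })
}

# Tiny survival_dataset with handmade values.
toy_dataset <- function(n = 6, p = 5, seed = 1) {
  withr::with_seed(seed, {
    survival_dataset(
      patient_id = sprintf("P%02d", seq_len(n)),
      time = round(rexp(n, 0.1), 2) + 0.5,
      event = rbinom(n, 1, 0.6),
      clinical = tibble::tibble(
        nodal = factor(sample(c("N0", "N1", "N2", "N3"), n, TRUE),
                       levels = c("N0", "N1", "N2", "N3")),
        er = factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes")),
        age = runif(n, 30, 80)
      ),
      omics = matrix(rnorm(n * p), n, p,
                     dimnames = list(NULL, sprintf("g%03d", seq_len(p))))
    )
  })
}

# A moderate synthetic study pair used by several pipeline tests
# (cached per test run).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study(scenario_config(
        n_train = 120L, n_val = 100L, p = 60L, s_indep = 2L, s_surr = 5L,
        seed = 99L))
    }
    cache
  }
})
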