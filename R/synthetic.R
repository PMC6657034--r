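# Synthetic training/validation cohorts with the clinical/omics structure
# the added-value analysis assumes: categorical clinical covariates, a
# continuous age with nonlinear effect, p >> n expression features of which
# some carry independent signal and some are surrogates of the clinical
# risk profile, Cox event times with a parametric baseline, and independent
# exponential censoring.

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe a desk-scale two-cohort breast-cancer-like study:
#' moderate sample sizes, 1000 expression features of which 20 are pure
#' surrogates of the clinical linear predictor (no signal of their own),
#' event times on a daily scale with roughly 25-30% events.
#'
#' @param n_train,n_val Cohort sizes.
#' @param p Number of omics features.
#' @param s_indep Features carrying survival signal independent of the
#'   clinical predictor.
#' @param s_surr Surrogate features, correlated with the clinical linear
#'   predictor but carrying no additional signal.
#' @param surrogate_strength Correlation `rho` in `[0, 1)` of each surrogate
#'   with the standardized clinical linear predictor:
#'   `X = rho * std(lp) + sqrt(1 - rho^2) * noise`.
#' @param omics_effect_size Log-hazard per SD for each independent-signal
#'   feature.
#' @param clinical_effects Named list of per-level log-hazard coefficients
#'   for `nodal` (N0,N1,N2,N3), `size` (T0_1,T2,T3,T4), `grade` (G1,G2,G3),
#'   `er` (no,yes), and an `age` shape spec
#'   `list(shape = "quadratic"|"power"|"linear"|"none", ...)`.
#' @param baseline Baseline hazard spec:
#'   `list(dist = "exponential", rate = )` or
#'   `list(dist = "weibull", shape = , scale = )` (per day).
#' @param censoring_rate Exponential censoring rate (per day), independent
#'   of covariates.
#' @param seed Integer master seed; all randomness flows from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_train = 300L, n_val = 200L, p = 1000L,
                            s_indep = 0L, s_surr = 20L,
                            surrogate_strength = 0.8,
                            omics_effect_size = 0.5,
                            clinical_effects = list(
                              nodal = c(0, 0.4, 0.8, 1.2),
                              size = c(0, 0.3, 0.6, 0.9),
                              grade = c(0, 0.3, 0.6),
                              er = c(0, -0.5),
                              age = list(shape = "quadratic", center = 55,
                                         scale = 10, coef = 0.15)
                            ),
                            baseline = list(dist = "exponential", rate = 1e-4),
                            censoring_rate = 3e-4,
                            seed = 1L) {
  stopifnot(n_train > 0, n_val > 0, p >= 0, s_indep >= 0, s_surr >= 0,
            surrogate_strength >= 0, surrogate_strength < 1,
            censoring_rate > 0)
  if (s_indep + s_surr > p) {
    stop("s_indep + s_surr must not exceed p", call. = FALSE)
  }
  structure(
    list(n_train = as.integer(n_train), n_val = as.integer(n_val),
         p = as.integer(p), s_indep = as.integer(s_indep),
         s_surr = as.integer(s_surr),
         surrogate_strength = surrogate_strength,
         omics_effect_size = omics_effect_size,
         clinical_effects = clinical_effects, baseline = baseline,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# Population frequencies of the clinical covariates (fixed across scenarios;
# loosely typical of breast-cancer cohorts).
clinical_population <- list(
  nodal = list(levels = c("N0", "N1", "N2", "N3"), prob = c(0.45, 0.30, 0.15, 0.10)),
  size = list(levels = c("T0_1", "T2", "T3", "T4"), prob = c(0.30, 0.45, 0.15, 0.10)),
  grade = list(levels = c("G1", "G2", "G3"), prob = c(0.20, 0.45, 0.35)),
  er = list(levels = c("no", "yes"), prob = c(0.25, 0.75)),
  age = list(mean = 55, sd = 12, lower = 25, upper = 90)
)

draw_clinical <- function(n) {
  pop <- clinical_population
  draw_cat <- function(spec) {
    factor(sample(spec$levels, n, replace = TRUE, prob = spec$prob),
           levels = spec$levels)
  }
  # truncated normal age by inversion
  a <- pop$age
  plo <- stats::pnorm(a$lower, a$mean, a$sd)
  phi <- stats::pnorm(a$upper, a$mean, a$sd)
  age <- stats::qnorm(stats::runif(n, plo, phi), a$mean, a$sd)
  tibble::tibble(nodal = draw_cat(pop$nodal), size = draw_cat(pop$size),
                 grade = draw_cat(pop$grade), er = draw_cat(pop$er),
                 age = age)
}

age_effect <- function(age, spec) {
  switch(spec$shape %||% "quadratic",
    none = rep(0, length(age)),
    linear = spec$coef * (age - spec$center) / spec$scale,
    quadratic = spec$coef * ((age - spec$center) / spec$scale)^2,
    power = spec$coef * (age / spec$scale)^spec$power,
    stop("unknown age effect shape '", spec$shape, "'", call. = FALSE)
  )
}

clinical_lp_true <- function(clinical, effects) {
  lp <- rep(0, nrow(clinical))
  for (nm in c("nodal", "size", "grade", "er")) {
    lp <- lp + effects[[nm]][as.integer(clinical[[nm]])]
  }
  lp + age_effect(clinical$age, effects$age)
}

#' Generate the omics matrix for given clinical linear predictors
#'
#' Column layout: first `s_indep` independent standard-Gaussian columns that
#' carry survival signal, then `s_surr` surrogate columns built as
#' `rho * std(lp) + sqrt(1 - rho^2) * N(0,1)`, then pure-noise columns.
#' Roles are recorded in `attr(, "roles")`.
#'
#' @param n Number of patients.
#' @param config A [scenario_config()].
#' @param clinical_lp The clinical linear predictor, length `n`.
#' @return Numeric matrix `n x p` with role attribute.
#' @export
generate_omics <- function(n, config, clinical_lp) {
  stopifnot(length(clinical_lp) == n)
  p <- config$p
  X <- matrix(rnorm(n * p), n, p)
  roles <- rep("noise", p)
  if (config$s_indep > 0) roles[seq_len(config$s_indep)] <- "signal"
  if (config$s_surr > 0) {
    surr_idx <- config$s_indep + seq_len(config$s_surr)
    roles[surr_idx] <- "surrogate"
    rho <- config$surrogate_strength
    z <- (clinical_lp - mean(clinical_lp)) / stats::sd(clinical_lp)
    X[, surr_idx] <- rho * z + sqrt(1 - rho^2) * X[, surr_idx]
  }
  colnames(X) <- sprintf("g%05d", seq_len(p))
  attr(X, "roles") <- roles
  X
}

#' Draw survival and censoring times from a Cox law
#'
#' Event times follow hazard `baseline_hazard(t) * exp(lp)`; censoring is
#' independent exponential. Times are drawn by inversion of the cumulative
#' hazard.
#'
#' @param lp Finite linear predictor.
#' @param baseline Baseline spec (see [scenario_config()]).
#' @param censoring_rate Positive exponential censoring rate.
#' @return A list with `time = min(T, C)` and `event = 1(T <= C)`.
#' @export
generate_survival <- function(lp, baseline, censoring_rate) {
  stopifnot(all(is.finite(lp)), censoring_rate > 0)
  n <- length(lp)
  u <- stats::runif(n)
  # Lambda0(T) * exp(lp) = -log(U)  =>  Lambda0(T) = -log(U) e^{-lp}
  target <- -log(u) * exp(-lp)
  T_ev <- switch(baseline$dist,
    exponential = {
      if (baseline$rate <= 0) stop("baseline rate must be positive", call. = FALSE)
      target / baseline$rate
    },
    weibull = {
      if (baseline$shape <= 0 || baseline$scale <= 0) {
        stop("weibull shape/scale must be positive", call. = FALSE)
      }
      baseline$scale * target^(1 / baseline$shape)
    },
    stop("unknown baseline distribution '", baseline$dist, "'", call. = FALSE)
  )
  C <- stats::rexp(n, rate = censoring_rate)
  list(time = pmin(T_ev, C), event = as.integer(T_ev <= C))
}

draw_cohort <- function(n, config, center, prefix) {
  clinical <- draw_clinical(n)
  clp <- clinical_lp_true(clinical, config$clinical_effects) - center
  X <- generate_omics(n, config, clp)
  roles <- attr(X, "roles")
  beta_true <- ifelse(roles == "signal", config$omics_effect_size, 0)
  lp <- clp + drop(X %*% beta_true)
  sv <- generate_survival(lp, config$baseline, config$censoring_rate)
  survival_dataset(
    patient_id = sprintf("%s%04d", prefix, seq_len(n)),
    time = sv$time, event = sv$event, clinical = clinical, omics = X,
    feature_roles = roles, true_lp = lp
  )
}

#' Generate a training/validation study pair
#'
#' Draws two cohorts i.i.d. from the same law described by `config`. The
#' true linear predictor and the role of every omics feature are recorded
#' in the datasets for oracle tests. All randomness flows from
#' `config$seed` through one RNG stream: the centering constant, the
#' training cohort, then the validation cohort are drawn in that fixed
#' order.
#'
#' @param config A [scenario_config()].
#' @return A list with `train` and `validation` [survival_dataset()]s; the
#'   true omics coefficients are in `attr(, "true_beta")`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, {
    # centering constant: expected clinical lp, so the event rate is set by
    # the baseline/censoring rates rather than by the covariate frequencies
    ref <- draw_clinical(20000L)
    center <- mean(clinical_lp_true(ref, config$clinical_effects))
    train <- draw_cohort(config$n_train, config, center, "TR")
    validation <- draw_cohort(config$n_val, config, center, "VA")
    roles <- train$feature_roles
    out <- list(train = train, validation = validation)
    attr(out, "true_beta") <- ifelse(roles == "signal",
                                     config$omics_effect_size, 0)
    attr(out, "config") <- config
    out
  })
}
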