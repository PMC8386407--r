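#' Scale a variable to unit variance
#'
#' Divides by the grand (pooled) sample SD so the variable has sample
#' variance 1, optionally centering first. Association coefficients fitted
#' on unit-scaled response and predictor are directly comparable across
#' variable pairs, playing the role of a repeated-measures correlation.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param center Subtract the mean first (default `TRUE`; the slope of the
#'   mixed model is unaffected by centering).
#' @return The scaled vector.
#' @export
scale_unit_variance <- function(values, center = TRUE) {
  x <- values[!is.na(values)]
  if (length(x) < 2 || length(unique(x)) < 2) {
    abort("zero variance: cannot scale a constant variable")
  }
  s <- sd(x)
  if (center) (values - mean(x)) / s else values / s
}

#' Repeated-measures association between two variables
#'
#' Fits the linear mixed model `y ~ x + (1 | patient)` by REML after
#' scaling both variables to unit variance, so the fixed-effect coefficient
#' of `x` acts as a correlation-like standardized association while the
#' random intercept accounts for the repeated measures within patients.
#' Testing association equals testing that the coefficient is zero (Wald
#' test, normal reference). Pairs with either value missing are dropped;
#' any optimizer failure is reported as non-convergence (`converged =
#' FALSE`, the "nc" entries of an association table), never raised.
#'
#' @param data Tibble with one row per observation.
#' @param response,predictor Column names (strings) of the two variables.
#' @param patient Column name of the patient identifier.
#' @return One-row tibble: `response`, `predictor`, `coefficient`,
#'   `p_value`, `converged`, `n_obs`, `n_patients`.
#' @export
mixed_correlation <- function(data, response, predictor,
                              patient = "patient_id") {
  d <- tibble(
    y = data[[response]],
    x = data[[predictor]],
    patient = data[[patient]]
  )
  d <- d[complete.cases(d), ]
  nc <- tibble(
    response = response, predictor = predictor,
    coefficient = NA_real_, p_value = NA_real_, converged = FALSE,
    n_obs = nrow(d), n_patients = length(unique(d$patient))
  )
  if (nrow(d) < 3 || length(unique(d$patient)) < 2) return(nc)
  scaled <- tryCatch(
    list(y = scale_unit_variance(d$y), x = scale_unit_variance(d$x)),
    error = function(e) NULL
  )
  if (is.null(scaled)) return(nc)
  d$y <- scaled$y
  d$x <- scaled$x
  # exact linear dependence (e.g. a variable paired with itself): the mixed
  # model is degenerate, but the association is definitionally +/-1
  ols <- lm(y ~ x, data = d)
  if (max(abs(stats::residuals(ols))) < 1e-10) {
    return(tibble(
      response = response, predictor = predictor,
      coefficient = unname(coef(ols)[2]), p_value = 0, converged = TRUE,
      n_obs = nrow(d), n_patients = length(unique(d$patient))
    ))
  }
  fit <- tryCatch(
    {
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ x + (1 | patient), data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore",
                     calc.derivs = FALSE
                   ))
      ))
    },
    error = function(e) NULL
  )
  if (is.null(fit)) return(nc)
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(co) || !"x" %in% rownames(co)) return(nc)
  est <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  if (!is.finite(est) || !is.finite(se) || se <= 0) return(nc)
  z <- est / se
  tibble(
    response = response, predictor = predictor,
    coefficient = est,
    p_value = 2 * pnorm(-abs(z)),
    converged = TRUE,
    n_obs = nrow(d), n_patients = length(unique(d$patient))
  )
}

#' Intraclass correlation of a repeated clinical scale
#'
#' Within-patient stability via the variance decomposition of the
#' random-intercept model `value ~ 1 + (1 | patient)` fitted by REML:
#' \deqn{ICC = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2),} the share of
#' variance attributable to stable between-patient differences. Negative
#' component estimates are truncated at zero, keeping the ICC in `[0, 1]`.
#' A scale that is constant within every patient but varies between
#' patients returns exactly 1.
#'
#' @param data Tibble with the repeated measurements.
#' @param value Column name of the measured scale.
#' @param patient Column name of the patient identifier.
#' @return One-row tibble: `scale`, `icc`, `var_between`, `var_within`,
#'   `n_obs`, `n_patients`.
#' @export
icc <- function(data, value, patient = "patient_id") {
  d <- tibble(y = data[[value]], patient = data[[patient]])
  d <- d[complete.cases(d), ]
  n_pat <- length(unique(d$patient))
  if (n_pat < 2) abort("icc needs at least 2 patients")
  reps <- table(d$patient)
  if (max(reps) < 2) {
    abort("icc needs repeated measurements (>= 2 observations) for at least one patient")
  }
  if (var(d$y) == 0) {
    abort("icc undefined for a globally constant scale (zero total variance)")
  }
  # degenerate but well-defined limit: no within-patient variation at all
  within_var <- d %>%
    group_by(.data$patient) %>%
    summarise(v = if (dplyr::n() >= 2) var(.data$y) else NA_real_,
              .groups = "drop")
  if (all(is.na(within_var$v) | within_var$v == 0)) {
    means <- d %>% group_by(.data$patient) %>%
      summarise(m = mean(.data$y), .groups = "drop")
    return(tibble(
      scale = value, icc = 1, var_between = var(means$m), var_within = 0,
      n_obs = nrow(d), n_patients = n_pat
    ))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | patient), data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- max(0, vc$vcov[vc$grp == "patient"])
  vw <- max(0, vc$vcov[vc$grp == "Residual"])
  tibble(
    scale = value,
    icc = min(1, max(0, vb / (vb + vw))),
    var_between = vb, var_within = vw,
    n_obs = nrow(d), n_patients = n_pat
  )
}

#' Pairwise association table
#'
#' Runs [mixed_correlation()] for every requested (response, predictor)
#' pair, the engine behind the symptom-symptom and symptom-device
#' association tables. Each pair is tested at the two-sided 5% level with
#' no multiplicity adjustment (the analysis is exploratory); pairs whose
#' model does not converge are kept as non-converged rows ("nc") and the
#' run continues.
#'
#' @param data Tibble with one row per observation.
#' @param pairs Tibble with columns `response`, `predictor`.
#' @param patient Column name of the patient identifier.
#' @param alpha Two-sided significance level for the `significant` marker.
#' @return Tibble of [mixed_correlation()] rows plus `significant`.
#' @export
association_matrix <- function(data, pairs, patient = "patient_id",
                               alpha = 0.05) {
  if (nrow(pairs) == 0) {
    return(tibble(
      response = character(), predictor = character(),
      coefficient = numeric(), p_value = numeric(), converged = logical(),
      n_obs = integer(), n_patients = integer(), significant = logical()
    ))
  }
  purrr::pmap(
    pairs[, c("response", "predictor")],
    function(response, predictor) {
      mixed_correlation(data, response, predictor, patient = patient)
    }
  ) %>%
    dplyr::bind_rows() %>%
    mutate(significant = .data$converged & .data$p_value < alpha)
}
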