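#' Validate a cohort table for mixed-effects modelling
#'
#' One row per (subject, velocity, stride): columns `subject_id`,
#' `stride_index`, `velocity`, `k`, and optionally `age`, `mass`, `method`.
#'
#' @param table data.frame.
#' @param require_subjects minimum number of distinct subjects.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_cohort_table <- function(table, require_subjects = 2) {
  need <- c("subject_id", "stride_index", "velocity", "k")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0)
    stop("cohort table missing column(s): ", paste(missing, collapse = ", "))
  if (anyNA(table$k)) stop("cohort table contains missing stiffness values")
  if (length(unique(table$subject_id)) < require_subjects)
    stop("cohort table needs at least ", require_subjects, " subjects")
  invisible(table)
}

#' Random-intercept mixed model of stiffness on stride (and speed)
#'
#' Fits `k ~ stride_index + (1 | subject_id)` (or additionally `+ velocity`)
#' by restricted maximum likelihood via [lmerTest::lmer()], with
#' Satterthwaite-approximated denominator degrees of freedom for the
#' fixed-effect t-tests.  A singular fit (zero random-intercept variance) is
#' returned with a `singular` flag rather than raising an error; in that
#' limit the fixed estimates coincide with pooled ordinary least squares.
#'
#' @param table a cohort table (see [validate_cohort_table()]).
#' @param include_velocity add treadmill velocity as a fixed effect;
#'   requires at least two distinct velocities.
#' @return an object of class `lmem_fit`: `fixed` (data.frame with columns
#'   term, estimate, se, df, t, p), `ranef_var`, `resid_var`, `singular`,
#'   `criterion` (`"REML"`), and the underlying `model`.
#' @examples
#' tab <- sim_cohort_table(n_subjects = 6, n_strides = 30, seed = 1)
#' fit_lmem(tab, include_velocity = TRUE)
#' @export
fit_lmem <- function(table, include_velocity = FALSE) {
  validate_cohort_table(table)
  if (length(unique(table$stride_index)) < 2)
    stop("need at least 2 distinct stride values")
  if (include_velocity && length(unique(table$velocity)) < 2)
    stop("velocity effect not estimable from a single velocity")
  fml <- if (include_velocity)
    k ~ stride_index + velocity + (1 | subject_id)
  else
    k ~ stride_index + (1 | subject_id)
  model <- lmerTest::lmer(fml, data = table, REML = TRUE)
  sm <- summary(model)$coefficients  # Satterthwaite df by default
  fixed <- data.frame(term = rownames(sm),
                      estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      df = sm[, "df"],
                      t = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(model))
  ranef_var <- vc$vcov[vc$grp == "subject_id"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  structure(list(fixed = fixed,
                 ranef_var = ranef_var, resid_var = resid_var,
                 singular = lme4::isSingular(model),
                 criterion = "REML", model = model),
            class = "lmem_fit")
}

#' @export
print.lmem_fit <- function(x, ...) {
  cat("Linear mixed-effects model (REML", if (x$singular) ", singular fit",
      "):\n", sep = "")
  out <- x$fixed
  out$estimate <- signif(out$estimate, 6)
  out$se <- signif(out$se, 6)
  out$df <- round(out$df, 3)
  out$t <- signif(out$t, 5)
  out$p <- signif(out$p, 4)
  print(out, row.names = FALSE)
  cat("Random-intercept sd:", signif(sqrt(x$ranef_var), 6),
      " residual sd:", signif(sqrt(x$resid_var), 6), "\n")
  invisible(x)
}

#' Simple regression of per-subject Ljung-Box p-values on a covariate
#'
#' Ordinary least squares of one p-value per subject on age or mass, with a
#' two-sided t-test on the slope — the follow-up analysis asking whether
#' stride dependence varies systematically across the cohort.
#'
#' @param p_values one Ljung-Box p-value per subject.
#' @param covariate numeric covariate (age in years or mass in kg), same
#'   length, non-constant.
#' @return list with `slope`, `intercept`, `p_value` (slope test), `model`.
#' @export
regress_pvalue_on_covariate <- function(p_values, covariate) {
  stopifnot(length(p_values) == length(covariate), length(p_values) >= 3)
  if (length(unique(covariate)) < 2) stop("constant covariate")
  fit <- lm(p_values ~ covariate)
  sm <- summary(fit)$coefficients
  list(slope = sm["covariate", "Estimate"],
       intercept = sm["(Intercept)", "Estimate"],
       p_value = sm["covariate", "Pr(>|t|)"],
       model = fit)
}

#' Simulate a cohort table with known mixed-model truth
#'
#' Generates `k = (intercept + b_subject) + beta_stride * S +
#' beta_velocity * v + e`, with `b_subject ~ N(0, subject_sd^2)` and
#' `e ~ N(0, resid_sd^2)`, over a crossed grid of subjects, velocities and
#' stride numbers.  The default effect sizes match the magnitudes of the
#' within-cohort stride and speed effects this package is designed to
#' detect.
#'
#' @param n_subjects number of subjects.
#' @param n_strides strides per subject per velocity.
#' @param velocities treadmill velocities, m/s.
#' @param intercept fixed intercept, N/m.
#' @param beta_stride fixed stride-number slope, N/m per stride.
#' @param beta_velocity fixed speed slope, N/m per (m/s).
#' @param subject_sd random-intercept sd, N/m.
#' @param resid_sd residual sd, N/m.
#' @param seed integer seed.
#' @return a cohort table data.frame with `age` and `mass` columns drawn
#'   from plausible adult ranges.
#' @export
sim_cohort_table <- function(n_subjects = 28, n_strides = 80,
                             velocities = c(2.5, 3.5, 4.5),
                             intercept = 15671, beta_stride = -6.6,
                             beta_velocity = 280, subject_sd = 1500,
                             resid_sd = 1200, seed = 1L) {
  with_seed(seed, {
    b <- rnorm(n_subjects, 0, subject_sd)
    age <- round(runif(n_subjects, 20, 45), 1)
    mass <- round(runif(n_subjects, 55, 90), 1)
    grid <- expand.grid(stride_index = seq_len(n_strides) - 1L,
                        velocity = velocities,
                        subject = seq_len(n_subjects))
    grid$subject_id <- sprintf("S%02d", grid$subject)
    grid$age <- age[grid$subject]
    grid$mass <- mass[grid$subject]
    grid$k <- intercept + b[grid$subject] +
      beta_stride * grid$stride_index +
      beta_velocity * grid$velocity +
      rnorm(nrow(grid), 0, resid_sd)
    grid$subject <- NULL
    grid
  })
}
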