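# light content hash so every output can be traced to its run configuration
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(txt))
  sprintf("%08x", sum(v * (seq_along(v) %% 251 + 1)) %% 4294967291)
}

#' Simulate and write a synthetic running cohort
#'
#' Generates one synthetic SLIP trial per (subject, velocity), with
#' per-subject anthropometrics (mass, leg rest length, age) and a
#' per-subject mean stiffness drawn around `mean_k`, and writes each trial's
#' marker/force CSV pair plus a ground-truth JSON sidecar and a cohort
#' manifest (`manifest.json`).  All randomness derives from `seed` through
#' fixed substreams, so the same call is bit-reproducible.
#'
#' @param out_dir output directory.
#' @param n_subjects number of subjects.
#' @param n_strides strides per trial.
#' @param velocities treadmill velocities, m/s.
#' @param mean_k cohort mean stiffness, N/m.
#' @param subject_k_sd between-subject sd of mean stiffness, N/m.
#' @param ar_coeffs AR coefficients of the latent stiffness process.
#' @param innovation_sd stiffness innovation sd, N/m.
#' @param marker_sd,force_sd measurement noise (see [noise_spec()]).
#' @param seed integer master seed.
#' @return the manifest as a list, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_simulate <- function(out_dir, n_subjects = 4, n_strides = 50,
                         velocities = c(2.5, 3.5, 4.5), mean_k = 20000,
                         subject_k_sd = 1500, ar_coeffs = 0.6,
                         innovation_sd = 1000, marker_sd = 0.001,
                         force_sd = 5, seed = 1L) {
  stopifnot(n_subjects >= 1, n_strides >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(n_subjects = n_subjects, n_strides = n_strides,
                 velocities = velocities, mean_k = mean_k,
                 subject_k_sd = subject_k_sd, ar_coeffs = ar_coeffs,
                 innovation_sd = innovation_sd, marker_sd = marker_sd,
                 force_sd = force_sd, seed = seed)
  subj <- with_seed(derive_seed(seed, 0), {
    data.frame(subject_id = sprintf("S%02d", seq_len(n_subjects)),
               age = round(runif(n_subjects, 20, 45), 1),
               mass = round(runif(n_subjects, 55, 90), 1),
               l0 = round(runif(n_subjects, 0.90, 1.05), 3),
               mean_k = mean_k + rnorm(n_subjects, 0, subject_k_sd))
  })
  trials <- list()
  trial_no <- 0L
  for (i in seq_len(n_subjects)) {
    meta <- subject_meta(subj$subject_id[i], subj$age[i], subj$mass[i],
                         subj$l0[i])
    params <- slip_params(mass = subj$mass[i], l0 = subj$l0[i],
                          touchdown_angle = 0.35,
                          apex_height = 1.02 * subj$l0[i])
    for (v in velocities) {
      trial_no <- trial_no + 1L
      proc <- stiffness_process_spec(subj$mean_k[i], ar_coeffs, innovation_sd,
                                     n_strides,
                                     seed = derive_seed(seed, trial_no * 8L + 1L))
      nz <- noise_spec(marker_sd, force_sd,
                       seed = derive_seed(seed, trial_no * 8L + 2L))
      tr <- assemble_trial(proc, params, nz, v = v, subject = meta)
      id <- sprintf("%s_v%s", meta$subject_id, gsub("[.]", "p", format(v)))
      paths <- write_trial(tr, out_dir, id)
      trials[[trial_no]] <- list(subject_id = meta$subject_id,
                                 age = meta$age, mass = meta$mass,
                                 l0 = meta$l0, velocity = v,
                                 markers = basename(paths[["markers"]]),
                                 force = basename(paths[["force"]]),
                                 truth = basename(paths[["truth"]]))
    }
  }
  manifest <- list(config = config, config_hash = config_hash(config),
                   trials = trials)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full stiffness-dependence analysis over a cohort manifest
#'
#' For every trial in the manifest: read, segment into stance phases,
#' estimate the per-stride stiffness series with each requested method, and
#' run the dependence battery ([dependence_report()]).  Failures of a single
#' trial are isolated, reported, and excluded from the cohort outputs.
#' Writes `stiffness.csv` (one row per stride), `cohort.csv` (one row per
#' subject x velocity x method, with the Ljung-Box p-value, its Bonferroni
#' decision across subjects, the maximum Yule-significant lag and the
#' variance ratio R), and one dependence-report JSON per series.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_simulate()] (or hand-written for real recordings).
#' @param out_dir output directory.
#' @param methods stiffness estimators to apply.
#' @param alpha significance level.
#' @param max_lag Ljung-Box / Yule maximum lag.
#' @param bonferroni_n family size for the Bonferroni adjustment of the
#'   Ljung-Box tests; defaults to the number of subjects.
#' @param threshold stance detection force threshold, N (raise to ~2x the
#'   force noise sd for noisy channels).
#' @param min_samples minimum stance run length, samples.
#' @param weight_correction [k_max()] convention.
#' @param recentre_mode [recentre()] mode.
#' @param vr_mode [variance_ratio_from_acf()] mode.
#' @return list with data.frames `stiffness` and `cohort` and the output
#'   `paths`, invisibly.
#' @export
run_analyze <- function(manifest_path, out_dir,
                        methods = c("kmax", "kols"), alpha = 0.05,
                        max_lag = 40, bonferroni_n = NULL, threshold = 0,
                        min_samples = 1, weight_correction = "subtract",
                        recentre_mode = "x-only",
                        vr_mode = "significant") {
  manifest <- jsonlite::read_json(manifest_path)
  if (length(manifest$trials) == 0) stop("no trials in manifest")
  base <- dirname(manifest_path)
  dir.create(file.path(out_dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  stiff_rows <- list(); cohort_rows <- list()
  for (tr in manifest$trials) {
    res <- tryCatch({
      meta <- subject_meta(tr$subject_id, tr$age, tr$mass, tr$l0)
      rec <- read_trial(file.path(base, tr$markers), file.path(base, tr$force),
                        meta, tr$velocity)
      strides <- extract_strides(rec, threshold = threshold,
                                 min_samples = min_samples,
                                 recentre_mode = recentre_mode)
      if (length(strides) == 0) stop("no stance phases detected")
      per_method <- list()
      for (m in methods) {
        ser <- if (m == "kmax")
          stiffness_series(strides, meta, m, velocity = tr$velocity,
                           weight_correction = weight_correction)
        else stiffness_series(strides, meta, m, velocity = tr$velocity)
        rep_ <- dependence_report(ser, alpha = alpha, max_lag = max_lag,
                                  vr_mode = vr_mode)
        per_method[[m]] <- list(series = ser, report = rep_)
      }
      per_method
    }, error = function(e) {
      message("trial ", tr$subject_id, " @ ", tr$velocity, " m/s failed: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    for (m in names(res)) {
      ser <- res[[m]]$series; rep_ <- res[[m]]$report
      stiff_rows[[length(stiff_rows) + 1]] <- as.data.frame(ser)
      cohort_rows[[length(cohort_rows) + 1]] <- data.frame(
        subject_id = tr$subject_id, velocity = tr$velocity, method = m,
        age = tr$age, mass = tr$mass, n_strides = length(ser$k),
        lb_Q = rep_$ljung_box$Q, lb_p = rep_$ljung_box$p_value,
        max_significant_lag = rep_$yule$max_significant_lag,
        R = rep_$variance_ratio$R)
      jsonlite::write_json(
        list(subject_id = tr$subject_id, velocity = tr$velocity, method = m,
             n = rep_$n, rho = rep_$acf$rho,
             yule = list(threshold = rep_$yule$threshold,
                         significant = rep_$yule$significant,
                         max_significant_lag = rep_$yule$max_significant_lag),
             ljung_box = unclass(rep_$ljung_box),
             variance_ratio = list(R = rep_$variance_ratio$R,
                                   mode = rep_$variance_ratio$mode)),
        file.path(out_dir, "reports",
                  sprintf("%s_v%s_%s.json", tr$subject_id,
                          gsub("[.]", "p", format(tr$velocity)), m)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  if (length(cohort_rows) == 0) stop("every trial failed; no cohort output")
  cohort <- do.call(rbind, cohort_rows)
  N <- if (is.null(bonferroni_n)) length(unique(cohort$subject_id)) else bonferroni_n
  cohort$lb_reject_bonferroni <- as.logical(
    stats::ave(cohort$lb_p, cohort$velocity, cohort$method,
               FUN = function(p) bonferroni_adjust(p, alpha = alpha, N = N)))
  stiffness <- do.call(rbind, stiff_rows)
  paths <- c(stiffness = file.path(out_dir, "stiffness.csv"),
             cohort = file.path(out_dir, "cohort.csv"))
  data.table::fwrite(stiffness, paths["stiffness"])
  data.table::fwrite(cohort, paths["cohort"])
  settings <- list(config_hash = manifest$config_hash, alpha = alpha,
                   max_lag = max_lag, bonferroni_n = N, threshold = threshold,
                   min_samples = min_samples,
                   weight_correction = weight_correction,
                   recentre_mode = recentre_mode, vr_mode = vr_mode,
                   methods = methods)
  jsonlite::write_json(settings, file.path(out_dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(stiffness = stiffness, cohort = cohort, paths = paths))
}

#' Summarise an analysis into report tables (and optional figures)
#'
#' Data-first reporting: every figure has a CSV twin so downstream checks
#' assert on numbers.  Produces per-subject maximum-significant-lag bars,
#' Ljung-Box p-values against the significance line, p-value-vs-age and
#' p-value-vs-mass regressions, a constant-correlation sweep of the
#' variance ratio, and (when at least two subjects and velocities are
#' present) the mixed-model coefficient tables per stiffness method.
#'
#' @param analysis_dir directory written by [run_analyze()].
#' @param out_dir report output directory.
#' @param alpha significance level drawn on the p-value summaries.
#' @param make_figures write PDF figures via ggplot2 (if installed).
#' @return named list of the report data.frames, invisibly.
#' @export
run_report <- function(analysis_dir, out_dir, alpha = 0.05,
                       make_figures = FALSE) {
  cohort <- as.data.frame(data.table::fread(file.path(analysis_dir, "cohort.csv")))
  stiffness <- as.data.frame(data.table::fread(file.path(analysis_dir, "stiffness.csv")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  out$max_lag <- cohort[, c("subject_id", "velocity", "method",
                            "max_significant_lag")]
  out$lb_pvalues <- cohort[, c("subject_id", "velocity", "method", "lb_p",
                               "lb_reject_bonferroni")]
  out$lb_pvalues$alpha <- alpha

  reg_rows <- list()
  for (m in unique(cohort$method)) for (v in unique(cohort$velocity)) {
    sub <- cohort[cohort$method == m & cohort$velocity == v, ]
    for (cv in c("age", "mass")) {
      if (nrow(sub) >= 3 && length(unique(sub[[cv]])) >= 2) {
        r <- regress_pvalue_on_covariate(sub$lb_p, sub[[cv]])
        reg_rows[[length(reg_rows) + 1]] <- data.frame(
          method = m, velocity = v, covariate = cv, slope = r$slope,
          intercept = r$intercept, p_value = r$p_value)
      }
    }
  }
  out$pvalue_regressions <- if (length(reg_rows)) do.call(rbind, reg_rows)
    else data.frame()

  sweep <- expand.grid(rho = seq(-0.02, 0.06, by = 0.005), n = c(11, 51, 101))
  sweep$R <- mapply(function(r, n) variance_ratio_constant(r, n)$R,
                    sweep$rho, sweep$n)
  out$r_sweep <- sweep

  lmem_rows <- list()
  if (length(unique(stiffness$subject_id)) >= 2 &&
      length(unique(stiffness$velocity)) >= 2) {
    for (m in unique(stiffness$method)) {
      tab <- stiffness[stiffness$method == m, ]
      fit <- fit_lmem(tab, include_velocity = TRUE)
      fx <- fit$fixed
      fx$method <- m
      lmem_rows[[length(lmem_rows) + 1]] <- fx
    }
  }
  out$lmem_coefficients <- if (length(lmem_rows)) do.call(rbind, lmem_rows)
    else data.frame()

  for (nm in names(out))
    data.table::fwrite(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))

  if (make_figures && requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot
    aes <- ggplot2::aes
    p1 <- gg(out$max_lag, aes(x = subject_id, y = max_significant_lag)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = 5, linetype = 2) +
      ggplot2::facet_grid(method ~ velocity)
    ggplot2::ggsave(file.path(out_dir, "max_lag.pdf"), p1,
                    width = 8, height = 5)
    p2 <- gg(out$lb_pvalues, aes(x = subject_id, y = lb_p)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
      ggplot2::facet_grid(method ~ velocity)
    ggplot2::ggsave(file.path(out_dir, "lb_pvalues.pdf"), p2,
                    width = 8, height = 5)
    p3 <- gg(out$r_sweep, aes(x = rho, y = R, colour = factor(n))) +
      ggplot2::geom_line()
    ggplot2::ggsave(file.path(out_dir, "r_sweep.pdf"), p3,
                    width = 6, height = 4)
  }
  invisible(out)
}
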