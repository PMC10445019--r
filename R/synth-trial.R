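# Fixed sagittal-plane offsets (m) of the six pelvis markers relative to the
# CoM.  They sum to zero per coordinate, so the unweighted six-marker mean
# recovers the CoM exactly on noiseless data.
marker_offsets <- function() {
  list(asis_L  = c(x =  0.10, y = -0.04),
       asis_R  = c(x =  0.10, y = -0.04),
       psis_L  = c(x = -0.10, y = -0.04),
       psis_R  = c(x = -0.10, y = -0.04),
       crest_L = c(x =  0.00, y =  0.08),
       crest_R = c(x =  0.00, y =  0.08))
}

# nearest-time lookup of a fine-grid series at arbitrary query times
nearest_lookup <- function(t_grid, v_grid, t_query) {
  j <- findInterval(t_query, t_grid, all.inside = TRUE)
  lo <- t_grid[j]; hi <- t_grid[j + 1]
  take_hi <- (t_query - lo) > (hi - t_query)
  v_grid[j + as.integer(take_hi)]
}

#' Assemble a synthetic multi-stride treadmill running trial
#'
#' Draws a per-stride stiffness series from `proc`, simulates one SLIP
#' stance per stride (every stance re-initialised from the nominal apex
#' state, so cross-stride dependence enters only through the stiffness
#' process), splices the stances together with ballistic flight phases of
#' exactly zero vertical force, emits the six pelvis marker channels (CoM
#' plus fixed offsets) at 150 Hz and the force channel at 300 Hz in the
#' treadmill-fixed frame (`x_treadmill = x_world - v * t`), and finally adds
#' Gaussian measurement noise per `noise`.  The returned object carries full
#' ground truth: the injected stiffness series and the exact stance sample
#' intervals on the 300 Hz clock (half-open, 0-based), recorded before noise
#' is added.
#'
#' @param proc a [stiffness_process_spec()].
#' @param params a [slip_params()]; its `forward_speed` is overridden by `v`.
#' @param noise a [noise_spec()].
#' @param v treadmill velocity, m/s.
#' @param subject a [subject_meta()]; defaults to a subject consistent with
#'   `params` (mass, l0).
#' @param dt SLIP integration step, s.
#' @return an object of class `synth_trial`: fields `recording`
#'   ([trial_recording()]), `true_k`, `true_stance_intervals`,
#'   `true_com_world` (pre-noise world-frame CoM at the marker clock),
#'   `spec`.
#' @examples
#' tr <- assemble_trial(
#'   stiffness_process_spec(20000, 0.6, 1000, n_strides = 5, seed = 1),
#'   slip_params(), noise_spec(0, 0), v = 2.5)
#' length(tr$true_k)
#' @export
assemble_trial <- function(proc, params = slip_params(), noise = noise_spec(),
                           v = params$forward_speed, subject = NULL,
                           dt = 1e-4) {
  stopifnot(inherits(proc, "stiffness_process_spec"),
            inherits(params, "slip_params"),
            inherits(noise, "noise_spec"))
  params$forward_speed <- v
  if (is.null(subject))
    subject <- subject_meta("synth", age = 30, mass = params$mass,
                            l0 = params$l0)

  k <- gen_stiffness_series(proc)
  n_str <- proc$n_strides
  td <- touchdown_state(params)
  g <- params$g

  stances <- vector("list", n_str)
  for (i in seq_len(n_str)) {
    stances[[i]] <- tryCatch(simulate_stance(k[i], params, dt = dt),
                             error = function(e)
                               stop("stride ", i, ": ", conditionMessage(e)))
  }
  D <- vapply(stances, `[[`, numeric(1), "duration")
  vy_to <- vapply(stances, function(s) s$takeoff$vy, numeric(1))
  if (any(vy_to <= 0))
    stop("stride ", which(vy_to <= 0)[1], ": non-ascending takeoff state")
  vx_to <- vapply(stances, function(s) s$takeoff$vx, numeric(1))
  t_up <- vy_to / g

  # touchdown times and foot world-x positions
  T_td <- numeric(n_str)
  X_foot <- numeric(n_str)
  T_td[1] <- td$t_fall
  X_foot[1] <- v * T_td[1] - td$x
  if (n_str > 1) {
    for (i in seq_len(n_str - 1)) {
      T_td[i + 1] <- T_td[i] + D[i] + t_up[i] + td$t_fall
      x_to <- X_foot[i] + stances[[i]]$takeoff$x
      x_apex <- x_to + vx_to[i] * t_up[i]
      X_foot[i + 1] <- x_apex + v * td$t_fall - td$x
    }
  }
  T_end <- T_td[n_str] + D[n_str] + t_up[n_str]

  # world-frame CoM at arbitrary times (vectorised over the trial timeline)
  com_world <- function(tt) {
    x <- numeric(length(tt)); y <- numeric(length(tt))
    # initial flight from the t = 0 apex
    pre <- tt < T_td[1]
    x[pre] <- v * tt[pre]
    y[pre] <- params$apex_height - 0.5 * g * tt[pre]^2
    for (i in seq_len(n_str)) {
      s <- stances[[i]]
      in_st <- tt >= T_td[i] & tt <= T_td[i] + D[i]
      if (any(in_st)) {
        tau <- tt[in_st] - T_td[i]
        x[in_st] <- X_foot[i] + nearest_lookup(s$t, s$x, tau)
        y[in_st] <- nearest_lookup(s$t, s$y, tau)
      }
      t0 <- T_td[i] + D[i]
      asc <- tt > t0 & tt <= t0 + t_up[i]
      if (any(asc)) {
        tau <- tt[asc] - t0
        x[asc] <- X_foot[i] + s$takeoff$x + vx_to[i] * tau
        y[asc] <- s$takeoff$y + vy_to[i] * tau - 0.5 * g * tau^2
      }
      t_apex <- t0 + t_up[i]
      t_next <- if (i < n_str) T_td[i + 1] else T_end + 1
      des <- tt > t_apex & tt < t_next
      if (any(des)) {
        tau <- tt[des] - t_apex
        x_apex <- X_foot[i] + s$takeoff$x + vx_to[i] * t_up[i]
        x[des] <- x_apex + v * tau
        y[des] <- params$apex_height - 0.5 * g * tau^2
      }
    }
    list(x = x, y = y)
  }

  n_marker <- floor(T_end * 150) + 1
  n_force <- 2 * n_marker - 1
  t_m <- (seq_len(n_marker) - 1) / 150
  t_f <- (seq_len(n_force) - 1) / 300

  com_m <- com_world(t_m)
  markers <- data.frame(time_s = t_m)
  for (ch in names(marker_offsets())) {
    off <- marker_offsets()[[ch]]
    markers[[paste0(ch, "_x")]] <- com_m$x + off["x"] - v * t_m  # treadmill frame
    markers[[paste0(ch, "_y")]] <- com_m$y + off["y"]
  }

  # force channel: exactly zero outside stance, nearest-grid inside
  F_y <- numeric(n_force)
  intervals <- vector("list", n_str)
  for (i in seq_len(n_str)) {
    s <- stances[[i]]
    idx <- which(t_f > T_td[i] & t_f < T_td[i] + D[i])
    if (length(idx) > 0)
      F_y[idx] <- nearest_lookup(s$t, s$F_y, t_f[idx] - T_td[i])
    pos <- idx[F_y[idx] > 0]
    if (length(pos) == 0)
      stop("stride ", i, ": stance shorter than one force sample")
    intervals[[i]] <- c(min(pos) - 1L, max(pos))  # 0-based half-open
  }
  force <- data.frame(time_s = t_f, Fy_N = F_y)

  # measurement noise, added last (ground truth above is pre-noise)
  if (noise$marker_sd > 0 || noise$force_sd > 0) {
    with_seed(noise$seed, {
      for (ch in names(marker_offsets())) {
        for (coord in c("x", "y")) {
          col <- paste0(ch, "_", coord)
          markers[[col]] <- markers[[col]] +
            rnorm(n_marker, 0, noise$marker_sd)
        }
      }
      force$Fy_N <- force$Fy_N + rnorm(n_force, 0, noise$force_sd)
    })
  }

  rec <- trial_recording(subject, v, markers, force)
  structure(list(recording = rec,
                 true_k = as.numeric(k),
                 true_stance_intervals = intervals,
                 true_com_world = list(x = com_m$x, y = com_m$y),
                 spec = list(proc = proc, params = params, noise = noise),
                 n_clipped = attr(k, "n_clipped")),
            class = "synth_trial")
}

#' @export
print.synth_trial <- function(x, ...) {
  cat("Synthetic SLIP trial:", length(x$true_k), "strides at",
      x$recording$velocity, "m/s; mean injected k",
      signif(mean(x$true_k), 6), "N/m\n")
  invisible(x)
}

#' Write a trial recording (and ground truth) to delimited text files
#'
#' Writes `<id>_markers.csv` (150 Hz channels) and `<id>_force.csv` (300 Hz
#' `time_s`, `Fy_N`); for a [assemble_trial()] result, also a
#' `<id>_truth.json` sidecar with the injected stiffness series, the true
#' stance intervals and the generating specification.  Numeric values are
#' written with round-trippable precision, so re-reading reproduces the
#' arrays bit-exactly.
#'
#' @param trial a `trial_recording` or `synth_trial`.
#' @param dir output directory (created if needed).
#' @param id file stem.
#' @return named character vector of file paths, invisibly.
#' @export
write_trial <- function(trial, dir, id) {
  truth <- NULL
  if (inherits(trial, "synth_trial")) {
    truth <- trial
    trial <- trial$recording
  }
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(markers = file.path(dir, paste0(id, "_markers.csv")),
             force = file.path(dir, paste0(id, "_force.csv")))
  # 17 significant digits: lossless round-trip for doubles
  fmt <- function(df) {
    df[] <- lapply(df, function(v) if (is.double(v)) sprintf("%.17g", v) else v)
    df
  }
  data.table::fwrite(fmt(trial$markers), paths["markers"], quote = FALSE)
  data.table::fwrite(fmt(trial$force), paths["force"], quote = FALSE)
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, paste0(id, "_truth.json"))
    jsonlite::write_json(
      list(true_k = truth$true_k,
           true_stance_intervals = truth$true_stance_intervals,
           proc = unclass(truth$spec$proc),
           params = unclass(truth$spec$params),
           noise = unclass(truth$spec$noise)),
      paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read a trial recording from delimited text files
#'
#' Counterpart of [write_trial()]: reads the marker and force tables
#' (comma- or tab-delimited, header row required) and validates them into a
#' [trial_recording()].
#'
#' @param marker_path path to the marker table (150 Hz).
#' @param force_path path to the force table (300 Hz).
#' @param meta a [subject_meta()].
#' @param velocity treadmill velocity, m/s.
#' @return a [trial_recording()].
#' @export
read_trial <- function(marker_path, force_path, meta, velocity) {
  markers <- as.data.frame(data.table::fread(marker_path))
  force <- as.data.frame(data.table::fread(force_path))
  trial_recording(meta, velocity, markers, force)
}
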