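#' Subject metadata
#'
#' @param subject_id character identifier.
#' @param age age in years (>= 0).
#' @param mass body mass, kg (> 0).
#' @param l0 centre-of-mass height at rest (leg rest length), m (> 0).
#' @return an object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, age, mass, l0) {
  stopifnot(is.character(subject_id), length(subject_id) == 1,
            is.numeric(age), age >= 0,
            is.numeric(mass), mass > 0,
            is.numeric(l0), l0 > 0)
  structure(list(subject_id = subject_id, age = age, mass = mass, l0 = l0),
            class = "subject_meta")
}

# the six pelvis markers used to approximate the CoM, and their channel names
marker_channels <- function() {
  m <- expand.grid(coord = c("x", "y"), side = c("L", "R"),
                   marker = c("asis", "psis", "crest"),
                   stringsAsFactors = FALSE)
  paste(m$marker, m$side, m$coord, sep = "_")
}

#' A single treadmill running trial recording
#'
#' One subject at one treadmill velocity: six sagittal-plane pelvis marker
#' channels (left/right anterior superior iliac spine, posterior iliac spine
#' and iliac crest; x forward, y upward, metres, treadmill-fixed frame)
#' sampled at `marker_rate`, and a vertical ground reaction force channel
#' (N) sampled at `force_rate = 2 * marker_rate`.  Force sample `2i` is
#' simultaneous with marker sample `i` (both clocks start at frame 0).
#'
#' @param subject a [subject_meta()].
#' @param velocity treadmill velocity, m/s.
#' @param markers data.frame with a `time_s` column and the 12 channels
#'   `<marker>_<L|R>_<x|y>` for markers `asis`, `psis`, `crest`; extra
#'   columns are preserved but unused.
#' @param force data.frame with columns `time_s` and `Fy_N`.
#' @param marker_rate marker sampling rate, Hz.
#' @param force_rate force sampling rate, Hz; must be `2 * marker_rate`.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(subject, velocity, markers, force,
                            marker_rate = 150, force_rate = 300) {
  stopifnot(inherits(subject, "subject_meta"),
            is.numeric(velocity), velocity >= 0,
            is.data.frame(markers), is.data.frame(force))
  if (force_rate != 2 * marker_rate)
    stop("force_rate must be exactly twice marker_rate")
  need <- marker_channels()
  missing <- setdiff(need, names(markers))
  if (length(missing) > 0)
    stop("missing required marker channel(s): ", paste(missing, collapse = ", "))
  if (!all(c("time_s", "Fy_N") %in% names(force)))
    stop("force table must have columns time_s and Fy_N")
  nm <- nrow(markers); nf <- nrow(force)
  if (nf < 2 * nm - 1 || nf > 2 * nm)
    stop("channel lengths inconsistent with rates: ", nf, " force samples vs ",
         nm, " marker samples (expected 2*nm - 1 or 2*nm)")
  for (ch in c(need, "time_s"))
    if (!is.numeric(markers[[ch]]))
      stop("non-numeric marker column: ", ch)
  if (!is.numeric(force$Fy_N)) stop("non-numeric force column: Fy_N")
  structure(list(subject = subject, velocity = velocity,
                 marker_rate = marker_rate, force_rate = force_rate,
                 markers = markers, force = force),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("Trial recording: subject", x$subject$subject_id, "at", x$velocity,
      "m/s;", nrow(x$markers), "marker samples @", x$marker_rate, "Hz,",
      nrow(x$force), "force samples @", x$force_rate, "Hz\n")
  invisible(x)
}

#' One stance phase of one stride
#'
#' Holds the recentred centre-of-mass coordinates and the (downsampled)
#' vertical force over one stance, the half-open sample interval
#' `[start, end)` on the common 150 Hz clock (0-based), and the 0-based
#' stride ordinal within the trial.
#'
#' @param stride_index 0-based stride ordinal.
#' @param interval integer length-2 vector, half-open `[start, end)`.
#' @param x,y recentred CoM coordinate series, m.
#' @param F_y vertical force series, N (same clock as `x`, `y`).
#' @return an object of class `stance_phase`.
#' @export
stance_phase <- function(stride_index, interval, x, y, F_y) {
  stopifnot(length(interval) == 2, interval[2] > interval[1],
            length(x) == interval[2] - interval[1],
            length(y) == length(x), length(F_y) == length(x))
  structure(list(stride_index = as.integer(stride_index),
                 interval = as.integer(interval),
                 x = as.numeric(x), y = as.numeric(y), F_y = as.numeric(F_y)),
            class = "stance_phase")
}

#' @export
print.stance_phase <- function(x, ...) {
  cat("Stance phase #", x$stride_index, ": samples [", x$interval[1], ", ",
      x$interval[2], "), peak Fy ", signif(max(x$F_y), 5), " N\n", sep = "")
  invisible(x)
}

#' Downsample a 300 Hz force series to the 150 Hz marker clock
#'
#' Keeps every other sample starting from the first, so output sample `i`
#' (0-based) is input sample `2i` — the sample simultaneous with marker
#' frame `i`.
#'
#' @param F_y numeric force series at 300 Hz.
#' @return numeric series at 150 Hz, length `ceiling(length(F_y) / 2)`.
#' @examples
#' downsample_forces(c(0, 5, 10, 15))  # 0 10
#' @export
downsample_forces <- function(F_y) {
  if (length(F_y) == 0) stop("empty force series")
  F_y[seq(1, length(F_y), by = 2)]
}

#' Centre-of-mass series from the six pelvis markers
#'
#' Unweighted per-sample mean of the left and right anterior superior iliac
#' spine, posterior iliac spine and iliac crest coordinates, per coordinate.
#' Interior NA runs of at most `max_gap` samples in a channel are linearly
#' interpolated (and reported); longer runs, or NAs at the channel ends, are
#' an error.
#'
#' @param markers marker data.frame as in [trial_recording()].
#' @param max_gap longest interior NA run to interpolate, samples.
#' @return list with numeric vectors `x` and `y`.
#' @export
compute_com <- function(markers, max_gap = 5) {
  need <- marker_channels()
  missing <- setdiff(need, names(markers))
  if (length(missing) > 0)
    stop("missing required marker channel(s): ", paste(missing, collapse = ", "))
  fill <- function(v, ch) {
    if (!anyNA(v)) return(v)
    r <- rle(is.na(v))
    runs <- r$lengths[r$values]
    if (is.na(v[1]) || is.na(v[length(v)]) || any(runs > max_gap))
      stop("NA gap longer than ", max_gap, " samples in channel ", ch)
    message("interpolated ", sum(runs), " NA sample(s) in channel ", ch)
    approx(seq_along(v), v, xout = seq_along(v))$y
  }
  xs <- grep("_x$", need, value = TRUE)
  ys <- grep("_y$", need, value = TRUE)
  xm <- vapply(xs, function(ch) fill(markers[[ch]], ch), numeric(nrow(markers)))
  ym <- vapply(ys, function(ch) fill(markers[[ch]], ch), numeric(nrow(markers)))
  list(x = rowMeans(xm), y = rowMeans(ym))
}

#' Recentre treadmill-frame coordinates to the world frame
#'
#' The recordings are expressed in a frame fixed to the treadmill, so the
#' runner's horizontal position stays bounded while the belt moves under
#' them.  Recentring adds the belt displacement back: `x' = x + v * t`.  By
#' default only `x` is shifted; `mode = "verbatim"` additionally applies the
#' same shift to `y` (an audit mode — a vertical belt-displacement ramp is
#' not physically meaningful, see the package vignette).
#'
#' @param x,y coordinate series, m.
#' @param t time from trial start, s (same length).
#' @param v treadmill velocity, m/s (>= 0).
#' @param mode `"x-only"` (default) or `"verbatim"`.
#' @return list with recentred `x` and `y`.
#' @examples
#' recentre(c(0, 0, 0), c(1, 1, 1), t = 0:2, v = 1)
#' @export
recentre <- function(x, y, t, v, mode = c("x-only", "verbatim")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(v), v >= 0)
  if (length(x) != length(t) || length(y) != length(t))
    stop("x, y and t must have equal length")
  list(x = x + v * t,
       y = if (mode == "verbatim") y + v * t else y)
}

#' Detect stance phases as runs of positive vertical force
#'
#' Maximal runs with `F_y > threshold` become half-open 0-based sample
#' intervals; runs shorter than `min_samples` are discarded (reported).
#'
#' @param F_y force series on the analysis clock.
#' @param threshold force threshold, N; the strict inequality
#'   `F_y > threshold` defines ground contact.
#' @param min_samples minimum run length to keep.
#' @return list of integer length-2 vectors `[start, end)`, sorted, disjoint.
#' @examples
#' detect_stances(c(0, 0, 10, 20, 10, 0, 0, 5, 0))
#' @export
detect_stances <- function(F_y, threshold = 0, min_samples = 1) {
  stopifnot(all(is.finite(F_y)))
  up <- F_y > threshold
  if (!any(up)) return(list())
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  iv <- Map(function(s, e) c(s, e), starts[keep], ends[keep])
  short <- vapply(iv, function(i) i[2] - i[1] < min_samples, logical(1))
  if (any(short))
    message("discarded ", sum(short), " stance run(s) shorter than ",
            min_samples, " samples")
  iv[!short]
}

#' Segment a trial into per-stride stance phases
#'
#' The full pre-processing pipeline: downsample the 300 Hz force channel to
#' the 150 Hz marker clock, average the six pelvis markers into a CoM
#' trajectory, recentre to the world frame, detect stance phases where the
#' force exceeds `threshold`, and slice one [stance_phase()] per detected
#' interval in temporal order.  A stance run touching the first or last
#' sample of the trial is a partial (truncated) stance and is excluded
#' (reported).  First and last complete strides are kept unless
#' `trim = TRUE`.
#'
#' @param trial a [trial_recording()].
#' @param threshold stance force threshold, N (use ~2x the force noise sd
#'   for noisy channels).
#' @param min_samples minimum stance length in samples.
#' @param recentre_mode passed to [recentre()].
#' @param trim drop the first and last detected complete stances.
#' @param max_gap passed to [compute_com()].
#' @return list of [stance_phase()] objects; attribute `n_truncated` counts
#'   excluded partial stances.
#' @export
extract_strides <- function(trial, threshold = 0, min_samples = 1,
                            recentre_mode = c("x-only", "verbatim"),
                            trim = FALSE, max_gap = 5) {
  stopifnot(inherits(trial, "trial_recording"))
  recentre_mode <- match.arg(recentre_mode)
  Fd <- downsample_forces(trial$force$Fy_N)
  nm <- nrow(trial$markers)
  n <- min(nm, length(Fd))
  Fd <- Fd[seq_len(n)]
  com <- compute_com(trial$markers, max_gap = max_gap)
  t <- (seq_len(n) - 1) / trial$marker_rate
  rc <- recentre(com$x[seq_len(n)], com$y[seq_len(n)], t, trial$velocity,
                 mode = recentre_mode)
  iv <- detect_stances(Fd, threshold = threshold, min_samples = min_samples)
  truncated <- vapply(iv, function(i) i[1] == 0 || i[2] == n, logical(1))
  if (any(truncated))
    message("excluded ", sum(truncated), " partial stance(s) at the trial boundary")
  iv <- iv[!truncated]
  if (trim && length(iv) > 2) iv <- iv[-c(1, length(iv))]
  if (length(iv) == 0) {
    warning("no complete stance phases detected")
    out <- list()
  } else {
    out <- Map(function(ord, i) {
      idx <- (i[1] + 1):i[2]
      stance_phase(ord, i, rc$x[idx], rc$y[idx], Fd[idx])
    }, seq_along(iv) - 1L, iv)
  }
  attr(out, "n_truncated") <- sum(truncated)
  out
}

#' Map a 300 Hz force-clock interval onto the 150 Hz marker clock
#'
#' A force-clock sample `j` survives downsampling iff `j = 2i`; the image of
#' the half-open interval `[a, b)` is therefore `[ceiling(a/2),
#' ceiling(b/2))` on the marker clock.
#'
#' @param interval integer length-2 half-open interval on the 300 Hz clock.
#' @return integer length-2 half-open interval on the 150 Hz clock.
#' @export
interval_to_marker_clock <- function(interval) {
  as.integer(c(ceiling(interval[1] / 2), ceiling(interval[2] / 2)))
}
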