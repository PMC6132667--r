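# Field potential scoring: peak-to-peak amplitude, population-spike
# detection and incidence, input/output curves, return-to-baseline check.

post_stim_index <- function(trace, from_ms, to_ms) {
  # R indices of 0-based samples in (from_ms, to_ms] post-stimulus
  dt <- trace$sampling_interval
  lo <- trace$stimulus_onset + floor(from_ms / dt) + 1L
  hi <- trace$stimulus_onset + floor(to_ms / dt)
  (lo + 1L):min(hi + 1L, length(trace$voltages))
}

#' Peak-to-peak field potential amplitude
#'
#' Distance from the most negative to the most positive peak inside the
#' post-stimulus window (default the 25 ms assessment horizon).
#'
#' @param trace An \code{fp_trace}.
#' @param window_ms Length of the post-stimulus window, ms.
#' @return Amplitude in mV.
#' @export
fp_amplitude <- function(trace, window_ms = 25) {
  idx <- post_stim_index(trace, 0, window_ms)
  v <- trace$voltages[idx]
  max(v) - min(v)
}

#' Detect population spikes in a field potential trace
#'
#' A population spike is scored as a brief, sharp, negative-going transient:
#' a contiguous run of first differences exceeding \code{k_sd} baseline
#' first-difference SDs in magnitude, lasting at most 3 ms, with a net
#' negative deflection.  Runs closer than 1 ms are merged.  Slow evoked
#' components fail either the duration cap or the polarity test.
#'
#' @param trace An \code{fp_trace}.
#' @param detection_window_ms Post-stimulus horizon, at most 25 ms.
#' @param k_sd Threshold multiplier (default 4).
#' @param max_duration_ms Fast-transient duration cap (default 3 ms).
#' @param abs_threshold_mV Absolute fallback threshold used (with a warning)
#'   when the baseline is noiseless.
#' @return A list of class \code{spike_score}: \code{slice_id},
#'   \code{condition}, \code{intensity_percent}, \code{n_spikes},
#'   \code{has_spike}, \code{spike_times_ms} (time of the steepest negative
#'   step of each run, ms post-stimulus).
#' @export
detect_population_spikes <- function(trace, detection_window_ms = 25,
                                     k_sd = 4, max_duration_ms = 3,
                                     abs_threshold_mV = 0.05) {
  if (detection_window_ms > 25)
    abort("detection window must be <= 25 ms", "invalid_parameter")
  dt <- trace$sampling_interval
  base_cols <- baseline_columns(trace$stimulus_onset, dt)
  sd_base <- stats::sd(diff(trace$voltages[base_cols]))
  if (!is.finite(sd_base) || sd_base == 0) {
    if (k_sd > 0)
      warning("zero baseline variance; falling back to absolute threshold")
    thr <- abs_threshold_mV
  } else {
    thr <- k_sd * sd_base
  }
  idx <- post_stim_index(trace, 0, detection_window_ms)
  idx <- c(idx[1] - 1L, idx)            # include the step into the window
  v <- trace$voltages[idx]
  d <- diff(v)                          # step k: sample k-1 -> k post-stimulus
  over <- abs(d) > thr
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  spikes <- list()
  for (ci in cand) {
    ks <- starts[ci]:ends[ci]
    dur <- length(ks) * dt
    # negative-going: the run must contain a suprathreshold downward step
    # (a one-sample spike is a down-step immediately undone by an up-step,
    # so the net deflection over the run is ~0 by construction)
    if (dur <= max_duration_ms && min(d[ks]) < -thr) {
      t_ms <- ks[which.min(d[ks])] * dt  # end sample of steepest down-step
      spikes[[length(spikes) + 1L]] <- c(time = t_ms, last = ks[length(ks)] * dt)
    }
  }
  times <- vapply(spikes, `[[`, numeric(1), "time")
  if (length(times) > 1) {              # merge runs separated by < 1 ms
    lasts <- vapply(spikes, `[[`, numeric(1), "last")
    keep <- c(TRUE, (times[-1] - lasts[-length(lasts)]) >= 1)
    times <- times[keep]
  }
  structure(list(slice_id = trace$slice_id, condition = trace$condition,
                 intensity_percent = trace$stimulation$intensity_percent,
                 layer = trace$layer,
                 n_spikes = length(times), has_spike = length(times) >= 1,
                 spike_times_ms = times, threshold_mV = thr),
            class = "spike_score")
}

#' Fraction of responses with population spikes
#'
#' The percentage of scored traces in which at least one population spike was
#' detected, per stimulation intensity.
#'
#' @param scores List of \code{spike_score} or a data.frame with columns
#'   \code{intensity_percent}, \code{has_spike}.
#' @return data.frame with \code{intensity_percent}, \code{n},
#'   \code{n_spiking}, \code{percent}.
#' @export
spike_fraction <- function(scores) {
  df <- if (is.data.frame(scores)) scores else
    do.call(rbind, lapply(scores, function(s)
      data.frame(intensity_percent = s$intensity_percent,
                 has_spike = s$has_spike)))
  agg <- aggregate(has_spike ~ intensity_percent, df,
                   function(x) c(n = length(x), k = sum(x)))
  data.frame(intensity_percent = agg$intensity_percent,
             n = agg$has_spike[, "n"],
             n_spiking = agg$has_spike[, "k"],
             percent = 100 * agg$has_spike[, "k"] / agg$has_spike[, "n"])
}

#' Input/output curve
#'
#' Mean +/- SEM of amplitude per stimulation intensity (ascending);
#' saturation is allowed, monotonicity is not enforced.
#'
#' @param df data.frame with columns \code{intensity_percent},
#'   \code{amplitude}, and optionally grouping columns \code{condition},
#'   \code{layer}.
#' @return data.frame with \code{intensity_percent}, \code{n}, \code{mean},
#'   \code{sem} (per group if grouping columns are present), intensities
#'   sorted ascending.
#' @export
io_curve <- function(df) {
  grp <- intersect(c("condition", "layer"), names(df))
  f <- stats::as.formula(paste("amplitude ~",
                               paste(c("intensity_percent", grp), collapse = "+")))
  agg <- aggregate(f, df, function(x)
    c(n = length(x), mean = mean(x), sem = stats::sd(x) / sqrt(length(x))))
  out <- cbind(agg[setdiff(names(agg), "amplitude")],
               as.data.frame(agg$amplitude))
  out[order(out$intensity_percent), , drop = FALSE]
}

#' Return-to-baseline check
#'
#' Whether the voltage has returned to baseline 25 ms after the stimulus:
#' the mean over the 25-30 ms post-stimulus window must lie within
#' \code{tolerance} of the pre-stimulus baseline.
#'
#' @param trace An \code{fp_trace}.
#' @param tolerance_mV Absolute tolerance; default 3 baseline SDs.
#' @return List with \code{returned} (logical) and \code{residual_mV}.
#' @export
baseline_return <- function(trace, tolerance_mV = NULL) {
  base_cols <- baseline_columns(trace$stimulus_onset, trace$sampling_interval)
  base <- trace$voltages[base_cols]
  if (is.null(tolerance_mV))
    tolerance_mV <- max(3 * stats::sd(base), 1e-6)
  idx <- post_stim_index(trace, 25, 30)
  residual <- mean(trace$voltages[idx]) - mean(base)
  list(returned = abs(residual) <= tolerance_mV, residual_mV = residual)
}

#' Measure an FP cohort
#'
#' Peak-to-peak amplitude, spike score and baseline-return check for every
#' trace.
#'
#' @param traces List of \code{fp_trace}.
#' @param window_ms Peak-to-peak window.
#' @param k_sd Spike-detector threshold multiplier.
#' @return data.frame: one row per trace with \code{amplitude} (mV),
#'   \code{n_spikes}, \code{has_spike}, \code{baseline_returned}.
#' @export
measure_fp_cohort <- function(traces, window_ms = 25, k_sd = 4) {
  rows <- lapply(traces, function(tr) {
    sc <- detect_population_spikes(tr, k_sd = k_sd)
    br <- baseline_return(tr)
    data.frame(slice_id = tr$slice_id, condition = tr$condition,
               layer = tr$layer,
               intensity_percent = tr$stimulation$intensity_percent,
               electrode_distance = tr$stimulation$electrode_distance,
               amplitude = fp_amplitude(tr, window_ms),
               n_spikes = sc$n_spikes, has_spike = sc$has_spike,
               baseline_returned = br$returned)
  })
  do.call(rbind, rows)
}
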