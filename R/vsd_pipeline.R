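# VSD analysis pipeline: fractional fluorescence, trial averaging, six-diode
# layer signals, amplitude/latency extraction, display normalisation and
# laminar spatiotemporal maps.

BASELINE_MS <- 50  # baseline window preceding the stimulus

baseline_columns <- function(stimulus_onset, sampling_interval,
                             window_ms = BASELINE_MS) {
  n_base <- floor(window_ms / sampling_interval)
  cols <- (stimulus_onset - n_base + 1):stimulus_onset  # [onset-50ms, onset)
  cols[cols >= 1]
}

#' Fractional fluorescence change (dI/I)
#'
#' Per diode, the resting light intensity is the mean over the 50 ms
#' preceding the stimulus, and the signal is
#' \eqn{(I_{rest} - I(t)) / I_{rest}}, reported in percent.  With this sign
#' convention membrane depolarisation (which quenches the dye's emission)
#' gives a positive deflection.
#'
#' @param recording A \code{vsd_recording}.
#' @return A \code{fractional_signal}: list with \code{values} (sites x
#'   samples matrix, \% dI/I), \code{stimulus_onset},
#'   \code{sampling_interval}, \code{slice_id}, \code{condition},
#'   \code{stimulation}, \code{n_trials_averaged}.
#' @export
fractional_fluorescence <- function(recording) {
  I <- recording$intensities
  cols <- baseline_columns(recording$stimulus_onset, recording$sampling_interval)
  I_rest <- rowMeans(I[, cols, drop = FALSE])
  if (any(I_rest <= 0))
    abort("non-positive resting light intensity", "degenerate_input")
  values <- 100 * (I_rest - I) / I_rest
  structure(list(values = values,
                 stimulus_onset = recording$stimulus_onset,
                 sampling_interval = recording$sampling_interval,
                 slice_id = recording$slice_id,
                 condition = recording$condition,
                 stimulation = recording$stimulation,
                 n_trials_averaged = 1L),
            class = "fractional_signal")
}

#' Average stimulus-locked trials
#'
#' Element-wise mean of fractional signals from repeated detections of the
#' same slice (the three-repeat protocol).  All inputs must share shape and
#' stimulus onset.
#'
#' @param signals List of \code{fractional_signal} objects.
#' @return A \code{fractional_signal} with \code{n_trials_averaged} set.
#' @export
average_trials <- function(signals) {
  if (!length(signals)) abort("no signals to average", "invalid_parameter")
  ref <- signals[[1]]
  for (s in signals) {
    if (!identical(dim(s$values), dim(ref$values)) ||
        s$stimulus_onset != ref$stimulus_onset)
      abort("signals differ in shape or stimulus onset", "invalid_parameter")
  }
  acc <- Reduce(`+`, lapply(signals, `[[`, "values")) / length(signals)
  out <- ref
  out$values <- acc
  out$n_trials_averaged <- length(signals)
  out
}

#' Six-diode layer signal
#'
#' The layer read-out is the mean time course of six adjacent diodes: the
#' in-band active site nearest to the recording-electrode position (the seed
#' diode) plus its five nearest in-band neighbours (Euclidean distance, ties
#' broken by site id).
#'
#' @param signal A \code{fractional_signal}.
#' @param geometry The matching \code{diode_geometry} with bands assigned.
#' @param layer \code{"supragranular"} or \code{"infragranular"}.
#' @param electrode_xy Electrode position (x, y) in mm; defaults to the
#'   band centroid.
#' @param n_diodes Number of diodes averaged (default 6).
#' @return Numeric vector (\% dI/I per sample) with attribute
#'   \code{"site_ids"} naming the averaged diodes.
#' @export
layer_signal <- function(signal, geometry, layer, electrode_xy = NULL,
                         n_diodes = 6L) {
  layer <- match.arg(layer, c("supragranular", "infragranular"))
  ids <- band_sites(geometry, layer)
  if (length(ids) < n_diodes)
    abort(sprintf("layer band has %d sites; %d needed", length(ids), n_diodes),
          "config_error")
  if (is.null(electrode_xy)) electrode_xy <- electrode_position(geometry, layer)
  idx <- match(ids, geometry$site_id)
  d_el <- sqrt((geometry$x[idx] - electrode_xy[1])^2 +
               (geometry$y[idx] - electrode_xy[2])^2)
  seed_i <- order(d_el, ids)[1]
  d_seed <- sqrt((geometry$x[idx] - geometry$x[idx][seed_i])^2 +
                 (geometry$y[idx] - geometry$y[idx][seed_i])^2)
  sel <- order(d_seed, ids)[seq_len(n_diodes)]
  rows <- active_row_index(geometry, ids[sel])
  out <- colMeans(signal$values[rows, , drop = FALSE])
  attr(out, "site_ids") <- ids[sel]
  out
}

# row of an active-sites matrix corresponding to given site ids
active_row_index <- function(geometry, site_ids) {
  act_ids <- geometry$site_id[geometry$active]
  match(site_ids, act_ids)
}

#' Amplitude and latency of an evoked response
#'
#' Baseline is the mean over the 50 ms preceding the stimulus; the peak is
#' the maximum of the baseline-subtracted trace in the post-stimulus search
#' window (half-open \code{(onset, onset + search]}).  Amplitude is the peak
#' value; latency the time from stimulus to peak, at sample resolution.
#'
#' @param trace Numeric time series (\% dI/I or mV).
#' @param stimulus_onset 0-based stimulus sample index.
#' @param sampling_interval Sampling interval, ms.
#' @param search_window_ms Post-stimulus search window (default 100 ms,
#'   comfortably containing all physiological stimulus-to-peak times while
#'   excluding late drift).
#' @param baseline_window_ms Baseline window (default 50 ms).
#' @return List with \code{amplitude}, \code{latency_ms}, \code{peak_sample}
#'   (0-based), \code{baseline} and \code{flag} (\code{"flat"} for an
#'   all-equal trace, else \code{"ok"}).
#' @export
amplitude_latency <- function(trace, stimulus_onset,
                              sampling_interval = SAMPLING_INTERVAL_MS,
                              search_window_ms = 100,
                              baseline_window_ms = BASELINE_MS) {
  n <- length(trace)
  n_search <- floor(search_window_ms / sampling_interval)
  search <- (stimulus_onset + 2):min(n, stimulus_onset + 1 + n_search)
  if (length(search) < 1 || search[1] > n)
    abort("search window outside trace", "invalid_parameter")
  cols <- baseline_columns(stimulus_onset, sampling_interval, baseline_window_ms)
  baseline <- mean(trace[cols])
  resid <- trace[search] - baseline
  if (all(trace == trace[1])) {
    return(list(amplitude = 0, latency_ms = sampling_interval,
                peak_sample = stimulus_onset + 1L, baseline = baseline,
                flag = "flat"))
  }
  i <- which.max(resid)
  peak_sample <- search[i] - 1L          # back to 0-based
  list(amplitude = resid[i],
       latency_ms = (peak_sample - stimulus_onset) * sampling_interval,
       peak_sample = peak_sample, baseline = baseline, flag = "ok")
}

#' Rescale a signal to a reference dI/I
#'
#' Display transform for pseudocolour comparison across groups: values are
#' divided by the reference so the colour-map full scale corresponds to
#' \code{reference_dI} (e.g. the 0.34\% control amplitude).  Never applied
#' before measurement.
#'
#' @param signal A \code{fractional_signal} or numeric vector/matrix in \%.
#' @param reference_dI Reference amplitude in \% dI/I.
#' @return Same shape as input, scaled so \code{reference_dI} maps to 1.
#' @export
normalize_to_reference <- function(signal, reference_dI) {
  if (reference_dI <= 0) abort("reference must be positive", "invalid_parameter")
  if (inherits(signal, "fractional_signal")) {
    signal$values <- signal$values / reference_dI
    signal
  } else {
    signal / reference_dI
  }
}

#' Pseudocolour activity frames
#'
#' Per requested frame, the per-site dI/I scaled to the session maximum, with
#' site positions attached, ready for hexagonal rendering.
#'
#' @param signal A \code{fractional_signal}.
#' @param geometry The matching \code{diode_geometry}.
#' @param frame_samples Integer sample indices (0-based) to extract.
#' @return A data.frame with columns \code{site_id}, \code{x}, \code{y},
#'   \code{frame}, \code{sample}, \code{value} (session-max scaled).
#' @export
activity_map <- function(signal, geometry, frame_samples) {
  act <- geometry[geometry$active, ]
  smax <- max(abs(signal$values))
  if (smax == 0) smax <- 1
  frames <- lapply(seq_along(frame_samples), function(i) {
    sm <- frame_samples[i]
    data.frame(site_id = act$site_id, x = act$x, y = act$y,
               frame = i, sample = sm,
               value = signal$values[, sm + 1L] / smax)
  })
  do.call(rbind, frames)
}

#' Laminar depth-by-time heat map
#'
#' Active sites are binned by cortical depth (projection on the geometry's
#' cortical axis) into \code{n_depth_bins} bins; per bin and sample, the mean
#' dI/I across in-bin sites and across all supplied slices is returned.
#' All signals must be aligned on the stimulus.
#'
#' @param signals List of \code{fractional_signal} (one per slice).
#' @param geometry The matching \code{diode_geometry}.
#' @param n_depth_bins Number of depth bins (default 6, one per anatomical
#'   layer).
#' @return Matrix (depth bins x samples), shallow bin first, with attribute
#'   \code{"bin_sites"} listing the site ids per bin.
#' @export
layer_time_heatmap <- function(signals, geometry, n_depth_bins = 6L) {
  if (!length(signals)) abort("empty cohort", "invalid_parameter")
  ax <- attr(geometry, "cortical_axis")
  if (is.null(ax)) ax <- c(0, -1)
  act <- geometry[geometry$active, ]
  depth <- act$x * ax[1] + act$y * ax[2]
  edges <- seq(min(depth), max(depth), length.out = n_depth_bins + 1L)
  bin <- findInterval(depth, edges, rightmost.closed = TRUE)
  n_samples <- ncol(signals[[1]]$values)
  acc <- matrix(0, n_depth_bins, n_samples)
  for (s in signals) {
    if (ncol(s$values) != n_samples || s$stimulus_onset != signals[[1]]$stimulus_onset)
      abort("signals not aligned", "invalid_parameter")
    for (b in seq_len(n_depth_bins))
      acc[b, ] <- acc[b, ] + colMeans(s$values[bin == b, , drop = FALSE])
  }
  out <- acc / length(signals)
  attr(out, "bin_sites") <- split(act$site_id, bin)
  attr(out, "stimulus_onset") <- signals[[1]]$stimulus_onset
  out
}

#' Measure a VSD cohort
#'
#' Full pipeline for a bundle: per slice and intensity, dI/I per trial,
#' three-trial average, six-diode layer signal and amplitude/latency for both
#' layer bands.
#'
#' @param recordings List of \code{vsd_recording} (e.g. from
#'   \code{\link{generate_cohort}} or \code{\link{read_bundle}}).
#' @param geometry The matching \code{diode_geometry}.
#' @param electrode_xy Optional named list
#'   \code{list(supragranular = c(x, y), infragranular = c(x, y))}.
#' @param search_window_ms Passed to \code{\link{amplitude_latency}}.
#' @return A data.frame of measurement results: one row per slice x
#'   intensity x layer with \code{amplitude} (\% dI/I), \code{latency_ms},
#'   \code{peak_sample}, \code{flag}.
#' @export
measure_vsd_cohort <- function(recordings, geometry, electrode_xy = NULL,
                               search_window_ms = 100) {
  key <- vapply(recordings, function(r)
    paste(r$slice_id, r$stimulation$intensity_percent, sep = "@"), character(1))
  rows <- list()
  for (k in unique(key)) {
    grp <- recordings[key == k]
    sig <- average_trials(lapply(grp, fractional_fluorescence))
    r1 <- grp[[1]]
    for (ly in c("supragranular", "infragranular")) {
      exy <- if (!is.null(electrode_xy)) electrode_xy[[ly]] else NULL
      ts <- layer_signal(sig, geometry, ly, electrode_xy = exy)
      al <- amplitude_latency(ts, sig$stimulus_onset, sig$sampling_interval,
                              search_window_ms = search_window_ms)
      rows[[length(rows) + 1L]] <- data.frame(
        slice_id = r1$slice_id, condition = r1$condition, layer = ly,
        intensity_percent = r1$stimulation$intensity_percent,
        electrode_distance = r1$stimulation$electrode_distance,
        amplitude = al$amplitude, latency_ms = al$latency_ms,
        peak_sample = al$peak_sample, flag = al$flag)
    }
  }
  do.call(rbind, rows)
}
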