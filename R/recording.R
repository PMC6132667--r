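# Recording containers: single-trial VSD intensity matrices, field potential
# traces, and the stimulus descriptor shared by both.

SAMPLING_INTERVAL_MS <- 1.274
MAX_SAMPLES <- 1024L  # floor(1305 ms / 1.274 ms): maximal exposure time

#' Stimulus descriptor
#'
#' @param intensity_percent Stimulation intensity as percent of maximum
#'   (~1 mA at 100%); one of 10, 50, 100.
#' @param pulse_width_us Pulse width in microseconds (default 150).
#' @param electrode_distance Position of the stimulation electrode in the
#'   thalamocortical fiber tract relative to the cortex: \code{"short"}
#'   (rostral) or \code{"long"} (caudal).
#' @param position Free label, \code{"rostral"} or \code{"caudal"}.
#' @return A \code{stimulus_spec} list.
#' @export
stimulus_spec <- function(intensity_percent = 50, pulse_width_us = 150,
                          electrode_distance = c("short", "long"),
                          position = NULL) {
  intensity_percent <- as.numeric(intensity_percent)
  if (!intensity_percent %in% c(10, 50, 100))
    abort("intensity_percent must be one of 10, 50, 100", "invalid_parameter")
  electrode_distance <- match.arg(electrode_distance)
  if (is.null(position))
    position <- if (electrode_distance == "short") "rostral" else "caudal"
  structure(list(intensity_percent = intensity_percent,
                 pulse_width_us = pulse_width_us,
                 electrode_distance = electrode_distance,
                 position = position),
            class = "stimulus_spec")
}

#' Single-trial VSD recording
#'
#' Raw photodiode intensities for one stimulus-locked trial.  Rows follow the
#' geometry's active sites in \code{site_id} order; intensities are in
#' arbitrary fluorescence units and must be strictly positive (resting light
#' is nonzero).
#'
#' @param intensities Numeric matrix, active sites x samples.
#' @param geometry The \code{diode_geometry} the rows refer to.
#' @param stimulus_onset 0-based sample index of the stimulus pulse; must
#'   leave room for the 50 ms baseline window (>= 40 samples).
#' @param sampling_interval Sampling interval in ms (default 1.274).
#' @param trial_index Trial number within the 3-repeat protocol.
#' @param slice_id,condition Identifiers carried through to results.
#' @param stimulation A \code{stimulus_spec}.
#' @return A \code{vsd_recording} object.
#' @export
vsd_recording <- function(intensities, geometry, stimulus_onset,
                          sampling_interval = SAMPLING_INTERVAL_MS,
                          trial_index = 1L, slice_id = "slice1",
                          condition = "control",
                          stimulation = stimulus_spec()) {
  intensities <- as.matrix(intensities)
  n_active <- sum(geometry$active)
  if (nrow(intensities) != n_active)
    abort(sprintf("intensity matrix has %d rows but geometry has %d active sites",
                  nrow(intensities), n_active), "format_error")
  if (ncol(intensities) > MAX_SAMPLES)
    abort(sprintf("sample count %d exceeds the maximal recording length (%d)",
                  ncol(intensities), MAX_SAMPLES), "format_error")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    abort("intensities must be finite and strictly positive", "format_error")
  if (stimulus_onset < 40)
    abort("stimulus_onset must be >= 40 samples (50 ms baseline window)", "format_error")
  structure(list(intensities = intensities,
                 stimulus_onset = as.integer(stimulus_onset),
                 sampling_interval = sampling_interval,
                 trial_index = as.integer(trial_index),
                 slice_id = slice_id, condition = condition,
                 stimulation = stimulation),
            class = "vsd_recording")
}

#' Field potential trace
#'
#' One recording electrode's voltage time series.  The trace must extend at
#' least 25 ms beyond the stimulus so the return-to-baseline criterion can be
#' assessed.
#'
#' @param voltages Numeric vector, mV.
#' @param stimulus_onset 0-based sample index of the stimulus.
#' @param layer \code{"supragranular"} or \code{"infragranular"}.
#' @inheritParams vsd_recording
#' @return An \code{fp_trace} object.
#' @export
fp_trace <- function(voltages, stimulus_onset,
                     layer = c("supragranular", "infragranular"),
                     sampling_interval = SAMPLING_INTERVAL_MS,
                     slice_id = "slice1", condition = "control",
                     stimulation = stimulus_spec()) {
  layer <- match.arg(layer)
  voltages <- as.numeric(voltages)
  if (any(!is.finite(voltages)))
    abort("voltages must be finite", "format_error")
  post_ms <- (length(voltages) - 1 - stimulus_onset) * sampling_interval
  if (post_ms < 25)
    abort("trace must cover >= 25 ms post-stimulus", "format_error")
  structure(list(voltages = voltages,
                 stimulus_onset = as.integer(stimulus_onset),
                 sampling_interval = sampling_interval,
                 layer = layer, slice_id = slice_id, condition = condition,
                 stimulation = stimulation),
            class = "fp_trace")
}

#' @export
print.vsd_recording <- function(x, ...) {
  cat(sprintf("<vsd_recording> %s/%s trial %d: %d sites x %d samples @ %.3f ms, onset %d, %g%% SI\n",
              x$condition, x$slice_id, x$trial_index, nrow(x$intensities),
              ncol(x$intensities), x$sampling_interval, x$stimulus_onset,
              x$stimulation$intensity_percent))
  invisible(x)
}

#' @export
print.fp_trace <- function(x, ...) {
  cat(sprintf("<fp_trace> %s/%s %s: %d samples @ %.3f ms, onset %d, %g%% SI\n",
              x$condition, x$slice_id, x$layer, length(x$voltages),
              x$sampling_interval, x$stimulus_onset,
              x$stimulation$intensity_percent))
  invisible(x)
}
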