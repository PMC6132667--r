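# Synthetic cohort generator.
#
# Forward model for the recordings the analysis pipeline consumes: VSD trials
# (hexagonal array, stimulus-locked laminar response kernels), field
# potential traces (biphasic slow wave with optional population spikes), and
# behaviour sessions (per-tone freezing percentages).  All draws are
# parameterised by a condition preset and are deterministic given
# (preset, seed); per-slice random streams are derived by counter-based
# seed splitting so changing cohort size never reshuffles earlier slices.

#' Derive a child seed from a master seed and counters
#'
#' Simple multiplicative hash onto [1, 2^31 - 2]; each (master, counter...)
#' tuple gets its own reproducible stream.
#'
#' @param master Integer master seed.
#' @param ... Integer counters (slice index, trial, stream id...).
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  ks <- c(master, ...)
  h <- 104729
  for (k in ks) h <- (h * 69069 + as.numeric(k) + 1) %% 2147483629
  as.integer(h + 1)
}

# moment-matched positive draw: Gamma with exact mean m and SD s
draw_pos <- function(n, m, s) {
  if (m <= 0) return(rep(0, n))
  if (s <= 0) return(rep(m, n))
  shape <- (m / s)^2
  rgamma(n, shape = shape, rate = shape / m)
}

# latency draw in ms: normal, floored at one sampling interval
draw_latency <- function(n, m, s, dt = SAMPLING_INTERVAL_MS) {
  pmax(dt, rnorm(n, m, s))
}

#' Slice-level generative parameters
#'
#' Draws the per-slice response parameters (peak dI/I and FP peak-to-peak
#' amplitude per layer at 50\% SI, stimulus-to-peak latency per layer and
#' electrode distance) from the preset's between-slice distributions.
#' Amplitudes use a moment-matched Gamma (positive support, exact mean and
#' SD); latencies are Gaussian and snapped to the sampling grid at use.
#' The draw depends only on (preset, seed, slice_index), so all trials,
#' intensities and modalities of one slice share one parameter set.
#'
#' @param preset A \code{condition_preset}.
#' @param slice_index Integer slice counter within the cohort.
#' @param seed Master seed.
#' @return Named list of slice parameters.
#' @export
slice_params <- function(preset, slice_index, seed) {
  set.seed(derive_seed(seed, 1000L + slice_index, 1L))
  p <- preset
  out <- list(slice_id = sprintf("%s_s%03d", p$label, slice_index))
  for (ly in c("supragranular", "infragranular")) {
    out[[paste0("vsd_amp_", ly)]] <-
      draw_pos(1, p$vsd_amp[[ly]]$mean, preset_sd(p$vsd_amp[[ly]], p$n_slices))
    out[[paste0("fp_amp_", ly)]] <-
      draw_pos(1, p$fp_amp[[ly]]$mean, preset_sd(p$fp_amp[[ly]], p$n_slices))
    for (d in c("short", "long")) {
      lm <- p$latency_ms[[ly]][[d]]
      out[[paste0("latency_", ly, "_", d)]] <-
        draw_latency(1, lm$mean, preset_sd(lm, p$latency_n))
    }
  }
  out
}

# laminar response kernel: linear rise from stimulus to the peak sample,
# exponential decay with a layer-specific time constant afterwards.  The
# peak falls exactly on a sample, so the kernel maximum is exactly 1.
response_kernel <- function(n_post, peak_sample, tau_ms, dt = SAMPLING_INTERVAL_MS) {
  u <- seq_len(n_post) - 1
  k <- ifelse(u <= peak_sample, u / peak_sample,
              exp(-(u - peak_sample) * dt / tau_ms))
  k
}

VSD_TAU_MS <- c(supragranular = 5, infragranular = 20)  # transient vs sustained

#' Generate one synthetic VSD trial
#'
#' Raw intensities are \code{resting_light * (1 - r(t, site)) + noise} where
#' the per-site response \code{r} rises linearly to its peak at the slice's
#' (grid-snapped) latency and decays exponentially: transiently in the
#' supragranular band (tau = 5 ms), sustained in the infragranular band
#' (tau = 20 ms).  Peak dI/I per layer is the slice's amplitude draw scaled
#' by the intensity's input/output factor.  Running the analysis pipeline on
#' the output recovers the drawn parameters (exactly at zero noise).
#'
#' @inheritParams slice_params
#' @param geometry A \code{diode_geometry} with layer bands assigned.
#' @param stimulation A \code{stimulus_spec}.
#' @param trial_index Trial number (1-3).
#' @param n_samples Recording length in samples (default 1024).
#' @param stimulus_onset Stimulus sample index (default 79, ~100 ms).
#' @return A \code{vsd_recording}; attribute \code{"ground_truth"} holds the
#'   realised per-layer amplitude (\% dI/I) and snapped latency (ms).
#' @export
generate_vsd_trial <- function(preset, geometry, stimulation, slice_index,
                               trial_index, seed, n_samples = 1024L,
                               stimulus_onset = 79L) {
  sp <- slice_params(preset, slice_index, seed)
  fac <- io_factor(preset, stimulation$intensity_percent, "vsd")
  dist <- stimulation$electrode_distance
  dt <- SAMPLING_INTERVAL_MS
  I0 <- preset$noise$resting_light
  n_post <- n_samples - stimulus_onset
  act <- geometry[geometry$active, ]
  mat <- matrix(I0, nrow = nrow(act), ncol = n_samples)
  truth <- list(slice_id = sp$slice_id)
  for (ly in c("supragranular", "infragranular")) {
    amp <- sp[[paste0("vsd_amp_", ly)]] * fac           # % dI/I
    lat <- sp[[paste0("latency_", ly, "_", dist)]]
    peak_sample <- max(1L, round(lat / dt))
    rows <- which(act$layer_band == ly)
    if (amp > 0) {
      k <- response_kernel(n_post, peak_sample, VSD_TAU_MS[[ly]], dt)
      mat[rows, (stimulus_onset + 1):n_samples] <-
        rep(I0 * (1 - (amp / 100) * k), each = length(rows))
    }
    truth[[paste0("amp_", ly)]] <- amp
    truth[[paste0("latency_", ly)]] <- peak_sample * dt
  }
  sd_I <- I0 * preset$noise$vsd_sd_percent / 100
  if (sd_I > 0) {
    set.seed(derive_seed(seed, 1000L + slice_index, 10L + trial_index,
                         as.integer(stimulation$intensity_percent)))
    mat <- mat + matrix(rnorm(length(mat), 0, sd_I), nrow = nrow(mat))
  }
  rec <- vsd_recording(mat, geometry, stimulus_onset,
                       trial_index = trial_index, slice_id = sp$slice_id,
                       condition = preset$label, stimulation = stimulation)
  attr(rec, "ground_truth") <- truth
  rec
}

# Field-potential wave-shape constants (sample units, dt = 1.274 ms).
# The fall limb's per-sample slope is kept outside the band where the
# derivative spike detector is ambiguous: large waves fall steeply over >= 3
# samples (rejected by the fast-transient duration cap), small waves fall
# with a slope safely below the detection threshold.  Constants are relative
# to the nominal baseline noise floor.
FP_RISE_END <- 1L        # rise complete one sample (~1.3 ms) after stimulus
FP_FALL_START <- 9L      # plateau carrying spikes ends ~11.5 ms post-stimulus
FP_RETURN_SAMPLE <- 19L  # back to baseline by sample 19 (~24.2 ms)
FP_POS_FRACTION <- 0.56  # share of peak-to-peak above baseline
FP_SPIKE_DEPTH <- 0.35   # mV, population-spike transient depth
FP_NOISE_FLOOR <- 0.005  # mV, nominal baseline noise for shape selection

fp_wave <- function(A, n_post, fp_sd) {
  s <- numeric(n_post)                  # sample 1 = stimulus sample (u = 0)
  if (A <= 0) return(s)
  P <- FP_POS_FRACTION * A
  N <- A - P
  sd_eff <- max(fp_sd, FP_NOISE_FLOOR)
  sigd <- sqrt(2) * sd_eff              # SD of baseline first differences
  steep_min <- 3 * 7.5 * sigd           # smallest p2p with a steep >=3-sample fall
  u <- seq_len(n_post) - 1
  if (A >= steep_min) {
    n_fall <- min(9L, max(3L, floor(A / (10 * sigd))))
    fall_from <- FP_FALL_START
  } else {
    n_fall <- FP_RETURN_SAMPLE - FP_RISE_END  # slow shallow descent
    fall_from <- FP_RISE_END
  }
  fall_to <- min(fall_from + n_fall, FP_RETURN_SAMPLE - 1L)
  bp_u <- c(0, FP_RISE_END, fall_from, fall_to, FP_RETURN_SAMPLE)
  bp_v <- c(0, P, P, -N, 0)
  keep <- !duplicated(bp_u)
  inside <- u <= FP_RETURN_SAMPLE
  s[inside] <- approx(bp_u[keep], bp_v[keep], xout = u[inside])$y
  s
}

#' Generate one synthetic field potential trace
#'
#' A stylised biphasic wave: fast rise to the positive peak, a plateau over
#' the 3-10 ms window where population spikes may occur, a negative-going
#' fall to the trough and a return to baseline by ~24 ms post-stimulus.  The
#' noiseless peak-to-peak amplitude on the sample grid equals the slice's
#' amplitude draw exactly.  With probability \code{spike_prob[intensity]},
#' 1-2 sharp (one-sample, ~1.3 ms) negative transients of 0.35 mV are
#' superimposed 3-10 ms post-stimulus.
#'
#' @inheritParams generate_vsd_trial
#' @param layer \code{"supragranular"} or \code{"infragranular"}.
#' @param n_samples Trace length (default 128).
#' @return An \code{fp_trace}; attribute \code{"ground_truth"} holds the
#'   drawn amplitude, the noiseless on-grid peak-to-peak value, and the
#'   injected spike count/times.
#' @export
generate_fp_trace <- function(preset, layer, stimulation, slice_index, seed,
                              n_samples = 128L, stimulus_onset = 79L) {
  layer <- match.arg(layer, c("supragranular", "infragranular"))
  sp <- slice_params(preset, slice_index, seed)
  fac <- io_factor(preset, stimulation$intensity_percent, "fp")
  A <- sp[[paste0("fp_amp_", layer)]] * fac
  fp_sd <- preset$noise$fp_sd_mV
  n_post <- n_samples - stimulus_onset
  wave <- fp_wave(A, n_post, fp_sd)

  key <- as.character(as.integer(stimulation$intensity_percent))
  p_spike <- preset$spike_prob[[key]]
  if (is.null(p_spike))
    abort(sprintf("unknown stimulation intensity %s%%", key), "invalid_parameter")
  # spike occurrence is a slice-level network event: one draw per
  # slice x intensity, shared by both recording electrodes
  set.seed(derive_seed(seed, 1000L + slice_index, 30L,
                       as.integer(stimulation$intensity_percent)))
  spike_occurs <- runif(1) < p_spike
  set.seed(derive_seed(seed, 1000L + slice_index,
                       20L + (layer == "infragranular"),
                       as.integer(stimulation$intensity_percent)))
  spike_samples <- integer(0)
  if (spike_occurs) {
    n_sp <- sample(1:2, 1)
    if (n_sp == 1L) {
      spike_samples <- sample(3:7, 1)
    } else {
      # pairs separated by >= 3 samples so the two transients stay distinct
      pairs <- list(c(3L, 6L), c(3L, 7L), c(4L, 7L))
      spike_samples <- pairs[[sample(length(pairs), 1)]]
    }
    wave[spike_samples + 1L] <- wave[spike_samples + 1L] - FP_SPIKE_DEPTH
  }
  v <- numeric(n_samples)
  v[(stimulus_onset + 1):n_samples] <- wave
  if (fp_sd > 0) v <- v + rnorm(n_samples, 0, fp_sd)
  tr <- fp_trace(v, stimulus_onset, layer = layer, slice_id = sp$slice_id,
                 condition = preset$label, stimulation = stimulation)
  attr(tr, "ground_truth") <- list(
    amp_drawn = A,
    p2p_noiseless = max(wave) - min(wave),
    n_spikes = length(spike_samples),
    spike_times_ms = spike_samples * SAMPLING_INTERVAL_MS)
  tr
}

#' Generate a full recording cohort
#'
#' Per slice and stimulation intensity: three repeated VSD trials (the
#' averaging protocol) plus one FP trace per layer.  Deterministic under a
#' fixed seed.
#'
#' @inheritParams generate_vsd_trial
#' @param n_slices Number of slices.
#' @param intensities Stimulation intensities in percent (subset of 10/50/100).
#' @param electrode_distance \code{"short"} or \code{"long"}.
#' @param n_samples,stimulus_onset Recording dimensions.
#' @param vsd Logical: generate the VSD trials (set \code{FALSE} for
#'   FP-only cohorts, which are much lighter).
#' @return List with \code{geometry}, \code{recordings}, \code{traces} (a
#'   bundle, writable with \code{\link{write_bundle}}) plus a
#'   \code{ground_truth} data.frame of the realised slice parameters.
#' @export
generate_cohort <- function(preset, geometry, n_slices = preset$n_slices,
                            intensities = 50, seed = 1L,
                            electrode_distance = "short",
                            n_samples = 1024L, stimulus_onset = 79L,
                            vsd = TRUE) {
  if (n_slices < 1) abort("n_slices must be >= 1", "config_error")
  recordings <- list(); traces <- list(); gt <- list()
  for (s in seq_len(n_slices)) {
    for (si in intensities) {
      stim <- stimulus_spec(si, electrode_distance = electrode_distance)
      if (vsd) {
        for (tr in 1:3) {
          rec <- generate_vsd_trial(preset, geometry, stim, s, tr, seed,
                                    n_samples = n_samples,
                                    stimulus_onset = stimulus_onset)
          recordings[[length(recordings) + 1L]] <- rec
          if (tr == 1L) {
            g <- attr(rec, "ground_truth")
            gt[[length(gt) + 1L]] <- data.frame(
              slice_id = g$slice_id, intensity_percent = si,
              amp_supragranular = g$amp_supragranular,
              amp_infragranular = g$amp_infragranular,
              latency_supragranular = g$latency_supragranular,
              latency_infragranular = g$latency_infragranular)
          }
        }
      }
      for (ly in c("supragranular", "infragranular")) {
        traces[[length(traces) + 1L]] <-
          generate_fp_trace(preset, ly, stim, s, seed,
                            stimulus_onset = stimulus_onset)
      }
    }
  }
  list(geometry = geometry, recordings = recordings, traces = traces,
       ground_truth = if (length(gt)) do.call(rbind, gt) else NULL)
}

#' Generate a behaviour cohort
#'
#' Per animal and tone (2.5 kHz neutral, 10 kHz conditioned), a freezing
#' percentage drawn from a Beta distribution moment-matched to the preset's
#' (mean, SD = SEM * sqrt(n)).  The paired structure (one animal, both
#' tones) is preserved through a Gaussian copula with correlation 0.5.
#'
#' @inheritParams slice_params
#' @param n_animals Number of animals.
#' @param rho Within-animal correlation of the two tone responses.
#' @return A data.frame with columns \code{animal_id}, \code{condition},
#'   \code{tone}, \code{freezing_percent}.
#' @export
generate_behavior_cohort <- function(preset, n_animals = preset$n_animals,
                                     seed = 1L, rho = 0.5) {
  tones <- c("2.5kHz", "10kHz")
  rows <- vector("list", n_animals * 2L)
  k <- 0L
  for (a in seq_len(n_animals)) {
    set.seed(derive_seed(seed, 2000L + a))
    z0 <- rnorm(1)
    for (tone in tones) {
      fz <- preset$freezing[[tone]]
      sdv <- preset_sd(fz, preset$n_animals)
      z <- rho * z0 + sqrt(1 - rho^2) * rnorm(1)
      val <- beta_quantile_pct(pnorm(z), fz$mean, sdv)
      k <- k + 1L
      rows[[k]] <- data.frame(
        animal_id = sprintf("%s_a%03d", preset$label, a),
        condition = preset$label, tone = tone, freezing_percent = val)
    }
  }
  do.call(rbind, rows)
}

# Beta quantile on the 0-100 scale, moment-matched to (mean, sd) in percent.
# Degenerate cases: sd 0 -> the mean; variance at/above the Bernoulli bound
# is shrunk to 95% of it.
beta_quantile_pct <- function(u, mean_pct, sd_pct) {
  if (sd_pct <= 0) return(mean_pct)
  m <- mean_pct / 100
  if (m <= 0) return(0)
  if (m >= 1) return(100)
  v <- min((sd_pct / 100)^2, 0.95 * m * (1 - m))
  nu <- m * (1 - m) / v - 1
  100 * qbeta(u, m * nu, (1 - m) * nu)
}

#' Variant of a preset with dispersion and/or noise removed
#'
#' Convenience for zero-noise identity checks and bias studies: optionally
#' sets every SEM to zero (all slices identical at the group mean) and/or the
#' measurement noise to zero.
#'
#' @param preset A \code{condition_preset}.
#' @param zero_sem Set all between-slice/between-animal SEMs to 0.
#' @param zero_noise Set diode and FP measurement noise to 0.
#' @return A modified \code{condition_preset}.
#' @export
preset_variant <- function(preset, zero_sem = FALSE, zero_noise = FALSE) {
  p <- unclass(preset)
  if (zero_sem) {
    for (ly in c("supragranular", "infragranular")) {
      p$vsd_amp[[ly]]$sem <- 0
      p$fp_amp[[ly]]$sem <- 0
      for (d in c("short", "long")) p$latency_ms[[ly]][[d]]$sem <- 0
    }
    for (tone in names(p$freezing)) p$freezing[[tone]]$sem <- 0
  }
  if (zero_noise) {
    p$noise$vsd_sd_percent <- 0
    p$noise$fp_sd_mV <- 0
  }
  class(p) <- "condition_preset"
  p
}
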