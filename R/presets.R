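# Condition presets: the generative parameters for each experimental group.

preset_cache <- new.env(parent = emptyenv())

#' All condition presets
#'
#' Loads the preset table shipped with the package (a YAML file under
#' \code{inst/extdata}).  Each preset carries per-layer VSD and FP amplitude
#' means with their SEM at the group size, per-layer/per-distance latencies,
#' per-intensity population-spike probabilities, per-tone freezing
#' parameters, and the shared noise model.
#'
#' @param file Optional path to an alternative preset YAML.
#' @return Named list of \code{condition_preset} objects.
#' @export
condition_presets <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(preset_cache$default)) return(preset_cache$default)
    file <- system.file("extdata", "condition_presets.yaml", package = "vsdlamina")
  }
  raw <- yaml::read_yaml(file)
  out <- lapply(names(raw$presets), function(lab) {
    new_condition_preset(lab, raw$presets[[lab]], raw$noise)
  })
  names(out) <- names(raw$presets)
  if (identical(file, system.file("extdata", "condition_presets.yaml",
                                  package = "vsdlamina")))
    preset_cache$default <- out
  out
}

#' A single condition preset
#' @param label Preset name, e.g. \code{"control"}, \code{"cuprizone"},
#'   \code{"remy7"}, \code{"remy7_dmf"}.
#' @return A \code{condition_preset} object.
#' @export
condition_preset <- function(label) {
  ps <- condition_presets()
  if (!label %in% names(ps))
    abort(sprintf("unknown preset '%s'", label), "config_error")
  ps[[label]]
}

new_condition_preset <- function(label, p, noise) {
  stopifnot(is.list(p))
  chk_ms <- function(x, what) {
    if (!is.numeric(x$mean) || !is.numeric(x$sem) || x$sem < 0)
      abort(sprintf("preset %s: bad %s", label, what), "config_error")
  }
  for (ly in c("supragranular", "infragranular")) {
    chk_ms(p$vsd_amp[[ly]], paste("vsd_amp", ly))
    chk_ms(p$fp_amp[[ly]], paste("fp_amp", ly))
    for (d in c("short", "long")) chk_ms(p$latency_ms[[ly]][[d]], paste("latency", ly, d))
  }
  if (any(unlist(p$spike_prob) < 0) || any(unlist(p$spike_prob) > 1))
    abort(sprintf("preset %s: spike_prob outside [0,1]", label), "config_error")
  for (tone in names(p$freezing)) {
    fz <- p$freezing[[tone]]
    if (fz$mean < 0 || fz$mean > 100 || fz$sem < 0)
      abort(sprintf("preset %s: freezing %s outside [0,100]", label, tone), "config_error")
  }
  structure(c(list(label = label), p, list(noise = noise)),
            class = "condition_preset")
}

#' Between-slice (or between-animal) SD implied by a printed mean +/- SEM
#'
#' Group dispersion is reconstructed as \code{sem * sqrt(n)} so that a
#' synthetic cohort of the printed size reproduces the printed SEM in
#' expectation.
#'
#' @param ms A list with \code{mean} and \code{sem}.
#' @param n Group size the SEM was printed at.
#' @return Numeric SD.
#' @export
preset_sd <- function(ms, n) ms$sem * sqrt(n)

#' Amplitude scaling across stimulation intensities
#' @noRd
io_factor <- function(preset, intensity_percent, what = c("vsd", "fp")) {
  what <- match.arg(what)
  tab <- if (what == "vsd") preset$io_scale else preset$fp_io_scale
  key <- as.character(as.integer(intensity_percent))
  if (!key %in% names(tab))
    abort(sprintf("unknown stimulation intensity %s%%", key), "invalid_parameter")
  tab[[key]]
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("<condition_preset> %s: n_slices=%d n_animals=%d\n",
              x$label, x$n_slices, x$n_animals))
  cat(sprintf("  vsd 50%%SI (%%dI/I): supra %.2f+/-%.2f, infra %.2f+/-%.2f\n",
              x$vsd_amp$supragranular$mean, x$vsd_amp$supragranular$sem,
              x$vsd_amp$infragranular$mean, x$vsd_amp$infragranular$sem))
  cat(sprintf("  fp 50%%SI (mV): supra %.2f+/-%.2f, infra %.2f+/-%.2f\n",
              x$fp_amp$supragranular$mean, x$fp_amp$supragranular$sem,
              x$fp_amp$infragranular$mean, x$fp_amp$infragranular$sem))
  cat(sprintf("  freezing %%: 2.5kHz %.1f+/-%.1f, 10kHz %.1f+/-%.1f\n",
              x$freezing[["2.5kHz"]]$mean, x$freezing[["2.5kHz"]]$sem,
              x$freezing[["10kHz"]]$mean, x$freezing[["10kHz"]]$sem))
  invisible(x)
}
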