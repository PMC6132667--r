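# Recording-bundle I/O.
#
# A bundle is a directory holding a JSON metadata sidecar plus one CSV matrix
# per VSD trial (rows = active sites in site_id order, columns = samples) and
# one single-column CSV per field potential trace.  All reals are serialised
# with 15 significant digits, so a write/read round trip is lossless at the
# stated precision.

#' Write a recording bundle
#'
#' @param geometry A \code{diode_geometry}.
#' @param recordings List of \code{vsd_recording} (may be empty).
#' @param traces List of \code{fp_trace} (may be empty).
#' @param path Directory to create (must not exist or be empty).
#' @return \code{path}, invisibly.
#' @export
write_bundle <- function(geometry, recordings, traces, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  stim_meta <- function(s) {
    list(intensity_percent = s$intensity_percent,
         pulse_width_us = s$pulse_width_us,
         electrode_distance = s$electrode_distance,
         position = s$position)
  }
  rec_meta <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    file <- sprintf("vsd_%03d.csv", i)
    data.table::fwrite(data.table::as.data.table(r$intensities),
                       file.path(path, file), col.names = FALSE)
    rec_meta[[i]] <- list(file = file, slice_id = r$slice_id,
                          condition = r$condition,
                          trial_index = r$trial_index,
                          stimulus_onset = r$stimulus_onset,
                          sampling_interval = r$sampling_interval,
                          n_samples = ncol(r$intensities),
                          stimulation = stim_meta(r$stimulation))
  }
  tr_meta <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    file <- sprintf("fp_%03d.csv", i)
    data.table::fwrite(data.table::data.table(voltage_mV = tr$voltages),
                       file.path(path, file))
    tr_meta[[i]] <- list(file = file, slice_id = tr$slice_id,
                         condition = tr$condition, layer = tr$layer,
                         stimulus_onset = tr$stimulus_onset,
                         sampling_interval = tr$sampling_interval,
                         n_samples = length(tr$voltages),
                         stimulation = stim_meta(tr$stimulation))
  }
  meta <- list(
    format = "vsdlamina-bundle",
    version = 1L,
    geometry = list(rings = attr(geometry, "rings"),
                    spacing = attr(geometry, "spacing"),
                    deactivated_sites = geometry$site_id[!geometry$active],
                    supra_fraction = attr(geometry, "supra_fraction"),
                    cortical_axis = attr(geometry, "cortical_axis")),
    recordings = rec_meta,
    traces = tr_meta
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording bundle
#'
#' Validates the sidecar against the stored matrices; malformed bundles raise
#' a \code{format_error} naming the offending field.
#'
#' @param path Bundle directory written by \code{\link{write_bundle}}.
#' @return A list with elements \code{geometry}, \code{recordings},
#'   \code{traces}.
#' @export
read_bundle <- function(path) {
  side <- file.path(path, "metadata.json")
  if (!file.exists(side)) abort("missing metadata.json sidecar", "format_error")
  meta <- tryCatch(jsonlite::read_json(side, simplifyVector = TRUE),
                   error = function(e) abort("unparseable metadata.json", "format_error"))
  if (is.null(meta$format) || meta$format != "vsdlamina-bundle")
    abort("sidecar field 'format' is not a vsdlamina bundle", "format_error")
  gm <- meta$geometry
  geometry <- build_hex_geometry(gm$rings, gm$spacing,
                                 deactivated_sites = as.integer(unlist(gm$deactivated_sites)))
  if (!is.null(gm$supra_fraction) && length(gm$supra_fraction))
    geometry <- assign_layer_bands(geometry, gm$supra_fraction,
                                   as.numeric(unlist(gm$cortical_axis)))
  n_active <- sum(geometry$active)

  as_records <- function(m) {
    # jsonlite may give a data.frame (several records) or a list (none)
    if (is.data.frame(m)) split(m, seq_len(nrow(m))) else list()
  }
  recordings <- lapply(as_records(meta$recordings), function(rm) {
    f <- file.path(path, rm$file)
    if (!file.exists(f)) abort(sprintf("missing matrix file %s", rm$file), "format_error")
    mat <- as.matrix(data.table::fread(f, header = FALSE))
    dimnames(mat) <- NULL
    if (nrow(mat) != n_active)
      abort(sprintf("sidecar claims %d sites but %s has %d rows",
                    n_active, rm$file, nrow(mat)), "format_error")
    if (ncol(mat) != rm$n_samples)
      abort(sprintf("sidecar field n_samples (%d) does not match %s (%d columns)",
                    rm$n_samples, rm$file, ncol(mat)), "format_error")
    st <- rm$stimulation
    vsd_recording(mat, geometry, rm$stimulus_onset,
                  sampling_interval = rm$sampling_interval,
                  trial_index = rm$trial_index, slice_id = rm$slice_id,
                  condition = rm$condition,
                  stimulation = stimulus_spec(st$intensity_percent,
                                              st$pulse_width_us,
                                              st$electrode_distance,
                                              st$position))
  })
  traces <- lapply(as_records(meta$traces), function(tm) {
    f <- file.path(path, tm$file)
    if (!file.exists(f)) abort(sprintf("missing trace file %s", tm$file), "format_error")
    v <- data.table::fread(f, header = TRUE)[[1]]
    if (length(v) != tm$n_samples)
      abort(sprintf("sidecar field n_samples (%d) does not match %s (%d rows)",
                    tm$n_samples, tm$file, length(v)), "format_error")
    st <- tm$stimulation
    fp_trace(v, tm$stimulus_onset, layer = tm$layer,
             sampling_interval = tm$sampling_interval, slice_id = tm$slice_id,
             condition = tm$condition,
             stimulation = stimulus_spec(st$intensity_percent,
                                         st$pulse_width_us,
                                         st$electrode_distance,
                                         st$position))
  })
  names(recordings) <- NULL
  names(traces) <- NULL
  list(geometry = geometry, recordings = recordings, traces = traces)
}
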