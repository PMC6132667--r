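# Hexagonal photodiode array geometry and cortical layer bands.
#
# The imaging detector is a centered hexagonal lattice of photodiodes.  A
# 12-ring lattice has 469 sites; deactivating 5 designated edge sites yields
# the 464 active channels of the recording system, covering 0.416 mm^2 of
# cortex under the objective.

#' Stop with a classed condition
#' @noRd
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("vsdlamina_", class), "error", "condition")))
}

#' Diode spacing that realises a given imaged area
#'
#' On a hexagonal lattice each site owns a hexagonal cell of area
#' \eqn{(\sqrt{3}/2) s^2} where \eqn{s} is the nearest-neighbour spacing, so
#' the field of view of \code{n_active} diodes fixes \eqn{s}.
#'
#' @param area_mm2 Total imaged area in mm^2.
#' @param n_active Number of active diodes.
#' @return Spacing in mm.
#' @export
hex_spacing_for_area <- function(area_mm2 = 0.416, n_active = 464L) {
  if (area_mm2 <= 0 || n_active <= 0) abort("area and count must be positive", "invalid_parameter")
  sqrt(area_mm2 / (n_active * sqrt(3) / 2))
}

#' Build a centered hexagonal diode-array geometry
#'
#' Sites are laid out on a centered hexagonal lattice of \code{rings} rings
#' around a central diode (\eqn{3 r (r+1) + 1} sites in total).  Axial
#' coordinates (q, r) follow the usual convention for pointy-top hex grids;
#' physical positions are in mm with the y axis pointing towards the pial
#' surface (shallow cortex up).  Site ordering, and therefore \code{site_id},
#' is a deterministic function of the lattice parameters.
#'
#' @param rings Number of rings around the central site (>= 1).
#' @param spacing Nearest-neighbour distance in mm (> 0).
#' @param deactivated_sites Integer vector of site ids to mark inactive
#'   (e.g. truncated corners of a commercial array).  Must be distinct and
#'   within the lattice.
#' @return An object of class \code{diode_geometry}: a data.frame with columns
#'   \code{site_id}, \code{q}, \code{r}, \code{x}, \code{y}, \code{active},
#'   \code{layer_band} plus attributes \code{rings} and \code{spacing}.
#' @examples
#' g <- build_hex_geometry(rings = 1, spacing = 0.1)
#' nrow(g)  # 7
#' @export
build_hex_geometry <- function(rings, spacing, deactivated_sites = integer(0)) {
  if (length(rings) != 1L || rings < 1 || rings != round(rings))
    abort("rings must be a positive integer", "invalid_parameter")
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    abort("spacing must be positive", "invalid_parameter")
  rings <- as.integer(rings)
  q <- integer(0); r <- integer(0)
  for (qq in seq(-rings, rings)) {
    rr <- seq(max(-rings, -qq - rings), min(rings, -qq + rings))
    q <- c(q, rep.int(qq, length(rr)))
    r <- c(r, rr)
  }
  n <- length(q)
  if (anyDuplicated(deactivated_sites))
    abort("duplicate deactivated sites", "invalid_parameter")
  if (length(deactivated_sites) &&
      (any(deactivated_sites < 1) || any(deactivated_sites > n)))
    abort("deactivated sites outside lattice", "invalid_parameter")
  geom <- data.frame(
    site_id = seq_len(n),
    q = q, r = r,
    x = spacing * (q + r / 2),
    y = spacing * (sqrt(3) / 2) * r,
    active = TRUE,
    layer_band = factor(rep("none", n), levels = c("supragranular", "infragranular", "none")),
    stringsAsFactors = FALSE
  )
  geom$active[as.integer(deactivated_sites)] <- FALSE
  structure(geom, class = c("diode_geometry", "data.frame"),
            rings = rings, spacing = spacing)
}

#' Site ids of selected lattice corners
#'
#' Helper returning the site ids of \code{n} of the six corners of the outer
#' ring; used to truncate the lattice down to the physical channel count.
#'
#' @param geometry A \code{diode_geometry}.
#' @param n How many corners (1-6).
#' @return Integer site ids.
#' @export
corner_sites <- function(geometry, n = 5L) {
  rings <- attr(geometry, "rings")
  corners <- rbind(c(rings, 0L), c(0L, rings), c(-rings, rings),
                   c(-rings, 0L), c(0L, -rings), c(rings, -rings))
  ids <- vapply(seq_len(n), function(i) {
    geometry$site_id[geometry$q == corners[i, 1] & geometry$r == corners[i, 2]]
  }, integer(1))
  ids
}

#' The standard 464-channel array
#'
#' A 12-ring centered hexagonal lattice (469 sites) with 5 corner sites
#' deactivated, giving 464 active channels; spacing is derived from the
#' 0.416 mm^2 field of view.  Layer bands are assigned with the default
#' partition (see \code{\link{assign_layer_bands}}).
#'
#' @param supra_fraction Fraction of the depth span assigned to the
#'   supragranular band (layers I-III of six), default 0.4.
#' @return A \code{diode_geometry} with 464 active sites and layer bands set.
#' @export
standard_geometry <- function(supra_fraction = 0.4) {
  g <- build_hex_geometry(rings = 12L, spacing = hex_spacing_for_area(0.416, 464L))
  g <- build_hex_geometry(rings = 12L, spacing = hex_spacing_for_area(0.416, 464L),
                          deactivated_sites = corner_sites(g, 5L))
  assign_layer_bands(g, supra_fraction = supra_fraction)
}

#' Assign supra- and infragranular layer bands by cortical depth
#'
#' Active sites are projected onto the cortical depth axis; those falling in
#' the shallow \code{supra_fraction} of the span become supragranular
#' (layers I-III), the rest infragranular (layers IV-VI).  The default axis
#' \code{c(0, -1)} maps the upper half of the hexagon to shallow cortex.
#'
#' @param geometry A \code{diode_geometry}.
#' @param supra_fraction Fraction in (0, 1) of the depth span that is
#'   supragranular.
#' @param cortical_axis Length-2 vector pointing from shallow to deep cortex.
#' @return The geometry with \code{layer_band} filled in for active sites.
#' @export
assign_layer_bands <- function(geometry, supra_fraction = 0.4,
                               cortical_axis = c(0, -1)) {
  if (!inherits(geometry, "diode_geometry")) abort("not a diode_geometry", "invalid_parameter")
  if (length(supra_fraction) != 1L || supra_fraction <= 0 || supra_fraction >= 1)
    abort("supra_fraction must be in (0,1)", "invalid_parameter")
  nrm <- sqrt(sum(cortical_axis^2))
  if (length(cortical_axis) != 2L || !is.finite(nrm) || nrm == 0)
    abort("degenerate cortical axis", "invalid_parameter")
  ax <- cortical_axis / nrm
  depth <- geometry$x * ax[1] + geometry$y * ax[2]
  act <- geometry$active
  span <- range(depth[act])
  cut <- span[1] + supra_fraction * diff(span)
  band <- ifelse(depth < cut, "supragranular", "infragranular")
  # both bands must be nonempty among active sites
  if (!any(band[act] == "supragranular") || !any(band[act] == "infragranular"))
    abort("layer partition degenerate: one band empty", "invalid_parameter")
  geometry$layer_band <- factor(ifelse(act, band, "none"),
                                levels = c("supragranular", "infragranular", "none"))
  attr(geometry, "supra_fraction") <- supra_fraction
  attr(geometry, "cortical_axis") <- ax
  geometry
}

#' Active sites of one layer band
#' @param geometry A \code{diode_geometry} with bands assigned.
#' @param layer \code{"supragranular"} or \code{"infragranular"}.
#' @return Integer site ids.
#' @export
band_sites <- function(geometry, layer) {
  layer <- match.arg(layer, c("supragranular", "infragranular"))
  geometry$site_id[geometry$active & geometry$layer_band == layer]
}

#' Default recording-electrode position for a layer band
#'
#' The centroid of the band's active sites; used as the reference point for
#' six-diode layer averaging when no measured electrode coordinate is given.
#'
#' @inheritParams band_sites
#' @return Length-2 numeric (x, y) in mm.
#' @export
electrode_position <- function(geometry, layer) {
  ids <- band_sites(geometry, layer)
  i <- match(ids, geometry$site_id)
  c(x = mean(geometry$x[i]), y = mean(geometry$y[i]))
}

#' @export
print.diode_geometry <- function(x, ...) {
  cat(sprintf("<diode_geometry> %d rings, %d sites (%d active), spacing %.4f mm\n",
              attr(x, "rings"), nrow(x), sum(x$active), attr(x, "spacing")))
  tab <- table(x$layer_band[x$active])
  cat(sprintf("  bands: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
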