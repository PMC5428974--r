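#' Mitotic spindle-plane angle
#'
#' Acute angle, in degrees, between the line connecting the two
#' centrosomes of a dividing cell and the ventricular surface line.
#' Symmetric in the order of the points; invariant under joint
#' translation, rotation and scaling.
#'
#' @param centrosome_a,centrosome_b numeric length-2 (x, y) positions of
#'   the centrosomes (same units, e.g. micrometres).
#' @param surface_a,surface_b two distinct points defining the
#'   ventricular surface line.
#' @return Angle in degrees, in [0, 90].
#' @examples
#' spindle_angle(c(0, 0), c(1, 1), c(0, 0), c(1, 0))  # 45
#' @export
spindle_angle <- function(centrosome_a, centrosome_b, surface_a, surface_b) {
  v <- as.numeric(centrosome_b) - as.numeric(centrosome_a)
  s <- as.numeric(surface_b) - as.numeric(surface_a)
  if (all(v == 0)) stop("centrosome points coincide")
  if (all(s == 0)) stop("surface points coincide")
  cosang <- abs(sum(v * s)) / (sqrt(sum(v^2)) * sqrt(sum(s^2)))
  acos(pmin(1, pmax(0, cosang))) * 180 / pi
}

#' Cavalieri estimate of a sectioned volume
#'
#' Volume from areas measured on every `sampling_interval`-th serial
#' section: `sum(areas) * section_thickness * sampling_interval`. With
#' 10 um sections sampled every tenth section the inter-section distance
#' is 100 um.
#'
#' @param section_areas numeric vector of measured areas (e.g. um^2),
#'   one per sampled section.
#' @param section_thickness physical thickness of one section (um).
#' @param sampling_interval every how-many-th section was measured.
#' @return Estimated volume (e.g. um^3).
#' @examples
#' cavalieri_volume(100, 10, 10)  # 10000
#' @export
cavalieri_volume <- function(section_areas, section_thickness,
                             sampling_interval = 1L) {
  if (!length(section_areas)) stop("empty section area list")
  stopifnot(all(section_areas >= 0), section_thickness > 0,
            sampling_interval >= 1)
  sum(section_areas) * section_thickness * sampling_interval
}

#' Dye-dilution proliferation index
#'
#' From flow-cytometry generation gates: total cells divided by the
#' back-calculated number of founding cells,
#' `PI = sum(N_Gi) / sum(N_Gi / 2^i)` for generations i = 0, 1, 2, ...
#' Equals 1 iff all cells are undivided and increases as cells move to
#' higher generations.
#'
#' @param counts non-negative numeric vector of cell counts per division
#'   generation, starting at generation 0.
#' @return Proliferation index (>= 1).
#' @examples
#' proliferation_index(c(0, 100))   # 2: every founder divided once
#' proliferation_index(c(50, 100))  # 1.5
#' @export
proliferation_index <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("generation counts must be non-negative")
  if (!any(counts > 0)) stop("at least one generation count must be nonzero")
  gens <- seq_along(counts) - 1L
  sum(counts) / sum(counts / 2^gens)
}
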