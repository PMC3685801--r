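# Plasmodesmal manifold feasibility: given an organ's observed phloem import
# flux, how many microchannels and plasmodesmata of a given radius are needed
# to carry it, and does the observed plasmodesma count suffice?

#' Plasmodesma geometry: microchannel packing in the cytoplasmic sleeve
#'
#' Microchannel equators (diameters) are taken to lie on a circle of half the
#' internal plasmodesmal radius (10.5 nm in the developing wheat grain, Wang
#' et al. 1995), occupying 50% of that circumference in a single row. The
#' occupied arc is quantised to the nearest nanometre (0.5 x 2 pi x 10.5 =
#' 32.99 -> 33 nm) before division by the microchannel diameter, with the
#' resulting count rounded half-up; this two-stage rule reproduces the
#' published per-plasmodesma counts (33 at r = 0.5 nm, 17 at r = 1.0 nm).
#'
#' @param sleeve_circle_radius_nm Radius of the circle carrying microchannel
#'   centres, nm.
#' @param occupancy_fraction Fraction of that circumference occupied by
#'   microchannels, in (0, 1].
#' @param wall_thickness_nm Plasmodesma (cell wall) length, nm.
#' @param rounding One of `"nearest-half-up"` or `"floor"` for the final
#'   count.
#' @return A list with class `pd_geometry`.
#' @examples
#' pd_geometry()
#' @export
pd_geometry <- function(sleeve_circle_radius_nm = 10.5,
                        occupancy_fraction = 0.5,
                        wall_thickness_nm = 500,
                        rounding = c("nearest-half-up", "floor")) {
  check_positive_finite(sleeve_circle_radius_nm, "sleeve circle radius (nm)")
  check_positive_finite(wall_thickness_nm, "wall thickness (nm)")
  if (!is.numeric(occupancy_fraction) || occupancy_fraction <= 0 || occupancy_fraction > 1) {
    abort_quantity("occupancy fraction must lie in (0, 1]", occupancy_fraction)
  }
  structure(
    list(
      sleeve_circle_radius_nm = sleeve_circle_radius_nm,
      occupancy_fraction = occupancy_fraction,
      wall_thickness_nm = wall_thickness_nm,
      rounding = match.arg(rounding)
    ),
    class = "pd_geometry"
  )
}

#' Organ import specification for the feasibility analysis
#'
#' Defaults are the developing wheat grain: a phloem import rate of 10 uL/day
#' unloaded across the SE/CC-to-vascular-parenchyma interface, an observed
#' 4.4e7 plasmodesmata per grain (Wang et al. 1995), and a measured
#' trans-interface pressure differential of 1.0 MPa (Fisher & Cash-Clark 2000).
#'
#' @param volume_import_ul_day Organ import rate, uL/day.
#' @param observed_pd_count Observed plasmodesmata at the unloading interface.
#' @param dP_mpa Trans-plasmodesmal pressure differential, MPa.
#' @return A list with class `organ_import_spec`.
#' @examples
#' organ_import_spec()
#' @export
organ_import_spec <- function(volume_import_ul_day = 10,
                              observed_pd_count = 4.4e7,
                              dP_mpa = 1.0) {
  check_positive_finite(volume_import_ul_day, "volume import rate (uL/day)")
  check_positive_finite(observed_pd_count, "observed plasmodesma count")
  check_positive_finite(dP_mpa, "pressure differential (MPa)")
  structure(
    list(
      volume_import_ul_day = volume_import_ul_day,
      observed_pd_count = observed_pd_count,
      dP_mpa = dP_mpa
    ),
    class = "organ_import_spec"
  )
}

#' Microchannels per plasmodesma under the annular packing rule
#'
#' @param radius_nm Microchannel radius, nm; must be smaller than the sleeve
#'   circle radius. Vectorised.
#' @param geometry A [pd_geometry()].
#' @return Integer count (>= 1) of microchannels per plasmodesma.
#' @examples
#' microchannels_per_pd(c(0.5, 1, 2)) # 33, 17, 8
#' @export
microchannels_per_pd <- function(radius_nm, geometry = pd_geometry()) {
  check_positive_finite(radius_nm, "microchannel radius (nm)")
  if (any(radius_nm >= geometry$sleeve_circle_radius_nm)) {
    rlang::abort(
      sprintf(
        "microchannel radius must be < sleeve circle radius (%g nm)",
        geometry$sleeve_circle_radius_nm
      ),
      class = "phloemanifold_geometry_error"
    )
  }
  arc_nm <- round_half_up(geometry$occupancy_fraction * 2 * pi * geometry$sleeve_circle_radius_nm)
  raw <- arc_nm / (2 * radius_nm)
  n <- switch(geometry$rounding,
    "nearest-half-up" = round_half_up(raw),
    "floor" = floor(raw)
  )
  pmax(1, n)
}

#' Plasmodesmal feasibility of an observed organ import flux
#'
#' For each microchannel radius: the per-microchannel Poiseuille flow, the
#' number of microchannels needed to carry the organ's import flux, the
#' microchannels each plasmodesma provides, the plasmodesmata required, and a
#' verdict against the observed plasmodesma count. Counts are reported as real
#' numbers (as published) with ceiling integers available through the margin.
#'
#' @param radii_nm Microchannel radii to evaluate, nm. An empty vector gives
#'   an empty table.
#' @param spec An [organ_import_spec()].
#' @param geometry A [pd_geometry()].
#' @param medium A [phloem_medium()].
#' @return A tibble with one row per radius: `radius_nm`,
#'   `per_channel_flow_nm3_s`, `microchannels_required`,
#'   `microchannels_per_pd`, `pd_required`, `observed_pd`, `feasible`,
#'   `margin` (observed / required).
#' @examples
#' pd_feasibility(c(0.5, 1, 2))
#' @export
pd_feasibility <- function(radii_nm,
                           spec = organ_import_spec(),
                           geometry = pd_geometry(),
                           medium = phloem_medium()) {
  if (length(radii_nm) == 0) {
    return(tibble::tibble(
      radius_nm = numeric(), per_channel_flow_nm3_s = numeric(),
      microchannels_required = numeric(), microchannels_per_pd = numeric(),
      pd_required = numeric(), observed_pd = numeric(),
      feasible = logical(), margin = numeric()
    ))
  }
  target_flow <- volume_flow_to_internal(spec$volume_import_ul_day)
  per_channel <- poiseuille_volume_flow(
    radii_nm, geometry$wall_thickness_nm, spec$dP_mpa, medium$viscosity_mpa_s
  )
  n_per_pd <- microchannels_per_pd(radii_nm, geometry)
  mc_required <- target_flow / per_channel
  pd_required <- mc_required / n_per_pd
  tibble::tibble(
    radius_nm = radii_nm,
    per_channel_flow_nm3_s = per_channel,
    microchannels_required = mc_required,
    microchannels_per_pd = n_per_pd,
    pd_required = pd_required,
    observed_pd = spec$observed_pd_count,
    feasible = pd_required <= spec$observed_pd_count,
    margin = spec$observed_pd_count / pd_required
  )
}

#' Feasibility verdict for a computed feasibility row
#'
#' A radius is feasible when the plasmodesmata required do not exceed the
#' observed count; the margin is observed / required (>= 1 when feasible,
#' exactly 1 at the boundary).
#'
#' @param row A one-or-more-row tibble as returned by [pd_feasibility()].
#' @return The input with `feasible` and `margin` recomputed.
#' @export
feasibility_verdict <- function(row) {
  dplyr::mutate(
    row,
    feasible = .data$pd_required <= .data$observed_pd,
    margin = .data$observed_pd / .data$pd_required
  )
}

#' Minimum pressure differential at which a radius remains feasible
#'
#' Walks a pressure grid `{resolution, 2 resolution, ...}` and returns the
#' smallest differential at which the plasmodesmata required (which scale as
#' 1/dP) do not exceed the observed count. For the wheat grain at r = 1 nm
#' this is 0.4 MPa: the measured 1.0 MPa differential carries spare capacity.
#'
#' @inheritParams pd_feasibility
#' @param radius_nm Single microchannel radius, nm.
#' @param resolution_mpa Grid resolution, MPa (> 0).
#' @param cap_mpa Upper search bound, MPa; above any measured sieve-tube
#'   pressure. `NA` is returned (with a warning) if no grid point at or below
#'   the cap is feasible.
#' @return The minimum feasible differential in MPa, or `NA_real_`.
#' @examples
#' min_pressure_differential(1.0) # 0.4 MPa
#' @export
min_pressure_differential <- function(radius_nm,
                                      spec = organ_import_spec(),
                                      geometry = pd_geometry(),
                                      medium = phloem_medium(),
                                      resolution_mpa = 0.1,
                                      cap_mpa = 5) {
  check_positive_finite(resolution_mpa, "resolution (MPa)")
  stopifnot(length(radius_nm) == 1)
  grid <- seq(resolution_mpa, cap_mpa, by = resolution_mpa)
  for (dP in grid) {
    spec_dp <- spec
    spec_dp$dP_mpa <- dP
    row <- pd_feasibility(radius_nm, spec_dp, geometry, medium)
    if (row$feasible) return(dP)
  }
  rlang::warn(sprintf(
    "no feasible pressure differential at or below %g MPa for radius %g nm",
    cap_mpa, radius_nm
  ))
  NA_real_
}
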