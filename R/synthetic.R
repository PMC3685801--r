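# Published measurement fixtures and synthetic parameter bundles. Fixtures
# carry provenance strings citing the primary measurement literature; bundles
# are drawn uniformly from the published physiological ranges so the whole
# pipeline can be exercised, deterministically per seed, with no external
# data.

fixture_registry <- function() {
  list(
    wheat_grain_table3 = list(
      description = "Developing wheat grain feasibility constants",
      values = tibble::tribble(
        ~quantity, ~value, ~unit, ~provenance,
        "viscosity", 2e-9, "MPa s", "phloem sap viscosity (Mullendore et al. 2010)",
        "wall_thickness", 500, "nm", "SE/CC-parenchyma wall thickness, wheat grain (Fisher & Cash-Clark 2000)",
        "volume_import", 10, "uL/day", "wheat grain phloem import rate (Fisher, aphid stylet exudation)",
        "observed_pd", 4.4e7, "count/grain", "plasmodesmata at the SE/CC-parenchyma interface (Wang et al. 1995)",
        "dP", 1.0, "MPa", "SE-to-parenchyma pressure differential, normal watered (Fisher & Cash-Clark 2000)",
        "sleeve_circle_radius", 10.5, "nm", "half the plasmodesmal internal radius (Wang et al. 1995)",
        "D_sucrose", 0.52e9, "nm^2/s", "sucrose diffusion coefficient in water, 25 C"
      )
    ),
    wheat_grain_normal = list(
      description = "Wheat grain SE and vascular parenchyma turgor, normal watered",
      values = tibble::tribble(
        ~quantity, ~value, ~unit, ~provenance,
        "se_pressure", 1.11, "MPa", "grain SE turgor, aphid stylet micromanometry (Fisher & Cash-Clark 2000)",
        "sink_pressure", 0.12, "MPa", "vascular parenchyma turgor, pressure probe (Fisher & Cash-Clark 2000)"
      )
    ),
    wheat_grain_stressed = list(
      description = "Wheat grain SE and vascular parenchyma turgor, water stressed",
      values = tibble::tribble(
        ~quantity, ~value, ~unit, ~provenance,
        "se_pressure", 1.30, "MPa", "grain SE turgor, water-stressed (Fisher & Cash-Clark 2000)",
        "sink_pressure", 0.08, "MPa", "vascular parenchyma turgor, water-stressed (Fisher & Cash-Clark 2000)"
      )
    ),
    barley_root_high_k = list(
      description = "Barley root tip SE and cortical turgor, potassium replete",
      values = tibble::tribble(
        ~quantity, ~value, ~unit, ~provenance,
        "se_pressure", 1.62, "MPa", "root SE turgor, high-K plants (Gould et al. 2004)",
        "se_pressure_sd", 0.05, "MPa", "reported spread (Gould et al. 2004)",
        "sink_pressure", 0.33, "MPa", "elongating cortical cell turgor (Gould et al. 2004)"
      )
    ),
    barley_root_low_k = list(
      description = "Barley root tip SE and cortical turgor, potassium deficient",
      values = tibble::tribble(
        ~quantity, ~value, ~unit, ~provenance,
        "se_pressure", 1.32, "MPa", "root SE turgor, low-K plants (Gould et al. 2004)",
        "sink_pressure", 0.32, "MPa", "elongating cortical cell turgor (Gould et al. 2004)"
      )
    ),
    ricinus_excision = list(
      description = "Castor bean fruit-excision flux experiment",
      values = tibble::tribble(
        ~quantity, ~value, ~unit, ~provenance,
        "se_pressure", 1.0, "MPa", "Ricinus ST pressure from osmotic/water potentials (Smith & Milburn 1982)",
        "sink_turgor_low", 0.1, "MPa", "fruit sink cell turgor, lower bound (Saladie et al. 2007; Wada et al. 2008)",
        "sink_turgor_high", 0.2, "MPa", "fruit sink cell turgor, upper bound (Saladie et al. 2007; Wada et al. 2008)",
        "observed_flux_fold", 19, "fold", "pedicel ST sucrose flux rise on fruit excision (Kallarackal & Milburn 1984)"
      )
    )
  )
}

#' Load a published parameter fixture by key
#'
#' @param key Fixture name; see `names(phloem_fixtures())`.
#' @return A tibble of quantities with values, units and provenance strings.
#' @examples
#' load_fixture("wheat_grain_normal")
#' @export
load_fixture <- function(key) {
  reg <- fixture_registry()
  if (!is.character(key) || length(key) != 1 || !key %in% names(reg)) {
    rlang::abort(
      sprintf(
        "unknown fixture %s; available: %s",
        deparse(key), paste(names(reg), collapse = ", ")
      ),
      class = "phloemanifold_unknown_fixture"
    )
  }
  reg[[key]]$values
}

#' List all published parameter fixtures
#'
#' @return Named list of fixture tibbles.
#' @export
phloem_fixtures <- function() {
  purrr::map(fixture_registry(), "values")
}

fixture_value <- function(key, quantity) {
  tbl <- load_fixture(key)
  tbl$value[match(quantity, tbl$quantity)]
}

# published physiological ranges used for sampling
default_ranges <- function() {
  list(
    se_pressure_mpa = c(0.5, 2.4),
    sink_turgor_mpa = c(0.08, 0.33),
    sucrose_se_mM = c(450, 600),
    sucrose_parenchyma_mM = c(200, 260),
    microchannel_radius_nm = c(0.5, 10),
    pd_count = c(1e7, 1e8),
    import_ul_day = c(5, 15)
  )
}

#' Sample a physiologically plausible parameter bundle
#'
#' Draws one measurement bundle uniformly from the published ranges: SE
#' pressures 0.5-2.4 MPa, parenchyma turgors 0.08-0.33 MPa, SE sucrose
#' 450-600 mM, parenchyma sucrose 200-260 mM, microchannel radii 0.5-10 nm;
#' plasmodesma counts are drawn log-uniformly over 1e7-1e8 (an order of
#' magnitude around the observed 4.4e7 per grain) and import rates uniformly
#' over 5-15 uL/day around the measured 10. The constraints SE pressure >
#' sink turgor and SE sucrose > parenchyma sucrose are enforced by rejection.
#' A pure function of `(seed, ranges)`.
#'
#' @param seed Integer seed.
#' @param ranges Optional named list overriding entries of the default range
#'   list.
#' @return A one-row tibble: `seed`, `se_pressure_mpa`, `sink_turgor_mpa`,
#'   `sucrose_se_mM`, `sucrose_parenchyma_mM`, `microchannel_radius_nm`,
#'   `pd_count`, `import_ul_day`.
#' @examples
#' sample_bundle(1)
#' @export
sample_bundle <- function(seed, ranges = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  rg <- utils::modifyList(default_ranges(), ranges)
  bad <- purrr::map_lgl(rg, ~ length(.x) != 2 || any(!is.finite(.x)) || .x[2] < .x[1])
  if (any(bad)) {
    rlang::abort(
      sprintf("infeasible sampling range(s): %s", paste(names(rg)[bad], collapse = ", ")),
      class = "phloemanifold_sampling_error"
    )
  }
  if (rg$se_pressure_mpa[2] <= rg$sink_turgor_mpa[1] ||
      rg$sucrose_se_mM[2] <= rg$sucrose_parenchyma_mM[1]) {
    rlang::abort(
      "infeasible override ranges: constraints se_pressure > sink_turgor and sucrose_se > sucrose_parenchyma cannot be met",
      class = "phloemanifold_sampling_error"
    )
  }
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(1000)) {
      b <- tibble::tibble(
        seed = as.integer(seed),
        se_pressure_mpa = stats::runif(1, rg$se_pressure_mpa[1], rg$se_pressure_mpa[2]),
        sink_turgor_mpa = stats::runif(1, rg$sink_turgor_mpa[1], rg$sink_turgor_mpa[2]),
        sucrose_se_mM = stats::runif(1, rg$sucrose_se_mM[1], rg$sucrose_se_mM[2]),
        sucrose_parenchyma_mM = stats::runif(1, rg$sucrose_parenchyma_mM[1], rg$sucrose_parenchyma_mM[2]),
        microchannel_radius_nm = stats::runif(1, rg$microchannel_radius_nm[1], rg$microchannel_radius_nm[2]),
        pd_count = 10^stats::runif(1, log10(rg$pd_count[1]), log10(rg$pd_count[2])),
        import_ul_day = stats::runif(1, rg$import_ul_day[1], rg$import_ul_day[2])
      )
      if (b$se_pressure_mpa > b$sink_turgor_mpa &&
          b$sucrose_se_mM > b$sucrose_parenchyma_mM) {
        return(b)
      }
    }
    rlang::abort("rejection sampling failed after 1000 draws",
      class = "phloemanifold_sampling_error"
    )
  })
}

#' Sample inputs for a manifold network
#'
#' Per-sink interface conductances are built physically: a sampled
#' plasmodesma count times microchannels per plasmodesma times the
#' per-microchannel hydraulic conductance of a 500 nm channel at the sampled
#' radius. Axial conductances are sampled as 1-1000 times (log-uniform) the
#' summed sink conductance, spanning the approach to the manifold regime.
#'
#' @param seed Integer seed.
#' @param n_sinks Number of sinks (>= 1).
#' @return A list with `axial_conductances`, `sink_conductances`,
#'   `source_pressure_mpa`, `sink_turgors_mpa`, and the per-sink `bundles`
#'   tibble.
#' @examples
#' make_network_bundle(1, 3)
#' @export
make_network_bundle <- function(seed, n_sinks) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!is.numeric(n_sinks) || length(n_sinks) != 1 || n_sinks < 1) {
    rlang::abort("n_sinks must be >= 1", class = "phloemanifold_sampling_error")
  }
  n_sinks <- as.integer(n_sinks)
  bundles <- purrr::map(seq_len(n_sinks), function(i) {
    sample_bundle(as.integer(seed) + i - 1L)
  })
  bundles <- dplyr::bind_rows(bundles)
  geometry <- pd_geometry()
  sink_g <- bundles$pd_count *
    microchannels_per_pd(bundles$microchannel_radius_nm, geometry) *
    hydraulic_conductance(bundles$microchannel_radius_nm, geometry$wall_thickness_nm)
  withr::with_seed(as.integer(seed) + 10000L, {
    mult <- 10^stats::runif(n_sinks, 0, 3)
  })
  list(
    axial_conductances = mult * sum(sink_g),
    sink_conductances = sink_g,
    source_pressure_mpa = max(bundles$se_pressure_mpa),
    sink_turgors_mpa = bundles$sink_turgor_mpa,
    bundles = bundles
  )
}
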