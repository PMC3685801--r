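# Published reference values for the wheat-grain desk analyses, shipped so
# reproduction tables can carry self-documenting deviation columns. Values
# trace to the feasibility and unloading studies of the developing wheat
# grain (Fisher & Cash-Clark 2000; Wang et al. 1995) and to the published
# tabulations derived from them. Known internal inconsistencies in those
# tabulations are annotated, never silently corrected.

#' Published reference feasibility table (wheat grain)
#'
#' Plasmodesma-count feasibility of the 10 uL/day wheat-grain import flux at
#' a 1.0 MPa differential, as published. Flows are in units of 1e4 nm^3/s,
#' microchannel counts in 1e4, plasmodesma counts in 1e3. Two rows carry
#' annotations: at r = 8 nm the published microchannel count is rounded to a
#' single significant digit and the published plasmodesma count inherits that
#' rounding; the r = 10 nm row is internally inconsistent in the published
#' source (its printed per-plasmodesma count, microchannel count and
#' plasmodesma count cannot all hold at once) and is flagged, not reproduced.
#'
#' @return A tibble with columns `radius_nm`, `per_channel_flow_1e4`,
#'   `microchannels_required_1e4`, `microchannels_per_pd`, `pd_required_1e3`,
#'   `annotation`.
#' @export
reference_feasibility_table <- function() {
  tibble::tribble(
    ~radius_nm, ~per_channel_flow_1e4, ~microchannels_required_1e4,
    ~microchannels_per_pd, ~pd_required_1e3, ~annotation,
    0.5, 2.46, 472313, 33, 143125, NA_character_,
    1.0, 39.3, 29524, 17, 17367, NA_character_,
    1.5, 199, 5832, 11, 5302, NA_character_,
    2.0, 629, 1845, 8, 2306, NA_character_,
    4.0, 10057, 115, 4, 288, NA_character_,
    8.0, 160916, 7, 2, 35.0,
    "published microchannel count rounded to one significant digit (7e4 for 7.2e4); the published pd count 35.0e3 is that rounded count over 2, 2.8% below full-precision arithmetic (36.0e3)",
    10.0, 392900, 3, 1, 10.0,
    "published row internally inconsistent (3e4 microchannels over 1 per pd implies 30e3 pd, not 10e3); excluded from comparisons"
  )
}

#' Published reference diffusion-versus-bulk-flow table (wheat grain)
#'
#' Sucrose transport rates (units of 1e-10 nmol/s) through a single 500 nm
#' microchannel: diffusion at concentration differences of 200 and 400 mM,
#' bulk flow at a 1.0 MPa differential carrying 450 or 600 mM sap. The two
#' bulk-flow cells at r = 0.5 nm do not follow from R_v x C (published 0.22
#' vs computed 0.11; published 0.14 vs computed 0.15) and are flagged.
#'
#' @return A tibble with columns `radius_nm`, `diffusion_dC200`,
#'   `diffusion_dC400`, `bulk_C450`, `bulk_C600`, `annotation`.
#' @export
reference_mode_table <- function() {
  tibble::tribble(
    ~radius_nm, ~diffusion_dC200, ~diffusion_dC400, ~bulk_C450, ~bulk_C600, ~annotation,
    0.5, 1.64, 3.28, 0.22, 0.14,
    "published bulk-flow cells differ from R_v x C (0.22 vs 0.11 at 450 mM; 0.14 vs 0.15 at 600 mM)",
    1.0, 6.53, 13.1, 1.77, 2.36, NA_character_,
    1.5, 14.7, 29.4, 8.95, 11.9, NA_character_,
    2.0, 26.2, 52.3, 28.2, 37.7, NA_character_,
    4.0, 105, 209, 453, 603, NA_character_,
    8.0, 418, 837, 7241, 9655, NA_character_
  )
}
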