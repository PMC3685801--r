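# Internal unit system: length nm, pressure MPa, time s, viscosity MPa s,
# volume flow nm^3/s, amount mol (reported as nmol where conventional),
# concentration mol/nm^3 internally, mM at the interface. Every published
# constant this package leans on (viscosity 2e-9 MPa s, wall thickness 500 nm,
# flows in nm^3/s) is printed in these units, so all formulas evaluate with no
# hidden factors; laboratory units are converted exactly at the boundary.

#' Exact conversion constants of the internal unit system
#'
#' Named vector of the exact decimal/rational factors used at the unit
#' boundary: seconds per day, nm^3 per litre, nm^3 per microlitre, MPa per Pa,
#' and mol nm^-3 per millimolar.
#'
#' @return Named numeric vector.
#' @examples
#' unit_constants()["seconds_per_day"]
#' @export
unit_constants <- function() {
  c(
    seconds_per_day = 86400,
    nm3_per_litre = 1e24,
    nm3_per_microlitre = 1e18,
    mpa_per_pa = 1e-6,
    mol_nm3_per_mM = 1e-3 / 1e24
  )
}

abort_quantity <- function(what, value) {
  rlang::abort(
    sprintf("invalid quantity: %s (got %s)", what, paste(format(value), collapse = ", ")),
    class = "phloemanifold_invalid_quantity"
  )
}

check_nonnegative_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x < 0)) {
    abort_quantity(paste0(what, " must be finite and >= 0"), x)
  }
  invisible(x)
}

check_positive_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    abort_quantity(paste0(what, " must be finite and > 0"), x)
  }
  invisible(x)
}

#' Convert an organ import rate from microlitres per day to nm^3 per second
#'
#' The wheat-grain phloem import rate is conventionally reported in
#' microlitres per day (10 uL/day for a developing grain); internal flow
#' calculations run in nm^3/s.
#'
#' @param ul_per_day Volume flow rate, uL/day. Vectorised; must be finite and
#'   non-negative.
#' @return Flow rate in nm^3/s (`10 uL/day` -> `1.157e14`).
#' @examples
#' volume_flow_to_internal(10) # the developing wheat grain
#' @export
volume_flow_to_internal <- function(ul_per_day) {
  check_nonnegative_finite(ul_per_day, "volume flow (uL/day)")
  ul_per_day * 1e18 / 86400
}

#' Convert a millimolar concentration to mol per nm^3
#'
#' @param mM Concentration in millimolar; finite, non-negative, vectorised.
#' @return Concentration in mol nm^-3 (`200 mM` -> `2e-25`).
#' @examples
#' concentration_to_internal(200)
#' @export
concentration_to_internal <- function(mM) {
  check_nonnegative_finite(mM, "concentration (mM)")
  mM * 1e-3 / 1e24
}

#' Convert a dynamic viscosity from Pa s to MPa s
#'
#' Phloem sap viscosity is about 2e-3 Pa s; the internal value is 2e-9 MPa s.
#'
#' @param pa_s Viscosity in Pa s; finite and strictly positive.
#' @return Viscosity in MPa s.
#' @examples
#' viscosity_to_internal(2e-3)
#' @export
viscosity_to_internal <- function(pa_s) {
  check_positive_finite(pa_s, "viscosity (Pa s)")
  pa_s * 1e-6
}

# Inverses, used by reporting and round-trip tests.
internal_to_volume_flow <- function(nm3_s) nm3_s * 86400 / 1e18
internal_to_concentration <- function(mol_nm3) mol_nm3 * 1e24 * 1e3

# round half away from zero; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)
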