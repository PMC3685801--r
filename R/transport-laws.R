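# Governing laws for flow through a cylindrical conduit (sieve pore or
# plasmodesmal microchannel), all in internal units (nm, MPa, s, mol).
#
# Bulk flow (Hagen-Poiseuille):   R_v = pi r^4 dP / (8 eta L)     [nm^3/s]
# Hydraulic conductance:          L_o = pi r^4 / (8 eta L)        [nm^3/(s MPa)]
# Diffusion (Fick's first law):   R_i = D A dC / dx, A = pi r^2   [mol/s]
#
# Solute carriage by bulk flow is advective: R_v times the carried
# concentration. Negative driving forces are permitted and flip the sign of
# the flow, so the network solver can use the same laws symmetrically.

#' Default transport medium: wheat-grain phloem sap
#'
#' Reference medium used throughout the wheat-grain analyses: sap viscosity
#' 2e-9 MPa s (2e-3 Pa s, Mullendore et al. 2010) and a sucrose diffusion
#' coefficient of 0.52e9 nm^2/s in water at 25 C.
#'
#' @param viscosity_mpa_s Dynamic viscosity, MPa s.
#' @param diffusion_coefficient_nm2_s Solute diffusion coefficient, nm^2/s.
#' @param solute Solute name (annotation only).
#' @return A list with class `phloem_medium`.
#' @examples
#' phloem_medium()
#' @export
phloem_medium <- function(viscosity_mpa_s = 2e-9,
                          diffusion_coefficient_nm2_s = 0.52e9,
                          solute = "sucrose") {
  check_positive_finite(viscosity_mpa_s, "viscosity (MPa s)")
  check_positive_finite(diffusion_coefficient_nm2_s, "diffusion coefficient (nm^2/s)")
  structure(
    list(
      viscosity_mpa_s = viscosity_mpa_s,
      diffusion_coefficient_nm2_s = diffusion_coefficient_nm2_s,
      solute = solute
    ),
    class = "phloem_medium"
  )
}

#' @export
print.phloem_medium <- function(x, ...) {
  cat(
    sprintf(
      "<phloem_medium> eta = %g MPa s, D_%s = %g nm^2/s\n",
      x$viscosity_mpa_s, x$solute, x$diffusion_coefficient_nm2_s
    )
  )
  invisible(x)
}

check_channel <- function(radius_nm, length_nm) {
  check_positive_finite(radius_nm, "channel radius (nm)")
  check_positive_finite(length_nm, "channel length (nm)")
}

#' Poiseuille volume flow through a cylindrical channel
#'
#' Hagen-Poiseuille law `pi r^4 dP / (8 eta L)`. At the wheat-grain reference
#' conditions (r = 1 nm, L = 500 nm, dP = 1 MPa, eta = 2e-9 MPa s) a single
#' plasmodesmal microchannel carries 3.93e5 nm^3/s.
#'
#' @param radius_nm Channel radius, nm (> 0; vectorised).
#' @param length_nm Channel length, nm (> 0).
#' @param dP_mpa Hydrostatic pressure differential, MPa. May be negative; the
#'   flow is signed.
#' @param viscosity_mpa_s Sap viscosity, MPa s (> 0).
#' @return Volume flow rate, nm^3/s.
#' @examples
#' poiseuille_volume_flow(1, 500, 1, 2e-9)
#' @export
poiseuille_volume_flow <- function(radius_nm, length_nm, dP_mpa,
                                   viscosity_mpa_s = 2e-9) {
  check_channel(radius_nm, length_nm)
  if (any(!is.finite(dP_mpa))) abort_quantity("pressure differential must be finite", dP_mpa)
  hydraulic_conductance(radius_nm, length_nm, viscosity_mpa_s) * dP_mpa
}

#' Hydraulic conductance of a cylindrical channel
#'
#' `L_o = pi r^4 / (8 eta L)`, so that flow = `L_o * dP` exactly. The r^4
#' dependence is the lever through which small radius changes exert large
#' control over bulk flow.
#'
#' @inheritParams poiseuille_volume_flow
#' @return Conductance, nm^3 s^-1 MPa^-1.
#' @examples
#' hydraulic_conductance(1, 500)
#' @export
hydraulic_conductance <- function(radius_nm, length_nm, viscosity_mpa_s = 2e-9) {
  check_channel(radius_nm, length_nm)
  check_positive_finite(viscosity_mpa_s, "viscosity (MPa s)")
  pi * radius_nm^4 / (8 * viscosity_mpa_s * length_nm)
}

#' Fick diffusion rate of a solute through a cylindrical channel
#'
#' `R_i = D A dC / dx` with `A = pi r^2` and the channel length as the
#' diffusion path. Concentrations enter in mM and are converted internally.
#'
#' @inheritParams poiseuille_volume_flow
#' @param dC_mM Concentration difference across the channel, mM (signed).
#' @param diffusion_coefficient_nm2_s Solute diffusion coefficient, nm^2/s.
#' @return Diffusion rate in nmol/s.
#' @examples
#' fick_diffusion_rate(1, 500, 200) # 6.53e-10 nmol/s for sucrose
#' @export
fick_diffusion_rate <- function(radius_nm, length_nm, dC_mM,
                                diffusion_coefficient_nm2_s = 0.52e9) {
  check_channel(radius_nm, length_nm)
  check_positive_finite(diffusion_coefficient_nm2_s, "diffusion coefficient (nm^2/s)")
  if (any(!is.finite(dC_mM))) abort_quantity("concentration difference must be finite", dC_mM)
  dC_internal <- sign(dC_mM) * concentration_to_internal(abs(dC_mM))
  mol_s <- diffusion_coefficient_nm2_s * pi * radius_nm^2 * dC_internal / length_nm
  mol_s * 1e9 # mol/s -> nmol/s
}

#' Advective solute transport rate carried by a bulk flow
#'
#' A volume flow `R_v` of sap at carried concentration `C` transports solute
#' at `R_v * C`; solutes and solvent move at identical velocity, which is the
#' operational signature of bulk flow as opposed to diffusion.
#'
#' @param volume_flow_nm3_s Volume flow rate, nm^3/s (signed).
#' @param concentration_mM Carried solute concentration, mM (>= 0).
#' @return Solute transport rate, nmol/s.
#' @examples
#' advective_solute_rate(poiseuille_volume_flow(1.5, 500, 1), 600)
#' @export
advective_solute_rate <- function(volume_flow_nm3_s, concentration_mM) {
  if (any(!is.finite(volume_flow_nm3_s))) {
    abort_quantity("volume flow must be finite", volume_flow_nm3_s)
  }
  volume_flow_nm3_s * concentration_to_internal(concentration_mM) * 1e9
}

#' Mean axial velocity of a flow through a channel
#'
#' Volume flow expressed on the internal cross-sectional area, `R_v / (pi r^2)`.
#'
#' @inheritParams advective_solute_rate
#' @param radius_nm Channel radius, nm.
#' @return Mean velocity, nm/s.
#' @examples
#' mean_velocity(poiseuille_volume_flow(1, 500, 1), 1)
#' @export
mean_velocity <- function(volume_flow_nm3_s, radius_nm) {
  check_positive_finite(radius_nm, "channel radius (nm)")
  volume_flow_nm3_s / (pi * radius_nm^2)
}
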