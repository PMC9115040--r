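#' Physical constants and unit conversions
#'
#' All internal computations use Hartree atomic units (hbar = m_e = e = 1,
#' energies in hartree, lengths in bohr, momenta in 1/bohr).  Public
#' interfaces accept and return energies in eV, momentum transfers in atomic
#' units, and macroscopic cross-section quantities in nm-based units.  This
#' is the single place where the conversion factors are defined.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_ev}{One hartree in electronvolt (27.211386).}
#'   \item{bohr_nm}{One bohr radius in nanometre (0.052917721).}
#' }
#' @export
#' @examples
#' elfxs_units$hartree_ev
elfxs_units <- list(
  hartree_ev = 27.211386,
  bohr_nm    = 0.052917721
)

## internal shorthands
.HA_EV   <- elfxs_units$hartree_ev
.BOHR_NM <- elfxs_units$bohr_nm

#' Convert energies between eV and hartree
#'
#' @param e energies (eV for `ev_to_ha`, hartree for `ha_to_ev`).
#' @return converted energies.
#' @export
ev_to_ha <- function(e) e / .HA_EV

#' @rdname ev_to_ha
#' @export
ha_to_ev <- function(e) e * .HA_EV
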