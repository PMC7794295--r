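#' Physical constants and unit conversions
#'
#' All internal computation is done in Hartree atomic units (energy in
#' Hartree, length in Bohr). Geometry I/O uses Angstrom.
#'
#' @format A named list with elements `bohr_per_angstrom`,
#'   `angstrom_per_bohr`, `ev_per_hartree`, `kjmol_per_hartree`.
#' @export
units_au <- list(
  bohr_per_angstrom = 1 / 0.52917721067,
  angstrom_per_bohr = 0.52917721067,
  ev_per_hartree    = 27.211386245988,
  kjmol_per_hartree = 2625.4996394799
)

#' Convert an energy in Hartree to a named vector in Ha, eV and kJ/mol
#'
#' @param e_hartree scalar energy in Hartree.
#' @return named numeric vector with elements `hartree`, `ev`, `kjmol`.
#' @export
energy_units <- function(e_hartree) {
  c(hartree = e_hartree,
    ev = e_hartree * units_au$ev_per_hartree,
    kjmol = e_hartree * units_au$kjmol_per_hartree)
}
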