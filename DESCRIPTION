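Package: mbddcs
Title: Many-Body Dispersion with Dipole-Correlated Coulomb Singles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models atoms as coupled quantum Drude oscillators to compute
    many-body van der Waals dispersion (MBD) energies and the first-order
    beyond-dipole Coulomb correction known as Dipole-Correlated Coulomb
    Singles (DCS). Provides the correlated Gaussian ground states of the
    dipole-coupled Hamiltonian, Gaussian-smeared Coulomb integrals with a
    Monte-Carlo validation oracle, fluctuation-density grids and the
    displaced-charge descriptor, geometric host-guest descriptors,
    programmatic builders for hydrogen-capped armchair carbon nanotubes and
    toy oscillator fixtures, and fragment-based binding-curve workflows with
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
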