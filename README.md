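# mbddcs

Many-body van der Waals dispersion from coupled quantum Drude
oscillators, with the first-order beyond-dipole Coulomb correction
known as **Dipole-Correlated Coulomb Singles (DCS)** — for
computational chemists and method developers studying dispersion
interactions under nanoscale confinement (encapsulated dimers,
host–guest complexes, molecules in tubes and cavities), where the
usual dipole-limit treatment misses a distinct, sometimes repulsive,
contribution.

## The model

Each atom is a quantum Drude oscillator with polarizability
`α_i` and frequency `ω_i = 4 C6_i / (3 α_i²)`, derived from free-atom
reference data scaled by Hirshfeld volume ratios. The dipole-coupled
Hamiltonian

    C_ii = ω_i² 1₃,   C_ij = ω_i ω_j √(α_i α_j) f_ij T_dd(R_ij)

(with `T_dd(r) = (r²1 − 3rrᵀ)/r⁵` and Fermi damping `f`) is solved by
eigenmode decomposition, giving the many-body dispersion energy
`E_MBD = ½ Σ_k ω_DC,k − (3/2) Σ_i ω_i`. The correlated ground state is
a 3N-dimensional Gaussian over Drude displacements; the DCS correction
is the first-order expectation of the damped beyond-dipole potential

    E_DCS = ⟨Ψ_DC | f·(V_Coul − T_dd) | Ψ_DC⟩ − ⟨Ψ_0 | f·V_Coul | Ψ_0⟩

evaluated through Gaussian-smeared Coulomb integrals, with the exact
decomposition `E_DCS = (J[ρ_DC] − J[ρ_0]) + (E_corr − E_dip)` into a
classical dispersion–polarization part and a beyond-dipole correlation
part. A Monte-Carlo oracle over the same Gaussian states validates the
quadrature path. The toolkit also computes fluctuation-density grids
and the displaced-charge descriptor (cube-file output), host–guest
geometry descriptors, hydrogen-capped armchair nanotube builders, and
fragment-based binding-curve workflows.

See `vignettes/mbd-dcs-methods.Rmd` for the full account of the
model, numerics, fixture design and limitations.

## Worked example

A xenon dimer encapsulated in a short hydrogen-capped (5,5) armchair
nanotube:

```r
library(mbddcs)

tube <- build_armchair_cnt(5, length = 8)        # 6.78 A diameter
sys  <- place_guests(tube, c("Xe", "Xe"), separation = 4)
osc  <- parametrize(sys)                          # free-atom Hirshfeld ratios

e <- interaction_energy(osc)                      # four-term fragment formula
#> E_int[MBD]     =    -0.5984 kJ/mol
#> E_int[DCS]     =     0.0051 kJ/mol
#> E_int[MBD+DCS] =    -0.5933 kJ/mol
```

The guest–guest dispersion attraction (−0.60 kJ/mol at 4 Å inside the
tube) is weakened by the confining host, and the beyond-dipole
correction contributes a small repulsion, as expected for guests in a
screening environment. The decomposition of the full system's DCS
energy shows both channels populated:

```r
bd <- dcs_decomposition(osc, ground_state(osc),
                        ground_state(osc, correlated = FALSE))
#> DCS breakdown [Hartree]:
#>   E_DCS          = +2.5594728494e-03
#>   J[rho_DC]-J[rho_0] = -8.2902674613e-04
#>   E_corr - E_dip     = +3.3884995955e-03
```

The characteristic long-range exponents — dispersion `R⁻⁶` versus the
slower `R⁻⁵` decay of the beyond-dipole interaction between bodies
carrying correlation-induced quadrupoles:

```r
curve <- embedded_body_curve(seq(20, 60, by = 5), orientation = "transverse")
fit_decay_exponent(curve$distance, curve$de_mbd)$slope   # -5.96
fit_decay_exponent(curve$distance, curve$de_dcs)$slope   # -5.30
```

A thin command-line front end wraps the same functions
(`inst/cli/mbddcs`): `build-cnt`, `mbd-energy`, `dcs-energy`,
`decompose`, `interaction`, `scan`, `delta-rho`, `descriptors`,
`fit-decay`, with YAML run configuration and JSON/CSV/cube/XYZ
outputs.

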