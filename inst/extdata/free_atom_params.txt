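# Free-atom reference data for Drude-oscillator parametrization.
# Columns: symbol  alpha_free (Bohr^3)  C6_free (Hartree*Bohr^6)  R_vdW (Bohr)
# Static dipole polarizabilities and C6 coefficients from the standard
# Tkatchenko-Scheffler compilation of Chu & Dalgarno reference data;
# vdW radii from the same scheme.
H   4.50    6.50   3.10
He  1.38    1.46   2.65
C   12.0    46.6   3.59
N   7.40    24.2   3.34
O   5.40    15.6   3.19
F   3.80    9.50   3.04
Ne  2.67    6.38   2.91
S   19.6    134.0  3.86
Cl  15.0    94.6   3.71
Ar  11.1    64.3   3.55
Kr  16.8    130.4  3.82
Xe  27.3    285.9  4.57
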