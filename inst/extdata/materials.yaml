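# Built-in material constants, version 1.
#
# Compound media are represented by a single effective atom chosen so that
# BOTH the electron density (density * N_A * Z / A) and the Rutherford
# scattering power (n_atoms * Z^2) of the real composition are preserved.
# Radiation lengths X0 are compiled from the PDG approximate elemental
# formula X0 = 716.4 A / (Z (Z+1) ln(287/sqrt(Z))), mass-combined for
# compounds; I values follow ICRU recommendations. All fields can be
# overridden from a run configuration.
#
# Units: A g/mol, density g/cm^3, I eV, X0 g/cm^2.
version: 1
materials:
  water:
    Z: 6.600
    A: 11.890
    density: 1.000
    I: 75.0
    X0: 36.33
  beryllium:
    Z: 4
    A: 9.0122
    density: 1.848
    I: 63.7
    X0: 65.00
  carbon:
    # graphite target
    Z: 6
    A: 12.011
    density: 2.210
    I: 78.0
    X0: 43.01
  te-gas:
    # propane-based tissue-equivalent gas; density at 1013.25 mbar, 293 K
    Z: 5.639
    A: 10.248
    density: 1.798e-3
    reference_pressure_mbar: 1013.25
    I: 59.5
    X0: 41.21
  air:
    Z: 7.361
    A: 14.747
    density: 1.205e-3
    reference_pressure_mbar: 1013.25
    I: 85.7
    X0: 36.85
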