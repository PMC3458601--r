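# Physical constants (CODATA / PDG values). Internal.
.const <- list(
  me_c2      = 0.51099895,     # electron rest energy, MeV
  mp_c2      = 938.27208816,   # proton rest energy, MeV
  amu_c2     = 931.49410242,   # atomic mass unit, MeV
  K_bethe    = 0.307075,       # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
  N_A        = 6.02214076e23,  # 1/mol
  hbar_c     = 197.3269804,    # MeV fm
  e2         = 1.43996454,     # alpha * hbar c, MeV fm (Gaussian units e^2)
  a0_fm      = 52917.72109,    # Bohr radius in fm
  fm2_to_cm2 = 1e-26,
  kev_per_j  = 6.241509074e15, # keV in one joule
  gy_per_kev_per_g = 1.602176634e-13 # Gy deposited by 1 keV in 1 g
)
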