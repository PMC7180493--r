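# Fitted constants of the four ionic-liquid speed-of-sound models.
# The package ships this file EMPTY (null values): the constants are the
# property of the original publications and must be transcribed by the user
# from the sources named below before the corresponding model can run.
# Unit conventions are those of each source and are declared here so that
# transcribed constants remain unit-consistent.
gardas:
  # log10(u) = alpha * log10(sigma * rho) + beta
  # Source: Gardas and Coutinho, surface-tension/density QSPR for ionic liquids.
  alpha: null
  beta: null
  sigma_units: mN/m
  rho_units: g/cm3
hekayati:
  # ln(u) = (a + b*Mw) * ln(sigma * rho) + c*Mw + d*Mw^2 - e*T + f
  # Source: Hekayati and Esmaeilzadeh, corresponding-states correlation for
  # ionic liquids. mw_term switches the ambiguous leading term between
  # "product" (a + b*Mw, default) and "inverse" (a + b/Mw).
  a: null
  b: null
  c: null
  d: null
  e: null
  f: null
  mw_term: product
  sigma_units: mN/m
  rho_units: g/cm3
singh:
  # log10(u) = psi * log10(sigma * rho) + xi
  # Source: Singh and Singh, ionic-liquid speed-of-sound correlation.
  psi: null
  xi: null
  sigma_units: mN/m
  rho_units: g/cm3
haghbakhsh:
  # u = A*Mw + B*T, A = sum(n_i * dA_i), B = sum(n_i * dB_i)
  # Source: Haghbakhsh et al., atomic-contribution speed-of-sound model for
  # ionic liquids. Increment maps are keyed by element symbol.
  # mw_term switches between u = A*Mw + B*T (product, default) and
  # u = A/Mw + B*T (inverse).
  dA: {}
  dB: {}
  mw_term: product
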