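# Head-and-neck NTCP model registry, version 1.
# Families:
#   logistic_d50k     NTCP = (1 + (D50/D)^k)^-1,          D = Dmean of a structure
#   probit_geud       NTCP = Phi((gEUD(n) - D50)/(m*D50))
#   multivar_logistic NTCP = (1 + exp(a - b*X1 - c*X2))^-1
# Doses in Gy(RBE); b and c in 1/Gy unless X2 is the constant indicator.
version: 1
models:
  - endpoint: oral_mucositis
    family: logistic_d50k
    structures: {D: ORAL_MUCOSA}
    params: {D50: 51.0, k: 1.0}
  - endpoint: xerostomia
    family: probit_geud
    structures: {gEUD: PAROTID_CONTRA}
    params: {D50: 39.9, m: 0.4, "n": 1.0}
  - endpoint: dysphagia_solids
    family: multivar_logistic
    structures: {X1: LARYNX_SUPRAGLOTTIC}
    params: {a: 5.98, b: 0.074, c: -1.209, x2const: 1.0}
  - endpoint: dysphagia_liquids
    family: multivar_logistic
    structures: {X1: PCM_SUPERIOR, X2: LARYNX_SUPRAGLOTTIC}
    params: {a: 6.89, b: 0.049, c: 0.048}
  - endpoint: dysphagia
    family: multivar_logistic
    structures: {X1: PCM_SUPERIOR, X2: LARYNX_SUPRAGLOTTIC}
    params: {a: 6.09, b: 0.057, c: 0.037}
  - endpoint: aspiration
    family: probit_geud
    structures: {gEUD: LARYNX}
    params: {D50: 46.5, m: 0.5, "n": 1.0}
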