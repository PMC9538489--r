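# Physical constants used by hand-computed oracle values in the tests
# (kept independent of the package internals).
R_GAS <- 8.314462618
N_AV <- 6.02214076e23

# Independent hand evaluation of the Gibbs-Langmuir equation of state,
# written out from the formula rather than calling the package.
gl_oracle <- function(gamma0, ginf, k, conc, temp) {
  gamma0 - 1000 * R_GAS * temp * ginf * log(1 + k * conc)
}

# Hyperbolic recovery model, written out independently.
frap_oracle <- function(t, f0, amp, th) f0 + amp * (t / th) / (1 + t / th)
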