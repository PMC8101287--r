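# Shared fixtures: published rate sets and small protocols used across files.

# global (multi-concentration) and local published bivalent rate sets
ref_global <- function(mw = 2e5) lag3_bivalent_params("global", analyte_mw = mw)
ref_local <- function(mw = 2e5) lag3_bivalent_params("local", analyte_mw = mw)

# twofold injection series ending at 7.1 uM (the kinetic design)
kinetic_concs <- function(n = 7) 7.1e-6 / 2^((n - 1):0)

# twofold series ending at 57 uM (the steady-state design)
steady_concs <- function(n = 10) 57e-6 / 2^((n - 1):0)

short_protocol <- function(conc, ...) {
  injection_protocol(conc, association_s = 30, dissociation_s = 300,
                     interval_s = 1, baseline_s = 30, ...)
}

# independent ODE oracle for the 1:1 model: integrates dR/dt directly with
# deSolve's R interface (never touches the package's closed form or C code)
ode_one_to_one_oracle <- function(k_on, k_off, r_max, C, times) {
  rhs <- function(t, y, p) list(k_on * C * (r_max - y[1]) - k_off * y[1])
  out <- deSolve::ode(c(R = 0), times, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  out[, "R"]
}
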