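#' Injection protocol for a sensorgram cycle
#'
#' Describes one analyte injection: the analyte concentration, how long the
#' association (analyte flowing) and dissociation (buffer only) phases last,
#' the sampling interval of the detector, and how much pre-injection baseline
#' is recorded. Time zero is the injection start; baseline samples carry
#' negative times.
#'
#' @param conc_M Analyte concentration during the injection (molar).
#' @param association_s Association-phase duration in seconds (default 30 s,
#'   the short-contact protocol typical for fast-kinetics analytes).
#' @param dissociation_s Dissociation-phase duration in seconds (default 300 s).
#' @param interval_s Sampling interval in seconds; must not exceed the
#'   association duration.
#' @param baseline_s Length of recorded baseline before the injection (s).
#'
#' @return A list of class `injection_protocol`.
#' @export
#' @examples
#' injection_protocol(1e-6)
injection_protocol <- function(conc_M, association_s = 30, dissociation_s = 300,
                               interval_s = 1, baseline_s = 30) {
  stopifnot(is.numeric(conc_M), length(conc_M) == 1)
  if (conc_M < 0) stop("invalid-parameter: analyte concentration must be >= 0")
  if (association_s <= 0 || dissociation_s <= 0 || baseline_s < 0) {
    stop("invalid-parameter: durations must be positive")
  }
  if (interval_s <= 0 || interval_s > association_s) {
    stop("invalid-parameter: sampling interval must be in (0, association_s]")
  }
  structure(
    list(conc_M = conc_M, association_s = association_s,
         dissociation_s = dissociation_s, interval_s = interval_s,
         baseline_s = baseline_s),
    class = "injection_protocol"
  )
}

#' 1:1 Langmuir binding parameters
#'
#' Rate and surface parameters of the one-to-one (Langmuir) interaction model:
#' association rate `k_on` (M^-1 s^-1), dissociation rate `k_off` (s^-1),
#' maximal analyte binding capacity `r_max` (RU) and bulk refractive-index
#' jump `ri` (RU) seen while analyte flows.
#'
#' @param k_on Association rate constant (M^-1 s^-1).
#' @param k_off Dissociation rate constant (s^-1).
#' @param r_max Maximal binding capacity of the surface (RU).
#' @param ri Bulk refractive-index offset during injection (RU).
#'
#' @return A list of class `one_to_one_params`.
#' @export
one_to_one_params <- function(k_on, k_off, r_max, ri = 0) {
  if (k_on <= 0 || k_off <= 0) stop("invalid-parameter: rates must be > 0")
  if (r_max <= 0) stop("invalid-parameter: r_max must be > 0")
  if (ri < 0) stop("invalid-parameter: ri must be >= 0")
  structure(list(k_on = k_on, k_off = k_off, r_max = r_max, ri = ri),
            class = "one_to_one_params")
}

#' Bivalent-analyte binding parameters
#'
#' Parameters of the two-step bivalent-analyte scheme in which a dimeric
#' analyte first binds one immobilized ligand (rates `k_on1`/`k_off1`) and the
#' bound complex can then engage a second ligand (`k_on2_ru`/`k_off2`),
#' producing avidity. The second-site association rate is kept natively in the
#' biosensor's surface units (RU^-1 s^-1); conversion to molar units for
#' reporting uses `k_on2 (M^-1 s^-1) = k_on2 (RU^-1 s^-1) * 100 * analyte MW`,
#' which is why the analyte molecular weight travels with the parameter set.
#'
#' @param k_on1,k_off1 First-site association (M^-1 s^-1) and dissociation
#'   (s^-1) rate constants.
#' @param k_on2_ru Second-site association rate constant (RU^-1 s^-1).
#' @param k_off2 Second-site dissociation rate constant (s^-1).
#' @param r_max Maximal binding capacity (RU).
#' @param ri Bulk refractive-index offset during injection (RU).
#' @param analyte_mw Analyte molecular weight (Da); required for conversion of
#'   `k_on2_ru` to molar units and for the derived bivalent constant K_D2.
#'
#' @return A list of class `bivalent_params`.
#' @seealso [kinetic_constants()] for the derived K_D1/K_D2.
#' @export
bivalent_params <- function(k_on1, k_off1, k_on2_ru, k_off2, r_max, ri = 0,
                            analyte_mw = NULL) {
  if (k_on1 <= 0 || k_off1 <= 0) {
    stop("invalid-parameter: first-site rate constants must be > 0")
  }
  # zero second-site rates are the admissible 1:1 degenerate limit
  if (k_on2_ru < 0 || k_off2 < 0) {
    stop("invalid-parameter: second-site rate constants must be >= 0")
  }
  if (r_max <= 0) stop("invalid-parameter: r_max must be > 0")
  if (ri < 0) stop("invalid-parameter: ri must be >= 0")
  if (!is.null(analyte_mw) && analyte_mw <= 0) {
    stop("invalid-parameter: analyte_mw must be > 0")
  }
  structure(
    list(k_on1 = k_on1, k_off1 = k_off1, k_on2_ru = k_on2_ru,
         k_off2 = k_off2, r_max = r_max, ri = ri, analyte_mw = analyte_mw),
    class = "bivalent_params"
  )
}

#' Published kinetic parameter sets for LAG-3:Fc binding pHLA-DR1
#'
#' Bivalent-analyte rate constants reported for the interaction between the
#' dimeric LAG-3:Fc fusion protein and HLA-DR1 presenting the influenza
#' HA(306-318) peptide, from global (multi-concentration, 0.1-7.1 uM) and
#' local (single 7.1 uM injection) fits at intermediate ligand density.
#' The published second-site rate is in molar units; it is converted back to
#' surface units here via the analyte molecular weight (the Fc-fused LAG-3
#' dimer, ~200 kDa by default since no exact mass accompanies the constants).
#'
#' @param fit `"global"` or `"local"` parameter set.
#' @param analyte_mw Assumed analyte molecular weight (Da).
#' @return A [bivalent_params()] object.
#' @export
#' @examples
#' kinetic_constants(lag3_bivalent_params("global"))
lag3_bivalent_params <- function(fit = c("global", "local"), analyte_mw = 2e5) {
  fit <- match.arg(fit)
  if (fit == "global") {
    bivalent_params(k_on1 = 5.22e4, k_off1 = 0.380,
                    k_on2_ru = 96.9 / (100 * analyte_mw), k_off2 = 4.10e-3,
                    r_max = 962, ri = 10, analyte_mw = analyte_mw)
  } else {
    bivalent_params(k_on1 = 7.24e4, k_off1 = 0.439,
                    k_on2_ru = 156.6 / (100 * analyte_mw), k_off2 = 4.30e-3,
                    r_max = 1190, ri = 6.6, analyte_mw = analyte_mw)
  }
}

# time grid and phase labels for one cycle; baseline times are <= 0
protocol_grid <- function(protocol) {
  dt <- protocol$interval_s
  t_base <- if (protocol$baseline_s > 0) {
    seq(-protocol$baseline_s, -dt, by = dt)
  } else numeric(0)
  t_assoc <- seq(0, protocol$association_s, by = dt)
  t_diss <- if (protocol$dissociation_s >= dt) {
    seq(protocol$association_s + dt,
        protocol$association_s + protocol$dissociation_s, by = dt)
  } else numeric(0)
  tibble::tibble(
    time_s = c(t_base, t_assoc, t_diss),
    phase = c(rep("baseline", length(t_base)),
              rep("association", length(t_assoc)),
              rep("dissociation", length(t_diss)))
  )
}

new_sensorgram <- function(grid, responses, conc_M, ligand_density_ru,
                           cycle_id) {
  tibble::tibble(
    cycle_id = cycle_id,
    time_s = grid$time_s,
    response_ru = responses,
    conc_M = conc_M,
    phase = grid$phase,
    ligand_density_ru = ligand_density_ru
  )
}

#' Validate a sensorgram table
#'
#' Checks the invariants of the long sensorgram format: per cycle, strictly
#' increasing times, known phase labels, and a single concentration.
#'
#' @param data A sensorgram tibble (`cycle_id`, `time_s`, `response_ru`,
#'   `conc_M`, `phase`, optionally `ligand_density_ru`).
#' @return The input, invisibly, or an error.
#' @export
validate_sensorgram <- function(data) {
  need <- c("cycle_id", "time_s", "response_ru", "conc_M", "phase")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("malformed-header: missing columns: ", paste(missing, collapse = ", "))
  }
  bad_phase <- setdiff(unique(data$phase),
                       c("baseline", "association", "dissociation"))
  if (length(bad_phase) > 0) {
    stop("unknown phase label: ", paste(bad_phase, collapse = ", "))
  }
  by_cycle <- split(data$time_s, data$cycle_id)
  if (any(!vapply(by_cycle, function(t) all(diff(t) > 0), logical(1)))) {
    stop("non-monotone time within a cycle")
  }
  invisible(data)
}

#' Closed-form 1:1 Langmuir sensorgram
#'
#' Analytic solution of the one-to-one interaction model over one injection
#' cycle. During association the bound response relaxes exponentially towards
#' the equilibrium level `R_eq = R_max * k_on * C / (k_on * C + k_off)` with
#' observed rate `k_on * C + k_off`; after the injection stops it decays as
#' `exp(-k_off * t)`. The bulk refractive-index jump `ri` is added only while
#' analyte flows; baseline response is zero.
#'
#' @param params A [one_to_one_params()] object.
#' @param protocol An [injection_protocol()].
#' @param ligand_density_ru Immobilized ligand level recorded with the trace
#'   (RU; informational).
#' @param cycle_id Cycle identifier.
#' @return A sensorgram tibble (one row per time sample).
#' @export
#' @examples
#' sg <- simulate_one_to_one(one_to_one_params(1e5, 0.5, 1000),
#'                           injection_protocol(5e-6))
#' max(sg$response_ru)
simulate_one_to_one <- function(params, protocol, ligand_density_ru = NA_real_,
                                cycle_id = "cycle_1") {
  stopifnot(inherits(params, "one_to_one_params"),
            inherits(protocol, "injection_protocol"))
  grid <- protocol_grid(protocol)
  C <- protocol$conc_M
  bound <- one_to_one_bound(grid$time_s, grid$phase, params$k_on, params$k_off,
                            params$r_max, C, protocol$association_s)
  resp <- bound + ifelse(grid$phase == "association", params$ri, 0)
  new_sensorgram(grid, resp, C, ligand_density_ru, cycle_id)
}

# bound (analyte-mass) response of the 1:1 model, no bulk term
one_to_one_bound <- function(time_s, phase, k_on, k_off, r_max, C, t_assoc) {
  kobs <- k_on * C + k_off
  r_eq <- if (C > 0) r_max * k_on * C / kobs else 0
  bound <- numeric(length(time_s))
  ia <- phase == "association"
  bound[ia] <- r_eq * (1 - exp(-kobs * time_s[ia]))
  id <- phase == "dissociation"
  r_end <- r_eq * (1 - exp(-kobs * t_assoc))
  bound[id] <- r_end * exp(-k_off * (time_s[id] - t_assoc))
  bound
}

# deSolve compiled-model call: integrate the stacked bivalent system for a
# vector of concentrations over one phase segment. y0 is length 2*n.
MAX_BIVALENT_CONC <- 64L

bivalent_segment <- function(y0, times, k_on1, k_off1, k_on2_ru, k_off2,
                             r_max, concs, occupancy,
                             rtol = 1e-8, atol = 1e-6) {
  n <- length(concs)
  if (n > MAX_BIVALENT_CONC) stop("too many concentrations in one series")
  parms <- c(k_on1, k_off1, k_on2_ru, k_off2, r_max, occupancy, n,
             concs, rep(0, MAX_BIVALENT_CONC - n))
  out <- deSolve::ode(y = y0, times = times, func = "derivs_bivalent",
                      parms = parms, dllname = "bindkin",
                      initfunc = "initmod_bivalent",
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) {
    stop("integration-failure: bivalent model solver did not converge")
  }
  out
}

# full two-phase bivalent solve for a vector of concentrations on a common
# grid; returns list(assoc = matrix, dissoc = matrix) of bound response
# (AB + AB2) with one column per concentration.
bivalent_bound_series <- function(params, concs, t_assoc_grid, t_diss_grid,
                                  occupancy = 1) {
  n <- length(concs)
  y0 <- rep(0, 2 * n)
  oa <- bivalent_segment(y0, t_assoc_grid, params$k_on1, params$k_off1,
                         params$k_on2_ru, params$k_off2, params$r_max,
                         concs, occupancy)
  states_a <- oa[, -1, drop = FALSE]
  bound_a <- states_a[, seq(1, 2 * n, by = 2), drop = FALSE] +
    states_a[, seq(2, 2 * n, by = 2), drop = FALSE]
  bound_d <- NULL
  if (length(t_diss_grid) > 0) {
    y_end <- states_a[nrow(states_a), ]
    t0 <- t_assoc_grid[length(t_assoc_grid)]
    od <- bivalent_segment(y_end, c(t0, t_diss_grid), params$k_on1,
                           params$k_off1, params$k_on2_ru, params$k_off2,
                           params$r_max, rep(0, n), occupancy)
    states_d <- od[-1, -1, drop = FALSE]
    bound_d <- states_d[, seq(1, 2 * n, by = 2), drop = FALSE] +
      states_d[, seq(2, 2 * n, by = 2), drop = FALSE]
  }
  list(assoc = bound_a, dissoc = bound_d)
}

#' Simulate a bivalent-analyte sensorgram
#'
#' Numerically integrates the two-step surface scheme in which the dimeric
#' analyte A binds a first immobilized ligand B to form AB and can then
#' engage a second ligand to form AB2:
#' \deqn{dAB/dt = k_{on1} C B_{free} - k_{off1} AB - k_{on2} AB B_{free} + k_{off2} AB2}
#' \deqn{dAB2/dt = k_{on2} AB B_{free} - k_{off2} AB2}
#' with \eqn{B_{free} = R_{max} - AB - AB2} (the second binding event consumes
#' a ligand site but adds no analyte mass, so both AB and AB2 contribute one
#' unit of response). `C` is the analyte concentration during association and
#' zero afterwards. Integration uses a stiff-capable solver (lsoda) at
#' relative tolerance 1e-8.
#'
#' @inheritParams simulate_one_to_one
#' @param params A [bivalent_params()] object.
#' @param occupancy Ligand equivalents consumed by the second binding event
#'   (1, the default, counts AB2 as occupying one ligand in `B_free`; set 2
#'   for the alternative site-stoichiometry bookkeeping).
#' @return A sensorgram tibble.
#' @export
#' @examples
#' sg <- simulate_bivalent(lag3_bivalent_params("global"),
#'                         injection_protocol(7.1e-6))
#' head(sg)
simulate_bivalent <- function(params, protocol, ligand_density_ru = NA_real_,
                              cycle_id = "cycle_1", occupancy = 1) {
  stopifnot(inherits(params, "bivalent_params"),
            inherits(protocol, "injection_protocol"))
  grid <- protocol_grid(protocol)
  ia <- grid$phase == "association"
  id <- grid$phase == "dissociation"
  bnd <- bivalent_bound_series(params, protocol$conc_M,
                               grid$time_s[ia], grid$time_s[id], occupancy)
  bound <- numeric(nrow(grid))
  bound[ia] <- bnd$assoc[, 1]
  bound[id] <- bnd$dissoc[, 1]
  resp <- bound + ifelse(ia, params$ri, 0)
  new_sensorgram(grid, resp, protocol$conc_M, ligand_density_ru, cycle_id)
}

#' Equilibrium bound response of the bivalent-analyte scheme
#'
#' Algebraic steady state of the scheme integrated by [simulate_bivalent()].
#' At steady state the second-site fluxes balance, leaving the first-site
#' balance \eqn{AB = (k_{on1} C / k_{off1}) B_{free}} and
#' \eqn{AB2 = (k_{on2}/k_{off2}) AB \cdot B_{free}}, so the free-ligand level
#' solves a quadratic; the physically admissible root (total bound response
#' between 0 and R_max) is returned in closed form. Bulk refractive index is
#' excluded: this is the bound-analyte response only.
#'
#' @param params A [bivalent_params()] object.
#' @param conc_M Analyte concentration (molar).
#' @param occupancy As in [simulate_bivalent()].
#' @return Equilibrium bound response in RU.
#' @export
equilibrium_response_bivalent <- function(params, conc_M, occupancy = 1) {
  stopifnot(inherits(params, "bivalent_params"))
  if (conc_M < 0) stop("invalid-parameter: concentration must be >= 0")
  if (conc_M == 0) return(0)
  a <- params$k_on1 * conc_M / params$k_off1
  b <- if (params$k_on2_ru == 0) 0 else {
    if (params$k_off2 == 0) {
      stop("no-root: irreversible second site has no finite equilibrium")
    }
    (params$k_on2_ru / params$k_off2) * a
  }
  rmax <- params$r_max
  if (occupancy == 1) {
    # Rmax = x + a x + b x^2 with x = B_free
    if (b == 0) {
      x <- rmax / (1 + a)
    } else {
      x <- (-(1 + a) + sqrt((1 + a)^2 + 4 * b * rmax)) / (2 * b)
    }
    resp <- rmax - x
  } else {
    # AB2 consumes `occupancy` ligand equivalents in B_free but still reports
    # one response unit: Rmax = x + a x + occupancy * b x^2; response is
    # x (a + b x) short of double counting
    f <- function(x) x + a * x + occupancy * b * x^2 - rmax
    x <- stats::uniroot(f, c(0, rmax), tol = 1e-12)$root
    resp <- a * x + b * x^2
  }
  if (!is.finite(resp) || resp < -1e-9 || resp > rmax * (1 + 1e-9)) {
    stop("no-root: equilibrium solution outside admissible range")
  }
  resp
}
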