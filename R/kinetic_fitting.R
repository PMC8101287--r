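#' Goodness-of-fit chi-square for sensorgram fits
#'
#' The evaluation statistic `sum((observed - expected)^2 / expected)` used by
#' biosensor model-comparison workflows. Because sensorgram expected values
#' pass through zero at baseline, the denominator is floored (default 1 RU) so
#' the statistic stays finite; the plain sum of squared residuals should be
#' (and, in [fit_kinetics()], is) reported alongside.
#'
#' @param observed,expected Equal-length numeric response vectors (RU).
#' @param floor Lower bound applied to the denominator (RU).
#' @return The chi-square statistic (dimensionless).
#' @export
#' @examples
#' gof_chisq(c(4, 9), c(2, 10)) # 2.1
gof_chisq <- function(observed, expected, floor = 1) {
  if (length(observed) == 0) stop("empty-input: no samples")
  if (length(observed) != length(expected)) {
    stop("mismatched-data: observed and expected differ in length")
  }
  sum((observed - expected)^2 / pmax(expected, floor))
}

#' Equilibrium dissociation constants from bivalent rate constants
#'
#' Derives the monovalent and bivalent equilibrium dissociation constants from
#' a fitted or published rate set. The second-site association rate is carried
#' in surface units (RU^-1 s^-1) and converted to molar units with
#' `k_on2 (M^-1 s^-1) = k_on2 (RU^-1 s^-1) * 100 * analyte MW (Da)`; then
#' `K_D1 = k_off1 / k_on1` and `K_D2 = k_off2 / k_on2`.
#'
#' @param params A [bivalent_params()] object with `analyte_mw` set.
#' @return A one-row tibble with `k_on2_molar` (M^-1 s^-1), `K_D1` (M),
#'   `K_D2` (M).
#' @export
#' @examples
#' kinetic_constants(lag3_bivalent_params("local"))
kinetic_constants <- function(params) {
  stopifnot(inherits(params, "bivalent_params"))
  if (is.null(params$analyte_mw)) {
    stop("missing molecular weight: analyte_mw is required to convert k_on2")
  }
  k_on2_molar <- params$k_on2_ru * 100 * params$analyte_mw
  tibble::tibble(
    k_on2_molar = k_on2_molar,
    K_D1 = params$k_off1 / params$k_on1,
    K_D2 = params$k_off2 / k_on2_molar
  )
}

# --- internal fitting machinery -------------------------------------------

# split a sensorgram tibble into the per-cycle structures the residual
# functions consume; baseline samples are excluded from fitting
prepare_cycles <- function(data) {
  validate_sensorgram(data)
  cycles <- split(data, data$cycle_id)
  cycles <- cycles[unique(data$cycle_id)] # preserve appearance order
  lapply(cycles, function(cy) {
    ia <- cy$phase == "association"
    id <- cy$phase == "dissociation"
    if (sum(ia) < 5 || sum(id) < 5) {
      stop("under-determined: a fitted phase has fewer than 5 samples")
    }
    list(cycle_id = cy$cycle_id[1], conc = cy$conc_M[1],
         t_assoc = cy$time_s[ia], t_dissoc = cy$time_s[id],
         obs_assoc = cy$response_ru[ia], obs_dissoc = cy$response_ru[id],
         obs_baseline = cy$response_ru[cy$phase == "baseline"])
  })
}

cycles_share_grid <- function(cycles) {
  ta <- cycles[[1]]$t_assoc; td <- cycles[[1]]$t_dissoc
  all(vapply(cycles, function(cy) {
    identical(length(cy$t_assoc), length(ta)) &&
      identical(length(cy$t_dissoc), length(td)) &&
      isTRUE(all.equal(cy$t_assoc, ta)) && isTRUE(all.equal(cy$t_dissoc, td))
  }, logical(1)))
}

# model responses for every fitted sample, bivalent scheme
bivalent_model_responses <- function(theta, cycles, occupancy) {
  k_on1 <- exp(theta[1]); k_off1 <- exp(theta[2])
  k_on2 <- exp(theta[3]); k_off2 <- exp(theta[4])
  r_max <- exp(theta[5])
  ri <- theta[5 + seq_along(cycles)]
  p <- list(k_on1 = k_on1, k_off1 = k_off1, k_on2_ru = k_on2,
            k_off2 = k_off2, r_max = r_max)
  # solver step warnings at extreme multi-start excursions are expected and
  # handled by the cost comparison, not surfaced per evaluation
  suppressWarnings(
  if (cycles_share_grid(cycles)) {
    concs <- vapply(cycles, `[[`, numeric(1), "conc")
    bnd <- bivalent_bound_series(p, concs, cycles[[1]]$t_assoc,
                                 cycles[[1]]$t_dissoc, occupancy)
    unlist(lapply(seq_along(cycles), function(i) {
      c(bnd$assoc[, i] + ri[i], bnd$dissoc[, i])
    }), use.names = FALSE)
  } else {
    unlist(lapply(seq_along(cycles), function(i) {
      cy <- cycles[[i]]
      bnd <- bivalent_bound_series(p, cy$conc, cy$t_assoc, cy$t_dissoc,
                                   occupancy)
      c(bnd$assoc[, 1] + ri[i], bnd$dissoc[, 1])
    }), use.names = FALSE)
  })
}

one_to_one_model_responses <- function(theta, cycles) {
  k_on <- exp(theta[1]); k_off <- exp(theta[2]); r_max <- exp(theta[3])
  ri <- theta[3 + seq_along(cycles)]
  unlist(lapply(seq_along(cycles), function(i) {
    cy <- cycles[[i]]
    t_end <- cy$t_assoc[length(cy$t_assoc)]
    ba <- one_to_one_bound(cy$t_assoc, rep("association", length(cy$t_assoc)),
                           k_on, k_off, r_max, cy$conc, t_end)
    bd <- one_to_one_bound(cy$t_dissoc, rep("dissociation", length(cy$t_dissoc)),
                           k_on, k_off, r_max, cy$conc, t_end)
    c(ba + ri[i], bd)
  }), use.names = FALSE)
}

observed_vector <- function(cycles) {
  unlist(lapply(cycles, function(cy) c(cy$obs_assoc, cy$obs_dissoc)),
         use.names = FALSE)
}

# deterministic multi-start design: multiplicative factors on the rate
# constants (first start = the default or user guess unchanged)
start_factor_table <- function(n_rates) {
  base <- list(rep(1, n_rates),
               c(10, 10, 0.1, 0.1), c(0.1, 0.1, 10, 10),
               c(10, 0.1, 10, 0.1), c(0.1, 10, 0.1, 10))
  lapply(base, function(f) f[seq_len(n_rates)])
}

default_start <- function(model, cycles) {
  r_max0 <- 1.2 * max(vapply(cycles, function(cy)
    max(cy$obs_assoc, cy$obs_dissoc), numeric(1)))
  ri0 <- vapply(cycles, function(cy) {
    base <- if (length(cy$obs_baseline) > 0) {
      mean(utils::tail(cy$obs_baseline, 10))
    } else 0
    max(cy$obs_assoc[1] - base, 0)
  }, numeric(1))
  if (model == "bivalent") {
    list(rates = c(k_on1 = 1e4, k_off1 = 0.1, k_on2_ru = 1e-4, k_off2 = 1e-3),
         r_max = r_max0, ri = ri0)
  } else {
    list(rates = c(k_on = 1e4, k_off = 0.1), r_max = r_max0, ri = ri0)
  }
}

#' Fit kinetic binding models to sensorgrams
#'
#' Simultaneous k_on/k_off nonlinear least-squares fitting of the 1:1
#' Langmuir or bivalent-analyte model to one (local) or several (global)
#' injection cycles. Global fits share all rate constants and `R_max` across
#' cycles (one ligand surface) with an independent bulk refractive-index
#' offset per cycle; only association and dissociation samples enter the cost.
#' Rates are optimized on the log scale (enforcing positivity) with a
#' trust-region Levenberg-Marquardt minimizer and a deterministic multi-start
#' design to escape local minima, so repeated calls with identical inputs and
#' settings are bit-reproducible.
#'
#' @param data Sensorgram tibble (long format; see [simulate_bivalent()]).
#' @param model `"bivalent"` or `"one_to_one"`.
#' @param scope `"global"` (all cycles jointly) or `"local"` (exactly one
#'   cycle).
#' @param mw Analyte molecular weight (Da), required for the derived
#'   equilibrium constants of a bivalent fit.
#' @param start Optional named list overriding the default initial guess:
#'   `rates` (named vector), `r_max`, `ri` (per cycle).
#' @param n_starts Number of multi-start initializations (1-5); the first is
#'   the default/user guess, the rest rescale the rate guesses by a fixed
#'   factor design.
#' @param occupancy Ligand-site bookkeeping for AB2, as in
#'   [simulate_bivalent()].
#' @param chisq_floor Denominator floor (RU) for the reported chi-square.
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults to
#'   `ftol = 1e-10, ptol = 1e-10, maxiter = 100`.
#' @return An object of class `kinetic_fit`; see [tidy.kinetic_fit()],
#'   [glance.kinetic_fit()], [autoplot.kinetic_fit()].
#' @export
#' @examples
#' \donttest{
#' truth <- lag3_bivalent_params("global")
#' sg <- gen_sensorgrams(truth, concs_M = 7.1e-6 / 2^(2:0), seed = 1,
#'                       noise_sd_ru = 0)
#' fit <- fit_kinetics(sg, model = "bivalent", scope = "global",
#'                     mw = 2e5, n_starts = 1)
#' glance(fit)
#' }
fit_kinetics <- function(data, model = c("bivalent", "one_to_one"),
                         scope = c("global", "local"), mw = NULL,
                         start = NULL, n_starts = 5, occupancy = 1,
                         chisq_floor = 1, control = NULL) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  cycles <- prepare_cycles(data)
  if (scope == "local" && length(cycles) != 1) {
    stop("local scope requires exactly one sensorgram cycle")
  }
  if (any(!is.finite(vapply(cycles, `[[`, numeric(1), "conc")))) {
    stop("invalid-parameter: analyte concentrations must be known")
  }
  obs <- observed_vector(cycles)
  s0 <- default_start(model, cycles)
  if (!is.null(start)) {
    for (nm in intersect(names(start), names(s0))) s0[[nm]] <- start[[nm]]
  }
  n_rates <- length(s0$rates)
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  c(list(ftol = 1e-10, ptol = 1e-10, maxiter = 100),
                    control))
  resid_fun <- function(theta) {
    # reject physically absurd excursions (rates or R_max beyond e^±45)
    # before they reach the integrator
    if (any(!is.finite(theta)) || any(abs(theta[seq_len(n_rates + 1)]) > 45)) {
      return(rep(1e6, length(obs)))
    }
    mod <- tryCatch({
      if (model == "bivalent") {
        bivalent_model_responses(theta, cycles, occupancy)
      } else {
        one_to_one_model_responses(theta, cycles)
      }
    }, error = function(e) NULL)
    if (is.null(mod) || length(mod) != length(obs) || any(!is.finite(mod))) {
      return(rep(1e6, length(obs)))
    }
    obs - mod
  }
  factors <- start_factor_table(n_rates)[seq_len(max(1, min(n_starts, 5)))]
  best <- NULL
  for (f in factors) {
    theta0 <- c(log(s0$rates * f), log(s0$r_max), s0$ri)
    res <- tryCatch(
      minpack.lm::nls.lm(par = theta0, fn = resid_fun, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    cost <- sum(res$fvec^2)
    if (is.null(best) || cost < best$cost - 1e-12) {
      best <- list(fit = res, cost = cost)
    }
  }
  if (is.null(best)) {
    stop("non-convergence: no start produced a valid least-squares solution")
  }
  res <- best$fit
  theta <- res$par
  converged <- res$info %in% 1:4
  ri <- theta[n_rates + 1 + seq_along(cycles)]
  rates <- exp(theta[seq_len(n_rates)])
  names(rates) <- names(s0$rates)
  r_max <- exp(theta[n_rates + 1])
  model_resp <- obs - res$fvec
  resid_tbl <- residual_table(cycles, res$fvec)
  params_tbl <- tibble::tibble(
    term = c(names(rates), "r_max", paste0("ri[", names(cycles), "]")),
    estimate = c(rates, r_max, ri))
  derived <- NULL
  params_obj <- NULL
  if (model == "bivalent") {
    params_obj <- bivalent_params(rates[["k_on1"]], rates[["k_off1"]],
                                  rates[["k_on2_ru"]], rates[["k_off2"]],
                                  r_max, ri = max(mean(ri), 0),
                                  analyte_mw = mw)
    if (!is.null(mw)) derived <- kinetic_constants(params_obj)
  } else {
    params_obj <- one_to_one_params(rates[["k_on"]], rates[["k_off"]],
                                    r_max, ri = max(mean(ri), 0))
    derived <- tibble::tibble(K_D = rates[["k_off"]] / rates[["k_on"]])
  }
  structure(
    list(model = model, scope = scope, params = params_tbl,
         params_obj = params_obj, ri = stats::setNames(ri, names(cycles)),
         chisq = gof_chisq(obs, model_resp, floor = chisq_floor),
         ssr = sum(res$fvec^2), residuals = resid_tbl, derived = derived,
         converged = converged,
         concentration_range = range(vapply(cycles, `[[`, numeric(1), "conc")),
         observed = obs, fitted = model_resp, n_obs = length(obs),
         n_cycles = length(cycles), occupancy = occupancy, mw = mw,
         solver_info = res$info, solver_message = res$message),
    class = "kinetic_fit"
  )
}

residual_table <- function(cycles, fvec) {
  idx <- 0
  purrr::map_dfr(cycles, function(cy) {
    n <- length(cy$t_assoc) + length(cy$t_dissoc)
    r <- fvec[idx + seq_len(n)]
    idx <<- idx + n
    tibble::tibble(
      cycle_id = cy$cycle_id,
      time_s = c(cy$t_assoc, cy$t_dissoc),
      phase = c(rep("association", length(cy$t_assoc)),
                rep("dissociation", length(cy$t_dissoc))),
      residual_ru = r)
  })
}

#' Rank competing kinetic fits of the same data
#'
#' Compares fits (e.g. 1:1 vs bivalent) of one dataset by the floored
#' chi-square, reporting the sum of squared residuals and the lag-1
#' autocorrelation of the residual trace alongside. Selection is a ranking,
#' not a hypothesis test; when the best chi-square improves on the runner-up
#' by less than `overparam_tol` (default 1%) the comparison is flagged as not
#' distinguishing the models, which with nested models usually signals
#' over-parameterization of the richer one.
#'
#' @param ... Two or more `kinetic_fit` objects of the same data.
#' @param overparam_tol Relative chi-square improvement below which models are
#'   declared comparable.
#' @return A tibble, one row per fit, ranked best first, with attribute
#'   `"comparable"`.
#' @export
compare_models <- function(..., overparam_tol = 0.01) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "kinetic_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  obs0 <- fits[[1]]$observed
  same <- vapply(fits, function(f) {
    length(f$observed) == length(obs0) && isTRUE(all.equal(f$observed, obs0))
  }, logical(1))
  if (!all(same)) stop("mismatched-data: fits cover different samples")
  tbl <- purrr::map_dfr(fits, function(f) {
    r <- f$residuals$residual_ru
    tibble::tibble(model = f$model, scope = f$scope, chisq = f$chisq,
                   ssr = f$ssr,
                   resid_lag1 = stats::cor(r[-length(r)], r[-1]),
                   converged = f$converged)
  })
  ord <- order(tbl$chisq)
  tbl <- tbl[ord, ]
  tbl$rank <- seq_len(nrow(tbl))
  chis <- tbl$chisq
  comparable <- (chis[2] - chis[1]) < overparam_tol * chis[2]
  attr(tbl, "comparable") <- comparable
  tbl
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s model, %s fit of %d cycle(s), %d samples\n",
              x$model, x$scope, x$n_cycles, x$n_obs))
  cat(sprintf("  chi-square %.3g | SSR %.3g RU^2 | converged: %s\n",
              x$chisq, x$ssr, x$converged))
  print(x$params, n = nrow(x$params))
  if (!is.null(x$derived)) {
    cat("derived equilibrium constants:\n")
    print(x$derived)
  }
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble of parameter estimates (one row per term).
#' @export
tidy.kinetic_fit <- function(x, ...) x$params

#' One-row summary of a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, scope, chi-square, SSR, sample count,
#'   convergence flag and (bivalent fits with known MW) K_D1/K_D2.
#' @export
glance.kinetic_fit <- function(x, ...) {
  out <- tibble::tibble(model = x$model, scope = x$scope, chisq = x$chisq,
                        ssr = x$ssr, n_obs = x$n_obs, n_cycles = x$n_cycles,
                        converged = x$converged)
  if (!is.null(x$derived)) out <- dplyr::bind_cols(out, x$derived)
  out
}

#' Residual-augmented data for a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Fitted samples with observed, fitted and residual columns.
#' @export
augment.kinetic_fit <- function(x, ...) {
  dplyr::mutate(x$residuals, observed_ru = x$observed,
                fitted_ru = x$fitted)
}
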