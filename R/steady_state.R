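#' Extract steady-state readouts from sensorgrams
#'
#' For each injection cycle, reads the response at the sample nearest the
#' requested time into the association phase and subtracts the mean baseline
#' over a window just before injection start, yielding one equilibrium point
#' (concentration, RU increase from baseline) per cycle. At low ligand
#' density with fast kinetics, 30 s into the injection is at steady state;
#' an optional check warns when the trailing association slope suggests the
#' plateau has not been reached.
#'
#' @param data Sensorgram tibble (one or more cycles).
#' @param readout_s Time into the association phase at which the plateau is
#'   read (s).
#' @param baseline_window_s Length of the pre-injection window averaged as
#'   baseline (s); must cover at least 3 baseline samples.
#' @param check_plateau If `TRUE`, warn when the mean slope over the last 5 s
#'   of association exceeds 1 RU/s.
#' @return A tibble with one row per cycle: `cycle_id`, `conc_M`,
#'   `response_ru`.
#' @export
extract_plateau <- function(data, readout_s = 30, baseline_window_s = 10,
                            check_plateau = FALSE) {
  validate_sensorgram(data)
  cycles <- split(data, data$cycle_id)
  cycles <- cycles[unique(data$cycle_id)]
  purrr::map_dfr(cycles, function(cy) {
    assoc <- cy[cy$phase == "association", ]
    if (nrow(assoc) == 0) stop("phase-missing: no association samples")
    if (readout_s > max(assoc$time_s)) {
      stop("readout time lies beyond the association phase")
    }
    base <- cy[cy$phase == "baseline" &
                 cy$time_s >= -baseline_window_s, ]
    if (nrow(base) < 3) {
      stop("baseline window must cover at least 3 samples")
    }
    i <- which.min(abs(assoc$time_s - readout_s))
    if (check_plateau) {
      tail_w <- assoc[assoc$time_s >= max(assoc$time_s) - 5, ]
      if (nrow(tail_w) >= 2) {
        slope <- stats::coef(stats::lm(response_ru ~ time_s, data = tail_w))[2]
        if (abs(slope) > 1) {
          warning("association still rising > 1 RU/s at readout; ",
                  "steady state may not be reached")
        }
      }
    }
    tibble::tibble(cycle_id = cy$cycle_id[1], conc_M = cy$conc_M[1],
                   response_ru = assoc$response_ru[i] -
                     mean(base$response_ru))
  })
}

#' One-site specific binding isotherm fit
#'
#' Least-squares fit of the saturation isotherm
#' `R(C) = B_max * C / (K_D + C)` to equilibrium points, the steady-state
#' route to a monovalent affinity that makes no kinetic assumptions. K_D and
#' B_max are optimized on the log scale with Levenberg-Marquardt; the fit is
#' deterministic given the data. When every concentration sits far above the
#' fitted K_D the isotherm is saturated and K_D is poorly constrained, which
#' is flagged rather than hidden.
#'
#' @param points Tibble with columns `conc_M` and `response_ru` (at least 4
#'   distinct concentrations).
#' @return An object of class `isotherm_fit` with elements `K_D` (M), `B_max`
#'   (RU), `ssr`, `converged`, `kd_constrained`, and the data.
#' @export
#' @examples
#' pts <- tibble::tibble(conc_M = 13.1e-6 * 2^(-3:3),
#'                       response_ru = 500 * conc_M / (13.1e-6 + conc_M))
#' fit_one_site(pts)
fit_one_site <- function(points) {
  stopifnot(all(c("conc_M", "response_ru") %in% names(points)))
  points <- points[is.finite(points$conc_M) & is.finite(points$response_ru), ]
  if (length(unique(points$conc_M)) < 4) {
    stop("under-determined: need >= 4 distinct concentrations")
  }
  C <- points$conc_M; R <- points$response_ru
  # starting values: B_max from top responses, K_D from half-max crossing
  b0 <- max(R) * 1.05
  kd0 <- stats::approx(R, C, xout = b0 / 2, ties = mean, rule = 2)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(C)
  resid_fun <- function(theta) {
    kd <- exp(theta[1]); bmax <- exp(theta[2])
    R - bmax * C / (kd + C)
  }
  res <- minpack.lm::nls.lm(
    par = c(log(kd0), log(b0)), fn = resid_fun,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 200))
  if (!(res$info %in% 1:4)) {
    stop("non-convergence: isotherm fit did not converge (", res$message, ")")
  }
  kd <- exp(res$par[1]); bmax <- exp(res$par[2])
  structure(
    list(K_D = kd, B_max = bmax, ssr = sum(res$fvec^2), converged = TRUE,
         kd_constrained = min(C) < 10 * kd, data = points,
         fitted = bmax * C / (kd + C)),
    class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit> K_D = %.3g M (%.3g uM), B_max = %.4g RU, SSR = %.3g\n",
              x$K_D, x$K_D * 1e6, x$B_max, x$ssr))
  if (!x$kd_constrained) {
    cat("  note: all concentrations >> K_D; K_D is poorly constrained\n")
  }
  invisible(x)
}

#' @export
tidy.isotherm_fit <- function(x, ...) {
  tibble::tibble(term = c("K_D", "B_max"), estimate = c(x$K_D, x$B_max))
}

#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble::tibble(K_D = x$K_D, B_max = x$B_max, ssr = x$ssr,
                 converged = x$converged, kd_constrained = x$kd_constrained,
                 n = nrow(x$data))
}

#' Dissociation behaviour across a ligand-density series
#'
#' Bivalent (avid) binding is density-dependent: crowded surfaces let the
#' dimeric analyte engage a second ligand, lengthening the apparent
#' dissociation. This summarizes, per immobilization density, the apparent
#' dissociation half-time (time after injection stop at which the bound
#' response first halves, linearly interpolated) and the fraction of response
#' remaining at fixed offsets, then flags whether half-time increases with
#' density. Under 1:1 kinetics half-times are density-independent.
#'
#' @param data Sensorgram tibble; cycles are grouped by `ligand_density_ru`.
#'   Comparisons assume a shared analyte concentration.
#' @param offsets_s Offsets into the dissociation phase (s) at which remaining
#'   fraction is reported.
#' @param tol_s Half-time differences below this are treated as no effect (s).
#' @return A tibble ordered by density with columns `ligand_density_ru`,
#'   `half_time_s`, `frac_remaining_<offset>`; attribute
#'   `"density_effect"` is `TRUE` when half-time is strictly increasing with
#'   density beyond `tol_s`.
#' @export
analyze_density_series <- function(data, offsets_s = c(10, 30, 60),
                                   tol_s = 0.5) {
  validate_sensorgram(data)
  if (!"ligand_density_ru" %in% names(data)) {
    stop("ligand_density_ru column required")
  }
  groups <- split(data, data$ligand_density_ru)
  if (length(groups) < 2) stop("need >= 2 ligand-density groups")
  rows <- purrr::map_dfr(groups, function(g) {
    cy <- g[g$cycle_id == g$cycle_id[1], ]
    diss <- cy[cy$phase == "dissociation", ]
    if (nrow(diss) == 0) stop("missing dissociation phase")
    t0 <- max(cy$time_s[cy$phase == "association"])
    r0 <- diss$response_ru[1]
    tt <- diss$time_s - t0
    rr <- diss$response_ru
    half <- if (all(rr > r0 / 2)) {
      NA_real_ # not reached within the recorded window
    } else {
      i <- which(rr <= r0 / 2)[1]
      if (i == 1) tt[1] else {
        tt[i - 1] + (tt[i] - tt[i - 1]) *
          (r0 / 2 - rr[i - 1]) / (rr[i] - rr[i - 1])
      }
    }
    fr <- vapply(offsets_s, function(off) {
      stats::approx(tt, rr, xout = off, rule = 2)$y / r0
    }, numeric(1))
    out <- tibble::tibble(ligand_density_ru = cy$ligand_density_ru[1],
                          half_time_s = half)
    out[paste0("frac_remaining_", offsets_s)] <- as.list(fr)
    out
  })
  rows <- rows[order(rows$ligand_density_ru), ]
  ht <- rows$half_time_s
  effect <- if (any(is.na(ht))) {
    # an unreached half-time at higher density itself indicates lengthening
    !is.unsorted(is.na(ht)) && any(is.na(ht) != is.na(ht[1]))
  } else {
    all(diff(ht) > tol_s)
  }
  attr(rows, "density_effect") <- effect
  rows
}
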