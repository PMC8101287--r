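#' Seeded synthetic sensorgram series
#'
#' Simulates an injection series (the noise-free model trace for each analyte
#' concentration) and adds i.i.d. Gaussian instrument noise and, optionally,
#' a linear baseline drift. The default design mirrors a twofold analyte
#' dilution series injected for 30 s with a 300 s dissociation. Ground-truth
#' parameters are attached as the `"truth"` attribute, so every downstream
#' fit can be scored against the generating values. Reproducible per seed.
#'
#' @param params A [bivalent_params()] or [one_to_one_params()] object (the
#'   generating model is chosen by the class).
#' @param concs_M Analyte concentration series (molar).
#' @param seed Integer seed.
#' @param noise_sd_ru Gaussian noise standard deviation (RU); 2 RU is typical
#'   short-noise for research-grade instruments and is the default study
#'   condition.
#' @param drift_ru_per_s Optional linear baseline drift (RU/s).
#' @param protocol_template An [injection_protocol()] whose timing fields are
#'   reused for every concentration.
#' @param ligand_density_ru Recorded immobilization level (RU).
#' @param occupancy Passed to [simulate_bivalent()].
#' @return A sensorgram tibble covering all cycles, with attribute `"truth"`
#'   (list: `params`, `noise_sd_ru`, `drift_ru_per_s`, `seed`).
#' @export
#' @examples
#' sg <- gen_sensorgrams(lag3_bivalent_params("global"),
#'                       concs_M = 7.1e-6 / 2^(6:0), seed = 1)
#' dplyr::count(sg, cycle_id)
gen_sensorgrams <- function(params, concs_M = 57e-6 / 2^(9:0), seed,
                            noise_sd_ru = 2, drift_ru_per_s = 0,
                            protocol_template = injection_protocol(1e-6),
                            ligand_density_ru = NA_real_, occupancy = 1) {
  stopifnot(length(concs_M) >= 1, noise_sd_ru >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- purrr::map_dfr(seq_along(concs_M), function(i) {
    proto <- injection_protocol(concs_M[i],
                                protocol_template$association_s,
                                protocol_template$dissociation_s,
                                protocol_template$interval_s,
                                protocol_template$baseline_s)
    clean <- if (inherits(params, "bivalent_params")) {
      simulate_bivalent(params, proto, ligand_density_ru,
                        cycle_id = sprintf("cycle_%02d", i),
                        occupancy = occupancy)
    } else {
      simulate_one_to_one(params, proto, ligand_density_ru,
                          cycle_id = sprintf("cycle_%02d", i))
    }
    noisy <- clean$response_ru
    if (noise_sd_ru > 0) {
      noisy <- noisy + stats::rnorm(length(noisy), 0, noise_sd_ru)
    }
    if (drift_ru_per_s != 0) {
      noisy <- noisy + drift_ru_per_s * (clean$time_s - min(clean$time_s))
    }
    clean$response_ru <- noisy
    clean
  })
  attr(out, "truth") <- list(params = params, noise_sd_ru = noise_sd_ru,
                             drift_ru_per_s = drift_ru_per_s, seed = seed)
  out
}

#' Seeded synthetic cross-titration plate
#'
#' Emulates a bead-proximity cross-titration: three acceptor-side
#' concentrations titrated against a one-in-three donor dilution series
#' (0.3-300 nM by default). Negative plates contain background noise only;
#' positive plates follow a saturating binding curve, optionally with a hook
#' (post-peak signal loss) beyond `hook_peak_nM`. The true label is attached.
#'
#' @param true_positive Should the plate contain real binding signal?
#' @param hook_peak_nM Donor concentration of maximal signal beyond which the
#'   hook suppresses counts, or `NULL` for no hook.
#' @param seed Integer seed.
#' @param donor_nM,acceptor_nM Concentration series (nM).
#' @param background_mean Mean buffer-alone counts (arbitrary units; the
#'   absolute count scale of such readers is instrument-specific).
#' @param signal_fold Peak specific signal as a multiple of background.
#' @param ec50_nM Donor concentration of half-maximal specific signal.
#' @param cv Multiplicative (lognormal-free, Gaussian) noise CV.
#' @return A [titration_plate()] with attribute `"truth"`.
#' @export
gen_titration_plate <- function(true_positive, hook_peak_nM = NULL, seed,
                                donor_nM = 300 / 3^(9:0),
                                acceptor_nM = c(0.3, 3, 30),
                                background_mean = 1000, signal_fold = 30,
                                ec50_nM = 10, cv = 0.05) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  donor_nM <- sort(donor_nM)
  n_a <- length(acceptor_nM); n_d <- length(donor_nM)
  clean <- matrix(background_mean, n_a, n_d)
  if (true_positive) {
    for (i in seq_len(n_a)) {
      spec <- background_mean * signal_fold * donor_nM / (ec50_nM + donor_nM)
      if (!is.null(hook_peak_nM)) {
        over <- donor_nM > hook_peak_nM
        # signal collapses with excess free analyte past the optimum
        spec[over] <- spec[over] *
          (hook_peak_nM / donor_nM[over])^1.5
      }
      clean[i, ] <- clean[i, ] + spec
    }
  }
  noise <- matrix(stats::rnorm(n_a * n_d, 0, cv), n_a, n_d)
  counts <- clean * (1 + noise)
  background <- background_mean *
    (1 + stats::rnorm(4, 0, cv))
  plate <- titration_plate(donor_nM, acceptor_nM, counts, background)
  attr(plate, "truth") <- list(true_positive = true_positive,
                               hook_peak_nM = hook_peak_nM, seed = seed,
                               ec50_nM = ec50_nM, cv = cv)
  plate
}

#' Seeded synthetic inhibition (blockade) series
#'
#' 4PL signal over a one-in-three inhibitor dilution series spanning several
#' decades around the true IC50, with multiplicative Gaussian noise. The
#' default IC50 of 1.32 nM reproduces the fab-blockade design this package's
#' inhibition fitting targets.
#'
#' @param ic50_nM True half-maximal inhibitory concentration (nM).
#' @param hill True Hill slope.
#' @param seed Integer seed.
#' @param inhibitor_nM Concentration series (nM); default one-in-three from
#'   1000 nM down (12 points, ~5 decades).
#' @param top,bottom Plateau signals (arbitrary units).
#' @param cv Multiplicative noise CV.
#' @return Tibble (`inhibitor_nM`, `signal`) with attribute `"truth"`.
#' @export
gen_inhibition_series <- function(ic50_nM = 1.32, hill = 1, seed,
                                  inhibitor_nM = 1000 / 3^(11:0),
                                  top = 10000, bottom = 200, cv = 0.05) {
  stopifnot(ic50_nM > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  clean <- bottom + (top - bottom) / (1 + (inhibitor_nM / ic50_nM)^hill)
  signal <- clean * (1 + stats::rnorm(length(clean), 0, cv))
  out <- tibble::tibble(inhibitor_nM = inhibitor_nM, signal = signal)
  attr(out, "truth") <- list(ic50_nM = ic50_nM, hill = hill, top = top,
                             bottom = bottom, cv = cv, seed = seed)
  out
}

#' Seeded synthetic multimer-staining event tables
#'
#' Generates a reference sample (single log-normal autofluorescence
#' population) and a stain sample in which a `positive_fraction` of events is
#' shifted to a brighter log-normal population, plus per-event live/dead
#' flags. Emulates dim multimer staining of a receptor-transduced line versus
#' its FMO/irrelevant-multimer control.
#'
#' @param positive_fraction Fraction of stain events in the bright
#'   population, in `[0, 1]`.
#' @param seed Integer seed.
#' @param n_events Events per sample.
#' @param log_mean_neg,log_sd Log-scale location and spread of the negative
#'   population.
#' @param log_shift Log-scale separation of the positive population.
#' @param dead_fraction Fraction of events flagged dead.
#' @return List of tibbles `stain` and `reference` (`intensity`, `live`) with
#'   attribute `"truth"`.
#' @export
gen_flow_events <- function(positive_fraction, seed, n_events = 20000,
                            log_mean_neg = log(100), log_sd = 0.5,
                            log_shift = 3, dead_fraction = 0.05) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gen_pop <- function(n, mu) stats::rlnorm(n, mu, log_sd)
  reference <- tibble::tibble(
    intensity = gen_pop(n_events, log_mean_neg),
    live = stats::runif(n_events) > dead_fraction)
  n_pos <- stats::rbinom(1, n_events, positive_fraction)
  stain_int <- c(gen_pop(n_events - n_pos, log_mean_neg),
                 gen_pop(n_pos, log_mean_neg + log_shift))
  stain_int <- sample(stain_int)
  stain <- tibble::tibble(
    intensity = stain_int,
    live = stats::runif(n_events) > dead_fraction)
  out <- list(stain = stain, reference = reference)
  attr(out, "truth") <- list(positive_fraction = positive_fraction,
                             seed = seed, log_shift = log_shift)
  out
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
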