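#' Geometric mean fluorescence intensity
#'
#' gMFI of the live events of a stained sample: `exp(mean(log(intensity)))`.
#' Fluorescence intensities are log-normally distributed to a good
#' approximation, so the geometric mean is the standard location summary.
#'
#' @param events Tibble with columns `intensity` (> 0) and `live` (logical);
#'   a bare numeric vector is treated as all-live intensities.
#' @return The gMFI (same arbitrary units as the input).
#' @export
#' @examples
#' geometric_mfi(c(10, 1000)) # 100
geometric_mfi <- function(events) {
  if (is.numeric(events)) {
    events <- tibble::tibble(intensity = events, live = TRUE)
  }
  stopifnot(all(c("intensity", "live") %in% names(events)))
  x <- events$intensity[events$live]
  if (length(x) == 0) stop("no-live-events: nothing to summarize")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("nonpositive-intensity: gMFI requires finite intensities > 0")
  }
  exp(mean(log(x)))
}

#' FMO background subtraction of gMFI
#'
#' Subtracts the fluorescence-minus-one (FMO) control gMFI from the stained
#' sample's gMFI, flooring at zero. A floored result means the stain was
#' dimmer than its control, which is flagged.
#'
#' @param stain_gmfi,fmo_gmfi Finite gMFI values.
#' @return A one-row tibble: `gmfi` (floored difference) and `floored`.
#' @export
fmo_subtract <- function(stain_gmfi, fmo_gmfi) {
  stopifnot(is.finite(stain_gmfi), is.finite(fmo_gmfi))
  d <- stain_gmfi - fmo_gmfi
  tibble::tibble(gmfi = max(d, 0), floored = d < 0)
}

#' Percent positive events relative to a reference sample
#'
#' Places the positivity threshold at a high quantile (default 99.9th
#' percentile) of the reference (FMO or irrelevant-multimer control) sample's
#' live-event intensities and returns the percentage of live stain events
#' above it. Because the rule is rank-based it is invariant under any strictly
#' monotone intensity transform applied to both samples.
#'
#' @param stain,reference Event tibbles (`intensity`, `live`) or numeric
#'   vectors.
#' @param quantile Reference quantile defining the gate, in (0, 1).
#' @return Percentage of stain events above the threshold (0-100).
#' @export
percent_positive <- function(stain, reference, quantile = 0.999) {
  stopifnot(quantile > 0, quantile < 1)
  as_events <- function(e) {
    if (is.numeric(e)) tibble::tibble(intensity = e, live = TRUE) else e
  }
  stain <- as_events(stain); reference <- as_events(reference)
  ref <- reference$intensity[reference$live]
  if (length(ref) == 0) stop("empty-reference: no live reference events")
  thr <- stats::quantile(ref, quantile, names = FALSE, type = 7)
  x <- stain$intensity[stain$live]
  100 * mean(x > thr)
}

#' Blockade staining normalized to control
#'
#' Expresses a blockade condition's background-subtracted gMFI as a
#' percentage of the control blockade's background-subtracted gMFI:
#' `100 * (condition - fmo) / (control - fmo)`, floored at zero. The ratio is
#' invariant to overall intensity rescaling.
#'
#' @param condition_gmfi gMFI under the blocking condition.
#' @param control_gmfi gMFI under the control (non-blocking) condition; must
#'   exceed `fmo_gmfi`.
#' @param fmo_gmfi FMO control gMFI.
#' @return Percent binding (>= 0; 100 means no blockade effect).
#' @export
normalize_blockade <- function(condition_gmfi, control_gmfi, fmo_gmfi) {
  if (control_gmfi <= fmo_gmfi) {
    stop("degenerate-control: control gMFI must exceed FMO gMFI")
  }
  max(100 * (condition_gmfi - fmo_gmfi) / (control_gmfi - fmo_gmfi), 0)
}
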