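#' Bead-proximity cross-titration plate
#'
#' Container for an AlphaScreen-style cross-titration: a matrix of assay
#' counts with one row per acceptor-side protein concentration and one column
#' per donor-side concentration, plus buffer-alone background wells.
#'
#' @param donor_nM Donor-side concentration series (nM), strictly monotone.
#' @param acceptor_nM Acceptor-side concentration series (nM), strictly
#'   monotone.
#' @param counts Numeric matrix, `length(acceptor_nM)` rows by
#'   `length(donor_nM)` columns.
#' @param background Vector of buffer-alone counts (>= 1 well).
#' @return An object of class `titration_plate`.
#' @export
titration_plate <- function(donor_nM, acceptor_nM, counts, background) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(acceptor_nM) ||
      ncol(counts) != length(donor_nM)) {
    stop("counts matrix dimensions must match the concentration series")
  }
  if (any(donor_nM < 0) || any(acceptor_nM < 0)) {
    stop("concentrations must be >= 0")
  }
  mono <- function(x) all(diff(x) > 0) || all(diff(x) < 0)
  if (!mono(donor_nM) || !mono(acceptor_nM)) {
    stop("concentration series must be strictly monotone")
  }
  structure(
    list(donor_nM = donor_nM, acceptor_nM = acceptor_nM, counts = counts,
         background = background, corrected = FALSE),
    class = "titration_plate")
}

#' @export
print.titration_plate <- function(x, ...) {
  cat(sprintf("<titration_plate> %d acceptor x %d donor concentrations%s\n",
              length(x$acceptor_nM), length(x$donor_nM),
              if (x$corrected) " (background-corrected)" else ""))
  invisible(x)
}

#' Long-format view of a titration plate
#'
#' @param x A `titration_plate`.
#' @param ... Unused.
#' @return Tibble with `acceptor_nM`, `donor_nM`, `counts`.
#' @export
tidy.titration_plate <- function(x, ...) {
  tibble::tibble(
    acceptor_nM = rep(x$acceptor_nM, times = length(x$donor_nM)),
    donor_nM = rep(x$donor_nM, each = length(x$acceptor_nM)),
    counts = as.vector(x$counts))
}

#' Background-correct a cross-titration plate
#'
#' Subtracts the mean buffer-alone count from every well, flooring at zero
#' (a corrected plate, whose background is zero, passes through unchanged, so
#' the operation is idempotent). Background statistics are retained on the
#' plate.
#'
#' @param plate A [titration_plate()].
#' @return The corrected plate; `$background_stats` holds the mean, sd and
#'   well count of the background used.
#' @export
subtract_background <- function(plate) {
  stopifnot(inherits(plate, "titration_plate"))
  if (length(plate$background) < 1) {
    stop("no-background-wells: at least one buffer-alone well required")
  }
  if (plate$corrected) return(plate) # idempotent
  bg <- mean(plate$background)
  plate$background_stats <- tibble::tibble(
    mean = bg, sd = stats::sd(plate$background),
    n_wells = length(plate$background))
  plate$counts <- pmax(plate$counts - bg, 0)
  plate$corrected <- TRUE
  plate
}

#' Hook-effect detection in a concentration series
#'
#' Bead-proximity assays lose signal at high analyte concentration once free
#' analyte saturates the beads separately (the "hook"). A hook is flagged
#' when, after the maximum of the concentration-ordered signal, the series
#' falls by at least `drop_frac` of that maximum.
#'
#' @param conc_nM Concentration series (nM).
#' @param signal Signal at each concentration.
#' @param drop_frac Fractional post-peak drop that declares a hook.
#' @return A one-row tibble: `hook`, `peak_conc_nM`, `post_peak_drop`.
#' @export
#' @examples
#' detect_hook(c(1, 3, 10, 30), c(100, 500, 1000, 700))
detect_hook <- function(conc_nM, signal, drop_frac = 0.2) {
  ord <- order(conc_nM)
  conc_nM <- conc_nM[ord]; signal <- signal[ord]
  if (length(signal) < 4 || max(signal) <= 0) {
    return(tibble::tibble(hook = FALSE, peak_conc_nM = NA_real_,
                          post_peak_drop = NA_real_))
  }
  imax <- which.max(signal)
  drop <- if (imax == length(signal)) 0 else {
    (signal[imax] - min(signal[imax:length(signal)])) / signal[imax]
  }
  tibble::tibble(hook = drop >= drop_frac, peak_conc_nM = conc_nM[imax],
                 post_peak_drop = drop)
}

#' Summarize a cross-titration plate
#'
#' For each acceptor concentration (plate row), reports fold-over-background
#' across the donor dilution series, a Spearman rank-correlation trend of
#' signal versus donor concentration over the pre-hook region, hook detection,
#' and a binding call: positive when the peak fold-over-background reaches
#' `fold_threshold` and the trend statistic reaches `trend_threshold`. These
#' thresholds formalize the by-eye "binding detected / not detected" reading
#' of such plates; a flat negative-control plate yields negative calls.
#'
#' @param plate A background-corrected [titration_plate()] (uncorrected plates
#'   are corrected first).
#' @param fold_threshold Minimum peak fold-over-background for a positive
#'   call.
#' @param trend_threshold Minimum pre-hook Spearman correlation for a positive
#'   call.
#' @param drop_frac Passed to [detect_hook()].
#' @return A tibble with one row per acceptor concentration: peak fold over
#'   background, trend statistic, hook fields and `positive` call.
#' @export
summarize_cross_titration <- function(plate, fold_threshold = 3,
                                      trend_threshold = 0.8,
                                      drop_frac = 0.2) {
  stopifnot(inherits(plate, "titration_plate"))
  if (length(plate$donor_nM) < 3) {
    stop("degenerate-series: need >= 3 donor concentrations")
  }
  if (!plate$corrected) plate <- subtract_background(plate)
  bg_mean <- plate$background_stats$mean
  # fold over raw background; guard degenerate zero-background plates
  bg_scale <- if (is.finite(bg_mean) && bg_mean > 0) bg_mean else 1
  ord <- order(plate$donor_nM)
  donor <- plate$donor_nM[ord]
  purrr::map_dfr(seq_along(plate$acceptor_nM), function(i) {
    sig <- plate$counts[i, ord]
    hk <- detect_hook(donor, sig, drop_frac)
    pre <- if (isTRUE(hk$hook)) seq_len(which.max(sig)) else seq_along(sig)
    trend <- if (length(pre) >= 3 && stats::sd(sig[pre]) > 0) {
      stats::cor(donor[pre], sig[pre], method = "spearman")
    } else 0
    peak_fold <- (max(sig) + bg_scale) / bg_scale
    tibble::tibble(
      acceptor_nM = plate$acceptor_nM[i], peak_fold = peak_fold,
      trend = trend, hook = hk$hook, peak_conc_nM = hk$peak_conc_nM,
      positive = peak_fold >= fold_threshold & trend >= trend_threshold)
  })
}

#' Four-parameter logistic (4PL) IC50 fit of a blockade titration
#'
#' Fits `S(c) = bottom + (top - bottom) / (1 + (c / IC50)^h)` to an inhibitor
#' dilution series by least squares, with IC50 optimized on the log scale.
#' The Hill slope is fitted, not fixed. Requires a signal transition: the
#' max/min signal ratio must be at least 2.
#'
#' @param inhibitor_nM Inhibitor concentrations (nM); zero-concentration
#'   control wells may be included and anchor `top`.
#' @param signal Assay counts at each concentration.
#' @return An object of class `ic50_fit` with `ic50_nM`, `hill`, `top`,
#'   `bottom`, `ssr`, `converged` and the data.
#' @export
#' @examples
#' conc <- 1000 / 3^(0:10)
#' fit_inhibition(conc, 1 / (1 + conc / 1.32))
fit_inhibition <- function(inhibitor_nM, signal) {
  stopifnot(length(inhibitor_nM) == length(signal))
  keep <- is.finite(inhibitor_nM) & is.finite(signal)
  inhibitor_nM <- inhibitor_nM[keep]; signal <- signal[keep]
  pos <- inhibitor_nM > 0
  if (sum(pos) < 5) {
    stop("under-determined: need >= 5 nonzero inhibitor concentrations")
  }
  smax <- max(signal); smin <- min(signal)
  if (smin <= 0) smin <- max(smin, smax * 1e-6)
  if (smax / max(smin, .Machine$double.eps) < 2) {
    stop("no-transition: max/min signal ratio < 2")
  }
  # starting IC50: concentration whose signal is closest to mid-range
  mid <- (smax + smin) / 2
  ic0 <- inhibitor_nM[pos][which.min(abs(signal[pos] - mid))]
  resid_fun <- function(theta) {
    ic <- exp(theta[1]); h <- theta[2]; top <- theta[3]; bot <- theta[4]
    pred <- ifelse(inhibitor_nM == 0, top,
                   bot + (top - bot) / (1 + (inhibitor_nM / ic)^h))
    signal - pred
  }
  res <- minpack.lm::nls.lm(
    par = c(log(ic0), 1, smax, smin),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 200))
  if (!(res$info %in% 1:4)) {
    stop("non-convergence: 4PL fit did not converge (", res$message, ")")
  }
  structure(
    list(ic50_nM = exp(res$par[1]), hill = res$par[2], top = res$par[3],
         bottom = res$par[4], ssr = sum(res$fvec^2), converged = TRUE,
         data = tibble::tibble(inhibitor_nM = inhibitor_nM, signal = signal)),
    class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit> IC50 = %.3g nM, Hill = %.3g, top = %.3g, bottom = %.3g, SSR = %.3g\n",
              x$ic50_nM, x$hill, x$top, x$bottom, x$ssr))
  invisible(x)
}

#' @export
tidy.ic50_fit <- function(x, ...) {
  tibble::tibble(term = c("ic50_nM", "hill", "top", "bottom"),
                 estimate = c(x$ic50_nM, x$hill, x$top, x$bottom))
}

#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50_nM = x$ic50_nM, hill = x$hill, top = x$top,
                 bottom = x$bottom, ssr = x$ssr, converged = x$converged,
                 n = nrow(x$data))
}
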