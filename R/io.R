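#' Read and write sensorgram CSV files
#'
#' The long sensorgram dialect: UTF-8 CSV with header columns `cycle_id`,
#' `time_s`, `response_ru`, `conc_M`, `phase`, `ligand_density_ru`. The writer
#' emits full precision; the reader tolerates a missing `ligand_density_ru`
#' column (treated as unknown) and validates phases and per-cycle time
#' monotonicity. Values round-trip bit-exactly.
#'
#' @param path File path.
#' @param data Sensorgram tibble.
#' @return `read_sensorgram_csv()`: a validated sensorgram tibble;
#'   `write_sensorgram_csv()`: `path`, invisibly.
#' @export
read_sensorgram_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  need <- c("cycle_id", "time_s", "response_ru", "conc_M", "phase")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("malformed-header: missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"ligand_density_ru" %in% names(data)) {
    data$ligand_density_ru <- NA_character_
  }
  # correctly-rounded text-to-double conversion so writer output round-trips
  # to the identical bit pattern
  for (col in c("time_s", "response_ru", "conc_M", "ligand_density_ru")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  data <- data[c(need, "ligand_density_ru")]
  data$cycle_id <- as.character(data$cycle_id)
  validate_sensorgram(data)
  data
}

#' @rdname read_sensorgram_csv
#' @export
write_sensorgram_csv <- function(data, path) {
  validate_sensorgram(data)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write equilibrium-point CSV files
#'
#' Two-column dialect for steady-state isotherm points: `conc_M`,
#' `response_ru`.
#'
#' @param path File path.
#' @param points Tibble with `conc_M`, `response_ru`.
#' @return The points tibble, or (writer) `path` invisibly.
#' @export
read_equilibrium_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("conc_M", "response_ru") %in% names(data))) {
    stop("malformed-header: need conc_M and response_ru columns")
  }
  data[c("conc_M", "response_ru")]
}

#' @rdname read_equilibrium_csv
#' @export
write_equilibrium_csv <- function(points, path) {
  readr::write_csv(points[c("conc_M", "response_ru")], path)
  invisible(path)
}

#' Read and write cross-titration plate CSV files
#'
#' Plate dialect: first column `acceptor_nM`, remaining column names the
#' donor concentrations (nM), body the counts. Background (buffer-alone)
#' wells occupy rows whose `acceptor_nM` field is the literal `buffer`; their
#' row values are the background counts.
#'
#' @param path File path.
#' @param plate A [titration_plate()].
#' @return The plate, or (writer) `path` invisibly.
#' @export
read_plate_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(acceptor_nM = "c"))
  if (names(raw)[1] != "acceptor_nM") {
    stop("malformed-header: first column must be acceptor_nM")
  }
  donor <- as.numeric(names(raw)[-1])
  if (any(!is.finite(donor))) {
    stop("malformed-header: donor columns must be numeric concentrations")
  }
  is_bg <- raw$acceptor_nM == "buffer"
  background <- unlist(raw[is_bg, -1], use.names = FALSE)
  background <- background[is.finite(background)]
  body <- raw[!is_bg, ]
  titration_plate(donor, as.numeric(body$acceptor_nM),
                  as.matrix(body[-1]), background)
}

#' @rdname read_plate_csv
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(inherits(plate, "titration_plate"))
  body <- as.data.frame(plate$counts)
  names(body) <- as.character(plate$donor_nM)
  body <- cbind(acceptor_nM = as.character(plate$acceptor_nM), body)
  nbg <- length(plate$background)
  if (nbg > 0) {
    pad <- matrix(NA_real_, 1, length(plate$donor_nM))
    pad[1, seq_len(min(nbg, ncol(pad)))] <-
      plate$background[seq_len(min(nbg, ncol(pad)))]
    bg_row <- as.data.frame(pad)
    names(bg_row) <- as.character(plate$donor_nM)
    bg_row <- cbind(acceptor_nM = "buffer", bg_row)
    body <- rbind(body, bg_row)
  }
  readr::write_csv(tibble::as_tibble(body), path, na = "")
  invisible(path)
}

#' End-to-end kinetic plus steady-state binding analysis
#'
#' Runs the package's analysis flow on supplied or synthetic data: a global
#' bivalent-analyte kinetic fit of an intermediate-density injection series,
#' a steady-state one-site isotherm fit of a low-density series, and a
#' consistency report comparing the kinetically derived monovalent constant
#' K_D1 with the steady-state K_D. Agreement of the two routes (ratio near 1)
#' is what licenses reading the low-density steady-state constant as the
#' monovalent affinity.
#'
#' @param kinetic_data Sensorgram tibble for the kinetic fit, or `NULL` to
#'   generate the default synthetic series (bivalent truth, twofold
#'   0.11-7.1 uM, noise sd 2 RU).
#' @param steady_data Sensorgram tibble for the steady-state analysis, or
#'   `NULL` to generate a low-density synthetic series over 0.11-57 uM.
#' @param seed Seed for the synthetic inputs.
#' @param mw Analyte molecular weight (Da).
#' @param n_starts Multi-start count for the kinetic fit.
#' @param readout_s,baseline_window_s Passed to [extract_plateau()].
#' @param output_dir If non-`NULL`, writes parameter, residual, isotherm and
#'   report files there (plus a manifest).
#' @return An object of class `binding_report`: `kinetic_fit`,
#'   `isotherm_fit`, `consistency` (one-row tibble), `errors` (character),
#'   `config`.
#' @export
run_binding_analysis <- function(kinetic_data = NULL, steady_data = NULL,
                                 seed = 1, mw = 2e5, n_starts = 5,
                                 readout_s = 30, baseline_window_s = 10,
                                 output_dir = NULL) {
  errors <- character(0)
  config <- list(seed = seed, mw = mw, n_starts = n_starts,
                 readout_s = readout_s,
                 baseline_window_s = baseline_window_s,
                 version = as.character(utils::packageVersion("bindkin")))
  if (is.null(kinetic_data)) {
    kinetic_data <- gen_sensorgrams(
      lag3_bivalent_params("global", analyte_mw = mw),
      concs_M = 7.1e-6 / 2^(6:0), seed = seed, noise_sd_ru = 2,
      ligand_density_ru = 525)
  }
  if (is.null(steady_data)) {
    steady_data <- gen_sensorgrams(
      low_density_params(mw), concs_M = 57e-6 / 2^(9:0),
      seed = seed + 1, noise_sd_ru = 2, ligand_density_ru = 244)
  }
  kin <- tryCatch(
    fit_kinetics(kinetic_data, model = "bivalent", scope = "global",
                 mw = mw, n_starts = n_starts),
    error = function(e) {
      errors <<- c(errors, paste("kinetic:", conditionMessage(e))); NULL
    })
  iso <- tryCatch({
    pts <- extract_plateau(steady_data, readout_s, baseline_window_s)
    fit_one_site(pts)
  }, error = function(e) {
    errors <<- c(errors, paste("steady-state:", conditionMessage(e))); NULL
  })
  consistency <- NULL
  if (!is.null(kin) && !is.null(iso) && !is.null(kin$derived)) {
    kd1 <- kin$derived$K_D1
    consistency <- tibble::tibble(
      kd1_kinetic_M = kd1, kd_steady_M = iso$K_D,
      ratio = kd1 / iso$K_D,
      affinity_range_uM_low = min(kd1, iso$K_D) * 1e6,
      affinity_range_uM_high = max(kd1, iso$K_D) * 1e6,
      consistent = kd1 / iso$K_D >= 0.3 & kd1 / iso$K_D <= 3)
  }
  if (length(errors) > 0 && is.null(kin) && is.null(iso)) {
    stop("all pipeline stages failed: ", paste(errors, collapse = "; "))
  }
  report <- structure(
    list(kinetic_fit = kin, isotherm_fit = iso, consistency = consistency,
         errors = errors, config = config),
    class = "binding_report")
  if (!is.null(output_dir)) write_binding_report(report, output_dir)
  report
}

# low-density surface used for the default synthetic steady-state series:
# the published rates with R_max set to the low immobilization level, where
# second-site engagement is minimal and 30 s injections reach steady state
low_density_params <- function(mw) {
  p <- lag3_bivalent_params("global", analyte_mw = mw)
  bivalent_params(p$k_on1, p$k_off1, p$k_on2_ru, p$k_off2,
                  r_max = 244, ri = p$ri, analyte_mw = mw)
}

write_binding_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name, writer) {
    p <- file.path(output_dir, name)
    writer(obj, p)
    files <<- c(files, name)
  }
  if (!is.null(report$kinetic_fit)) {
    emit(tidy(report$kinetic_fit), "kinetic_parameters.csv", readr::write_csv)
    emit(augment(report$kinetic_fit), "kinetic_residuals.csv",
         readr::write_csv)
  }
  if (!is.null(report$isotherm_fit)) {
    emit(glance(report$isotherm_fit), "isotherm_fit.csv", readr::write_csv)
  }
  if (!is.null(report$consistency)) {
    emit(report$consistency, "consistency.csv", readr::write_csv)
  }
  rep_path <- file.path(output_dir, "report.txt")
  lines <- c(
    "bindkin binding analysis report",
    paste0("version = ", report$config$version),
    paste0("seed = ", report$config$seed),
    paste0("analyte_mw_da = ", report$config$mw),
    if (!is.null(report$kinetic_fit)) {
      g <- glance(report$kinetic_fit)
      sprintf("kinetic: model=%s scope=%s chisq=%.6g ssr=%.6g K_D1=%.6g M",
              g$model, g$scope, g$chisq, g$ssr,
              if ("K_D1" %in% names(g)) g$K_D1 else NA)
    },
    if (!is.null(report$isotherm_fit)) {
      sprintf("steady-state: K_D=%.6g M B_max=%.6g RU",
              report$isotherm_fit$K_D, report$isotherm_fit$B_max)
    },
    if (!is.null(report$consistency)) {
      sprintf("consistency: ratio=%.4g consistent=%s",
              report$consistency$ratio, report$consistency$consistent)
    },
    if (length(report$errors) > 0) paste("error:", report$errors))
  writeLines(lines, rep_path)
  files <- c(files, "report.txt")
  writeLines(files, file.path(output_dir, "manifest.txt"))
  invisible(output_dir)
}

#' @export
print.binding_report <- function(x, ...) {
  cat("<binding_report>\n")
  if (!is.null(x$kinetic_fit)) {
    g <- glance(x$kinetic_fit)
    cat(sprintf("  kinetic %s/%s fit: chisq=%.4g", g$model, g$scope, g$chisq))
    if ("K_D1" %in% names(g)) {
      cat(sprintf(", K_D1=%.3g uM", g$K_D1 * 1e6))
    }
    cat("\n")
  }
  if (!is.null(x$isotherm_fit)) {
    cat(sprintf("  steady-state: K_D=%.3g uM\n", x$isotherm_fit$K_D * 1e6))
  }
  if (!is.null(x$consistency)) {
    cat(sprintf("  kinetic/steady-state K_D ratio = %.3g (consistent: %s)\n",
                x$consistency$ratio, x$consistency$consistent))
  }
  if (length(x$errors) > 0) cat("  errors:", x$errors, sep = "\n    ")
  invisible(x)
}
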