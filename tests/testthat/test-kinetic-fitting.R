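test_that("goodness-of-fit chi-square matches hand arithmetic and brute force", {
  expect_equal(gof_chisq(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(gof_chisq(c(4, 9), c(2, 10)), 2.1)
  expect_error(gof_chisq(numeric(0), numeric(0)), "empty-input")
  expect_error(gof_chisq(1:3, 1:2), "mismatched-data")
  set.seed(42)
  obs <- stats::runif(100, 0, 500)
  exp_ <- stats::runif(100, 0, 500)
  brute <- 0
  for (i in seq_len(100)) {
    brute <- brute + (obs[i] - exp_[i])^2 / max(exp_[i], 1)
  }
  expect_equal(gof_chisq(obs, exp_), brute)
})

test_that("derived equilibrium constants reproduce the published values", {
  # local fit rates: K_D1 = k_off1/k_on1 = 6.06e-6 M at 3 s.f.
  loc <- kinetic_constants(ref_local())
  expect_equal(signif(loc$K_D1, 3), 6.06e-6)
  expect_equal(signif(loc$K_D2, 3), 2.75e-5)
  expect_equal(signif(loc$k_on2_molar, 4), 156.6)
  glo <- kinetic_constants(ref_global())
  expect_equal(signif(glo$K_D1, 3), 7.28e-6)
  expect_equal(signif(glo$K_D2, 3), 4.23e-5)
  expect_equal(signif(glo$k_on2_molar, 3), 96.9)
  # identity case and missing-MW error
  expect_equal(kinetic_constants(
    bivalent_params(1, 1, 1e-6, 1e-3, 100, analyte_mw = 1))$K_D1, 1)
  expect_error(kinetic_constants(bivalent_params(1, 1, 1e-6, 1e-3, 100)),
               "molecular weight")
})

test_that("K_D2 is invariant to the assumed analyte molecular weight", {
  k1 <- kinetic_constants(lag3_bivalent_params("global", analyte_mw = 1e5))
  k2 <- kinetic_constants(lag3_bivalent_params("global", analyte_mw = 3e5))
  expect_equal(k1$K_D2, k2$K_D2)
  expect_equal(k1$K_D1, k2$K_D1)
})

test_that("noise-free global bivalent fit recovers generating parameters within 1%", {
  truth <- ref_global()
  sg <- gen_sensorgrams(truth, concs_M = kinetic_concs(), seed = 1,
                        noise_sd_ru = 0)
  fit <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5,
                      n_starts = 1)
  est <- setNames(fit$params$estimate, fit$params$term)
  for (nm in c("k_on1", "k_off1", "k_on2_ru", "k_off2", "r_max")) {
    expect_lt(abs(est[[nm]] / truth[[nm]] - 1), 0.01, label = nm)
  }
  expect_true(fit$converged)
  # derived constants satisfy their identities to machine precision
  expect_equal(fit$derived$K_D1 * est[["k_on1"]], est[["k_off1"]])
})

test_that("1:1 data are recovered by the 1:1 model; bivalent fit collapses k_on2", {
  truth <- one_to_one_params(8e4, 0.3, 700, ri = 8)
  sg <- gen_sensorgrams(truth, concs_M = kinetic_concs(5), seed = 3,
                        noise_sd_ru = 0)
  fit1 <- fit_kinetics(sg, model = "one_to_one", scope = "global",
                       n_starts = 1)
  est <- setNames(fit1$params$estimate, fit1$params$term)
  expect_lt(abs(est[["k_on"]] / truth$k_on - 1), 0.01)
  expect_lt(abs(est[["k_off"]] / truth$k_off - 1), 0.01)
  fit2 <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5,
                       n_starts = 1)
  est2 <- setNames(fit2$params$estimate, fit2$params$term)
  # second site contributes nothing: its on-rate collapses towards zero
  # relative to the generating scale of real bivalent surfaces (~1e-6)
  expect_lt(est2[["k_on2_ru"]] * est2[["r_max"]] / est2[["k_off2"]], 0.05)
})

test_that("local fit at a single concentration mirrors the published layout", {
  truth <- ref_local()
  sg <- gen_sensorgrams(truth, concs_M = 7.1e-6, seed = 5, noise_sd_ru = 0)
  fit <- fit_kinetics(sg, model = "bivalent", scope = "local", mw = 2e5,
                      n_starts = 1)
  expect_equal(fit$scope, "local")
  expect_equal(fit$n_cycles, 1)
  expect_length(fit$ri, 1)
  expect_equal(unname(fit$concentration_range), c(7.1e-6, 7.1e-6))
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(abs(est[["k_on1"]] / truth$k_on1 - 1), 0.01)
  expect_lt(abs(fit$derived$K_D1 / 6.06e-6 - 1), 0.02)
  # local scope rejects multi-cycle input
  sg2 <- gen_sensorgrams(truth, concs_M = c(1e-6, 7.1e-6), seed = 5,
                         noise_sd_ru = 0)
  expect_error(fit_kinetics(sg2, scope = "local"), "exactly one")
})

test_that("global and local fits agree on K_D1 within 25% on synthetic data", {
  truth <- ref_global()
  sg <- gen_sensorgrams(truth, concs_M = kinetic_concs(), seed = 7,
                        noise_sd_ru = 2)
  glob <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5,
                       n_starts = 1)
  # single-cycle fit at the top concentration, the published local design
  top <- sg[sg$cycle_id == "cycle_07", ] # 7.1 uM
  loc <- fit_kinetics(top, model = "bivalent", scope = "local", mw = 2e5)
  expect_lt(abs(loc$derived$K_D1 / glob$derived$K_D1 - 1), 0.25)
})

test_that("fits are deterministic: identical inputs give bit-identical output", {
  sg <- gen_sensorgrams(ref_global(), concs_M = kinetic_concs(3), seed = 11,
                        noise_sd_ru = 2)
  f1 <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5,
                     n_starts = 2)
  f2 <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5,
                     n_starts = 2)
  expect_identical(f1$params$estimate, f2$params$estimate)
  expect_identical(f1$chisq, f2$chisq)
})

test_that("under-determined phases and unknown concentrations are refused", {
  sg <- gen_sensorgrams(ref_global(), concs_M = 7.1e-6, seed = 1,
                        noise_sd_ru = 0,
                        protocol_template = injection_protocol(
                          1e-6, association_s = 30, dissociation_s = 300,
                          interval_s = 10, baseline_s = 30))
  short <- sg[sg$phase != "dissociation" | sg$time_s <= 60, ]
  expect_error(fit_kinetics(short, n_starts = 1), "under-determined")
  sg2 <- gen_sensorgrams(ref_global(), concs_M = 7.1e-6, seed = 1,
                         noise_sd_ru = 0)
  sg2$conc_M <- NA_real_
  expect_error(fit_kinetics(sg2, n_starts = 1), "concentrations")
})

test_that("model comparison ranks the generating model first", {
  truth <- ref_global()
  sg <- gen_sensorgrams(truth, concs_M = kinetic_concs(5), seed = 13,
                        noise_sd_ru = 2)
  fb <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5,
                     n_starts = 1)
  f1 <- fit_kinetics(sg, model = "one_to_one", scope = "global", n_starts = 1)
  cmp <- compare_models(fb, f1)
  expect_equal(cmp$model[1], "bivalent")
  expect_true(all(c("chisq", "ssr", "resid_lag1") %in% names(cmp)))
  expect_false(attr(cmp, "comparable"))
  # identical fits tie and are reported as comparable
  cmp2 <- compare_models(fb, fb)
  expect_equal(cmp2$chisq[1], cmp2$chisq[2])
  expect_true(attr(cmp2, "comparable"))
  # mismatched data refused
  sg_other <- gen_sensorgrams(truth, concs_M = kinetic_concs(4), seed = 14,
                              noise_sd_ru = 2)
  f_other <- fit_kinetics(sg_other, model = "bivalent", scope = "global",
                          mw = 2e5, n_starts = 1)
  expect_error(compare_models(fb, f_other), "mismatched-data")
})

test_that("1:1-generated data leave the models statistically comparable", {
  truth <- one_to_one_params(8e4, 0.3, 700, ri = 8)
  sg <- gen_sensorgrams(truth, concs_M = kinetic_concs(5), seed = 17,
                        noise_sd_ru = 2)
  f1 <- fit_kinetics(sg, model = "one_to_one", scope = "global", n_starts = 1)
  fb <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5,
                     n_starts = 1)
  cmp <- compare_models(f1, fb)
  expect_true(attr(cmp, "comparable"))
})

test_that("tidy, glance and augment expose the fit consistently", {
  sg <- gen_sensorgrams(ref_global(), concs_M = kinetic_concs(3), seed = 19,
                        noise_sd_ru = 2)
  fit <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5,
                      n_starts = 1)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(nrow(td), 5 + 3) # five shared parameters + one RI per cycle
  gl <- glance(fit)
  expect_equal(gl$n_obs, fit$n_obs)
  aug <- augment(fit)
  expect_equal(nrow(aug), fit$n_obs)
  expect_equal(aug$observed_ru - aug$fitted_ru, aug$residual_ru)
  expect_equal(sum(aug$residual_ru^2), fit$ssr)
})
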