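test_that("parameter and protocol constructors enforce invariants", {
  expect_error(one_to_one_params(-1, 0.5, 100), "invalid-parameter")
  expect_error(one_to_one_params(1e5, 0, 100), "invalid-parameter")
  expect_error(bivalent_params(0, 1, 1e-6, 1e-3, 100), "invalid-parameter")
  expect_error(bivalent_params(1e5, 0.5, -1, 1e-3, 100), "invalid-parameter")
  expect_error(injection_protocol(-1e-6), "invalid-parameter")
  expect_error(injection_protocol(1e-6, interval_s = 60), "invalid-parameter")
  # zero second-site rates are the 1:1 degenerate limit, not an error
  expect_s3_class(bivalent_params(1e5, 0.5, 0, 0, 100), "bivalent_params")
})

test_that("1:1 closed form: no analyte gives bulk shift only", {
  p <- one_to_one_params(1e5, 0.5, 1000, ri = 12)
  sg <- simulate_one_to_one(p, injection_protocol(0, association_s = 20))
  expect_equal(unique(sg$response_ru[sg$phase == "baseline"]), 0)
  expect_equal(unique(sg$response_ru[sg$phase == "association"]), 12)
  expect_equal(unique(sg$response_ru[sg$phase == "dissociation"]), 0)
})

test_that("1:1 closed form approaches R_max + RI in the irreversible limit", {
  p <- one_to_one_params(1e6, 1e-9, 800, ri = 5)
  sg <- simulate_one_to_one(p, injection_protocol(1e-4, association_s = 600,
                                                  dissociation_s = 10))
  plateau <- max(sg$response_ru)
  expect_equal(plateau, 800 + 5, tolerance = 1e-6)
})

test_that("1:1 closed form matches formula and an independent ODE oracle", {
  k_on <- 1e5; k_off <- 0.5; r_max <- 1000; C <- 5e-6
  p <- one_to_one_params(k_on, k_off, r_max)
  sg <- simulate_one_to_one(p, injection_protocol(C))
  r30 <- sg$response_ru[sg$phase == "association" & sg$time_s == 30]
  kd <- k_off / k_on
  expect_equal(r30, r_max * C / (C + kd) * (1 - exp(-(k_on * C + k_off) * 30)),
               tolerance = 1e-12)
  # full association trace against direct numerical integration
  t_assoc <- sg$time_s[sg$phase == "association"]
  oracle <- ode_one_to_one_oracle(k_on, k_off, r_max, C, t_assoc)
  expect_equal(sg$response_ru[sg$phase == "association"], unname(oracle),
               tolerance = 1e-7)
})

test_that("bivalent simulator reduces to the 1:1 closed form", {
  for (C in c(0.5e-6, 5e-6, 50e-6)) {
    pb <- bivalent_params(1e5, 0.5, 0, 0, 1000, ri = 5)
    p1 <- one_to_one_params(1e5, 0.5, 1000, ri = 5)
    proto <- injection_protocol(C)
    sb <- simulate_bivalent(pb, proto)
    s1 <- simulate_one_to_one(p1, proto)
    expect_lt(max(abs(sb$response_ru - s1$response_ru)), 1e-6 * 1000)
  }
})

test_that("bivalent trajectories conserve ligand and stay admissible", {
  p <- ref_global()
  proto <- injection_protocol(7.1e-6)
  grid <- bindkin:::protocol_grid(proto)
  ia <- grid$phase == "association"; id <- grid$phase == "dissociation"
  bnd <- bindkin:::bivalent_bound_series(p, c(7.1e-6, 0.5e-6),
                                         grid$time_s[ia], grid$time_s[id])
  all_bound <- rbind(bnd$assoc, bnd$dissoc)
  expect_true(all(all_bound >= -1e-9))
  expect_true(all(all_bound <= p$r_max + 1e-6))
})

test_that("association response is non-decreasing in concentration", {
  p <- ref_global()
  concs <- kinetic_concs()
  at30 <- vapply(concs, function(C) {
    sg <- simulate_bivalent(p, injection_protocol(C))
    sg$response_ru[sg$phase == "association" & sg$time_s == 30]
  }, numeric(1))
  expect_true(all(diff(at30) > 0))
})

test_that("higher ligand density prolongs bivalent dissociation", {
  p0 <- ref_global()
  frac60 <- vapply(c(244, 525, 1000), function(rmax) {
    p <- bivalent_params(p0$k_on1, p0$k_off1, p0$k_on2_ru, p0$k_off2,
                         r_max = rmax, ri = 0, analyte_mw = p0$analyte_mw)
    sg <- simulate_bivalent(p, injection_protocol(7.1e-6))
    diss <- sg[sg$phase == "dissociation", ]
    r0 <- diss$response_ru[1]
    diss$response_ru[diss$time_s == 90] / r0  # 60 s into dissociation
  }, numeric(1))
  expect_true(all(diff(frac60) >= 0))
})

test_that("long-time ODE plateau matches the algebraic equilibrium", {
  p <- ref_global()
  # frozen oracle: long-time integration of the scheme at 7.1 uM gave
  # 566.3329 RU for this parameter set (computed independently pre-build)
  expect_equal(equilibrium_response_bivalent(p, 7.1e-6), 566.3329,
               tolerance = 1e-6)
  for (C in c(0.5e-6, 7.1e-6, 30e-6)) {
    long <- injection_protocol(C, association_s = 20000, dissociation_s = 1,
                               interval_s = 20)
    sg <- simulate_bivalent(p, long)
    plateau <- max(sg$response_ru[sg$phase == "association"]) - p$ri
    expect_lt(abs(plateau - equilibrium_response_bivalent(p, C)), 0.1)
  }
})

test_that("equilibrium response handles degenerate inputs", {
  p <- ref_global()
  expect_equal(equilibrium_response_bivalent(p, 0), 0)
  # k_on2 = 0 reduces to the Langmuir isotherm
  p1 <- bivalent_params(1e5, 0.5, 0, 0, 1000)
  C <- 5e-6; kd <- 0.5 / 1e5
  expect_equal(equilibrium_response_bivalent(p1, C), 1000 * C / (C + kd),
               tolerance = 1e-12)
  expect_error(equilibrium_response_bivalent(p, -1e-6), "invalid-parameter")
})

test_that("published local parameters give fast association and dissociation", {
  p <- ref_local()
  sg <- simulate_bivalent(p, injection_protocol(7.1e-6))
  assoc <- sg[sg$phase == "association", ]
  # most of the final association response develops within seconds
  r_end <- assoc$response_ru[nrow(assoc)]
  expect_gt(assoc$response_ru[assoc$time_s == 5], 0.8 * r_end)
  # dissociation is predominantly fast: most bound material gone in seconds
  diss <- sg[sg$phase == "dissociation", ]
  r0 <- diss$response_ru[1]
  expect_lt(diss$response_ru[diss$time_s == 40] / r0, 0.35)
})

test_that("alternative site-occupancy bookkeeping is exposed and consistent", {
  p <- ref_global()
  sg1 <- simulate_bivalent(p, injection_protocol(7.1e-6), occupancy = 1)
  sg2 <- simulate_bivalent(p, injection_protocol(7.1e-6), occupancy = 2)
  # doubling site consumption cannot increase the bound response
  expect_true(all(sg2$response_ru <= sg1$response_ru + 1e-9))
  # and each occupancy's ODE plateau matches its own algebraic fixed point
  long <- injection_protocol(7.1e-6, association_s = 20000,
                             dissociation_s = 1, interval_s = 20)
  sg2l <- simulate_bivalent(p, long, occupancy = 2)
  plateau <- max(sg2l$response_ru[sg2l$phase == "association"]) - p$ri
  expect_lt(abs(plateau - equilibrium_response_bivalent(p, 7.1e-6,
                                                        occupancy = 2)), 0.1)
})
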