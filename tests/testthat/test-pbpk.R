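phys <- itm_physiology()

test_that("derivatives vanish with no drug and balance without elimination", {
  cmpd <- make_compound()
  expect_equal(unname(pbpk_derivatives(numeric(9), cmpd, phys)), numeric(9))

  # no elimination: the rate components must sum to zero at any state
  cons <- make_compound(Vmax_met = 0, Vmax_targetMet = 0, CLr = 0)
  set.seed(7)
  for (i in 1:20) {
    st <- stats::runif(9, 0, 2)
    st[9] <- stats::runif(1, 0, cons$X_TotalR)
    expect_equal(sum(pbpk_derivatives(st, cons, phys)), 0, tolerance = 1e-12)
  }
})

test_that("a fully bound receptor with no free drug relaxes by pure dissociation", {
  cmpd <- make_compound()
  st <- numeric(9)
  st[9] <- cmpd$X_TotalR
  d <- pbpk_derivatives(st, cmpd, phys)
  expect_equal(unname(d["receptor_complex"]), -cmpd$koff * cmpd$X_TotalR)
})

test_that("derivatives reject invalid states", {
  cmpd <- make_compound()
  expect_error(pbpk_derivatives(rep(NaN, 9), cmpd, phys), "integration failure")
  expect_error(pbpk_derivatives(c(-1, numeric(8)), cmpd, phys),
               "integration failure")
  expect_error(pbpk_derivatives(numeric(5), cmpd, phys), "length 9")
})

test_that("compiled and R right-hand sides produce identical trajectories", {
  cmpd <- make_compound()
  doses <- list(dose_event(0, 5, "iv_blood"), dose_event(6, 5, "iv_blood"))
  s_c <- simulate_pbpk(cmpd, phys, doses, duration = 12)
  s_r <- simulate_pbpk(cmpd, phys, doses, duration = 12, compiled = FALSE)
  expect_equal(s_c$amounts, s_r$amounts, tolerance = 1e-6)
})

test_that("no doses means identically zero trajectories", {
  sim <- simulate_pbpk(make_compound(), phys, doses = list())
  expect_true(all(sim$amounts == 0))
  expect_equal(sim$avg_ro, 0)
})

test_that("total drug is conserved without elimination over 240 h", {
  cons <- make_compound(Vmax_met = 0, Vmax_targetMet = 0, CLr = 0)
  sim <- simulate_pbpk(cons, phys, list(dose_event(0, 1, "iv_blood")),
                       duration = 240)
  total <- rowSums(sim$amounts)
  expect_true(max(abs(total - 1)) < 10 * 1e-8)
})

test_that("zeroing tissue exchange collapses to one-compartment IV kinetics", {
  oc <- make_compound(Vmax_uptake = 0, Vmax_met = 0, PSdif_inf = 0,
                      Vmax_targetUptake = 0, Vmax_targetMet = 0,
                      PSdiff_target = 0, CLr = 3)
  sim <- simulate_pbpk(oc, no_flow_physiology(), list(dose_event(0, 1, "iv_blood")),
                       duration = 24)
  pred <- exp(-oc$CLr * sim$times / no_flow_physiology()$Vb)
  expect_true(max(abs(sim$amounts[, "blood"] - pred) / pred) < 1e-3)
  expect_true(all(sim$amounts[, setdiff(colnames(sim$amounts), "blood")] == 0))
})

test_that("linear-regime infusion reaches blood conc = rate / CL_total", {
  cmpd <- make_compound()
  rate <- 1e-4  # umol/h, far below all Km * V scales
  sim <- simulate_pbpk(cmpd, phys, infusion_rate = rate,
                       infusion_window = c(0, 1e4), duration = 2000, dt = 1)
  cb <- utils::tail(sim$amounts[, "blood"], 1) / phys$Vb
  pred <- rate / linear_clearances(cmpd, phys)$CL_total
  expect_lt(abs(cb - pred) / pred, 0.02)
})

test_that("states stay non-negative and occupancy bounded for random compounds", {
  cmpds <- sampled_compounds(1000, seed = 303)
  worst_neg <- 0
  ok <- TRUE
  for (cm in cmpds) {
    sim <- simulate_pbpk(cm, phys, list(dose_event(0, 10, "iv_blood")),
                         duration = 24, dt = 0.5)
    if (inherits(sim, "itm_sim_failure")) next
    worst_neg <- min(worst_neg, min(sim$amounts))
    if (any(sim$amounts[, "receptor_complex"] > cm$X_TotalR * (1 + 1e-6))) {
      ok <- FALSE
    }
  }
  expect_gt(worst_neg, -1e-9)
  expect_true(ok)
})

test_that("average occupancy is the windowed trapezoidal mean", {
  tt <- seq(0, 48, by = 0.05)
  expect_equal(average_ro(list(times = tt, ro = rep(0, length(tt)))), 0)
  expect_equal(average_ro(list(times = tt, ro = rep(0.6, length(tt)))), 0.6)
  # linear ramp: mean over [0, 24] of t/48 is 0.25
  expect_equal(average_ro(list(times = tt, ro = tt / 48), c(0, 24)), 0.25,
               tolerance = 1e-10)
  expect_error(average_ro(list(times = tt, ro = tt), c(10, 10)), "increasing")
  expect_error(average_ro(list(times = tt, ro = tt), c(0, 100)), "span")
})

test_that("occupancy at a clamped free concentration C = Kd settles at 1/2", {
  # independent oracle: binding subsystem dRC/dt = kon*C*(R-RC) - koff*RC at
  # constant C has the closed form RC(t) = Req * (1 - exp(-(kon*C+koff) t))
  Kd <- 0.002; koff <- 0.5; kon <- koff / Kd; C <- Kd; R <- 0.01
  k_obs <- kon * C + koff
  tt <- seq(0, 24, by = 0.05)
  ro <- (C / (C + Kd)) * (1 - exp(-k_obs * tt))
  # after t >> 1/koff the windowed average sits at the equilibrium value
  avg <- average_ro(list(times = tt, ro = ro), c(20, 24))
  expect_lt(abs(avg - 0.5), 0.005)
})

test_that("hepatic clearance obeys the flow-limited and restrictive limits", {
  # flow-limited: enormous intrinsic clearance drives CLh toward Qh
  fast <- make_compound(Vmax_uptake = 1e9, Vmax_met = 1e9, fub = 1)
  expect_equal(linear_clearances(fast, phys)$CLh, phys$Qh,
               tolerance = 1e-4)
  # no metabolism: nothing is eliminated in the liver
  none <- make_compound(Vmax_met = 0)
  expect_equal(linear_clearances(none, phys)$CLh, 0)
  # restrictive: fub*CLint << Qh means CLh ~ fub*CLint within 1 %
  slow <- make_compound(Vmax_uptake = 0.1, Km_uptake = 10, Vmax_met = 0.1,
                        Km_met = 10, PSdif_inf = 1, fub = 0.01)
  CLmet <- 0.1 / 10
  CLint <- (0.1 / 10 + 1) * CLmet / (1 + CLmet)
  cl <- linear_clearances(slow, phys)
  expect_lt(abs(cl$CLh - 0.01 * CLint) / (0.01 * CLint), 0.01)
  expect_equal(cl$CL_total, cl$CLh + slow$CLr + cl$CL_target)
})

test_that("average occupancy is monotone in dose", {
  for (cm in sampled_compounds(8, seed = 99)) {
    ro <- vapply(c(1, 2, 4), function(d) {
      sim <- simulate_pbpk(cm, phys, list(dose_event(0, d, "iv_blood")))
      if (inherits(sim, "itm_sim_failure")) return(NA_real_)
      sim$avg_ro
    }, numeric(1))
    ro <- ro[!is.na(ro)]
    if (length(ro) > 1) expect_true(all(diff(ro) >= -1e-9))
  }
})

test_that("simulations export as tidy long tables", {
  sim <- simulate_pbpk(make_compound(), phys, list(dose_event(0, 1, "iv_blood")),
                       duration = 2, dt = 0.5)
  tidy <- sim_as_tidy(sim)
  expect_equal(nrow(tidy), length(sim$times) * 9)
  expect_named(tidy, c("time", "compartment", "amount", "ro"))
})
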