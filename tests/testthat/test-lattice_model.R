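test_that("lattice discretization floors to 8 nm sites and clips at 1", {
  expect_equal(build_lattice(2400, 8)$n_sites, 300L)
  expect_equal(build_lattice(666.7, 8)$n_sites, 83L)
  expect_equal(build_lattice(4, 8)$n_sites, 1L)
  expect_error(build_lattice(0), "length")
  expect_error(build_lattice(100, -1), "site_size")
})

test_that("free concentration obeys conservation of matter", {
  p <- model_parameters(kip2_total = 35, volume = 1)
  expect_equal(free_concentration(p, 0), 35)
  # far more bound motors than the pool holds: floored at zero
  expect_equal(free_concentration(p, 1e6), 0)
  # 602 molecules in 1 fL is ~1000 nM, which empties a 35 nM pool
  expect_equal(free_concentration(p, 602), 0)
  # independent arithmetic oracle: c = total - n/(N_A * V), V = 1000 fL
  p2 <- model_parameters(kip2_total = 35, volume = 1000)
  oracle <- 35 - 602 / (6.02214076e23 * 1000e-15 * 1e-9)
  expect_equal(free_concentration(p2, 602), oracle, tolerance = 1e-12)
  expect_true(free_concentration(p2, 602) > 33.9 &&
                free_concentration(p2, 602) < 34.1)
  # unlimited pool ignores binding
  p3 <- model_parameters(kip2_total = 35, finite_pool = FALSE)
  expect_equal(free_concentration(p3, 500), 35)
  expect_error(model_parameters(volume = 0), "volume")
  expect_error(free_concentration(p, -1), "n_bound")
})

test_that("exact stationary solver reproduces closed forms", {
  # no entry paths: the empty lattice is stationary
  p0 <- toy_params(k_in = 0, k_on = 0)
  me0 <- master_equation_stationary(p0, build_lattice(32))
  expect_equal(me0$mean_occupancy, rep(0, 4))

  # single site: two-state birth-death, occupancy r_in / (r_in + k_out)
  p1 <- model_parameters(k_in = 0.7, k_on = 0, k_off = 0.2, k_out = 1.3,
                         kip2_total = 3, finite_pool = FALSE)
  me1 <- master_equation_stationary(p1, build_lattice(8))
  r_in <- 0.7 * 3
  expect_equal(me1$mean_occupancy, r_in / (r_in + 1.3), tolerance = 1e-12)

  # decoupled sites (k_step = 0, k_in = 0, k_out = k_off): independent
  # Langmuir isotherms k_on c / (k_on c + k_off)
  p3 <- model_parameters(k_in = 0, k_on = 0.05, k_off = 0.4, k_step = 0,
                         k_out = 0.4, kip2_total = 2, finite_pool = FALSE)
  me3 <- master_equation_stationary(p3, build_lattice(24))
  langmuir <- 0.05 * 2 / (0.05 * 2 + 0.4)
  expect_equal(me3$mean_occupancy, rep(langmuir, 3), tolerance = 1e-12)

  expect_error(master_equation_stationary(toy_params(), build_lattice(200)),
               "2\\^n")
})

test_that("Gillespie matches trivial limits and stays exclusive", {
  # no entry paths: identically empty trajectory
  run0 <- gillespie_simulate(toy_params(k_in = 0, k_on = 0),
                             build_lattice(32), t_end = 10,
                             record_interval = 1, seed = 3)
  expect_true(all(run0$snapshots == 0))
  expect_equal(run0$mean_occupancy, rep(0, 4))

  # snapshots are 0/1 only (hard exclusion)
  run1 <- gillespie_simulate(toy_params(), build_lattice(48), t_end = 50,
                             record_interval = 0.5, seed = 4)
  expect_true(all(run1$snapshots %in% c(0L, 1L)))

  # reproducible under a fixed seed
  run2 <- gillespie_simulate(toy_params(), build_lattice(48), t_end = 50,
                             record_interval = 0.5, seed = 4)
  expect_identical(run1$snapshots, run2$snapshots)
})

test_that("single-site Gillespie long-run mean matches the closed form", {
  p1 <- model_parameters(k_in = 0.7, k_on = 0, k_off = 0.2, k_out = 1.3,
                         kip2_total = 3, finite_pool = FALSE)
  est <- gillespie_mean_and_se(p1, build_lattice(8), t_end = 800)
  truth <- 0.7 * 3 / (0.7 * 3 + 1.3)
  expect_lt(abs(est$mean - truth), 3 * est$se)
})

test_that("Gillespie agrees with the exact master equation (oracle suite)", {
  for (n_sites in c(2L, 3L, 4L, 6L)) {
    lat <- build_lattice(n_sites * 8)
    exact <- master_equation_stationary(toy_params(), lat)$mean_occupancy
    est <- gillespie_mean_and_se(toy_params(), lat, t_end = 600,
                                 n_batches = 16, seed0 = 40 + 20 * n_sites)
    expect_true(all(abs(est$mean - exact) < 3 * pmax(est$se, 4e-3)),
                label = sprintf("n_sites = %d within 3 SE", n_sites))
  }
})

test_that("mean-field solves the stationary equations and dilute limit", {
  # Langmuir limit: k_step = 0, k_in = 0, terminal k_out = k_off
  pL <- model_parameters(k_in = 0, k_on = 0.05, k_off = 0.4, k_step = 0,
                         k_out = 0.4, kip2_total = 2, finite_pool = FALSE)
  mfL <- mean_field_steady_state(pL, build_lattice(80))
  langmuir <- 0.05 * 2 / (0.05 * 2 + 0.4)
  expect_equal(mfL$mean_occupancy, rep(langmuir, 10), tolerance = 1e-8)

  # fixed point satisfies terminal flux balance to within tol
  p <- toy_params()
  mf <- mean_field_steady_state(p, build_lattice(48), tol = 1e-10)
  rho <- mf$mean_occupancy
  L <- length(rho)
  influx <- p$k_on * p$kip2_total * (1 - rho[L]) +
    p$k_step * rho[L - 1] * (1 - rho[L])
  expect_equal(influx, p$k_out * rho[L], tolerance = 1e-8)

  # dilute limit: mean-field error vs exact oracle < 5% relative and
  # shrinking as k_on c -> 0
  errs <- sapply(c(0.008, 8e-4), function(kon) {
    pd <- model_parameters(k_in = 0.002, k_on = kon, k_off = 0.3,
                           k_step = 1.5, k_out = 0.8, kip2_total = 2,
                           finite_pool = FALSE)
    lat <- build_lattice(32)
    exact <- master_equation_stationary(pd, lat)$mean_occupancy
    approxm <- mean_field_steady_state(pd, lat)$mean_occupancy
    max(abs(approxm - exact) / exact)
  })
  expect_lt(errs[1], 0.05)
  expect_lt(errs[2], errs[1])
})

test_that("raising the plus-end detachment rate empties the tip", {
  tip_mf <- sapply(c(0.4, 0.8, 1.6), function(k_out) {
    p <- toy_params(k_out = k_out)
    tail(mean_field_steady_state(p, build_lattice(48))$mean_occupancy, 1)
  })
  expect_true(all(diff(tip_mf) < 0))
  tip_me <- sapply(c(0.4, 0.8, 1.6), function(k_out) {
    p <- toy_params(k_out = k_out)
    tail(master_equation_stationary(p, build_lattice(48))$mean_occupancy, 1)
  })
  expect_true(all(diff(tip_me) < 0))
})

test_that("motor numbers are conserved under a finite pool", {
  p <- model_parameters(kip2_total = 5, volume = 1, k_out = 0.5)
  run <- gillespie_simulate(p, build_lattice(160), t_end = 60, seed = 11)
  expect_equal(run$c_free,
               free_concentration(p, run$n_bound), tolerance = 1e-12)
  expect_true(run$c_free >= 0 && run$c_free <= p$kip2_total)
})

test_that("mean plus-end residence time is 1/k_out when unobstructed", {
  # sparse traffic: rare entry, no landing, fast stepping, so the tip is
  # almost always reachable and departures are exponential with rate k_out
  p <- model_parameters(k_in = 0.02, k_on = 0, k_off = 0, k_step = 50,
                        k_out = 2, kip2_total = 1, finite_pool = FALSE)
  run <- gillespie_simulate(p, build_lattice(80), t_end = 4000, seed = 5,
                            log_events = TRUE)
  res <- tip_residence_times(run)
  expect_gt(length(res), 30)
  expect_lt(abs(mean(res) - 1 / 2), 3 * sd(res) / sqrt(length(res)))
})

test_that("kymograph has the acquisition shape and spans 80 frames", {
  p <- ref_params()
  ky <- simulate_kymograph(p, build_lattice(1600), n_frames = 80,
                           frame_interval = 1.07, seed = 2)
  expect_equal(dim(ky), c(80L, 200L))
  run <- attr(ky, "run")
  expect_equal(max(run$record_times), 79 * 1.07, tolerance = 1e-9)
  expect_equal(79 * 1.07, 84.53)
  ky0 <- simulate_kymograph(model_parameters(k_in = 0, k_on = 0),
                            build_lattice(400), n_frames = 10, seed = 1)
  expect_true(all(ky0 == 0))
})
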