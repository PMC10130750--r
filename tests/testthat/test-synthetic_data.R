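test_that("profile generator is deterministic and exact without noise", {
  cfg0 <- profile_generator_config(n_cells = 1, noise_sd = 0, scale_cv = 0,
                                   seed = 5)
  gen0 <- generate_profiles(cfg0)
  p <- gen0$profiles[[1]]
  # the noiseless emitted profile equals the deterministic forward map
  # (up to the margin padding and the background offset)
  mf <- mean_field_steady_state(cfg0$params,
                                build_lattice(gen0$truth$lengths_nm[1]))
  clean <- occupancy_to_profile(mf)
  m <- cfg0$margin_px
  core <- p$gfp_au[(m + 1):(nrow(p) - m)] - cfg0$background
  expect_equal(core, clean$gfp_au, tolerance = 1e-12)

  # same seed twice: identical outputs (files byte-identical)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- profile_generator_config(n_cells = 3, seed = 9)
  generate_profiles(cfg, dir = d1)
  generate_profiles(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = sprintf("%s deterministic", f))
  }
})

test_that("many noisy cells average back to the noiseless forward map", {
  cfg <- profile_generator_config(n_cells = 400, seed = 21)
  gen <- generate_profiles(cfg)
  ds <- bin_by_length(lapply(gen$profiles, align_to_reference_peak))
  # pick the best-populated canonical bin and compare its mean profile
  # with the forward map at the bin's member lengths (law of large numbers)
  sizes <- vapply(ds$bins, `[[`, numeric(1), "n_profiles")
  b <- ds$bins[[which.max(sizes)]]
  pxs <- round(b$summary$position_nm / 133.35)
  ld <- kip2traffic:::.likelihood_data(ds)
  fp <- kip2traffic:::.forward_predict(ld, cfg$params, 1e-10, 20000L)
  z <- (fp$obs - (fp$pred + cfg$background)) / fp$sem
  # almost all standardized residuals within 3 SEM, none absurd
  expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("track generator arithmetic and reflection at zero", {
  # no switching, no noise, growth 1 um/min from 0:
  # length at frame 80 is 79 * 1.07 s / 60 = 1.40855 um
  cfg <- track_generator_config(growth_speed = 1, catastrophe_rate = 0,
                                noise_sd_nm = 0, start_length_um = 0,
                                n_tracks = 1, seed = 2)
  gen <- generate_tracks(cfg)
  lens <- length_series(gen$tracks[[1]])
  expect_equal(lens[80], 79 * 1.07 / 60, tolerance = 1e-9)
  expect_equal(lens[1], 0, tolerance = 1e-9)

  # shrinkage-only from zero length stays at the reflecting floor
  cfg0 <- track_generator_config(growth_speed = 0, catastrophe_rate = 0,
                                 noise_sd_nm = 0, start_length_um = 0,
                                 n_tracks = 1, seed = 3)
  lens0 <- length_series(generate_tracks(cfg0)$tracks[[1]])
  expect_true(all(lens0 < 1e-9))

  # determinism under seed
  cfgd <- track_generator_config(n_tracks = 2, seed = 11)
  g1 <- generate_tracks(cfgd); g2 <- generate_tracks(cfgd)
  expect_identical(g1$tracks[[2]]$plus_end, g2$tracks[[2]]$plus_end)
  expect_identical(g1$truth, g2$truth)
})

test_that("switch counts are Poisson-consistent with the programmed rate", {
  f_star <- 2.0 # catastrophes per minute of growth
  cfg <- track_generator_config(catastrophe_rate = f_star,
                                rescue_rate = 2.5, noise_sd_nm = 0,
                                start_length_um = 2.0, n_tracks = 300,
                                seed = 14)
  gen <- generate_tracks(cfg)
  n_cat <- sum(vapply(gen$truth$tracks, function(t)
    sum(t$switch_kind == "catastrophe"), numeric(1)))
  # total growth time from the truth switch records
  g_time <- sum(vapply(seq_along(gen$truth$tracks), function(i) {
    t <- gen$truth$tracks[[i]]
    # growth spans: track starts growing; catastrophes end growth spells
    sw <- c(t$switch_times_s, (cfg$n_frames - 1) * cfg$frame_interval_s)
    kinds <- c(t$switch_kind, "end")
    state <- "growth"; t0 <- 0; g <- 0
    for (j in seq_along(sw)) {
      if (state == "growth") g <- g + sw[j] - t0
      t0 <- sw[j]
      if (kinds[j] == "catastrophe") state <- "shrinkage"
      if (kinds[j] == "rescue") state <- "growth"
    }
    g
  }, numeric(1)))
  rate_hat <- n_cat / (g_time / 60)
  p_val <- stats::poisson.test(n_cat, g_time / 60 * f_star)$p.value
  expect_gt(p_val, 0.01)
  expect_equal(rate_hat, f_star, tolerance = 0.15)
})

test_that("dynamics pipeline round-trips noiseless generated tracks", {
  cfg <- track_generator_config(noise_sd_nm = 0, n_tracks = 30,
                                start_length_um = 1.3, seed = 6)
  gen <- generate_tracks(cfg)
  for (i in seq_along(gen$tracks)) {
    lens <- length_series(gen$tracks[[i]])
    truth <- gen$truth$tracks[[i]]
    # programmed per-frame lengths recovered exactly from 3D coordinates
    expect_equal(lens, truth$lengths_um, tolerance = 1e-9)
    # detectable max length matches the sampled-truth max
    cens <- censor_below_limit(lens)
    if (any(cens$detectable))
      expect_equal(max_length_and_lifetime(cens)$max_length_um,
                   max(truth$lengths_um), tolerance = 1e-9)
  }
})

test_that("noiseless phase speeds come back exactly", {
  cfg <- track_generator_config(growth_speed = 1.8, shrink_speed = 3.2,
                                catastrophe_rate = 1.2, rescue_rate = 1.5,
                                noise_sd_nm = 0, start_length_um = 1.5,
                                n_tracks = 40, seed = 19)
  gen <- generate_tracks(cfg)
  speeds_g <- c(); speeds_s <- c()
  for (i in seq_along(gen$tracks)) {
    lens <- length_series(gen$tracks[[i]])
    if (min(lens) < 0.05) next # skip floor-touching tracks
    ph <- segment_phases(lens, gen$tracks[[i]]$times, noise_sd_um = 1e-6)
    speeds_g <- c(speeds_g, ph$speed_um_min[ph$kind == "growth"])
    speeds_s <- c(speeds_s, ph$speed_um_min[ph$kind == "shrinkage"])
  }
  # speeds are exact except for the one partial frame at each switch,
  # which biases an endpoint-based speed by at most one frame in its span
  expect_gt(length(speeds_g), 20)
  expect_equal(median(speeds_g), 1.8, tolerance = 0.06)
  if (length(speeds_s) > 5)
    expect_equal(median(speeds_s), 3.2, tolerance = 0.12)
})
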