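px <- 133.35

test_that("alignment shifts the mCherry peak to zero and is idempotent", {
  # peak already at pixel 0: alignment is the identity
  p0 <- two_peak_profile(mch_peak_px = 0, gfp_peak_px = 9)
  a0 <- align_to_reference_peak(p0)
  expect_equal(a0$position_nm, p0$position_nm)
  expect_equal(attr(a0, "profile_length_nm"), 9 * px)

  # peak at pixel 3: all positions shift by -3 pixels
  p3 <- two_peak_profile(mch_peak_px = 3, gfp_peak_px = 12)
  a3 <- align_to_reference_peak(p3)
  expect_equal(a3$position_nm, p3$position_nm - 3 * px)
  expect_equal(attr(a3, "profile_length_nm"), 9 * px)

  # known peak-to-peak distance of 1200.15 nm (9 pixels)
  expect_equal(attr(a3, "gfp_peak_nm"), 1200.15)

  # idempotence
  a3b <- align_to_reference_peak(a3)
  expect_equal(a3b$position_nm, a3$position_nm)
  expect_equal(attr(a3b, "profile_length_nm"),
               attr(a3, "profile_length_nm"))

  flat <- line_scan_profile((0:9) * px, rep(1, 10), rep(2, 10))
  expect_error(align_to_reference_peak(flat), "flat mCherry")
})

test_that("binning partitions profiles and averages with CLT-scaled CIs", {
  # a single profile of length 1.2 um falls in the [1.0668, 1.3335) um bin
  one <- align_to_reference_peak(two_peak_profile(2, 11)) # 9 px = 1.2 um
  ds1 <- bin_by_length(list(one))
  expect_length(ds1$bins, 1)
  expect_equal(ds1$bins[[1]]$edges_nm, c(4, 5) * 266.7)
  expect_equal(ds1$bins[[1]]$n_profiles, 1)
  expect_equal(ds1$bins[[1]]$summary$mean_gfp, one$gfp_au)

  # two identical profiles: zero CI half-width
  ds2 <- bin_by_length(list(one, one))
  expect_true(all(ds2$bins[[1]]$summary$ci95 == 0))

  # 100 profiles with i.i.d. Gaussian noise: CI ~ 1.96 sigma / 10
  set.seed(31)
  sigma <- 0.3
  noisy <- lapply(1:100, function(i) {
    p <- two_peak_profile(2, 11)
    p$gfp_au <- p$gfp_au + rnorm(nrow(p), sd = sigma)
    align_to_reference_peak(p)
  })
  ds3 <- bin_by_length(noisy)
  expect_equal(length(ds3$bins), 1) # the GFP spike keeps every peak at 11
  mean_ci <- mean(ds3$bins[[1]]$summary$ci95)
  expect_equal(mean_ci, 1.96 * sigma / sqrt(100), tolerance = 0.15)

  # partition: profiles of different lengths land in exactly one bin each
  mixed <- lapply(c(7, 9, 9, 14), function(g)
    align_to_reference_peak(two_peak_profile(2, 2 + g, n_px = 30)))
  dsm <- bin_by_length(mixed)
  expect_equal(sum(vapply(dsm$bins, `[[`, numeric(1), "n_profiles")), 4)
  expect_error(bin_by_length(mixed, bin_width_nm = 0), "bin_width")
  # unaligned input is refused
  expect_error(bin_by_length(list(two_peak_profile(2, 11))), "aligned")
})

test_that("occupancy-to-profile maps density, PSF mass, and is linear", {
  flat <- occupancy_profile(rep(0, 125), site_size = 8)
  prof0 <- occupancy_to_profile(flat, scale = 2, background = 0.7)
  expect_true(all(abs(prof0$gfp_au - 0.7) < 1e-12))

  # uniform occupancy: interior pixels hold background + scale*rho*(px/8)
  unif <- occupancy_profile(rep(0.3, 250), site_size = 8)
  prof1 <- occupancy_to_profile(unif, scale = 2, background = 0.5)
  interior <- prof1$gfp_au[3:(nrow(prof1) - 1)]
  expect_equal(mean(interior), 0.5 + 2 * 0.3 * 133.35 / 8,
               tolerance = 0.02)

  # delta mass at the terminal site survives PSF blurring to 1%
  delta <- occupancy_profile(c(rep(0, 249), 1), site_size = 8)
  prof2 <- occupancy_to_profile(delta, scale = 3, background = 0.1,
                                psf_sigma = 150)
  mass <- sum(prof2$gfp_au - 0.1) / 3
  expect_equal(mass, 1, tolerance = 0.01)
  # bump is centred at the tip pixel
  tip_pos <- attr(prof2, "profile_length_nm")
  expect_lt(abs(prof2$position_nm[which.max(prof2$gfp_au)] - tip_pos),
            1.5 * 133.35)

  # linearity in occupancy at fixed scale/background
  o1 <- occupancy_profile(runif(125, 0, 0.5), site_size = 8)
  o2 <- occupancy_profile(runif(125, 0, 0.5), site_size = 8)
  o12 <- occupancy_profile(o1$mean_occupancy + o2$mean_occupancy,
                           site_size = 8)
  s1 <- occupancy_to_profile(o1, background = 0)$gfp_au
  s2 <- occupancy_to_profile(o2, background = 0)$gfp_au
  s12 <- occupancy_to_profile(o12, background = 0)$gfp_au
  expect_equal(s12, s1 + s2, tolerance = 1e-12)

  expect_error(occupancy_to_profile(unif, psf_sigma = -1), "psf_sigma")
  expect_error(occupancy_to_profile(unif, scale = 0), "scale")
})

test_that("plus-end regression reproduces weighted least squares", {
  mk_bin <- function(len_um, value, sem = 1) {
    list(edges_nm = c(len_um * 1000 - 133, len_um * 1000 + 133),
         centre_nm = len_um * 1000, n_profiles = 10,
         lengths_nm = rep(len_um * 1000, 10),
         summary = data.frame(position_nm = c(0, len_um * 1000),
                              mean_gfp = c(value / 2, value),
                              sd = sem * sqrt(10), sem = sem,
                              ci95 = 1.96 * sem, n = 10))
  }
  ds <- structure(list(bins = list(mk_bin(1, 10), mk_bin(2, 20)),
                       bin_width_nm = 266.7, pixel_nm = px,
                       n_profiles = 20), class = "profile_dataset")
  reg <- plus_end_regression(ds)
  expect_equal(reg$slope, 10, tolerance = 1e-9)
  expect_equal(reg$intercept, 0, tolerance = 1e-9)

  # constant plus-end value: zero slope, intercept at the value
  ds2 <- structure(list(bins = list(mk_bin(1, 7), mk_bin(1.5, 7),
                                    mk_bin(2, 7)),
                        bin_width_nm = 266.7, pixel_nm = px,
                        n_profiles = 30), class = "profile_dataset")
  reg2 <- plus_end_regression(ds2)
  expect_equal(reg2$slope, 0, tolerance = 1e-9)
  expect_equal(reg2$intercept, 7, tolerance = 1e-9)

  ds3 <- structure(list(bins = list(mk_bin(1, 10)), bin_width_nm = 266.7,
                        pixel_nm = px, n_profiles = 10),
                   class = "profile_dataset")
  expect_error(plus_end_regression(ds3), "insufficient")
})

test_that("plus-end regression recovers a generated slope within 2 SE", {
  set.seed(77)
  s_true <- 4 # a.u. per um of microtubule length
  profiles <- lapply(1:240, function(i) {
    n_pk <- sample(7:17, 1)
    p <- two_peak_profile(2, 2 + n_pk, n_px = 26)
    p$gfp_au[2 + n_pk + 1] <- 1 + s_true * (n_pk * px / 1000) +
      rnorm(1, sd = 0.3)
    align_to_reference_peak(p)
  })
  reg <- plus_end_regression(bin_by_length(profiles))
  se <- sqrt(diag(vcov(reg$fit)))[2]
  expect_lt(abs(reg$slope - s_true), 2 * se + 0.5)
})

test_that("line-scan CSV round trip preserves data and flags bad files", {
  d <- withr::local_tempdir()
  p <- two_peak_profile(1, 8)
  f <- file.path(d, "cellA.csv")
  write_line_scan_csv(p, f)
  p2 <- read_line_scan_csv(f)
  expect_equal(p2$gfp_au, p$gfp_au)
  expect_equal(p2$position_nm, p$position_nm)
  expect_equal(attr(p2, "cell_id"), "cellA")

  bad <- file.path(d, "bad.csv")
  writeLines(c("position_nm,gfp_au", "0,1", "133,2"), bad)
  expect_error(read_line_scan_csv(bad), "mcherry_au")
  bad2 <- file.path(d, "bad2.csv")
  writeLines(c("position_nm,gfp_au,mcherry_au", "0,1,0", "133,x,0"), bad2)
  expect_error(read_line_scan_csv(bad2), "row 2")
})
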