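#' Configuration for the synthetic line-scan generator
#'
#' Defines the ground truth and noise structure of synthetic per-cell
#' line-scan profiles: true model parameters, a microtubule length
#' distribution (default uniform over 0.8-2.4 um, the span of the
#' canonical length bins), additive Gaussian pixel noise, a lognormal
#' cell-to-cell intensity scale (expression variability, mean 1), and an
#' additive background.
#'
#' @param params true [model_parameters()].
#' @param n_cells number of cells (>= 1).
#' @param length_range_um range of true microtubule lengths, um.
#' @param scale intensity per motor, a.u.
#' @param scale_cv coefficient of variation of the lognormal cell-to-cell
#'   scale factor.
#' @param background additive background, a.u.
#' @param noise_sd additive Gaussian noise per pixel, a.u.
#' @param mcherry_amplitude peak amplitude of the SPB marker channel, a.u.
#' @param psf_sigma optional Gaussian PSF sigma, nm.
#' @param pixel_size_nm pixel size, nm.
#' @param margin_px background-only pixels padded on both sides of the
#'   microtubule span.
#' @param seed integer RNG seed.
#' @return A `profile_generator_config` list.
#' @export
profile_generator_config <- function(params = model_parameters(),
                                     n_cells = 500L,
                                     length_range_um = c(0.8, 2.4),
                                     scale = 1, scale_cv = 0.2,
                                     background = 0.2, noise_sd = 0.05,
                                     mcherry_amplitude = 5,
                                     psf_sigma = 0,
                                     pixel_size_nm = 133.35,
                                     margin_px = 4L, seed = 1L) {
  stopifnot(inherits(params, "model_parameters"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (noise_sd < 0 || scale_cv < 0) stop("noise parameters must be >= 0")
  structure(list(params = params, n_cells = as.integer(n_cells),
                 length_range_um = length_range_um, scale = scale,
                 scale_cv = scale_cv, background = background,
                 noise_sd = noise_sd,
                 mcherry_amplitude = mcherry_amplitude,
                 psf_sigma = psf_sigma, pixel_size_nm = pixel_size_nm,
                 margin_px = as.integer(margin_px),
                 seed = as.integer(seed)),
            class = "profile_generator_config")
}

#' Generate synthetic line-scan profiles with known ground truth
#'
#' For each synthetic cell: draw a microtubule length, solve the mean-field
#' steady state of the true model, map it through
#' [occupancy_to_profile()], multiply by a lognormal per-cell scale, add
#' background and Gaussian pixel noise, and attach an mCherry SPB-marker
#' channel (a narrow peak at the minus-end). Positions carry a random
#' integer-pixel offset so that alignment is exercised. If `dir` is given,
#' per-cell CSVs (the dialect of [read_line_scan_csv()]) and a
#' ground-truth sidecar JSON are written; the profiles are always returned.
#'
#' @param config a [profile_generator_config()].
#' @param dir optional output directory for CSVs + sidecar.
#' @return List with `profiles` (unaligned `line_scan_profile`s) and
#'   `truth` (generating parameters, per-cell lengths and scales, seed).
#' @export
generate_profiles <- function(config, dir = NULL) {
  stopifnot(inherits(config, "profile_generator_config"))
  set.seed(config$seed)
  p <- config$params
  px <- config$pixel_size_nm
  lens_nm <- runif(config$n_cells, config$length_range_um[1] * 1000,
                   config$length_range_um[2] * 1000)
  sdlog <- sqrt(log(1 + config$scale_cv^2))
  cell_scales <- rlnorm(config$n_cells, meanlog = -sdlog^2 / 2,
                        sdlog = sdlog)
  profiles <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    prof <- NULL
    for (try in 1:5) {
      prof <- tryCatch(
        mean_field_steady_state(p, build_lattice(lens_nm[i])),
        error = function(e) NULL)
      if (!is.null(prof)) break
      warning("forward model failed; resampling length")
      lens_nm[i] <- runif(1, config$length_range_um[1] * 1000,
                          config$length_range_um[2] * 1000)
    }
    if (is.null(prof)) stop("forward model failed repeatedly")
    clean <- occupancy_to_profile(prof,
                                  scale = config$scale * cell_scales[i],
                                  background = 0,
                                  psf_sigma = config$psf_sigma,
                                  pixel_size_nm = px)
    # extend the aligned pixel grid with background-only margin pixels
    m <- config$margin_px
    kk <- c(seq(min(clean$position_nm / px) - m, by = 1, length.out = m),
            clean$position_nm / px,
            seq(max(clean$position_nm / px) + 1, by = 1, length.out = m))
    gfp <- c(rep(0, m), clean$gfp_au, rep(0, m)) + config$background
    n_px <- length(gfp)
    if (config$noise_sd > 0) gfp <- gfp + rnorm(n_px, sd = config$noise_sd)
    # SPB marker: diffraction-limited peak at the true (sub-pixel) SPB
    spb_nm <- attr(clean, "spb_offset_nm")
    mch <- config$mcherry_amplitude *
      exp(-(kk * px - spb_nm)^2 / (2 * 150^2))
    if (config$noise_sd > 0) mch <- mch + rnorm(n_px, sd = config$noise_sd)
    offset <- sample.int(10L, 1) # arbitrary scan start, integer pixels
    profiles[[i]] <- line_scan_profile((kk - min(kk) + offset) * px,
                                       gfp, mch,
                                       cell_id = sprintf("cell%04d", i))
  }
  truth <- list(params = unclass(p), lengths_nm = lens_nm,
                cell_scales = cell_scales, scale = config$scale,
                background = config$background,
                noise_sd = config$noise_sd, seed = config$seed,
                schema = "kip2traffic/profile-truth/v1")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(profiles))
      write_line_scan_csv(profiles[[i]],
                          file.path(dir, sprintf("cell%04d.csv", i)))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(profiles = profiles, truth = truth)
}

#' Configuration for the synthetic 3D track generator
#'
#' Two-state dynamic-instability model: the length grows or shrinks at
#' constant speed and switches states as a Poisson process (catastrophe
#' rate while growing, rescue rate while shrinking), reflecting at zero.
#' The length is embedded in 3D with a slowly pivoting direction and
#' i.i.d. Gaussian localization noise per axis on both ends. Speed and
#' rate scales follow in-vivo astral-microtubule measurements
#' (growth on the order of 2 um/min and roughly one catastrophe per
#' minute of growth).
#'
#' @param growth_speed,shrink_speed um/min.
#' @param catastrophe_rate,rescue_rate switching rates, min^-1.
#' @param noise_sd_nm localization noise per axis, nm.
#' @param frame_interval_s frame spacing, s.
#' @param n_frames frames per track (>= 2).
#' @param n_tracks number of tracks.
#' @param start_length_um initial length, um.
#' @param spindle_um fixed inter-SPB distance, um.
#' @param pivot_sd_rad per-frame angular diffusion of the microtubule
#'   direction, rad.
#' @param seed integer RNG seed.
#' @return A `track_generator_config` list.
#' @export
track_generator_config <- function(growth_speed = 2.0, shrink_speed = 3.0,
                                   catastrophe_rate = 1.0,
                                   rescue_rate = 1.0,
                                   noise_sd_nm = 50,
                                   frame_interval_s = 1.07,
                                   n_frames = 80L, n_tracks = 100L,
                                   start_length_um = 1.0,
                                   spindle_um = 1.5,
                                   pivot_sd_rad = 0.03, seed = 1L) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (any(c(growth_speed, shrink_speed, catastrophe_rate, rescue_rate,
            noise_sd_nm) < 0))
    stop("speeds, rates and noise must be >= 0")
  structure(list(growth_speed = growth_speed, shrink_speed = shrink_speed,
                 catastrophe_rate = catastrophe_rate,
                 rescue_rate = rescue_rate, noise_sd_nm = noise_sd_nm,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 n_tracks = as.integer(n_tracks),
                 start_length_um = start_length_um,
                 spindle_um = spindle_um, pivot_sd_rad = pivot_sd_rad,
                 seed = as.integer(seed)),
            class = "track_generator_config")
}

# one telegraph-process length trajectory sampled at frame times;
# returns lengths plus the true switch times/frames within the window
.telegraph_lengths <- function(cfg) {
  dt <- cfg$frame_interval_s
  t_end <- (cfg$n_frames - 1) * dt
  v_g <- cfg$growth_speed / 60   # um/s
  v_s <- cfg$shrink_speed / 60
  state <- "growth"
  t <- 0; len <- cfg$start_length_um
  seg_t <- c(0); seg_len <- c(len); seg_state <- character(0)
  switch_times <- numeric(0); switch_kind <- character(0)
  while (t < t_end) {
    rate <- if (state == "growth") cfg$catastrophe_rate / 60 else
      cfg$rescue_rate / 60
    tau <- if (rate > 0) rexp(1, rate) else Inf
    t_next <- min(t + tau, t_end)
    v <- if (state == "growth") v_g else -v_s
    # reflecting floor at zero length
    if (v < 0 && len + v * (t_next - t) < 0) {
      t_floor <- t + len / (-v)
      if (t_floor < t_next) {
        seg_state <- c(seg_state, state)
        seg_t <- c(seg_t, t_floor); seg_len <- c(seg_len, 0)
        len <- 0; t <- t_floor
        v <- 0 # sit at zero until the next rescue
      }
    }
    len <- max(0, len + v * (t_next - t))
    seg_state <- c(seg_state, state)
    seg_t <- c(seg_t, t_next); seg_len <- c(seg_len, len)
    if (t_next < t_end) {
      switch_times <- c(switch_times, t_next)
      switch_kind <- c(switch_kind,
                       if (state == "growth") "catastrophe" else "rescue")
      state <- if (state == "growth") "shrinkage" else "growth"
    }
    t <- t_next
  }
  times <- (seq_len(cfg$n_frames) - 1) * dt
  lens <- approx(seg_t, seg_len, xout = times)$y
  list(times = times, lengths_um = lens,
       switch_times = switch_times, switch_kind = switch_kind,
       # frame index of the last sample belonging to the old phase
       switch_frames = floor(switch_times / dt) + 1,
       max_length_um = max(seg_len))
}

#' Generate synthetic 3D end-coordinate tracks with known ground truth
#'
#' Draws two-state dynamic-instability length trajectories, embeds each in
#' 3D (proximal SPB at the origin, distal SPB at a fixed spindle offset,
#' plus-end along a slowly pivoting unit direction so that the end-to-end
#' distance equals the programmed length), and adds Gaussian localization
#' noise per axis to the plus-end and both SPBs. If `dir` is given, writes
#' per-track CSVs (the [read_track_csv()] dialect) plus a ground-truth
#' sidecar JSON.
#'
#' @param config a [track_generator_config()].
#' @param dir optional output directory.
#' @return List with `tracks` (list of [end_track_series()]) and `truth`
#'   (per-track switch times/frames, speeds, true max lengths, seed).
#' @export
generate_tracks <- function(config, dir = NULL) {
  stopifnot(inherits(config, "track_generator_config"))
  set.seed(config$seed)
  tracks <- vector("list", config$n_tracks)
  truth_tracks <- vector("list", config$n_tracks)
  for (i in seq_len(config$n_tracks)) {
    tg <- .telegraph_lengths(config)
    n <- config$n_frames
    # pivoting direction: small random rotation per frame
    u <- matrix(NA_real_, n, 3)
    v <- c(1, 0, 0)
    for (f in seq_len(n)) {
      if (f > 1 && config$pivot_sd_rad > 0) {
        step <- rnorm(3, sd = config$pivot_sd_rad)
        v <- v + c(step[2] * v[3] - step[3] * v[2],
                   step[3] * v[1] - step[1] * v[3],
                   step[1] * v[2] - step[2] * v[1])
        v <- v / sqrt(sum(v^2))
      }
      u[f, ] <- v
    }
    spbp <- matrix(0, n, 3)
    spbd <- matrix(rep(c(0, 0, config$spindle_um * 1000), each = n), n, 3)
    plus <- u * tg$lengths_um * 1000
    if (config$noise_sd_nm > 0) {
      plus <- plus + matrix(rnorm(3 * n, sd = config$noise_sd_nm), n, 3)
      spbp <- spbp + matrix(rnorm(3 * n, sd = config$noise_sd_nm), n, 3)
      spbd <- spbd + matrix(rnorm(3 * n, sd = config$noise_sd_nm), n, 3)
    }
    tracks[[i]] <- end_track_series(tg$times, plus, spbp, spbd,
                                    track_id = sprintf("track%04d", i))
    truth_tracks[[i]] <- list(lengths_um = tg$lengths_um,
                              switch_times_s = tg$switch_times,
                              switch_kind = tg$switch_kind,
                              switch_frames = tg$switch_frames,
                              max_length_um = tg$max_length_um)
  }
  truth <- list(config = unclass(config), tracks = truth_tracks,
                schema = "kip2traffic/track-truth/v1")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(tracks))
      write_track_csv(tracks[[i]],
                      file.path(dir, sprintf("track%04d.csv", i)))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tracks = tracks, truth = truth)
}
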