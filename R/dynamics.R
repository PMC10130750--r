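#' Construct a 3D end-coordinate track
#'
#' Time-stamped 3D coordinates of a microtubule plus-end and of both
#' spindle pole bodies (SPBs), as produced by particle tracking of a
#' volumetric time lapse (default convention: 80 frames, 1.07 s apart).
#'
#' @param times frame times in s, strictly increasing.
#' @param plus_end,spb_proximal,spb_distal n x 3 matrices of x, y, z in nm;
#'   `spb_distal` may be `NULL` when no spindle filtering is needed.
#' @param track_id identifier.
#' @return An object of class `end_track`.
#' @export
end_track_series <- function(times, plus_end, spb_proximal,
                             spb_distal = NULL, track_id = NA_character_) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  plus_end <- as.matrix(plus_end); spb_proximal <- as.matrix(spb_proximal)
  n <- length(times)
  if (nrow(plus_end) != n || nrow(spb_proximal) != n ||
      ncol(plus_end) != 3 || ncol(spb_proximal) != 3)
    stop("coordinate arrays must be n x 3 and match times")
  if (!is.null(spb_distal)) {
    spb_distal <- as.matrix(spb_distal)
    if (nrow(spb_distal) != n || ncol(spb_distal) != 3)
      stop("spb_distal must be n x 3")
  }
  structure(list(times = times, plus_end = plus_end,
                 spb_proximal = spb_proximal, spb_distal = spb_distal,
                 track_id = track_id),
            class = "end_track")
}

#' Per-frame microtubule length from a 3D track
#'
#' The microtubule length is the 3D Euclidean distance between the plus-end
#' and the corresponding (proximal) SPB at each frame.
#'
#' @param track an [end_track_series()].
#' @return Numeric vector of lengths in um.
#' @export
length_series <- function(track) {
  stopifnot(inherits(track, "end_track"))
  d <- track$plus_end - track$spb_proximal
  if (any(!is.finite(d))) stop("track contains missing coordinates")
  sqrt(rowSums(d^2)) / 1000
}

#' Spindle-length filter
#'
#' A cell is excluded when its spindle (the inter-SPB distance) exceeds
#' 2 um in any frame; "longer than" is strict, so a spindle of exactly
#' 2 um is kept.
#'
#' @param track an [end_track_series()] with both SPBs.
#' @param max_spindle_um threshold in um.
#' @return `TRUE` to keep the track, `FALSE` to drop it.
#' @export
spindle_filter <- function(track, max_spindle_um = 2.0) {
  stopifnot(inherits(track, "end_track"))
  if (is.null(track$spb_distal)) stop("both SPB tracks are required")
  spindle <- sqrt(rowSums((track$spb_distal - track$spb_proximal)^2)) / 1000
  all(spindle <= max_spindle_um)
}

#' Censor lengths below the detection limit
#'
#' Frames with length at or below the microscope detection limit (5 pixels
#' = 666.7 nm) are flagged undetectable; a track that never exceeds the
#' limit reports a maximum length of 0 um.
#'
#' @param lengths_um per-frame lengths in um.
#' @param limit_nm detection limit in nm (> 0).
#' @return List with `lengths_um` (undetectable frames set to 0) and
#'   logical `detectable` mask.
#' @export
censor_below_limit <- function(lengths_um, limit_nm = 666.7) {
  if (!is.finite(limit_nm) || limit_nm <= 0) stop("limit must be > 0")
  detectable <- lengths_um * 1000 > limit_nm
  out <- lengths_um
  out[!detectable] <- 0
  list(lengths_um = out, detectable = detectable)
}

#' Maximum length and lifetime of a censored track
#'
#' The maximum length is taken over detectable frames (0 um if none). The
#' lifetime is the longest contiguous detectable span times the frame
#' interval, capped at the acquisition window; isolated single-frame
#' detections are treated as noise and contribute no lifetime.
#'
#' @param censored result of [censor_below_limit()].
#' @param frame_interval_s frame spacing in s.
#' @param min_run_frames shortest contiguous run counted as real (default
#'   2 frames).
#' @return List with `max_length_um` and `lifetime_s`.
#' @export
max_length_and_lifetime <- function(censored, frame_interval_s = 1.07,
                                    min_run_frames = 2L) {
  det <- censored$detectable
  n <- length(det)
  max_len <- if (any(det)) max(censored$lengths_um[det]) else 0
  r <- rle(det)
  runs <- r$lengths[r$values & r$lengths >= min_run_frames]
  lifetime <- if (length(runs)) max(runs) * frame_interval_s else 0
  lifetime <- min(lifetime, n * frame_interval_s)
  list(max_length_um = max_len, lifetime_s = lifetime)
}

# Least-squares line fit; returns SSE (and slope) for y over index window.
.seg_sse <- function(t, y) {
  n <- length(y)
  if (n < 2) return(list(sse = 0, slope = 0))
  tm <- t - mean(t); ym <- y - mean(y)
  stt <- sum(tm^2)
  slope <- if (stt > 0) sum(tm * ym) / stt else 0
  list(sse = sum((ym - slope * tm)^2), slope = slope)
}

# Exact penalized piecewise-linear partitioning by dynamic programming:
# minimizes total SSE + penalty * (number of segments) over all
# segmentations with segments of at least `min_len` frames. Segment SSEs
# come from prefix sums in O(1), so the whole solve is O(n^2). Returns the
# internal breakpoints (last frame of each segment but the final one).
# Unlike greedy binary splitting, this detects short excursions that need
# two simultaneous cuts.
.optseg <- function(t, y, min_len, penalty) {
  n <- length(y)
  if (n < 2 * min_len) return(integer(0))
  c1 <- cumsum(c(0, t)); c2 <- cumsum(c(0, t^2))
  cy <- cumsum(c(0, y)); cy2 <- cumsum(c(0, y^2)); cty <- cumsum(c(0, t * y))
  seg_sse <- function(i, j) { # frames i..j inclusive
    m <- j - i + 1
    st <- c1[j + 1] - c1[i]; stt <- c2[j + 1] - c2[i]
    sy <- cy[j + 1] - cy[i]; syy <- cy2[j + 1] - cy2[i]
    sty <- cty[j + 1] - cty[i]
    sxx <- stt - st * st / m
    sxy <- sty - st * sy / m
    syy_c <- syy - sy * sy / m
    if (sxx <= 0) return(max(syy_c, 0))
    max(syy_c - sxy * sxy / sxx, 0)
  }
  F <- c(0, rep(Inf, n)) # F[j+1]: best cost of frames 1..j
  prev <- integer(n)
  for (j in min_len:n) {
    for (i in seq(1, j - min_len + 1)) {
      if (i > 1 && i - 1 < min_len) next
      cost <- F[i] + seg_sse(i, j) + penalty
      if (cost < F[j + 1]) { F[j + 1] <- cost; prev[j] <- i }
    }
  }
  cuts <- integer(0)
  j <- n
  while (j > 0) {
    i <- prev[j]
    if (i > 1) cuts <- c(i - 1, cuts)
    j <- i - 1
  }
  cuts
}

#' Segment a length series into growth and shrinkage phases
#'
#' Piecewise-linear segmentation of the detectable length series by exact
#' penalized partitioning (dynamic programming over least-squares segment
#' costs), followed by merging of adjacent segments of equal slope sign,
#' removal of direction changes whose fitted displacement falls below
#' `min_displacement_um`, and local refinement of each switch frame.
#' Transitions growth -> shrinkage are catastrophes; shrinkage -> growth
#' are rescues. Phase speed is the end-to-end length change divided by
#' the elapsed time.
#'
#' @param lengths_um detectable per-frame lengths in um.
#' @param times_s frame times in s (defaults to 1.07 s spacing).
#' @param min_displacement_um smallest net length change that counts as a
#'   real direction change (default 0.3 um).
#' @param min_duration_frames shortest phase in frames (default 3).
#' @param noise_sd_um localization noise of the length series, used to
#'   scale the splitting penalty. `NULL` (default) estimates it robustly
#'   from the median absolute second difference of the series.
#' @return A `phase_table` data frame with columns `kind` ("growth" or
#'   "shrinkage"), `t_start`, `t_end` (s), `frame_start`, `frame_end`,
#'   `delta_um` and `speed_um_min`; attributes `n_catastrophes`,
#'   `n_rescues`, `switch_frames`. Too few frames yield an empty table
#'   with a warning.
#' @export
segment_phases <- function(lengths_um,
                           times_s = (seq_along(lengths_um) - 1) * 1.07,
                           min_displacement_um = 0.3,
                           min_duration_frames = 3L,
                           noise_sd_um = NULL) {
  empty <- structure(
    data.frame(kind = character(0), t_start = numeric(0),
               t_end = numeric(0), frame_start = integer(0),
               frame_end = integer(0), delta_um = numeric(0),
               speed_um_min = numeric(0)),
    n_catastrophes = 0L, n_rescues = 0L, switch_frames = integer(0),
    class = c("phase_table", "data.frame"))
  n <- length(lengths_um)
  if (n < 3) {
    warning("too few detectable frames to segment")
    return(empty)
  }
  if (is.null(noise_sd_um)) {
    # second differences of a piecewise-linear series are pure noise away
    # from kinks; their MAD gives a kink-robust noise estimate
    d2 <- diff(lengths_um, differences = 2)
    noise_sd_um <- stats::mad(d2) / sqrt(6)
  }
  # each extra segment must beat the SSE drop expected from fitting two
  # extra line parameters to noise (BIC-like scaling with series length)
  penalty <- max(3 * noise_sd_um^2 * log(n), 1e-12)
  cuts <- .optseg(times_s, lengths_um, max(2L, min_duration_frames), penalty)
  bounds <- c(1L, cuts, n) # segment k spans bounds[k]..bounds[k+1]

  segs <- data.frame(start = head(bounds, -1), end = bounds[-1])
  # displacement of a segment from its least-squares line (robust to the
  # single-frame noise of the raw endpoints); the reported phase speed
  # below still uses the raw endpoint convention
  fit_delta <- function(s) {
    vapply(seq_len(nrow(s)), function(i) {
      span <- s$start[i]:s$end[i]
      .seg_sse(times_s[span], lengths_um[span])$slope *
        (times_s[s$end[i]] - times_s[s$start[i]])
    }, numeric(1))
  }
  # continuity-aware boundary refinement: re-place each internal boundary
  # at the knot minimizing the two-line SSE in a local window, so that
  # neighbouring (possibly absorbed) kinks do not attract it
  refine_bounds <- function(s) {
    if (nrow(s) <= 1) return(s)
    for (i in seq_len(nrow(s) - 1)) {
      b0 <- s$end[i]
      lo <- max(s$start[i], b0 - 20)
      hi <- min(s$end[i + 1], b0 + 20)
      if (hi - lo < 5) next
      cand <- max(lo + 2, b0 - 6):min(hi - 2, b0 + 6)
      if (length(cand) > 1) {
        sse <- vapply(cand, function(k)
          .seg_sse(times_s[lo:k], lengths_um[lo:k])$sse +
            .seg_sse(times_s[k:hi], lengths_um[k:hi])$sse,
          numeric(1))
        b_new <- cand[which.min(sse)]
        s$end[i] <- b_new
        s$start[i + 1] <- b_new
      }
    }
    s
  }
  merge_same_sign <- function(s) {
    i <- 1
    while (i < nrow(s)) {
      d <- fit_delta(s)
      if (sign(d[i]) == sign(d[i + 1])) {
        s$end[i] <- s$end[i + 1]
        s <- s[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    s
  }
  segs <- merge_same_sign(segs)
  segs <- refine_bounds(segs)
  # iterate: (i) merge adjacent same-direction segments; (ii) drop
  # sub-threshold segments at the track edges (a truncated tail of the
  # recording is not a countable phase, and merging it across the kink
  # would dilute the neighbour's speed); (iii) split sub-threshold
  # interior wiggles (which usually straddle a kink) between their
  # neighbours
  repeat {
    if (nrow(segs) <= 1) break
    changed <- FALSE
    n0 <- nrow(segs)
    segs <- merge_same_sign(segs)
    if (nrow(segs) != n0) changed <- TRUE
    d <- fit_delta(segs)
    if (nrow(segs) > 1 && abs(d[1]) < min_displacement_um) {
      segs <- segs[-1, , drop = FALSE]; changed <- TRUE; d <- fit_delta(segs)
    }
    if (nrow(segs) > 1 && abs(d[length(d)]) < min_displacement_um) {
      segs <- segs[-nrow(segs), , drop = FALSE]; changed <- TRUE
      d <- fit_delta(segs)
    }
    if (nrow(segs) > 2) {
      small <- which(abs(d[-c(1, length(d))]) < min_displacement_um) + 1
      if (length(small)) {
        i <- small[1]
        mid <- floor((segs$start[i] + segs$end[i]) / 2)
        segs$end[i - 1] <- mid
        segs$start[i + 1] <- mid
        segs <- segs[-i, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!nrow(segs)) return(empty)
  segs <- refine_bounds(segs)
  seg_delta <- lengths_um[segs$end] - lengths_um[segs$start]
  dt <- times_s[segs$end] - times_s[segs$start]
  out <- data.frame(
    kind = ifelse(seg_delta >= 0, "growth", "shrinkage"),
    t_start = times_s[segs$start], t_end = times_s[segs$end],
    frame_start = segs$start, frame_end = segs$end,
    delta_um = seg_delta,
    speed_um_min = abs(seg_delta) / dt * 60)
  kinds <- out$kind
  n_cat <- sum(kinds[-length(kinds)] == "growth" &
                 kinds[-1] == "shrinkage")
  n_res <- sum(kinds[-length(kinds)] == "shrinkage" &
                 kinds[-1] == "growth")
  structure(out, n_catastrophes = n_cat, n_rescues = n_res,
            switch_frames = out$frame_end[-nrow(out)],
            class = c("phase_table", "data.frame"))
}

#' Catastrophe and rescue frequencies from a phase table
#'
#' Catastrophe frequency is the number of growth-to-shrinkage transitions
#' per minute of growth time; rescue frequency the number of
#' shrinkage-to-growth transitions per minute of shrinkage time. A
#' frequency with zero time in the corresponding state is reported as
#' `NA` (absent).
#'
#' @param phases a `phase_table` from [segment_phases()].
#' @return List with `catastrophe_per_min`, `rescue_per_min`,
#'   `growth_time_s`, `shrinkage_time_s`, `n_catastrophes`, `n_rescues`.
#' @export
event_frequencies <- function(phases) {
  stopifnot(inherits(phases, "phase_table"))
  g_time <- sum(phases$t_end[phases$kind == "growth"] -
                  phases$t_start[phases$kind == "growth"])
  s_time <- sum(phases$t_end[phases$kind == "shrinkage"] -
                  phases$t_start[phases$kind == "shrinkage"])
  n_cat <- attr(phases, "n_catastrophes")
  n_res <- attr(phases, "n_rescues")
  list(catastrophe_per_min = if (g_time > 0) n_cat / (g_time / 60) else
         NA_real_,
       rescue_per_min = if (s_time > 0) n_res / (s_time / 60) else NA_real_,
       growth_time_s = g_time, shrinkage_time_s = s_time,
       n_catastrophes = n_cat, n_rescues = n_res)
}

#' Full dynamic-instability summary of one track
#'
#' Applies the pipeline: length extraction, optional spindle filter,
#' censoring at the detection limit, maximum length and lifetime, phase
#' segmentation on the longest detectable span, and event frequencies.
#' Missing frames (NaN coordinates) are linearly interpolated up to
#' `max_gap` consecutive frames.
#'
#' @param track an [end_track_series()].
#' @param limit_nm detection limit (nm).
#' @param frame_interval_s frame spacing (s).
#' @param ... passed to [segment_phases()].
#' @param max_gap longest interpolated gap in frames.
#' @return A `dynamics_summary` list.
#' @export
summarize_track <- function(track, limit_nm = 666.7,
                            frame_interval_s = 1.07, max_gap = 2L, ...) {
  stopifnot(inherits(track, "end_track"))
  keep <- if (!is.null(track$spb_distal)) spindle_filter(track) else TRUE
  tr <- track
  bad <- !is.finite(rowSums(tr$plus_end) + rowSums(tr$spb_proximal))
  if (any(bad)) {
    r <- rle(bad)
    if (any(r$lengths[r$values] > max_gap))
      stop(sprintf("gap longer than %d frames; split the track", max_gap))
    for (m in list("plus_end", "spb_proximal"))
      for (j in 1:3)
        tr[[m]][, j] <- approx(tr$times[!bad], tr[[m]][!bad, j],
                               xout = tr$times, rule = 2)$y
  }
  lens <- length_series(tr)
  cens <- censor_below_limit(lens, limit_nm)
  ml <- max_length_and_lifetime(cens, frame_interval_s)
  # segment the longest contiguous detectable span
  r <- rle(cens$detectable)
  phases <- NULL; freqs <- NULL
  if (any(r$values & r$lengths >= 3)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    i <- which(r$values)[which.max(r$lengths[r$values])]
    span <- starts[i]:ends[i]
    phases <- segment_phases(lens[span], tr$times[span], ...)
    freqs <- event_frequencies(phases)
  }
  structure(list(track_id = track$track_id, kept = keep,
                 max_length_um = ml$max_length_um,
                 lifetime_s = ml$lifetime_s,
                 detectable_fraction = mean(cens$detectable),
                 phases = phases, frequencies = freqs),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("Track %s: max length %.2f um, lifetime %.1f s%s\n",
              x$track_id, x$max_length_um, x$lifetime_s,
              if (!x$kept) " [excluded by spindle filter]" else ""))
  if (!is.null(x$phases) && nrow(x$phases))
    cat(sprintf("  %d phase(s), %d catastrophe(s), %d rescue(s)\n",
                nrow(x$phases), attr(x$phases, "n_catastrophes"),
                attr(x$phases, "n_rescues")))
  invisible(x)
}

#' Read a 3D end-coordinate track CSV
#'
#' One file per microtubule with header columns `frame`, `time_s`,
#' `plus_x_nm`, `plus_y_nm`, `plus_z_nm`, `spbp_x_nm`, `spbp_y_nm`,
#' `spbp_z_nm` and optionally `spbd_x_nm`, `spbd_y_nm`, `spbd_z_nm`.
#'
#' @param path CSV file path.
#' @return An [end_track_series()].
#' @export
read_track_csv <- function(path) {
  x <- read.csv(path)
  need <- c("frame", "time_s", "plus_x_nm", "plus_y_nm", "plus_z_nm",
            "spbp_x_nm", "spbp_y_nm", "spbp_z_nm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(x$frame))
    stop(sprintf("%s: duplicate frame number %d", basename(path),
                 x$frame[anyDuplicated(x$frame)]))
  spbd <- NULL
  if (all(c("spbd_x_nm", "spbd_y_nm", "spbd_z_nm") %in% names(x)))
    spbd <- as.matrix(x[, c("spbd_x_nm", "spbd_y_nm", "spbd_z_nm")])
  end_track_series(x$time_s,
                   as.matrix(x[, c("plus_x_nm", "plus_y_nm", "plus_z_nm")]),
                   as.matrix(x[, c("spbp_x_nm", "spbp_y_nm", "spbp_z_nm")]),
                   spbd, track_id = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_track_csv
#' @param track an [end_track_series()] (for writing).
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "end_track"))
  df <- data.frame(frame = seq_along(track$times) - 1L,
                   time_s = track$times,
                   plus_x_nm = track$plus_end[, 1],
                   plus_y_nm = track$plus_end[, 2],
                   plus_z_nm = track$plus_end[, 3],
                   spbp_x_nm = track$spb_proximal[, 1],
                   spbp_y_nm = track$spb_proximal[, 2],
                   spbp_z_nm = track$spb_proximal[, 3])
  if (!is.null(track$spb_distal)) {
    df$spbd_x_nm <- track$spb_distal[, 1]
    df$spbd_y_nm <- track$spb_distal[, 2]
    df$spbd_z_nm <- track$spb_distal[, 3]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
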