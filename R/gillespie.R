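#' Exact stochastic simulation of motor traffic on a lattice
#'
#' Simulates the five-rate exclusion process by the Gillespie direct method:
#' minus-end entry at site 1 with propensity `k_in * c_free` (empty site 1),
#' landing on every empty site with `k_on * c_free` per site, hops
#' `i -> i+1` with `k_step` where site `i+1` is free, lattice detachment
#' with `k_off`, and plus-end exit with `k_out` (replacing `k_off` at the
#' terminal site unless `terminal_additive`). With a finite pool the free
#' concentration is updated from [free_concentration()] after every binding
#' or unbinding event.
#'
#' @param params a [model_parameters()] object.
#' @param lattice a [build_lattice()] object (its `occupancy` is the initial
#'   condition).
#' @param t_end simulated time, s (> 0).
#' @param record_interval snapshot spacing, s; snapshots are taken at
#'   `seq(0, t_end, by = record_interval)`. `NULL` disables snapshots.
#' @param seed integer RNG seed; the trajectory is reproducible under it.
#' @param avg_start start of the time-averaging window for the long-run
#'   per-site mean occupancy (default `t_end / 2`, i.e. the second half of
#'   the run is treated as stationary).
#' @param log_events keep a per-event log (time, type, site)? Types are
#'   `enter`, `land`, `hop`, `detach`, `exit`. Off by default to bound
#'   memory.
#' @return A list of class `gillespie_run` with snapshot matrix
#'   (`snapshots`, frames x sites), `record_times`, time-averaged
#'   `mean_occupancy` over `[avg_start, t_end]`, `exit_count` (plus-end
#'   exits in that window), `flux_out` (exits per second), final state, the
#'   final free concentration, and optionally `events`.
#' @examples
#' p <- model_parameters(finite_pool = FALSE)
#' run <- gillespie_simulate(p, build_lattice(160), t_end = 50, seed = 1)
#' run$flux_out
#' @export
gillespie_simulate <- function(params, lattice, t_end,
                               record_interval = NULL, seed = 1L,
                               avg_start = t_end / 2,
                               log_events = FALSE) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(lattice, "lattice"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0")
  record_times <- if (is.null(record_interval)) numeric(0)
                  else seq(0, t_end, by = record_interval)
  res <- .gillespie_core(
    n_sites = lattice$n_sites,
    k_in = params$k_in, k_on = params$k_on, k_off = params$k_off,
    k_step = params$k_step, k_out = params$k_out,
    kip2_total = params$kip2_total, volume_fl = params$volume,
    n_mt = params$n_microtubules, finite_pool = params$finite_pool,
    terminal_additive = params$terminal_additive,
    record_times = record_times, t_end = t_end, avg_start = avg_start,
    seed = as.integer(seed), log_events = isTRUE(log_events),
    init_occupancy = as.integer(lattice$occupancy))
  res$flux_out <- res$exit_count / (t_end - avg_start)
  if (!is.null(res$events)) {
    res$events$type <- c("enter", "land", "hop", "detach",
                         "exit")[res$events$type]
  }
  res$params <- params
  res$seed <- as.integer(seed)
  class(res) <- "gillespie_run"
  res
}

#' @export
print.gillespie_run <- function(x, ...) {
  cat(sprintf("Gillespie run: %d sites, %g events, flux out %.4g /s, c_free %.4g nM\n",
              length(x$mean_occupancy), x$n_events, x$flux_out, x$c_free))
  invisible(x)
}

#' In-silico kymograph of motor traffic
#'
#' Runs one stochastic trajectory and snapshots the lattice occupancy at
#' evenly spaced frame times, emulating a time-lapse acquisition (default
#' convention: 80 frames every 1.07 s).
#'
#' @inheritParams gillespie_simulate
#' @param n_frames number of frames (>= 1).
#' @param frame_interval time between frames, s.
#' @return A matrix of shape `(n_frames, n_sites)` of 0/1 occupancies, with
#'   frame times as row names; attribute `run` holds the full
#'   `gillespie_run`.
#' @examples
#' p <- model_parameters(finite_pool = FALSE)
#' ky <- simulate_kymograph(p, build_lattice(800), n_frames = 10, seed = 1)
#' dim(ky)
#' @export
simulate_kymograph <- function(params, lattice, n_frames = 80L,
                               frame_interval = 1.07, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  t_end <- (n_frames - 1) * frame_interval
  if (t_end == 0) t_end <- frame_interval # single frame: snapshot at 0
  run <- gillespie_simulate(params, lattice, t_end = t_end,
                            record_interval = frame_interval, seed = seed,
                            avg_start = 0)
  kymo <- run$snapshots[seq_len(n_frames), , drop = FALSE]
  rownames(kymo) <- format((seq_len(n_frames) - 1) * frame_interval)
  attr(kymo, "run") <- run
  kymo
}

#' Plus-end residence times from an event log
#'
#' Pairs each arrival at the terminal site (hop into it, landing on it, or
#' entry when the lattice has a single site) with the following plus-end
#' exit and returns the dwell durations. In the unobstructed limit their
#' mean is `1/k_out`.
#'
#' @param run a `gillespie_run` produced with `log_events = TRUE`.
#' @return Numeric vector of residence times, s.
#' @export
tip_residence_times <- function(run) {
  stopifnot(inherits(run, "gillespie_run"))
  ev <- run$events
  if (is.null(ev)) stop("run the simulation with log_events = TRUE")
  n <- length(run$mean_occupancy)
  arrive <- ev$time[(ev$site == n & ev$type %in% c("land", "enter")) |
                    (ev$site == n - 1 & ev$type == "hop")]
  leave <- ev$time[ev$site == n & ev$type %in% c("exit", "detach")]
  k <- min(length(arrive), length(leave))
  if (k == 0) return(numeric(0))
  leave[seq_len(k)] - arrive[seq_len(k)]
}
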