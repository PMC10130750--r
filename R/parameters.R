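#' Parameters of the kinesin traffic model
#'
#' Bundles the five rate constants of the motor-traffic model together with
#' the total motor concentration and the pool geometry. Motors enter the
#' lattice at the spindle-pole-body-anchored minus-end (site 1) with rate
#' `k_in * c_free` when that site is empty, land on any empty lattice site
#' with rate `k_on * c_free` per site, detach from the lattice with `k_off`,
#' step one site toward the plus-end with `k_step` when the next site is
#' free, and leave the terminal (plus-end) site with `k_out`.
#'
#' Defaults are the in-silico reference set: `k_on = 6.1e-4` and
#' `k_in = 0.31` (nM s)^-1, `k_off = 0.023` s^-1, total concentration 35 nM.
#' `k_step` defaults to the measured speckle speed of 6.3 um/min divided by
#' the 8 nm step, i.e. 13.125 s^-1, and `k_out` to 3.3 s^-1 (a plus-end
#' residence below 0.3 s). The in-vitro-scale plus-end residence of ~30 s
#' corresponds to `k_out = 1/30` s^-1.
#'
#' @param k_in minus-end entry rate constant, (nM s)^-1.
#' @param k_on per-site lattice landing rate constant, (nM s)^-1.
#' @param k_off lattice detachment rate, s^-1.
#' @param k_step stepping rate, s^-1.
#' @param k_out plus-end detachment rate, s^-1.
#' @param kip2_total total motor concentration, nM.
#' @param volume effective cytoplasmic volume for pool depletion, fL
#'   (default 3 fL; at the reference rates this reproduces the observed
#'   regime of shaft density rising toward the plus-end with a distinct
#'   tip accumulation and no traffic jam).
#' @param n_microtubules number of lattices sharing the pool.
#' @param finite_pool logical; deplete the free pool as motors bind
#'   (conservation of matter)? If `FALSE` the free concentration stays at
#'   `kip2_total`.
#' @param terminal_additive logical; if `FALSE` (default) the terminal site
#'   detaches with `k_out` *instead of* `k_off`; if `TRUE` both act.
#' @return An object of class `model_parameters`.
#' @examples
#' p <- model_parameters()
#' free_concentration(p, n_bound = 0)
#' @export
model_parameters <- function(k_in = 0.31, k_on = 6.1e-4, k_off = 0.023,
                             k_step = 13.125, k_out = 3.3,
                             kip2_total = 35, volume = 3,
                             n_microtubules = 1,
                             finite_pool = TRUE,
                             terminal_additive = FALSE) {
  rates <- c(k_in = k_in, k_on = k_on, k_off = k_off, k_step = k_step,
             k_out = k_out, kip2_total = kip2_total)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates and concentrations must be finite and >= 0")
  if (!is.finite(volume) || volume <= 0)
    stop("volume must be > 0 fL")
  if (n_microtubules < 1)
    stop("n_microtubules must be >= 1")
  structure(list(k_in = k_in, k_on = k_on, k_off = k_off, k_step = k_step,
                 k_out = k_out, kip2_total = kip2_total, volume = volume,
                 n_microtubules = as.numeric(n_microtubules),
                 finite_pool = isTRUE(finite_pool),
                 terminal_additive = isTRUE(terminal_additive)),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Kinesin traffic model parameters\n")
  cat(sprintf("  k_in  = %.4g (nM s)^-1   k_on = %.4g (nM s)^-1\n",
              x$k_in, x$k_on))
  cat(sprintf("  k_off = %.4g s^-1        k_step = %.4g s^-1   k_out = %.4g s^-1\n",
              x$k_off, x$k_step, x$k_out))
  cat(sprintf("  [Kip2]_total = %.4g nM, volume = %.4g fL, %g lattice(s), %s pool\n",
              x$kip2_total, x$volume, x$n_microtubules,
              if (x$finite_pool) "finite" else "unlimited"))
  invisible(x)
}

#' Free motor concentration under conservation of matter
#'
#' The free concentration is the total concentration minus the bound motors
#' converted back to a concentration in the effective cytoplasmic volume,
#' floored at zero: `c_free = max(0, kip2_total - n_bound * n_microtubules /
#' (N_A * volume))`. `n_bound` counts motors bound per lattice; with
#' `n_microtubules` lattices sharing the pool the bound total is scaled
#' accordingly. 1 nM in 1 fL corresponds to about 0.602 molecules.
#'
#' @param params a [model_parameters()] object.
#' @param n_bound number of bound motors per lattice (>= 0).
#' @return Free concentration in nM, in `[0, kip2_total]`.
#' @examples
#' p <- model_parameters(kip2_total = 35, volume = 1000)
#' free_concentration(p, 602) # ~34 nM: 602 molecules in 1000 fL ~ 1 nM
#' @export
free_concentration <- function(params, n_bound) {
  stopifnot(inherits(params, "model_parameters"))
  if (any(n_bound < 0)) stop("n_bound must be >= 0")
  if (params$volume <= 0) stop("volume must be > 0 fL")
  if (!params$finite_pool) return(rep(params$kip2_total, length(n_bound)))
  c_free <- params$kip2_total -
    n_bound * params$n_microtubules / (MOLECULES_PER_NM_FL * params$volume)
  pmax(0, c_free)
}

#' Discretize a microtubule into a lattice of motor-binding sites
#'
#' One site per 8 nm (the length of a tubulin dimer along a protofilament,
#' and the motor's step size). Site 1 is the minus-end anchored at the
#' spindle pole body; the last site is the plus-end.
#'
#' @param length_nm physical microtubule length in nm (> 0).
#' @param site_size_nm site size in nm (default 8).
#' @return An object of class `lattice` with fields `n_sites`, `site_size`,
#'   and an all-empty `occupancy` vector.
#' @examples
#' build_lattice(2400)$n_sites # 300
#' @export
build_lattice <- function(length_nm, site_size_nm = 8) {
  if (!is.finite(length_nm) || length_nm <= 0)
    stop("length_nm must be > 0")
  if (!is.finite(site_size_nm) || site_size_nm <= 0)
    stop("site_size_nm must be > 0")
  n <- max(1L, as.integer(floor(length_nm / site_size_nm)))
  structure(list(n_sites = n, site_size = site_size_nm,
                 length_nm = length_nm,
                 occupancy = integer(n)),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("Microtubule lattice: %d sites x %g nm (%.3g um), %d occupied\n",
              x$n_sites, x$site_size, x$n_sites * x$site_size / 1000,
              sum(x$occupancy)))
  invisible(x)
}

occupancy_profile <- function(mean_occupancy, flux_out = NA_real_,
                              c_free = NA_real_, site_size = 8,
                              method = "unknown") {
  structure(list(mean_occupancy = as.numeric(mean_occupancy),
                 total_bound = sum(mean_occupancy),
                 flux_out = flux_out,
                 c_free = c_free,
                 site_size = site_size,
                 method = method),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf(
    "Occupancy profile (%s): %d sites, total bound %.3f, tip occupancy %.4f\n",
    x$method, length(x$mean_occupancy), x$total_bound,
    tail(x$mean_occupancy, 1)))
  invisible(x)
}
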