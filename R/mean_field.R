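#' Mean-field steady state of the traffic model
#'
#' Solves the stationary mean-field (first-order closure) density profile of
#' the five-rate exclusion process: per-site densities `rho_i` obey
#' \deqn{0 = (k_{in}+k_{on}) c (1-\rho_1) - k_{step}\rho_1(1-\rho_2) - k_{off}\rho_1}
#' \deqn{0 = k_{on} c (1-\rho_i) + k_{step}\rho_{i-1}(1-\rho_i) - k_{step}\rho_i(1-\rho_{i+1}) - k_{off}\rho_i}
#' \deqn{0 = k_{on} c (1-\rho_L) + k_{step}\rho_{L-1}(1-\rho_L) - k_{out}\rho_L}
#' with the free concentration `c` self-consistent under conservation of
#' matter ([free_concentration()]) when the pool is finite. The solver uses
#' damped Gauss-Seidel fixed-point sweeps with a pseudo-time integration
#' fallback; the residual is the max-norm of the time derivatives.
#'
#' @inheritParams gillespie_simulate
#' @param tol convergence tolerance on the residual (default 1e-10).
#' @param max_iter maximum fixed-point sweeps before the fallback engages.
#' @param init optional warm start: a list with `rho` (per-site densities)
#'   and `c` (free concentration), e.g. a previous solution at nearby
#'   parameters.
#' @return An `occupancy_profile` with per-site densities, the
#'   self-consistent free concentration `c_free`, and `flux_out`.
#' @examples
#' p <- model_parameters()
#' prof <- mean_field_steady_state(p, build_lattice(1600))
#' prof$c_free # depleted below kip2_total by the bound motors
#' @export
mean_field_steady_state <- function(params, lattice, tol = 1e-10,
                                    max_iter = 20000L, init = NULL) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(lattice, "lattice"))
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0")
  init_rho <- if (is.null(init)) numeric(0) else as.numeric(init$rho)
  init_c <- if (is.null(init)) -1 else init$c
  res <- .mean_field_core(
    n_sites = lattice$n_sites,
    k_in = params$k_in, k_on = params$k_on, k_off = params$k_off,
    k_step = params$k_step, k_out = params$k_out,
    kip2_total = params$kip2_total, volume_fl = params$volume,
    n_mt = params$n_microtubules, finite_pool = params$finite_pool,
    terminal_additive = params$terminal_additive,
    tol = tol, max_iter = as.integer(max_iter),
    init_rho = init_rho, init_c = init_c)
  if (!res$converged) {
    cond <- simpleError(sprintf(
      "mean-field solver did not converge: residual %.3g > tol %.3g",
      res$residual, tol))
    cond$residual <- res$residual
    stop(cond)
  }
  prof <- occupancy_profile(res$rho, flux_out = res$flux_out,
                            c_free = res$c_free,
                            site_size = lattice$site_size,
                            method = "mean_field")
  attr(prof, "residual") <- res$residual
  attr(prof, "iterations") <- res$iterations
  prof
}
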