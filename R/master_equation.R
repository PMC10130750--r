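#' Exact stationary occupancy of the traffic model on a small lattice
#'
#' Enumerates all `2^n` occupancy configurations of the lattice, builds the
#' generator of the continuous-time Markov chain defined by the five rates,
#' and solves for its stationary distribution (the normalized null space of
#' the generator). Serves as the exact oracle against which the stochastic
#' simulator and the mean-field solver are checked. The free concentration
#' is held constant at `kip2_total` (unlimited pool) so that the chain is a
#' fixed-rate Markov chain.
#'
#' @inheritParams gillespie_simulate
#' @param max_sites refuse lattices above this size (state space is `2^n`).
#' @return An `occupancy_profile` with exact per-site marginal occupancies,
#'   `flux_out = k_out * P(terminal occupied)`, and the full stationary
#'   distribution in attribute `stationary`.
#' @examples
#' p <- model_parameters(k_in = 1, k_on = 0, k_out = 2, kip2_total = 1,
#'                       finite_pool = FALSE)
#' master_equation_stationary(p, build_lattice(8))$mean_occupancy
#' # = r_in / (r_in + k_out)
#' @export
master_equation_stationary <- function(params, lattice, max_sites = 14L) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(lattice, "lattice"))
  n <- lattice$n_sites
  if (n > max_sites)
    stop(sprintf("lattice has %d sites; exact solver limited to %d (2^n states)",
                 n, max_sites))
  c_free <- params$kip2_total
  m <- 2L^n
  # state s in 0:(m-1); bit i-1 set <=> site i occupied
  occ_bit <- function(s, i) bitwAnd(bitwShiftR(s, i - 1L), 1L)

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(s, t, r) {
    if (r > 0) {
      from <<- c(from, s); to <<- c(to, t); rate <<- c(rate, r)
    }
  }
  out_rate <- if (params$terminal_additive) params$k_off + params$k_out
              else params$k_out
  for (s in 0:(m - 1L)) {
    for (i in seq_len(n)) {
      oi <- occ_bit(s, i)
      if (oi == 0L) {
        r <- params$k_on * c_free + if (i == 1L) params$k_in * c_free else 0
        add(s, bitwOr(s, bitwShiftL(1L, i - 1L)), r)
      } else {
        if (i < n) {
          add(s, bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L))), params$k_off)
          if (occ_bit(s, i + 1L) == 0L)
            add(s, bitwOr(bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L))),
                          bitwShiftL(1L, i)), params$k_step)
        } else {
          add(s, bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L))), out_rate)
        }
      }
    }
  }
  Q <- Matrix::sparseMatrix(i = from + 1L, j = to + 1L, x = rate,
                            dims = c(m, m))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  # stationary pi solves t(Q) pi = 0, sum(pi) = 1: replace one equation
  A <- Matrix::t(Q)
  A[m, ] <- 1
  b <- c(rep(0, m - 1L), 1)
  pi_s <- as.numeric(Matrix::solve(A, b))
  pi_s[pi_s < 0 & pi_s > -1e-12] <- 0
  pi_s <- pi_s / sum(pi_s)

  marg <- vapply(seq_len(n), function(i) {
    states <- which(vapply(0:(m - 1L), occ_bit, integer(1), i = i) == 1L)
    sum(pi_s[states])
  }, numeric(1))
  prof <- occupancy_profile(marg, flux_out = out_rate * marg[n],
                            c_free = c_free, site_size = lattice$site_size,
                            method = "master_equation")
  attr(prof, "stationary") <- pi_s
  prof
}
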