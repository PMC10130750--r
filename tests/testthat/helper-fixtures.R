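# Shared fixtures built in code.

# reference in-silico parameter set (bik1-delta-like): the four printed
# rate constants plus the documented k_step / k_out defaults
ref_params <- function(...) model_parameters(...)

# a small parameter set whose exact stationary state is cheap to compute
toy_params <- function(...) {
  args <- utils::modifyList(
    list(k_in = 0.4, k_on = 0.02, k_off = 0.3, k_step = 1.5,
         k_out = 0.8, kip2_total = 2, finite_pool = FALSE),
    list(...))
  do.call(model_parameters, args)
}

# batch-mean standard error of a per-site Gillespie time average: split the
# averaging window into n_batches independent runs with different seeds
gillespie_mean_and_se <- function(params, lattice, t_end, n_batches = 8,
                                  seed0 = 100) {
  means <- sapply(seq_len(n_batches), function(b)
    gillespie_simulate(params, lattice, t_end = t_end,
                       seed = seed0 + b)$mean_occupancy)
  means <- matrix(means, nrow = lattice$n_sites)
  list(mean = rowMeans(means),
       se = apply(means, 1, sd) / sqrt(n_batches))
}

# build an aligned synthetic line-scan with explicit peak positions
two_peak_profile <- function(mch_peak_px, gfp_peak_px, n_px = 24,
                             px = 133.35) {
  mch <- rep(0.1, n_px); mch[mch_peak_px + 1] <- 5
  gfp <- rep(0.5, n_px); gfp[gfp_peak_px + 1] <- 3
  line_scan_profile((seq_len(n_px) - 1) * px, gfp, mch, cell_id = "fix")
}
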