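# Affine-invariant ensemble sampler (Goodman-Weare stretch moves).
# Generic over a log-density on a d-dimensional box; used by
# sample_likelihood() with a flat prior in log10-parameter space.

ensemble_sampler <- function(log_post, init, n_steps, a = 2,
                             lower = -Inf, upper = Inf) {
  X <- init # n_walkers x d
  K <- nrow(X); d <- ncol(X)
  if (K < max(3, d + 2)) stop("need more walkers than dimensions")
  lp <- apply(X, 1, log_post)
  keep <- array(NA_real_, dim = c(n_steps, K, d))
  keep_lp <- matrix(NA_real_, n_steps, K)
  n_acc <- 0L
  for (s in seq_len(n_steps)) {
    for (k in seq_len(K)) {
      j <- sample(seq_len(K)[-k], 1)
      z <- (((a - 1) * runif(1) + 1)^2) / a
      y <- X[j, ] + z * (X[k, ] - X[j, ])
      if (all(y >= lower) && all(y <= upper)) {
        lpy <- log_post(y)
        if (is.finite(lpy) || is.finite(lp[k])) {
          log_acc <- (d - 1) * log(z) + lpy - lp[k]
          if (is.finite(log_acc) && log(runif(1)) < log_acc) {
            X[k, ] <- y; lp[k] <- lpy; n_acc <- n_acc + 1L
          }
        }
      }
    }
    keep[s, , ] <- X
    keep_lp[s, ] <- lp
  }
  list(chain = keep, log_post = keep_lp,
       acceptance = n_acc / (n_steps * K))
}

# Split-chain potential scale reduction factor per dimension.
split_rhat <- function(chain) {
  n <- dim(chain)[1]
  if (n < 4) return(rep(NA_real_, dim(chain)[3]))
  half <- floor(n / 2)
  vapply(seq_len(dim(chain)[3]), function(p) {
    pieces <- rbind(t(chain[seq_len(half), , p]),
                    t(chain[(n - half + 1):n, , p]))
    m <- nrow(pieces); len <- ncol(pieces)
    mu <- rowMeans(pieces)
    B <- len * var(mu)
    W <- mean(apply(pieces, 1, var))
    if (W <= 0) return(1)
    sqrt(((len - 1) / len * W + B / len) / W)
  }, numeric(1))
}
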