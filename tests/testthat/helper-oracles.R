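# Independent oracles used across tests.

# Euler-Maruyama single-boundary diffusion first-passage sampler:
# paths of dX = drift*dt + noise*dW from 0 to `threshold`, absorbed at
# the boundary; Inf for paths that never cross within t_max. Within-step
# crossings are caught by the Brownian-bridge probability
# exp(-2 (b - x0)(b - x1) / (noise^2 dt)), removing the O(sqrt(dt))
# discretisation bias of the naive scheme.
em_fpt <- function(n_paths, drift, noise = 1, threshold = 1,
                   dt = 1e-3, t_max = 10) {
  x <- numeric(n_paths)
  out <- rep(Inf, n_paths)
  alive <- rep(TRUE, n_paths)
  sdt <- noise * sqrt(dt)
  steps <- ceiling(t_max / dt)
  for (s in seq_len(steps)) {
    idx <- which(alive)
    if (!length(idx)) break
    x_old <- x[idx]
    x_new <- x_old + drift * dt + rnorm(length(idx), 0, sdt)
    p_bridge <- exp(-2 * pmax(threshold - x_old, 0) *
                      pmax(threshold - x_new, 0) / (noise^2 * dt))
    hit <- x_new >= threshold | runif(length(idx)) < p_bridge
    out[idx[hit]] <- s * dt
    alive[idx[hit]] <- FALSE
    x[idx] <- x_new
  }
  out
}

# model CDF of RT conditional on a choice, by trapezoid integration of
# the defective density on a fine grid; returns a function of t
race_cond_cdf <- function(choice, params, s_l, s_r, t_max = 20,
                          n_grid = 20000) {
  grid <- seq(params$t0, t_max, length.out = n_grid)
  dens <- drace(grid, choice, params, s_l, s_r)
  cum <- cumsum(c(0, diff(grid) * (head(dens, -1) + dens[-1]) / 2))
  total <- cum[length(cum)]
  function(t) approx(grid, cum, t, rule = 2)$y / total
}

# one-sample Kolmogorov-Smirnov distance
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

# fixed stimulus set: the full contrast grid replicated
grid_stim <- function(reps) {
  g <- contrast_grid()
  g[rep(seq_len(nrow(g)), reps), , drop = FALSE]
}

ref_trdm_params <- function() {
  race_params("TRDM", omega = 0.5, t0 = 0.1, v0 = 1, vd = 3, vs = 0.5,
              eta_c = 1, rho_t = 3, eta_t = 0.5, gamma = 0.2)
}
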