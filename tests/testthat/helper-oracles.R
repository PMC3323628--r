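# Shared helpers: random system draws and brute-force oracles that stay
# independent of the closed forms they are used to check.

# log-uniform draw
runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

random_system <- function(dose_range = c(1e-3, 1e3),
                          factor_range = c(1e-2, 1e2),
                          xp_range = c(1e-3, 1e1)) {
  two_activator_system(
    x_P = runif_log(1, xp_range[1], xp_range[2]),
    x_A = runif_log(1, dose_range[1], dose_range[2]),
    x_B = runif_log(1, dose_range[1], dose_range[2]),
    w_A = runif_log(1, factor_range[1], factor_range[2]),
    w_B = runif_log(1, factor_range[1], factor_range[2]),
    omega_AB = runif_log(1, factor_range[1], factor_range[2]),
    omega3 = runif_log(1, factor_range[1], factor_range[2])
  )
}

# Saturated synergy difference for equal activators with neutral omega
# factors, written directly from the saturation limits (oracle for the
# critical x_P curve).
saturated_D_equal <- function(x_P, w) {
  x_P * w^2 / (1 + x_P * w^2) - 2 * x_P * w / (1 + x_P * w)
}

# Synergy difference evaluated through the exported occupancy function only.
D_via_occupancy <- function(sys, x_A = sys$x_A, x_B = sys$x_B) {
  occupancy_two(sys, x_A, x_B) - occupancy_two(sys, x_A, 0) -
    occupancy_two(sys, 0, x_B)
}

# Maximum of D over full log grids of doses and two-body factors at neutral
# omega factors, chunked over factor pairs to bound memory.
max_D_grid <- function(x_P, dose_grid, w_grid) {
  xa <- rep(dose_grid, times = length(dose_grid))
  xb <- rep(dose_grid, each = length(dose_grid))
  best <- -Inf
  for (wa in w_grid) for (wb in w_grid) {
    sys <- two_activator_system(x_P, 0, 0, wa, wb)
    m <- max(D_via_occupancy(sys, xa, xb))
    if (m > best) best <- m
  }
  best
}
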