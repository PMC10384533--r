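# Shared fixtures: small grids and parameter sets used across the suite.

small_bay <- function(nx = 20, ny = 10, depth_head = 8, depth_mouth = 12) {
  build_idealized_bay(nx, ny, nx * 500, ny * 500, depth_head, depth_mouth)
}

# fully closed version of a bay (mouth column converted to interior sea)
close_mouth <- function(grid) {
  grid$mask[grid$mask == 2L] <- 1L
  grid
}

# fate parameters with every kinetic process switched off (pure tracer)
tracer_params <- function(...) {
  args <- list(K0 = 0, K1 = 0, C_equ = 0, omega = 0,
               k_l = 1e-12, k_g = 1e-12, D_sw = 1e-12,
               sigma_tx = 0, sigma_ty = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(fate_params, args)
}

# a single-row channel grid open at the first column
channel_grid <- function(nx, dx, H0, dy = 500) {
  bay_grid(matrix(H0, nx, 1), dx = dx, dy = dy,
           mask = matrix(c(2L, rep(1L, nx - 1)), nx, 1))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps), tol)
}
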