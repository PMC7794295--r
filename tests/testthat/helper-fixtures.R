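# Shared toy fixtures and geometry helpers. All quantities in atomic
# units unless noted.

# two identical oscillators on the z axis
toy_dimer <- function(R = 8, alpha = 10, omega = 0.5, r_vdw = 3) {
  oscillator_set(rbind(c(0, 0, 0), c(0, 0, R)),
                 rep(alpha, 2), rep(omega, 2), rep(r_vdw, 2))
}

# scalene triangle in the xz plane (no accidental symmetry)
toy_trimer <- function(alpha = 10, omega = 0.5, r_vdw = 3) {
  oscillator_set(rbind(c(0, 0, 0), c(8, 0, 0), c(3, 0, 7)),
                 rep(alpha, 3), rep(omega, 3), rep(r_vdw, 3))
}

# proper rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_oscillators <- function(osc, Q, shift = c(0, 0, 0)) {
  oscillator_set(sweep(osc$positions %*% t(Q), 2, -shift),
                 osc$alpha, osc$omega, osc$r_vdw, osc$charge,
                 elements = osc$elements, labels = osc$labels)
}

# covariantly rotate a Gaussian state (block rotation per atom)
rotate_state <- function(state, Q) {
  n <- state$n_atoms
  B <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) B[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <- Q
  structure(list(covariance = B %*% state$covariance %*% t(B),
                 correlated = state$correlated, n_atoms = n),
            class = "gaussian_state")
}

# correlated + uncorrelated states in one call
both_states <- function(osc, params = damping_params("mbd"),
                        damping = "none") {
  list(dc = ground_state(osc, params = params, damping = damping),
       uc = ground_state(osc, correlated = FALSE))
}
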