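#' Damping parameters for short-range attenuation
#'
#' The Fermi-type damping switches interatomic coupling off at short range
#' to avoid the divergence of bare dipolar or beyond-dipolar potentials.
#' Two parameter sets are used: the `mbd` variant (default a = 6,
#' beta = 0.83) damps the dipole coupling in the Hamiltonian, the `dcs`
#' variant (a = 10.12, beta = 1.4) damps the beyond-dipole Coulomb
#' correction.
#'
#' @param variant "mbd" or "dcs".
#' @param a sigmoid steepness (dimensionless); NULL takes the variant default.
#' @param beta range scaling of the vdW-radius sum; NULL takes the default.
#' @return a `damping_params` list with fields `a`, `beta`, `variant`.
#' @export
damping_params <- function(variant = c("mbd", "dcs"), a = NULL, beta = NULL) {
  variant <- match.arg(variant)
  defaults <- list(mbd = c(a = 6, beta = 0.83),
                   dcs = c(a = 10.12, beta = 1.4))[[variant]]
  if (is.null(a)) a <- defaults[["a"]]
  if (is.null(beta)) beta <- defaults[["beta"]]
  if (a <= 0 || beta <= 0) stop("damping parameters must be positive")
  structure(list(a = a, beta = beta, variant = variant),
            class = "damping_params")
}

#' Dipole tensor (Hessian of 1/r)
#'
#' T_ab = (3 r_a r_b - |r|^2 delta_ab)/|r|^5; symmetric and traceless.
#' Note that the dipole-dipole *interaction* tensor between two centers,
#' grad_A x grad_B (1/|R_A - R_B|), is the negative of this.
#'
#' @param r 3-vector separation (Bohr), nonzero.
#' @return 3 x 3 matrix (Bohr^-3).
#' @export
dipole_tensor <- function(r) {
  r <- as.numeric(r)
  r2 <- sum(r * r)
  if (r2 == 0) stop("dipole tensor singular: zero separation")
  (3 * outer(r, r) - r2 * diag(3)) / r2^2.5
}

#' Fermi damping function
#'
#' f(R) = 1/(1 + exp(-a*(R/(beta*(R_A + R_B)) - 1))) with R_A, R_B the
#' van der Waals radii of the pair; monotone increasing in R, 1/2 at
#' R = beta*(R_A + R_B).
#'
#' @param R interatomic distance(s), Bohr (vectorized).
#' @param r_vdw_a,r_vdw_b vdW radii of the two atoms (Bohr).
#' @param params a `damping_params`.
#' @return damping factor(s) in (0, 1).
#' @export
fermi_damping <- function(R, r_vdw_a, r_vdw_b, params) {
  if (any(R < 0)) stop("distance must be non-negative")
  s <- params$beta * (r_vdw_a + r_vdw_b)
  1 / (1 + exp(-params$a * (R / s - 1)))
}

#' Dipole-coupled Hamiltonian matrix
#'
#' Builds the 3N x 3N symmetric matrix C of the mass-weighted coupled
#' oscillator Hamiltonian H = p^2/2 + xi' C xi / 2: diagonal 3x3 blocks
#' omega_i^2 I, off-diagonal blocks
#' omega_i omega_j sqrt(alpha_i alpha_j) f_ij Tdd(R_ij), where Tdd is the
#' dipole-dipole interaction tensor (|r|^2 I - 3 r r')/|r|^5 obtained from
#' the second-order expansion of the Coulomb interaction between two
#' neutral Drude oscillators.
#'
#' @param osc an `oscillator_set`.
#' @param params a `damping_params`; the coupling may be switched off
#'   entirely with `damping = "none"`.
#' @param damping "fermi" (default) or "none" (f == 1).
#' @return 3N x 3N symmetric matrix (Hartree^2).
#' @export
interaction_matrix <- function(osc, params = damping_params("mbd"),
                               damping = c("fermi", "none")) {
  damping <- match.arg(damping)
  n <- nrow(osc$positions)
  C <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    C[ii, ii] <- osc$omega[i]^2 * diag(3)
  }
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- osc$positions[j, ] - osc$positions[i, ]
    if (sum(r * r) == 0) stop("coincident atoms in oscillator set")
    f <- if (damping == "none") 1 else
      fermi_damping(sqrt(sum(r * r)), osc$r_vdw[i], osc$r_vdw[j], params)
    B <- -osc$omega[i] * osc$omega[j] * sqrt(osc$alpha[i] * osc$alpha[j]) *
      f * dipole_tensor(r)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    C[ii, jj] <- B
    C[jj, ii] <- t(B)
  }
  C
}

#' Solve the coupled-oscillator eigenmodes
#'
#' Diagonalizes the Hamiltonian matrix; the collective mode frequencies
#' are omega_DC,k = sqrt(lambda_k). A non-positive eigenvalue signals a
#' polarization catastrophe (unphysically strong dipole coupling).
#'
#' @param C 3N x 3N symmetric matrix from [interaction_matrix()].
#' @param omega_0 optional per-atom uncoupled frequencies, carried along.
#' @return a `mode_spectrum`: `eigenvalues` (ascending), `mode_matrix`
#'   (orthogonal, columns are modes), `omega_dc`, `omega_0`.
#' @export
solve_modes <- function(C, omega_0 = NULL) {
  if (!isSymmetric(unname(C), tol = 1e-10))
    stop("interaction matrix must be symmetric")
  es <- eigen((C + t(C)) / 2, symmetric = TRUE)
  ev <- rev(es$values)
  vec <- es$vectors[, rev(seq_along(es$values)), drop = FALSE]
  if (ev[1] <= 0)
    stop(sprintf(paste0("polarization catastrophe: non-positive eigenvalue ",
                        "%.6e in coupled-oscillator matrix"), ev[1]))
  structure(list(eigenvalues = ev, mode_matrix = vec,
                 omega_dc = sqrt(ev),
                 omega_0 = if (is.null(omega_0)) NULL else
                   rep(omega_0, each = 3)),
            class = "mode_spectrum")
}

#' Many-body dispersion energy
#'
#' E_MBD = sum_k omega_DC,k / 2 - 3/2 sum_i omega_i: the zero-point energy
#' of the dipole-coupled oscillators minus that of the non-interacting set.
#'
#' @param osc an `oscillator_set`.
#' @param params `damping_params` for the dipole coupling.
#' @param damping "fermi" or "none".
#' @return scalar energy (Hartree).
#' @examples
#' dimer <- oscillator_set(rbind(c(0, 0, 0), c(0, 0, 10)),
#'                         alpha = c(1, 1), omega = c(1, 1),
#'                         r_vdw = c(3, 3))
#' mbd_energy(dimer, damping = "none")  # ~ -(3/4)/10^6
#' @export
mbd_energy <- function(osc, params = damping_params("mbd"),
                       damping = c("fermi", "none")) {
  damping <- match.arg(damping)
  if (nrow(osc$positions) == 1L) return(0)
  spec <- solve_modes(interaction_matrix(osc, params, damping), osc$omega)
  sum(spec$omega_dc) / 2 - 3 * sum(osc$omega) / 2
}

#' Gaussian ground state of the oscillator system
#'
#' The ground state of a set of (coupled or uncoupled) harmonic
#' oscillators is a zero-mean 3N-dimensional Gaussian over the Drude
#' displacements. In mass-weighted coordinates the covariance is
#' C^(-1/2)/2; mapped back to displacements,
#' Sigma = M^(-1/2) (C^(-1/2)/2) M^(-1/2). The uncorrelated state is
#' block-diagonal with isotropic blocks (alpha_i omega_i / 2) I (q = 1).
#'
#' @param osc an `oscillator_set`.
#' @param spectrum a `mode_spectrum` (required when `correlated = TRUE`);
#'   for convenience, NULL recomputes it with `params`/`damping`.
#' @param correlated TRUE for the dipole-coupled ground state.
#' @param params,damping used only when `spectrum` is NULL and
#'   `correlated = TRUE`.
#' @return a `gaussian_state`: `covariance` (3N x 3N, Bohr^2),
#'   `correlated` flag, `n_atoms`.
#' @export
ground_state <- function(osc, spectrum = NULL, correlated = TRUE,
                         params = damping_params("mbd"),
                         damping = c("fermi", "none")) {
  n <- nrow(osc$positions)
  if (!correlated) {
    Sigma <- matrix(0, 3 * n, 3 * n)
    for (i in seq_len(n)) {
      ii <- (3 * i - 2):(3 * i)
      Sigma[ii, ii] <- (osc$alpha[i] * osc$omega[i] / 2) * diag(3)
    }
  } else {
    if (is.null(spectrum)) {
      damping <- match.arg(damping)
      spectrum <- solve_modes(interaction_matrix(osc, params, damping),
                              osc$omega)
    }
    V <- spectrum$mode_matrix
    Chalf_inv <- V %*% (t(V) / sqrt(spectrum$eigenvalues))
    w <- rep(1 / sqrt(osc$mass), each = 3)  # M^(-1/2) diagonal
    Sigma <- (outer(w, w) * Chalf_inv) / 2
    Sigma <- (Sigma + t(Sigma)) / 2
    if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("ground-state covariance not positive definite")
  }
  structure(list(covariance = Sigma, correlated = correlated, n_atoms = n),
            class = "gaussian_state")
}

#' Extract a 3x3 covariance block of a Gaussian state
#' @param state a `gaussian_state`.
#' @param i,j atom indices; `i == j` gives the marginal block.
#' @return 3 x 3 matrix (Bohr^2).
#' @export
covariance_block <- function(state, i, j = i) {
  state$covariance[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j), drop = FALSE]
}
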