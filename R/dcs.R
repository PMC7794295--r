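# Dipole-Correlated Coulomb Singles: first-order beyond-dipole Coulomb
# correction over the dipole-coupled oscillator ground state.

# dipole-dipole interaction tensor between two centers:
# grad_A (x) grad_B 1/|R_A - R_B| = (|r|^2 I - 3 r r')/|r|^5
dipole_interaction_tensor <- function(r) -dipole_tensor(r)

#' Pair Coulomb expectation over a Gaussian oscillator state
#'
#' Expectation of the full Coulomb interaction between two neutral Drude
#' oscillators A and B (nucleus +q at R, cloud -q displaced by d) over a
#' Gaussian state: q_A q_B [1/R - K(R, Sigma_BB) - K(R, Sigma_AA)
#' + K(R, Sigma_AA + Sigma_BB - Sigma_AB - Sigma_BA)], with covariance
#' blocks read from the state (cross blocks vanish for the uncorrelated
#' state).
#'
#' @param osc an `oscillator_set`.
#' @param state a `gaussian_state` built from the same set.
#' @param i,j distinct atom indices.
#' @return scalar energy (Hartree).
#' @export
pair_coulomb_expectation <- function(osc, state, i, j) {
  if (i == j) stop("pair expectation needs two distinct atoms")
  R <- osc$positions[j, ] - osc$positions[i, ]
  rmod <- sqrt(sum(R * R))
  qq <- osc$charge[i] * osc$charge[j]
  Saa <- covariance_block(state, i)
  Sbb <- covariance_block(state, j)
  Srel <- Saa + Sbb - covariance_block(state, i, j) -
    covariance_block(state, j, i)
  qq * (1 / rmod - gaussian_coulomb_kernel(R, Sbb) -
          gaussian_coulomb_kernel(R, Saa) +
          gaussian_coulomb_kernel(R, Srel))
}

#' Pair dipole expectation over a Gaussian oscillator state
#'
#' Expectation of the dipolar coupling term for one pair,
#' q_A q_B Tr(Tdd(R_AB) Sigma_AB) with Tdd the dipole-dipole interaction
#' tensor; exactly zero for the uncorrelated state (no cross covariance).
#'
#' @inheritParams pair_coulomb_expectation
#' @return scalar energy (Hartree).
#' @export
pair_dipole_expectation <- function(osc, state, i, j) {
  if (i == j) stop("pair expectation needs two distinct atoms")
  R <- osc$positions[j, ] - osc$positions[i, ]
  qq <- osc$charge[i] * osc$charge[j]
  qq * sum(dipole_interaction_tensor(R) * t(covariance_block(state, i, j)))
}

# per-pair ingredients of E_DCS and its decomposition
dcs_pair_terms <- function(osc, state_dc, state_0, params,
                           damping = c("fermi", "none")) {
  damping <- match.arg(damping)
  n <- nrow(osc$positions)
  if (state_dc$n_atoms != n || state_0$n_atoms != n)
    stop("states and oscillator set disagree on atom count")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- data.frame(i = pairs[, 1], j = pairs[, 2], f = NA_real_,
                    vc_dc = NA_real_, vd_dc = NA_real_, j_dc = NA_real_,
                    j_0 = NA_real_)
  for (k in seq_len(nrow(out))) {
    i <- out$i[k]; j <- out$j[k]
    R <- osc$positions[j, ] - osc$positions[i, ]
    rmod <- sqrt(sum(R * R))
    qq <- osc$charge[i] * osc$charge[j]
    out$f[k] <- if (damping == "none") 1 else
      fermi_damping(rmod, osc$r_vdw[i], osc$r_vdw[j], params)
    out$vc_dc[k] <- pair_coulomb_expectation(osc, state_dc, i, j)
    out$vd_dc[k] <- pair_dipole_expectation(osc, state_dc, i, j)
    # classical (mean-density) Coulomb terms: marginal covariances only
    jterm <- function(st) {
      Saa <- covariance_block(st, i); Sbb <- covariance_block(st, j)
      qq * (1 / rmod - gaussian_coulomb_kernel(R, Sbb) -
              gaussian_coulomb_kernel(R, Saa) +
              gaussian_coulomb_kernel(R, Saa + Sbb))
    }
    out$j_dc[k] <- jterm(state_dc)
    out$j_0[k] <- jterm(state_0)
  }
  out
}

#' Dipole-Correlated Coulomb Singles energy
#'
#' First-order perturbation correction toward full Coulomb coupling:
#' E_DCS = <Psi_DC|V'|Psi_DC> - <Psi_0|V'|Psi_0> with
#' V' = sum over pairs of f_damp (V_Coul - V_dip). The uncorrelated
#' expectation of V_dip vanishes, so per pair the damped summand is
#' [V_Coul^DC - V_dip^DC] - V_Coul^0.
#'
#' @param osc an `oscillator_set`.
#' @param state_dc correlated `gaussian_state` (dipole-coupled ground state).
#' @param state_0 uncorrelated `gaussian_state`.
#' @param params `damping_params`, normally the "dcs" variant.
#' @param damping "fermi" or "none".
#' @return scalar energy (Hartree).
#' @export
dcs_energy <- function(osc, state_dc, state_0,
                       params = damping_params("dcs"),
                       damping = c("fermi", "none")) {
  if (nrow(osc$positions) == 1L) return(0)
  pt <- dcs_pair_terms(osc, state_dc, state_0, params, damping)
  sum(pt$f * ((pt$vc_dc - pt$vd_dc) - pt$j_0))
}

#' Decomposition of the DCS energy
#'
#' Splits E_DCS into its classical dispersion-polarization part and the
#' beyond-dipole correlation part:
#' E_DCS = (J[rho_DC] - J[rho_0]) + (E_corr[Psi_DC] - E_dip[Psi_DC]),
#' where J[rho] is the classical Coulomb energy of the mean fluctuation
#' density (marginal covariances only), E_corr = <V_Coul> - J[rho_DC],
#' and E_dip = <T_pp>. The damping factor is applied uniformly to every
#' pair term, so the identity holds exactly.
#'
#' @inheritParams dcs_energy
#' @return a `dcs_breakdown`: `e_dcs`, `j_dc`, `j_0`, `e_corr`, `e_dip`
#'   (all Hartree) plus a `pairs` data frame of per-pair contributions.
#' @export
dcs_decomposition <- function(osc, state_dc, state_0,
                              params = damping_params("dcs"),
                              damping = c("fermi", "none")) {
  n <- nrow(osc$positions)
  if (n == 1L) {
    return(structure(list(e_dcs = 0, j_dc = 0, j_0 = 0, e_corr = 0,
                          e_dip = 0,
                          pairs = data.frame()),
                     class = "dcs_breakdown"))
  }
  pt <- dcs_pair_terms(osc, state_dc, state_0, params, damping)
  pairs <- data.frame(i = pt$i, j = pt$j, f = pt$f,
                      j_dc = pt$f * pt$j_dc,
                      j_0 = pt$f * pt$j_0,
                      e_corr = pt$f * (pt$vc_dc - pt$j_dc),
                      e_dip = pt$f * pt$vd_dc)
  pairs$e_dcs <- (pairs$j_dc - pairs$j_0) + (pairs$e_corr - pairs$e_dip)
  structure(list(e_dcs = sum(pairs$e_dcs),
                 j_dc = sum(pairs$j_dc), j_0 = sum(pairs$j_0),
                 e_corr = sum(pairs$e_corr), e_dip = sum(pairs$e_dip),
                 pairs = pairs),
            class = "dcs_breakdown")
}

#' @export
print.dcs_breakdown <- function(x, ...) {
  cat("DCS breakdown [Hartree]:\n")
  cat(sprintf("  E_DCS          = %+.10e\n", x$e_dcs))
  cat(sprintf("  J[rho_DC]-J[rho_0] = %+.10e\n", x$j_dc - x$j_0))
  cat(sprintf("  E_corr - E_dip     = %+.10e\n", x$e_corr - x$e_dip))
  invisible(x)
}

# evaluate a function with a temporary RNG seed, restoring global state
with_seed_ <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Monte-Carlo estimate of the damped beyond-dipole expectation
#'
#' Brute-force oracle for [dcs_energy()]: draws Drude displacements from
#' the state's 3N-dimensional Gaussian and averages the damped summand
#' sum over pairs of f_AB (V_Coul(d) - V_dip(d)) evaluated exactly per
#' sample. Reproducible for a fixed seed; the global RNG state is left
#' untouched.
#'
#' @param osc an `oscillator_set`.
#' @param state a `gaussian_state`.
#' @param params `damping_params` (dcs variant by default).
#' @param n number of samples (>= 1000).
#' @param seed integer RNG seed; default 20210108.
#' @param damping "fermi" or "none".
#' @param chunk samples per vectorized block.
#' @return an `mc_estimate`: `mean`, `stderr` (Hartree), `n_samples`, `seed`.
#' @export
mc_expectation <- function(osc, state, params = damping_params("dcs"),
                           n = 1e6, seed = 20210108,
                           damping = c("fermi", "none"), chunk = 1e6) {
  damping <- match.arg(damping)
  if (n < 1e3) stop("use at least 1000 Monte-Carlo samples")
  natom <- nrow(osc$positions)
  L <- tryCatch(chol(state$covariance), error = function(e)
    stop("state covariance not positive definite"))
  pairs <- which(upper.tri(matrix(0, natom, natom)), arr.ind = TRUE)
  prec <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    R <- osc$positions[j, ] - osc$positions[i, ]
    rmod <- sqrt(sum(R * R))
    prec[[k]] <- list(i = i, j = j, R = R, rmod = rmod,
                      qq = osc$charge[i] * osc$charge[j],
                      f = if (damping == "none") 1 else
                        fermi_damping(rmod, osc$r_vdw[i], osc$r_vdw[j],
                                      params),
                      Tdd = dipole_interaction_tensor(R))
  }
  tot <- 0; tot2 <- 0; done <- 0
  with_seed_(seed, {
    while (done < n) {
      m <- min(chunk, n - done)
      d <- matrix(stats::rnorm(m * 3 * natom), m, 3 * natom) %*% L
      v <- numeric(m)
      for (p in prec) {
        ii <- (3 * p$i - 2):(3 * p$i); jj <- (3 * p$j - 2):(3 * p$j)
        dA <- d[, ii, drop = FALSE]; dB <- d[, jj, drop = FALSE]
        nrm <- function(x, y, z) sqrt(x^2 + y^2 + z^2)
        rBn <- nrm(p$R[1] + dB[, 1], p$R[2] + dB[, 2], p$R[3] + dB[, 3])
        rAn <- nrm(p$R[1] - dA[, 1], p$R[2] - dA[, 2], p$R[3] - dA[, 3])
        dd <- dB - dA
        rABn <- nrm(p$R[1] + dd[, 1], p$R[2] + dd[, 2], p$R[3] + dd[, 3])
        vcoul <- p$qq * (1 / p$rmod - 1 / rBn - 1 / rAn + 1 / rABn)
        vdip <- p$qq * rowSums((dA %*% p$Tdd) * dB)
        v <- v + p$f * (vcoul - vdip)
      }
      tot <- tot + sum(v); tot2 <- tot2 + sum(v^2)
      done <- done + m
    }
  })
  mu <- tot / n
  varhat <- max(tot2 / n - mu^2, 0)
  structure(list(mean = mu, stderr = sqrt(varhat / n),
                 n_samples = n, seed = seed),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("MC estimate: %+.8e +/- %.2e Ha (n = %g, seed = %d)\n",
              x$mean, x$stderr, x$n_samples, x$seed))
  invisible(x)
}
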