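# Cache for Gauss-Legendre nodes, keyed by node count.
.gl_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gl_cache[[key]]
}

#' Expectation of the Coulomb kernel over a Gaussian charge cloud
#'
#' Computes K(r, Sigma) = E[1/|r + u|] for u ~ N(0, Sigma): the
#' electrostatic potential at displacement r of a unit Gaussian charge
#' distribution with covariance Sigma. Evaluated through the
#' one-dimensional integral
#' (2/sqrt(pi)) * int_0^inf det(I + 2 t^2 Sigma)^(-1/2)
#'   exp(-t^2 r' (I + 2 t^2 Sigma)^(-1) r) dt,
#' reduced to scalar form in Sigma's eigenbasis. Isotropic covariances
#' take the closed-form path erf(|r|/(sqrt(2) sigma))/|r|.
#'
#' @param r 3-vector (Bohr).
#' @param sigma 3 x 3 symmetric positive semi-definite covariance (Bohr^2).
#' @param rel_tol relative quadrature tolerance (default 1e-10).
#' @return scalar potential (Bohr^-1).
#' @examples
#' gaussian_coulomb_kernel(c(0, 0, 2), 0.25 * diag(3))  # erf(2.8284)/2
#' @export
gaussian_coulomb_kernel <- function(r, sigma, rel_tol = 1e-10) {
  r <- as.numeric(r)
  if (!isSymmetric(unname(sigma), tol = 1e-9))
    stop("covariance must be symmetric")
  es <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  d <- es$values
  if (min(d) < -1e-10 * max(abs(d), 1))
    stop("covariance must be positive semi-definite")
  d <- pmax(d, 0)
  rmod <- sqrt(sum(r * r))
  dmax <- max(d)
  if (dmax <= 0) {                       # point-charge limit
    if (rmod == 0) stop("kernel singular: zero separation and zero spread")
    return(1 / rmod)
  }
  # isotropic closed form when eigenvalue spread is negligible
  if (min(d) > 0 && dmax / min(d) < 1 + 1e-10) {
    s <- sqrt(mean(d))
    if (rmod == 0) return(sqrt(2 / pi) / s)
    return(erf_(rmod / (sqrt(2) * s)) / rmod)
  }
  rt <- as.numeric(crossprod(es$vectors, r))   # r in Sigma's eigenbasis
  scale <- 1 / sqrt(rmod^2 + 2 * dmax)         # integrand width in t
  integrand <- function(s) {
    t <- scale * s / (1 - s)
    jac <- scale / (1 - s)^2
    t2 <- t^2
    den <- 1 + 2 * outer(t2, d)                # m x 3
    detf <- 1 / sqrt(den[, 1] * den[, 2] * den[, 3])
    expo <- t2 * ((rt[1]^2 / den[, 1]) + (rt[2]^2 / den[, 2]) +
                    (rt[3]^2 / den[, 3]))
    detf * exp(-expo) * jac
  }
  prev <- NA_real_
  n <- 64L
  repeat {
    gl <- gl_nodes(n)
    val <- (2 / sqrt(pi)) * sum(gl$w * integrand(gl$x))
    if (!is.na(prev) && abs(val - prev) <= rel_tol * abs(val)) return(val)
    if (n >= 16384L)
      stop(sprintf(paste0("Gaussian-Coulomb quadrature did not converge: ",
                          "achieved relative change %.3e at %d nodes"),
                   abs(val - prev) / abs(val), n))
    prev <- val
    n <- n * 2L
  }
}

# error function via pnorm
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
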