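# Fluctuation-density analysis: real-space density of the Drude clouds,
# density differences, and the displaced-charge descriptor.

#' Define a regular orthorhombic density grid
#'
#' @param osc an `oscillator_set` the grid must enclose, or NULL when
#'   `origin` and `npts` are given explicitly.
#' @param spacing voxel edge (Bohr), default 0.25.
#' @param padding margin beyond the atoms (Bohr); NULL takes
#'   max(6, 5 * sigma_max) with sigma_max the largest uncoupled cloud
#'   standard deviation, so that the clouds are captured to well below
#'   the 0.1% integration tolerance.
#' @param origin,npts explicit lower corner (Bohr) and point counts
#'   (length-3 integer), overriding the automatic box.
#' @return a `density_grid` without values: `origin`, `spacing`, `npts`.
#' @export
density_grid_spec <- function(osc = NULL, spacing = 0.25, padding = NULL,
                              origin = NULL, npts = NULL) {
  if (spacing <= 0) stop("grid spacing must be positive")
  if (is.null(origin) || is.null(npts)) {
    stopifnot(inherits(osc, "oscillator_set"))
    if (is.null(padding)) {
      sig_max <- sqrt(max(osc$alpha * osc$omega / 2))
      padding <- max(6, 5 * sig_max)
    }
    lo <- apply(osc$positions, 2, min) - padding
    hi <- apply(osc$positions, 2, max) + padding
    npts <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    ctr <- (hi + lo) / 2
    origin <- ctr - (npts - 1) * spacing / 2
  }
  npts <- as.integer(npts)
  stopifnot(length(origin) == 3, length(npts) == 3, all(npts >= 2))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 npts = npts, values = NULL),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("density_grid:", paste(x$npts, collapse = " x "),
      "points, spacing", x$spacing, "Bohr\n")
  if (!is.null(x$values))
    cat(sprintf("  integral = %.6f e, displaced charge = %.6f e\n",
                grid_integral(x), displaced_charge(x)))
  invisible(x)
}

grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$npts[a]) - 1) * grid$spacing)
}

#' Integral of a density grid
#' @param grid a `density_grid` with values.
#' @return sum(values) * voxel volume (e).
#' @export
grid_integral <- function(grid) sum(grid$values) * grid$spacing^3

#' Density of electronic fluctuations on a grid
#'
#' Rasterizes the cloud part of the mean charge density of a Gaussian
#' oscillator state: rho(r) = -sum_i q_i N(r; R_i, Sigma_ii), with
#' Sigma_ii the per-atom marginal covariance. Nuclear point charges are
#' not rasterized (they cancel identically in all density differences).
#' The grid integral is checked against -sum(q) to 0.1%.
#'
#' @param osc an `oscillator_set`.
#' @param state a `gaussian_state` for the same set.
#' @param grid a `density_grid` spec; default built from `osc`.
#' @param check_capture validate the integrated charge (default TRUE).
#' @return the `density_grid` with `values` filled (e / Bohr^3).
#' @export
fluctuation_density <- function(osc, state, grid = density_grid_spec(osc),
                                check_capture = TRUE) {
  ax <- grid_axes(grid)
  nx <- grid$npts[1]; ny <- grid$npts[2]; nz <- grid$npts[3]
  rho <- array(0, c(nx, ny, nz))
  for (i in seq_len(nrow(osc$positions))) {
    S <- covariance_block(state, i)
    P <- solve(S)
    dx <- ax[[1]] - osc$positions[i, 1]
    dy <- ax[[2]] - osc$positions[i, 2]
    dz <- ax[[3]] - osc$positions[i, 3]
    Q <- outer(outer(P[1, 1] * dx^2, P[2, 2] * dy^2, "+"), P[3, 3] * dz^2,
               "+")
    Q <- Q + outer(2 * P[1, 2] * outer(dx, dy), rep(1, nz))
    Q <- Q + outer(outer(dx, rep(1, ny)), 2 * P[1, 3] * dz)
    Q <- Q + outer(outer(rep(1, nx), dy), 2 * P[2, 3] * dz)
    norm <- sqrt(det(P)) / (2 * pi)^1.5
    rho <- rho - osc$charge[i] * norm * exp(-Q / 2)
  }
  grid$values <- rho
  if (check_capture) {
    want <- -sum(osc$charge)
    got <- grid_integral(grid)
    if (abs(got - want) > 1e-3 * abs(want))
      stop(sprintf(paste0("grid too small: captured %.4f%% of the cloud ",
                          "charge (integral %.6f vs %.6f)"),
                   100 * got / want, got, want))
  }
  grid
}

#' Difference of densities on a common grid
#'
#' Computes `complex` minus the sum of `monomers`, all on identical grid
#' geometry. With fluctuation-density differences
#' (rho_DC - rho_0) as inputs this gives the change in the density of
#' electronic fluctuations upon complexation.
#'
#' @param complex a `density_grid` with values.
#' @param monomers a single `density_grid` or list of them.
#' @return a `density_grid` with the difference values.
#' @export
delta_rho <- function(complex, monomers) {
  if (inherits(monomers, "density_grid")) monomers <- list(monomers)
  out <- complex
  for (m in monomers) {
    if (!isTRUE(all.equal(m$origin, complex$origin)) ||
        !isTRUE(all.equal(m$spacing, complex$spacing)) ||
        !identical(m$npts, complex$npts))
      stop("grid geometry mismatch in delta_rho")
    out$values <- out$values - m$values
  }
  out
}

#' Dipole-coupling-induced density change of one system
#'
#' Convenience wrapper: rho_DC - rho_0 for a single oscillator set, i.e.
#' the polarization of the fluctuation density induced by dipole coupling.
#'
#' @param osc an `oscillator_set`.
#' @param grid a `density_grid` spec; default built from `osc`.
#' @param params `damping_params` for the dipole coupling.
#' @param damping "fermi" or "none".
#' @return a `density_grid` of rho_DC - rho_0.
#' @export
coupling_density_change <- function(osc, grid = density_grid_spec(osc),
                                    params = damping_params("mbd"),
                                    damping = c("fermi", "none")) {
  damping <- match.arg(damping)
  st_dc <- ground_state(osc, correlated = TRUE, params = params,
                        damping = damping)
  st_0 <- ground_state(osc, correlated = FALSE)
  delta_rho(fluctuation_density(osc, st_dc, grid),
            fluctuation_density(osc, st_0, grid))
}

#' Displaced charge
#'
#' Integral of the absolute density difference over the grid; a
#' descriptor that tracks the magnitude of the DCS contribution.
#'
#' @param grid a `density_grid` with values (normally a density
#'   difference).
#' @return non-negative scalar (e).
#' @export
displaced_charge <- function(grid) {
  if (is.null(grid$values)) stop("grid has no values")
  sum(abs(grid$values)) * grid$spacing^3
}

element_z <- function(sym) {
  z <- c(H = 1, He = 2, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
         P = 15, S = 16, Cl = 17, Ar = 18, Kr = 36, Xe = 54)
  out <- unname(z[sym])
  out[is.na(out)] <- 0
  out
}

#' Write a density grid as a Gaussian cube file
#'
#' Standard cube layout: two comment lines, atom count and grid origin,
#' three axis records, atom records, then values with the z index
#' running fastest. Lengths in Bohr (positive point counts signal atomic
#' units per the cube convention).
#'
#' @param grid a `density_grid` with values.
#' @param osc the `oscillator_set` the density belongs to (atom records).
#' @param path output path.
#' @param comment second header line; the customary iso-surface level for
#'   fluctuation-density differences is +/-0.003 a.u.
#' @return invisibly, `path`.
#' @export
write_cube <- function(grid, osc, path,
                       comment = "iso-surface level +/-0.003 a.u.") {
  if (is.null(grid$values)) stop("grid has no values")
  n <- nrow(osc$positions)
  zn <- if (is.null(osc$elements)) rep(0L, n) else element_z(osc$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("fluctuation charge density (e/Bohr^3)", comment), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", n, grid$origin[1],
                     grid$origin[2], grid$origin[3]), con)
  for (a in 1:3) {
    v <- c(0, 0, 0); v[a] <- grid$spacing
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$npts[a],
                       v[1], v[2], v[3]), con)
  }
  for (i in seq_len(n))
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", zn[i], zn[i],
                       osc$positions[i, 1], osc$positions[i, 2],
                       osc$positions[i, 3]), con)
  # z fastest, then y, then x
  for (ix in seq_len(grid$npts[1])) for (iy in seq_len(grid$npts[2])) {
    row <- grid$values[ix, iy, ]
    for (k in seq(1, length(row), by = 6))
      writeLines(paste(sprintf("%13.5e", row[k:min(k + 5, length(row))]),
                       collapse = " "), con)
  }
  invisible(path)
}
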