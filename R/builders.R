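# Programmatic structure builders: hydrogen-capped armchair nanotubes,
# encapsulated guests, and toy oscillator fixtures.

#' Build a hydrogen-capped armchair carbon nanotube
#'
#' Rolls an armchair graphene strip onto a cylinder with the tube axis
#' along z. The carbon radius follows the chiral-index formula
#' d = (sqrt(3) a_CC / pi) sqrt(n^2 + n m + m^2) with m = n, i.e.
#' d = 3 n a_CC / pi. Atom pairs are placed so that every C-C chord on
#' the cylinder is exactly `a_cc`: the in-pair half-angle is
#' asin(a_cc/d) and the ring spacing h solves the diagonal-bond length.
#' Rim carbons are terminated with hydrogens along the direction of the
#' missing sp2 neighbour.
#'
#' @param n armchair chiral index (m = n >= 3).
#' @param length target tube length (Angstrom); realized as the largest
#'   whole number of unit cells (2 carbon rings) fitting the target.
#' @param a_cc C-C bond length (Angstrom), default 1.42.
#' @param c_h C-H bond length for the caps (Angstrom), default 1.09.
#' @param cap terminate rim carbons with H (default TRUE).
#' @return a `geometry` centred at the origin, tube axis z; attribute
#'   `actual_length` gives the realized carbon-to-carbon length.
#' @examples
#' tube <- build_armchair_cnt(5, length = 30)
#' cnt_diameter(tube)  # 6.78 Angstrom
#' @export
build_armchair_cnt <- function(n, length = 30, a_cc = 1.42, c_h = 1.09,
                               cap = TRUE) {
  if (n < 3) stop("armchair index must be >= 3")
  if (length <= 0 || a_cc <= 0 || c_h <= 0)
    stop("lengths must be positive")
  radius <- 3 * n * a_cc / (2 * pi)
  delta <- asin(a_cc / (2 * radius))           # in-pair half-angle
  dth <- pi / n - 2 * delta                    # inter-row angular offset
  chord <- 2 * radius * sin(dth / 2)
  h2 <- a_cc^2 - chord^2
  if (h2 <= 0) stop("tube too narrow for the requested bond length")
  h <- sqrt(h2)                                # ring spacing
  n_cells <- floor(length / (2 * h))
  if (n_cells < 1) stop("target length shorter than one unit cell")
  n_rows <- 2L * n_cells
  atom_angle <- function(row, k, side) {       # side = +/-1
    offs <- if (row %% 2 == 0) 0 else pi / n
    k * 2 * pi / n + offs + side * delta
  }
  rows <- seq_len(n_rows) - 1L
  z0 <- (n_rows - 1) * h / 2
  ang <- c(); zz <- c(); side <- c(); rowid <- c()
  for (r in rows) for (k in seq_len(n) - 1L) for (s in c(-1, 1)) {
    ang <- c(ang, atom_angle(r, k, s)); zz <- c(zz, r * h - z0)
    side <- c(side, s); rowid <- c(rowid, r)
  }
  cart <- cbind(radius * cos(ang), radius * sin(ang), zz)
  elements <- rep("C", nrow(cart))
  if (cap) {
    hpos <- NULL
    for (idx in which(rowid == 0 | rowid == n_rows - 1)) {
      up <- if (rowid[idx] == n_rows - 1) 1 else -1
      a_ph <- ang[idx] + side[idx] * dth       # phantom neighbour angle
      ph <- c(radius * cos(a_ph), radius * sin(a_ph), zz[idx] + up * h)
      dir <- ph - cart[idx, ]
      dir <- dir / sqrt(sum(dir^2))
      hpos <- rbind(hpos, cart[idx, ] + c_h * dir)
    }
    cart <- rbind(cart, hpos)
    elements <- c(elements, rep("H", nrow(hpos)))
  }
  g <- geometry(elements, cart)
  attr(g, "actual_length") <- (n_rows - 1) * h
  g
}

#' Carbon-ring diameter of a nanotube geometry
#'
#' Maximum-extent diameter through carbon centres, measured from the
#' tube axis (z).
#'
#' @param geom a `geometry` with the tube axis along z.
#' @return diameter (Angstrom).
#' @export
cnt_diameter <- function(geom) {
  carbon <- geom$elements == "C"
  if (!any(carbon)) stop("no carbon atoms in geometry")
  2 * max(sqrt(rowSums(geom$coordinates[carbon, 1:2, drop = FALSE]^2)))
}

#' Place guest atoms on the axis of a host structure
#'
#' Centres `elements` guests on the tube axis (z), symmetric about the
#' host midpoint, with the stated separation. Fragment labels are set to
#' "host", "guestA", "guestB", ...
#'
#' @param host a `geometry` (tube axis along z).
#' @param elements character vector of guest element symbols (usually 2).
#' @param separation axial guest-guest spacing (Angstrom).
#' @return combined `geometry` with fragment labels.
#' @export
place_guests <- function(host, elements = c("Xe", "Xe"), separation) {
  if (separation < 0) stop("separation must be non-negative")
  k <- length(elements)
  zmid <- mean(range(host$coordinates[, 3]))
  zs <- zmid + (seq_len(k) - (k + 1) / 2) * separation
  zr <- range(host$coordinates[, 3])
  if (any(zs < zr[1]) || any(zs > zr[2]))
    stop("guest outside the host cavity")
  guests <- geometry(elements, cbind(0, 0, zs),
                     labels = paste0("guest", LETTERS[seq_len(k)]))
  hostl <- geometry(host$elements, host$coordinates, host$hirshfeld_ratios,
                    labels = rep("host", n_atoms(host)))
  combine_geometries(hostl, guests)
}

embedded_body_positions <- function(distance, internal_separation,
                                    orientation) {
  s <- internal_separation / 2
  if (orientation == "collinear")
    cbind(0, 0, c(-distance / 2 - s, -distance / 2 + s,
                  distance / 2 - s, distance / 2 + s))
  else
    rbind(c(-s, 0, -distance / 2), c(s, 0, -distance / 2),
          c(-s, 0, distance / 2), c(s, 0, distance / 2))
}

#' Embedded-body fixture
#'
#' Two rigid two-atom "bodies" separated along the z axis, each with a
#' fixed internal separation, the centre of mass at the origin.
#' Distances are taken in Bohr (the natural scale for toy oscillator
#' fixtures) and converted to Angstrom for the geometry container. Used
#' to probe body-body interaction asymptotics: within each body the
#' dipole correlation induces a permanent quadrupole, so the classical
#' part of the beyond-dipole interaction between bodies decays as R^-5
#' while the MBD interaction decays as R^-6. With `orientation =
#' "collinear"` the body axes lie along the separation axis; with
#' `"transverse"` they are perpendicular to it, which keeps the
#' apparent decay exponents free of odd (d/R) finite-size corrections
#' inside a finite fit window.
#'
#' @param distance body-centre to body-centre distance (Bohr).
#' @param internal_separation intra-body atom spacing (Bohr), default 4.
#' @param orientation "collinear" (default) or "transverse".
#' @param element element symbol for all four atoms, default "Ar".
#' @return a `geometry` with fragment labels "body1"/"body2".
#' @export
build_embedded_body_fixture <- function(distance, internal_separation = 4,
                                        orientation = c("collinear",
                                                        "transverse"),
                                        element = "Ar") {
  orientation <- match.arg(orientation)
  if (distance <= internal_separation)
    stop("body-body distance must exceed the internal separation")
  pos <- embedded_body_positions(distance, internal_separation, orientation)
  geometry(rep(element, 4), pos * units_au$angstrom_per_bohr,
           labels = c("body1", "body1", "body2", "body2"))
}

#' Embedded-body fixture as a toy oscillator set
#'
#' Same geometry as [build_embedded_body_fixture()] but parametrized
#' directly with toy oscillator values in atomic units. The defaults
#' (alpha = 6 Bohr^3, omega = 0.15 Ha) give compact Drude clouds
#' (sigma ~ 0.67 Bohr at the 4 Bohr internal separation), which keeps
#' the overlap-driven intra-body beyond-dipole terms small so that the
#' induced-quadrupole R^-5 channel dominates the body-body DCS
#' interaction within a finite distance window.
#'
#' @inheritParams build_embedded_body_fixture
#' @param alpha,omega,r_vdw per-atom toy parameters (Bohr^3, Ha, Bohr).
#' @return an `oscillator_set` with labels "body1"/"body2".
#' @export
embedded_body_oscillators <- function(distance, internal_separation = 4,
                                      orientation = c("collinear",
                                                      "transverse"),
                                      alpha = 6, omega = 0.15, r_vdw = 3) {
  orientation <- match.arg(orientation)
  if (distance <= internal_separation)
    stop("body-body distance must exceed the internal separation")
  pos <- embedded_body_positions(distance, internal_separation, orientation)
  oscillator_set(pos, rep(alpha, 4), rep(omega, 4), rep(r_vdw, 4),
                 labels = c("body1", "body1", "body2", "body2"))
}

#' Generate a sweep of embedded-body fixtures
#'
#' @param distances strictly increasing body-body distances (Bohr).
#' @inheritParams build_embedded_body_fixture
#' @return list of `geometry` objects.
#' @export
embedded_body_sweep <- function(distances, internal_separation = 4,
                                orientation = "collinear",
                                element = "Ar") {
  if (any(diff(distances) <= 0))
    stop("distances must be strictly increasing")
  lapply(distances, build_embedded_body_fixture,
         internal_separation = internal_separation,
         orientation = orientation, element = element)
}

#' Toy oscillator tube with axial guests
#'
#' Stacked rings of identical host oscillators forming a finite open
#' tube along z (rings alternately rotated by half an angular step),
#' plus two guest oscillators on the axis, symmetric about the origin.
#' A desk-scale stand-in for guests confined in a nanotube: the host
#' screens the guest-guest dispersion and mediates a beyond-dipole
#' (DCS) repulsion. Defaults use compact clouds (small alpha*omega) so
#' that cloud-overlap terms do not mask the confinement physics.
#'
#' @param guest_separation axial guest-guest distance (Bohr).
#' @param n_ring oscillators per ring (default 6).
#' @param radius ring radius (Bohr, default 5).
#' @param n_rings number of rings (default 5).
#' @param ring_spacing axial ring spacing (Bohr, default 3.5).
#' @param alpha_host,omega_host,r_vdw_host host parameters.
#' @param alpha_guest,omega_guest,r_vdw_guest guest parameters.
#' @return an `oscillator_set` with labels "host"/"guestA"/"guestB".
#' @export
build_oscillator_tube <- function(guest_separation, n_ring = 6, radius = 5,
                                  n_rings = 5, ring_spacing = 3.5,
                                  alpha_host = 6, omega_host = 0.15,
                                  r_vdw_host = 3,
                                  alpha_guest = 10, omega_guest = 0.12,
                                  r_vdw_guest = 3.5) {
  th <- (seq_len(n_ring) - 1) * 2 * pi / n_ring
  pos <- NULL
  for (j in seq_len(n_rings)) {
    off <- if (j %% 2 == 0) pi / n_ring else 0
    pos <- rbind(pos, cbind(radius * cos(th + off), radius * sin(th + off),
                            (j - (n_rings + 1) / 2) * ring_spacing))
  }
  nh <- nrow(pos)
  pos <- rbind(pos, c(0, 0, -guest_separation / 2),
               c(0, 0, guest_separation / 2))
  oscillator_set(pos,
                 c(rep(alpha_host, nh), rep(alpha_guest, 2)),
                 c(rep(omega_host, nh), rep(omega_guest, 2)),
                 c(rep(r_vdw_host, nh), rep(r_vdw_guest, 2)),
                 labels = c(rep("host", nh), "guestA", "guestB"))
}

#' Toy oscillator ring with axial guests
#'
#' A ring of identical oscillators in the xy plane (the confining
#' "host") plus optional guest oscillators on the z axis, symmetric
#' about the origin. Parameters are given directly in atomic units,
#' bypassing the element table; useful for controlled studies of
#' confinement effects.
#'
#' @param n_ring number of host oscillators (default 8).
#' @param radius ring radius (Bohr).
#' @param guest_separation axial guest-guest distance (Bohr); NULL for a
#'   bare ring.
#' @param alpha_host,omega_host,r_vdw_host host oscillator parameters
#'   (Bohr^3, Hartree, Bohr).
#' @param alpha_guest,omega_guest,r_vdw_guest guest parameters.
#' @param central_atom add one host-type oscillator at the origin.
#' @return an `oscillator_set` with labels "host"/"guestA"/"guestB".
#' @export
build_oscillator_ring <- function(n_ring = 8, radius,
                                  guest_separation = NULL,
                                  alpha_host = 6, omega_host = 0.5,
                                  r_vdw_host = 3,
                                  alpha_guest = 10, omega_guest = 0.4,
                                  r_vdw_guest = 3.5,
                                  central_atom = FALSE) {
  if (radius <= 0) stop("ring radius must be positive")
  th <- (seq_len(n_ring) - 1) * 2 * pi / n_ring
  pos <- cbind(radius * cos(th), radius * sin(th), 0)
  lab <- rep("host", n_ring)
  alpha <- rep(alpha_host, n_ring)
  omega <- rep(omega_host, n_ring)
  rv <- rep(r_vdw_host, n_ring)
  if (central_atom) {
    pos <- rbind(pos, c(0, 0, 0)); lab <- c(lab, "guestA")
    alpha <- c(alpha, alpha_guest); omega <- c(omega, omega_guest)
    rv <- c(rv, r_vdw_guest)
  }
  if (!is.null(guest_separation)) {
    pos <- rbind(pos, c(0, 0, -guest_separation / 2),
                 c(0, 0, guest_separation / 2))
    lab <- c(lab, "guestA", "guestB")
    alpha <- c(alpha, rep(alpha_guest, 2))
    omega <- c(omega, rep(omega_guest, 2))
    rv <- c(rv, rep(r_vdw_guest, 2))
  }
  oscillator_set(pos, alpha, omega, rv, labels = lab)
}
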