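# Geometric and energetic descriptors for host-guest complexes.

pair_distances <- function(a, b) {
  # all distances between rows of a and rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Proximity measure f_d
#'
#' Sum of inverse distances between every guest atom and every host atom.
#'
#' @param guest,host `geometry` objects (or N x 3 coordinate matrices)
#'   with disjoint atoms.
#' @return scalar (inverse-length units of the coordinates).
#' @export
proximity_fd <- function(guest, host) {
  inverse_distance_sum(guest, host, power = 1)
}

#' Inverse-distance-power sum between two fragments
#'
#' @inheritParams proximity_fd
#' @param power positive exponent p in sum(1/R^p).
#' @return scalar.
#' @export
inverse_distance_sum <- function(guest, host, power = 1) {
  ga <- if (inherits(guest, "geometry")) guest$coordinates else as.matrix(guest)
  ha <- if (inherits(host, "geometry")) host$coordinates else as.matrix(host)
  if (nrow(ga) == 0 || nrow(ha) == 0) stop("fragments must be non-empty")
  d <- pair_distances(ga, ha)
  if (any(d == 0)) stop("overlapping atoms between fragments")
  sum(1 / d^power)
}

#' Quadrupole-like R^-5 proximity metric
#'
#' Sum of inverse fifth powers of guest-host atom distances; resembles
#' the interaction of quadrupoles induced by long-range correlation and
#' is the best simple geometric proxy for the DCS contribution.
#'
#' @inheritParams proximity_fd
#' @return scalar.
#' @export
r5_metric <- function(guest, host) {
  inverse_distance_sum(guest, host, power = 5)
}

principal_axis <- function(coords) {
  ctr <- colMeans(coords)
  x <- sweep(coords, 2, ctr)
  inertia <- sum(rowSums(x^2)) * diag(3) - crossprod(x)
  es <- eigen(inertia, symmetric = TRUE)
  ev <- es$values  # decreasing; elongation axis has the smallest moment
  if (abs(ev[2] - ev[3]) <= 1e-6 * max(abs(ev), 1))
    stop("guest principal axis ambiguous: degenerate inertia moments")
  list(axis = es$vectors[, 3], center = ctr)
}

#' Axial-radial asymmetry descriptor f_a
#'
#' Splits the host's ring units into an "axial" and a "radial" half by
#' their centroid distance to the P_v plane -- the plane containing the
#' guest's elongated principal axis (smallest inertia moment) and
#' perpendicular to the mean plane of the ring-unit centroids. Axial and
#' radial vicinities A_par and A_perp are guest-to-unit inverse-distance
#' sums (atom to atom), and f_a = (A_par - A_perp)/(A_par + A_perp).
#'
#' @param guest a `geometry` (or coordinate matrix) of the guest.
#' @param host_units list of `geometry` objects (or coordinate
#'   matrices), one per ring unit; the count must be even and >= 2.
#' @return list with `A_par`, `A_perp`, `f_a`, `axial` (unit indices).
#' @export
axial_radial_asymmetry <- function(guest, host_units) {
  k <- length(host_units)
  if (k < 2 || k %% 2 != 0)
    stop("need an even number (>= 2) of host ring units")
  gc <- if (inherits(guest, "geometry")) guest$coordinates else
    as.matrix(guest)
  unit_coords <- lapply(host_units, function(u)
    if (inherits(u, "geometry")) u$coordinates else as.matrix(u))
  centroids <- do.call(rbind, lapply(unit_coords, colMeans))
  pa <- principal_axis(gc)
  # host-ring mean plane: normal = least-variance direction of centroids
  cc <- sweep(centroids, 2, colMeans(centroids))
  n_host <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 3]
  n_p <- pracma::cross(pa$axis, n_host)
  nrm <- sqrt(sum(n_p^2))
  if (nrm < 1e-8)
    stop("guest axis parallel to host-plane normal: P_v plane undefined")
  n_p <- n_p / nrm
  dist_to_plane <- abs(as.numeric(sweep(centroids, 2, pa$center) %*% n_p))
  axial <- order(dist_to_plane)[seq_len(k / 2)]
  a_par <- sum(vapply(axial, function(u)
    inverse_distance_sum(gc, unit_coords[[u]]), 0))
  a_perp <- sum(vapply(setdiff(seq_len(k), axial), function(u)
    inverse_distance_sum(gc, unit_coords[[u]]), 0))
  list(A_par = a_par, A_perp = a_perp,
       f_a = (a_par - a_perp) / (a_par + a_perp), axial = sort(axial))
}

#' Relative DCS contribution f_e
#'
#' Ratio of each system's DCS energy to that of a reference system.
#'
#' @param e_dcs named numeric vector of DCS energies.
#' @param reference name (or index) of the reference entry.
#' @return named vector of signed ratios; 1 for the reference.
#' @export
relative_dcs <- function(e_dcs, reference) {
  ref <- e_dcs[[reference]]
  if (!is.finite(ref) || ref == 0)
    stop("reference DCS energy must be nonzero")
  e_dcs / ref
}

#' Full descriptor set for a labeled complex
#'
#' @param geom a `geometry` with fragment labels.
#' @param guest_frag label of the guest fragment.
#' @param ring_frags character vector of ring-unit labels (even count)
#'   for the asymmetry measure; NULL skips f_a.
#' @param host_frags labels forming the host for f_d and the R^-5
#'   metric; default everything that is not the guest.
#' @return list with `f_d`, `r5`, and (when ring units are given)
#'   `A_par`, `A_perp`, `f_a`.
#' @export
descriptor_set <- function(geom, guest_frag = "guest", ring_frags = NULL,
                           host_frags = NULL) {
  if (is.null(geom$labels)) stop("geometry has no fragment labels")
  guest <- subset_geometry(geom, guest_frag)
  if (is.null(host_frags))
    host_frags <- setdiff(unique(geom$labels), guest_frag)
  host <- subset_geometry(geom, host_frags)
  out <- list(f_d = proximity_fd(guest, host), r5 = r5_metric(guest, host))
  if (!is.null(ring_frags)) {
    units <- lapply(ring_frags, function(l) subset_geometry(geom, l))
    out <- c(out, axial_radial_asymmetry(guest, units)[c("A_par", "A_perp",
                                                         "f_a")])
  }
  out
}
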