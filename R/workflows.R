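# End-to-end workflows: fragment-based interaction energies, binding
# scans, decay-exponent fits and structured reports.

method_energies <- function(osc, methods, params_mbd, params_dcs, damping) {
  out <- list()
  n <- nrow(osc$positions)
  if (n == 0L) return(lapply(stats::setNames(methods, methods),
                             function(m) 0))
  need_mbd <- any(c("mbd", "mbd+dcs") %in% methods)
  need_dcs <- any(c("dcs", "mbd+dcs") %in% methods)
  e_mbd <- e_dcs <- 0
  if (n > 1L) {
    spec <- solve_modes(interaction_matrix(osc, params_mbd, damping),
                        osc$omega)
    if (need_mbd)
      e_mbd <- sum(spec$omega_dc) / 2 - 3 * sum(osc$omega) / 2
    if (need_dcs) {
      st_dc <- ground_state(osc, spec)
      st_0 <- ground_state(osc, correlated = FALSE)
      e_dcs <- dcs_energy(osc, st_dc, st_0, params_dcs, damping)
    }
  }
  for (m in methods)
    out[[m]] <- switch(m, mbd = e_mbd, dcs = e_dcs,
                       `mbd+dcs` = e_mbd + e_dcs)
  out
}

#' Fragment-based interaction energy
#'
#' Computes the host-mediated guest-guest interaction
#' E_int = E(host + all guests) + E(host) - sum_g E(host + g)
#' per method, each subsystem re-solved with its own modes and states
#' but the same per-atom oscillator parameters as the full system. With
#' an empty host this reduces to the plain dimer formula
#' E(AB) - E(A) - E(B).
#'
#' @param osc a labeled `oscillator_set` (fragment labels required).
#' @param guests character vector of guest fragment labels; default all
#'   labels starting with "guest".
#' @param host_label label(s) of the host fragment; fragments carrying
#'   these labels may be absent (vacuum dimer).
#' @param methods subset of c("mbd", "dcs", "mbd+dcs").
#' @param params_mbd,params_dcs damping parameter sets.
#' @param damping "fermi" or "none".
#' @return named list of interaction energies (Hartree), one per method.
#' @export
interaction_energy <- function(osc, guests = NULL, host_label = "host",
                               methods = c("mbd", "dcs", "mbd+dcs"),
                               params_mbd = damping_params("mbd"),
                               params_dcs = damping_params("dcs"),
                               damping = c("fermi", "none")) {
  damping <- match.arg(damping)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(osc$labels)) stop("oscillator set has no fragment labels")
  if (is.null(guests))
    guests <- sort(unique(osc$labels[startsWith(osc$labels, "guest")]))
  known <- c(host_label, guests)
  if (!all(osc$labels %in% known))
    stop("fragment labels do not cover all atoms: ",
         paste(setdiff(unique(osc$labels), known), collapse = ", "))
  if (length(unique(osc$labels)) == 1L)   # single fragment: nothing interacts
    return(lapply(stats::setNames(methods, methods), function(m) 0))
  host_idx <- osc$labels %in% host_label
  sub_energy <- function(sel, name) {
    if (!any(sel))
      return(lapply(stats::setNames(methods, methods), function(m) 0))
    tryCatch(
      method_energies(subset_oscillators(osc, sel), methods,
                      params_mbd, params_dcs, damping),
      error = function(e)
        stop(sprintf("subsystem '%s': %s", name, conditionMessage(e))))
  }
  e_full <- sub_energy(rep(TRUE, length(osc$labels)), "full")
  e_host <- sub_energy(host_idx, "host")
  e_hg <- lapply(guests, function(g)
    sub_energy(host_idx | osc$labels == g, paste0("host+", g)))
  if (length(guests) == 1L) {     # host-guest binding: E(full)-E(host)-E(g)
    e_g <- sub_energy(osc$labels == guests, guests)
    return(lapply(stats::setNames(methods, methods), function(m)
      e_full[[m]] - e_host[[m]] - e_g[[m]]))
  }
  lapply(stats::setNames(methods, methods), function(m) {
    e_full[[m]] + (length(guests) - 1) * e_host[[m]] -
      sum(vapply(e_hg, function(x) x[[m]], 0))
  })
}

#' Binding-curve scan over guest separations
#'
#' Evaluates MBD, DCS and their sum for a family of systems generated by
#' `builder(R)` over a monotone separation grid, via
#' [interaction_energy()].
#'
#' @param builder function taking one separation value and returning a
#'   labeled `oscillator_set` (see [vacuum_dimer_builder()],
#'   [cnt_guest_builder()], or a closure over [build_oscillator_ring()]).
#' @param separations strictly increasing separations; units are
#'   whatever `builder` expects (Angstrom for geometry-based builders,
#'   Bohr for toy fixtures).
#' @param ... passed to [interaction_energy()].
#' @return a `binding_curve` data frame with columns `separation`,
#'   `e_mbd`, `e_dcs`, `e_vdw` (kJ/mol), `ratio` = |e_dcs/e_mbd|, and
#'   Hartree columns `e_mbd_ha`, `e_dcs_ha`.
#' @export
binding_scan <- function(builder, separations, ...) {
  if (any(diff(separations) <= 0))
    stop("separations must be strictly increasing")
  rows <- vector("list", length(separations))
  failed <- character()
  for (k in seq_along(separations)) {
    R <- separations[k]
    rows[[k]] <- tryCatch({
      e <- interaction_energy(builder(R), ...)
      data.frame(separation = R, e_mbd_ha = e$mbd, e_dcs_ha = e$dcs)
    }, error = function(err) {
      failed <<- c(failed, sprintf("R = %g (%s)", R, conditionMessage(err)))
      NULL
    })
  }
  if (length(failed) > 0)
    stop("binding scan failed at: ", paste(failed, collapse = "; "))
  out <- do.call(rbind, rows)
  out$e_mbd <- out$e_mbd_ha * units_au$kjmol_per_hartree
  out$e_dcs <- out$e_dcs_ha * units_au$kjmol_per_hartree
  out$e_vdw <- out$e_mbd + out$e_dcs
  out$ratio <- ifelse(out$e_mbd_ha != 0, abs(out$e_dcs_ha / out$e_mbd_ha),
                      NA_real_)
  class(out) <- c("binding_curve", class(out))
  out
}

#' Builder for a vacuum guest dimer
#'
#' @param element guest element symbol.
#' @param alpha_scale polarizability scaling applied to the guests.
#' @param table free-atom reference table.
#' @return function(R_angstrom) -> labeled `oscillator_set`.
#' @export
vacuum_dimer_builder <- function(element = "Xe", alpha_scale = 1,
                                 table = load_free_atom_table()) {
  function(R) {
    g <- geometry(rep(element, 2), cbind(0, 0, c(-R / 2, R / 2)),
                  labels = c("guestA", "guestB"))
    parametrize(g, table, alpha_scale)
  }
}

#' Builder for guests encapsulated in a host structure
#'
#' The polarizability scaling applies to the guest atoms only,
#' mirroring response-property studies such as increasing the Xe
#' polarizability by 50%.
#'
#' @param host a `geometry` host (e.g. from [build_armchair_cnt()]).
#' @param elements guest element symbols.
#' @param alpha_scale_guest polarizability scaling for guest atoms.
#' @param table free-atom reference table.
#' @return function(R_angstrom) -> labeled `oscillator_set`.
#' @export
cnt_guest_builder <- function(host, elements = c("Xe", "Xe"),
                              alpha_scale_guest = 1,
                              table = load_free_atom_table()) {
  function(R) {
    g <- place_guests(host, elements, R)
    s <- ifelse(startsWith(g$labels, "guest"), alpha_scale_guest, 1)
    parametrize(g, table, s)
  }
}

#' Body-body interaction curve for the embedded-body fixture
#'
#' For each body-body distance, evaluates the MBD and DCS body-body
#' interaction Delta E(R) = E(both bodies) - E(body1) - E(body2) using
#' [embedded_body_oscillators()]. The isolated-body energies are
#' distance-independent and computed once. Coupling is undamped by
#' default, the clean setting for asymptotic-exponent analysis.
#'
#' @param distances strictly increasing body-body distances (Bohr).
#' @param orientation "collinear" or "transverse".
#' @param damping "none" (default) or "fermi".
#' @param ... passed to [embedded_body_oscillators()].
#' @return data frame with columns `distance`, `de_mbd`, `de_dcs`
#'   (Hartree).
#' @export
embedded_body_curve <- function(distances, orientation = "transverse",
                                damping = c("none", "fermi"), ...) {
  damping <- match.arg(damping)
  if (any(diff(distances) <= 0))
    stop("distances must be strictly increasing")
  e_both <- function(o) {
    st_dc <- ground_state(o, damping = damping)
    st_0 <- ground_state(o, correlated = FALSE)
    c(mbd = mbd_energy(o, damping = damping),
      dcs = dcs_energy(o, st_dc, st_0, damping = damping))
  }
  ref <- embedded_body_oscillators(max(distances), orientation = orientation,
                                   ...)
  e1 <- e_both(subset_oscillators(ref, "body1"))
  e2 <- e_both(subset_oscillators(ref, "body2"))
  rows <- t(vapply(distances, function(R) {
    e_both(embedded_body_oscillators(R, orientation = orientation, ...))
  }, c(mbd = 0, dcs = 0)))
  data.frame(distance = distances,
             de_mbd = rows[, "mbd"] - e1["mbd"] - e2["mbd"],
             de_dcs = rows[, "dcs"] - e1["dcs"] - e2["dcs"],
             row.names = NULL)
}

#' Log-log decay exponent of an interaction curve
#'
#' Least-squares slope of log|E| versus log R inside a fit window; the
#' instrument for verifying R^-6 (dispersion) and R^-5
#' (induced-quadrupole) asymptotics.
#'
#' @param R separations.
#' @param E energies (all of one sign within the window).
#' @param window length-2 numeric range of R to fit; default all points.
#' @return list with `slope`, `stderr`, `n_points`.
#' @export
fit_decay_exponent <- function(R, E, window = range(R)) {
  keep <- R >= window[1] & R <= window[2] & is.finite(E) & E != 0
  if (sum(keep) < 5) stop("need at least 5 points inside the fit window")
  E <- E[keep]; R <- R[keep]
  if (length(unique(sign(E))) != 1)
    stop("energy changes sign inside the fit window")
  x <- log(R); y <- log(abs(E))
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sxx)
  list(slope = slope, stderr = se, n_points = length(R))
}

#' Structured energy report
#'
#' Full MBD + DCS evaluation of one system with totals in Hartree, eV
#' and kJ/mol, the DCS decomposition with its per-pair table, damping
#' parameters and provenance.
#'
#' @param osc an `oscillator_set`.
#' @param params_mbd,params_dcs damping parameter sets.
#' @param damping "fermi" or "none".
#' @param input_file optional source file path recorded (with an md5
#'   hash) in the provenance block.
#' @param seed seed recorded for any Monte-Carlo follow-up.
#' @return a nested list serializable with [write_energy_report()].
#' @export
energy_report <- function(osc, params_mbd = damping_params("mbd"),
                          params_dcs = damping_params("dcs"),
                          damping = c("fermi", "none"),
                          input_file = NULL, seed = 20210108) {
  damping <- match.arg(damping)
  n <- nrow(osc$positions)
  spec <- if (n > 1)
    solve_modes(interaction_matrix(osc, params_mbd, damping), osc$omega)
  else NULL
  e_mbd <- if (n > 1) sum(spec$omega_dc) / 2 - 3 * sum(osc$omega) / 2 else 0
  if (n > 1) {
    st_dc <- ground_state(osc, spec)
    st_0 <- ground_state(osc, correlated = FALSE)
    bd <- dcs_decomposition(osc, st_dc, st_0, params_dcs, damping)
  } else {
    bd <- list(e_dcs = 0, j_dc = 0, j_0 = 0, e_corr = 0, e_dip = 0,
               pairs = data.frame())
  }
  prov <- list(n_atoms = n, seed = seed)
  if (!is.null(input_file)) {
    prov$input_file <- input_file
    prov$input_md5 <- unname(tools::md5sum(input_file))
  }
  list(
    totals = list(e_mbd = as.list(energy_units(e_mbd)),
                  e_dcs = as.list(energy_units(bd$e_dcs)),
                  e_vdw = as.list(energy_units(e_mbd + bd$e_dcs))),
    dcs_components = list(j_dc = bd$j_dc, j_0 = bd$j_0,
                          e_corr = bd$e_corr, e_dip = bd$e_dip),
    pair_table = bd$pairs,
    damping = list(mbd = params_mbd[c("a", "beta")],
                   dcs = params_dcs[c("a", "beta")],
                   scheme = damping),
    provenance = prov)
}

#' Write an energy report as JSON
#' @param report output of [energy_report()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_energy_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a run-configuration file
#'
#' YAML configuration with optional sections `parameters`
#' (alpha_scale), `damping_mbd`, `damping_dcs` (a, beta), `grid`
#' (spacing, padding), `scan` (from, to, step), `seeds` (mc).
#'
#' @param path YAML file path.
#' @return list with `alpha_scale`, `params_mbd`, `params_dcs`, `grid`,
#'   `scan`, `seed`.
#' @export
read_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  dp <- function(section, variant) {
    s <- cfg[[section]]
    damping_params(variant, a = s$a, beta = s$beta)
  }
  list(alpha_scale = if (is.null(cfg$parameters$alpha_scale)) 1 else
         cfg$parameters$alpha_scale,
       params_mbd = dp("damping_mbd", "mbd"),
       params_dcs = dp("damping_dcs", "dcs"),
       grid = cfg$grid,
       scan = cfg$scan,
       seed = if (is.null(cfg$seeds$mc)) 20210108 else cfg$seeds$mc)
}
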