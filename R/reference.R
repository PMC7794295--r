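#' Load a free-atom reference parameter table
#'
#' Reads a plain-text table of per-element free-atom dipole polarizability
#' (Bohr^3), C6 dispersion coefficient (Hartree*Bohr^6) and van der Waals
#' radius (Bohr). The package ships a table with standard
#' Tkatchenko-Scheffler free-atom reference values; a user table with the
#' same four-column layout (symbol, alpha, C6, R_vdW; `#` comments) can be
#' supplied instead.
#'
#' @param path path to a table file; default is the shipped table.
#' @return data frame with columns `symbol`, `alpha_free`, `c6_free`,
#'   `r_vdw_free`, of class `free_atom_table`.
#' @export
load_free_atom_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "free_atom_params.txt", package = "mbddcs",
                        mustWork = TRUE)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("symbol", "alpha_free", "c6_free",
                                         "r_vdw_free"),
                           stringsAsFactors = FALSE)
  if (any(tab$alpha_free <= 0) || any(tab$c6_free <= 0) ||
      any(tab$r_vdw_free <= 0))
    stop("free-atom table entries must be strictly positive")
  if (anyDuplicated(tab$symbol)) stop("duplicate element in free-atom table")
  class(tab) <- c("free_atom_table", class(tab))
  tab
}

#' Parametrize a geometry as a set of quantum Drude oscillators
#'
#' Each atom becomes a charged harmonic (Drude) oscillator whose
#' parameters derive from free-atom reference data scaled by the atom's
#' Hirshfeld volume ratio v and an optional polarizability scaling s:
#' alpha = s*v*alpha_free, C6 = (s*v)^2*C6_free, R_vdW = v^(1/3)*R_free,
#' and the characteristic frequency omega = 4*C6/(3*alpha^2). The Drude
#' charge convention is q = 1, hence the oscillator mass
#' m = 1/(alpha*omega^2) so that alpha = q^2/(m*omega^2) holds exactly.
#'
#' @param geom a `geometry` (coordinates in Angstrom; converted to Bohr).
#' @param table a `free_atom_table`; default the shipped one.
#' @param alpha_scale scalar or per-atom positive polarizability scaling
#'   factor (e.g. 1.5 to increase a guest's polarizability by 50%).
#' @return an `oscillator_set`: list with `positions` (N x 3, Bohr),
#'   `alpha` (Bohr^3), `omega` (Hartree), `r_vdw` (Bohr), `charge` (e),
#'   `mass` (electron masses), plus the originating `elements` and `labels`.
#' @examples
#' osc <- parametrize(geometry("Xe", matrix(0, 1, 3)))
#' all.equal(osc$alpha, osc$charge^2 / (osc$mass * osc$omega^2))
#' @export
parametrize <- function(geom, table = load_free_atom_table(),
                        alpha_scale = 1) {
  stopifnot(inherits(geom, "geometry"))
  n <- n_atoms(geom)
  if (length(alpha_scale) == 1L) alpha_scale <- rep(alpha_scale, n)
  if (length(alpha_scale) != n)
    stop("alpha_scale must be scalar or per-atom")
  if (any(!is.finite(alpha_scale)) || any(alpha_scale <= 0))
    stop("alpha_scale must be positive")
  idx <- match(geom$elements, table$symbol)
  if (anyNA(idx))
    stop("element(s) not in free-atom table: ",
         paste(unique(geom$elements[is.na(idx)]), collapse = ", "))
  v <- geom$hirshfeld_ratios
  sv <- alpha_scale * v
  alpha <- sv * table$alpha_free[idx]
  c6 <- sv^2 * table$c6_free[idx]
  r_vdw <- v^(1 / 3) * table$r_vdw_free[idx]
  omega <- 4 * c6 / (3 * alpha^2)
  oscillator_set(geom$coordinates * units_au$bohr_per_angstrom,
                 alpha, omega, r_vdw,
                 elements = geom$elements, labels = geom$labels)
}

#' Construct an oscillator set directly from parameters
#'
#' Low-level constructor used by [parametrize()] and by toy fixtures that
#' bypass the element table.
#'
#' @param positions N x 3 matrix (Bohr).
#' @param alpha,omega,r_vdw per-atom polarizability (Bohr^3), frequency
#'   (Hartree) and vdW radius (Bohr).
#' @param charge Drude charges; default 1 for every atom.
#' @param elements,labels optional bookkeeping carried through reports.
#' @return an `oscillator_set`.
#' @export
oscillator_set <- function(positions, alpha, omega, r_vdw, charge = NULL,
                           elements = NULL, labels = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3,
            length(alpha) == n, length(omega) == n, length(r_vdw) == n)
  if (is.null(charge)) charge <- rep(1, n)
  if (any(alpha <= 0) || any(omega <= 0) || any(r_vdw <= 0) ||
      any(charge <= 0))
    stop("oscillator parameters must be strictly positive")
  mass <- charge^2 / (alpha * omega^2)
  dimnames(positions) <- NULL
  structure(list(positions = positions, alpha = as.numeric(alpha),
                 omega = as.numeric(omega), r_vdw = as.numeric(r_vdw),
                 charge = as.numeric(charge), mass = as.numeric(mass),
                 elements = elements, labels = labels),
            class = "oscillator_set")
}

#' @export
print.oscillator_set <- function(x, ...) {
  cat("oscillator_set:", nrow(x$positions), "Drude oscillators\n")
  cat("  alpha [Bohr^3]:", paste(signif(range(x$alpha), 4), collapse = " - "),
      " omega [Ha]:", paste(signif(range(x$omega), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Subset an oscillator set by atom index or fragment label
#' @param osc an `oscillator_set`.
#' @param which integer/logical index vector or character fragment labels.
#' @return an `oscillator_set` with the selected oscillators.
#' @export
subset_oscillators <- function(osc, which) {
  if (is.character(which)) {
    if (is.null(osc$labels)) stop("oscillator set has no fragment labels")
    which <- osc$labels %in% which
    if (!any(which)) stop("no atoms match the requested fragment labels")
  }
  oscillator_set(osc$positions[which, , drop = FALSE], osc$alpha[which],
                 osc$omega[which], osc$r_vdw[which], osc$charge[which],
                 elements = osc$elements[which],
                 labels = if (is.null(osc$labels)) NULL else osc$labels[which])
}
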