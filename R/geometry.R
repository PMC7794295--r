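#' Molecular geometry container
#'
#' A light-weight container for a molecular structure: element symbols,
#' Cartesian coordinates in Angstrom, optional per-atom Hirshfeld
#' volume ratios (atom-in-molecule volume over free-atom volume, used to
#' rescale free-atom polarizabilities) and optional fragment labels.
#'
#' @param elements character vector of element symbols.
#' @param coordinates N x 3 numeric matrix of Cartesian positions (Angstrom).
#' @param hirshfeld_ratios optional numeric vector of positive ratios
#'   (default 1 for every atom).
#' @param labels optional character vector of fragment tags
#'   (e.g. "host", "guest").
#' @return an object of class `geometry`.
#' @examples
#' g <- geometry(c("Xe", "Xe"), rbind(c(0, 0, 0), c(0, 0, 4.2)))
#' @export
geometry <- function(elements, coordinates, hirshfeld_ratios = NULL,
                     labels = NULL) {
  coordinates <- as.matrix(coordinates)
  if (is.null(dim(coordinates)) || ncol(coordinates) != 3)
    stop("coordinates must be an N x 3 matrix")
  n <- nrow(coordinates)
  if (n < 1L) stop("geometry needs at least one atom")
  if (length(elements) != n)
    stop("elements and coordinates disagree on atom count")
  if (is.null(hirshfeld_ratios)) hirshfeld_ratios <- rep(1, n)
  if (length(hirshfeld_ratios) != n)
    stop("hirshfeld_ratios must have one entry per atom")
  if (any(!is.finite(hirshfeld_ratios)) || any(hirshfeld_ratios <= 0))
    stop("hirshfeld_ratios must be positive")
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per atom")
  if (n > 1L) {
    d <- stats::dist(coordinates)
    if (min(d) <= 0) stop("coincident atoms in geometry")
  }
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  structure(list(elements = as.character(elements),
                 coordinates = coordinates,
                 hirshfeld_ratios = as.numeric(hirshfeld_ratios),
                 labels = if (is.null(labels)) NULL else as.character(labels)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("geometry:", length(x$elements), "atoms (",
      paste(names(sort(table(x$elements), decreasing = TRUE)),
            sort(table(x$elements), decreasing = TRUE),
            sep = ":", collapse = " "), ")\n")
  if (!is.null(x$labels))
    cat("fragments:", paste(unique(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a `geometry`.
#' @return integer atom count.
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Subset a geometry by atom index or fragment label
#'
#' @param geom a `geometry`.
#' @param which integer/logical atom index vector, or a character vector of
#'   fragment labels (requires `geom$labels`).
#' @return a `geometry` with the selected atoms.
#' @export
subset_geometry <- function(geom, which) {
  if (is.character(which)) {
    if (is.null(geom$labels)) stop("geometry has no fragment labels")
    which <- geom$labels %in% which
    if (!any(which)) stop("no atoms match the requested fragment labels")
  }
  geometry(geom$elements[which], geom$coordinates[which, , drop = FALSE],
           geom$hirshfeld_ratios[which],
           if (is.null(geom$labels)) NULL else geom$labels[which])
}

#' Concatenate geometries
#' @param ... `geometry` objects.
#' @return combined `geometry`.
#' @export
combine_geometries <- function(...) {
  gs <- list(...)
  labs <- lapply(gs, function(g)
    if (is.null(g$labels)) rep(NA_character_, n_atoms(g)) else g$labels)
  labs <- unlist(labs)
  geometry(unlist(lapply(gs, `[[`, "elements")),
           do.call(rbind, lapply(gs, `[[`, "coordinates")),
           unlist(lapply(gs, `[[`, "hirshfeld_ratios")),
           if (all(is.na(labs))) NULL else labs)
}

#' Read an (extended) XYZ file
#'
#' Standard XYZ with an optional extended-XYZ `Properties=` comment line.
#' Per-atom columns `hirsh_ratio` (numeric) and `frag` (string) are parsed
#' into `hirshfeld_ratios` and `labels` when declared in the properties
#' specification.
#'
#' @param path file path.
#' @return a `geometry` (coordinates in Angstrom).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 1) stop("malformed XYZ: bad atom count")
  comment <- if (length(lines) >= 2) lines[2] else ""
  body <- lines[3:(2 + n)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  cols <- list(species = 1L, pos = 2L)  # default column layout
  hirsh_col <- NA_integer_; frag_col <- NA_integer_
  m <- regmatches(comment, regexpr("Properties=[^ ]+", comment))
  if (length(m) == 1L) {
    propspec <- sub("Properties=", "", m)
    fields <- strsplit(propspec, ":")[[1]]
    if (length(fields) %% 3 != 0) stop("malformed extended-XYZ Properties")
    at <- 1L
    for (k in seq(1, length(fields), by = 3)) {
      nm <- fields[k]; width <- as.integer(fields[k + 2])
      if (nm == "pos") cols$pos <- at
      if (nm == "species") cols$species <- at
      if (nm == "hirsh_ratio") hirsh_col <- at
      if (nm == "frag") frag_col <- at
      at <- at + width
    }
  }
  getcol <- function(i) vapply(toks, `[[`, "", i)
  elements <- getcol(cols$species)
  xyz <- cbind(as.numeric(getcol(cols$pos)),
               as.numeric(getcol(cols$pos + 1L)),
               as.numeric(getcol(cols$pos + 2L)))
  hr <- if (!is.na(hirsh_col)) as.numeric(getcol(hirsh_col)) else NULL
  fr <- if (!is.na(frag_col)) getcol(frag_col) else NULL
  geometry(elements, xyz, hr, fr)
}

#' Write an (extended) XYZ file
#'
#' Hirshfeld ratios are written as a `hirsh_ratio` column whenever any
#' ratio differs from 1; fragment labels as a `frag` column when present.
#'
#' @param geom a `geometry`.
#' @param path output path.
#' @param comment optional extra text appended to the comment line.
#' @return invisibly, `path`.
#' @export
write_xyz <- function(geom, path, comment = "") {
  n <- n_atoms(geom)
  props <- "Properties=species:S:1:pos:R:3"
  tab <- data.frame(el = geom$elements,
                    x = geom$coordinates[, 1],
                    y = geom$coordinates[, 2],
                    z = geom$coordinates[, 3])
  fmt <- c("%-3s", "%16.8f", "%16.8f", "%16.8f")
  if (any(geom$hirshfeld_ratios != 1)) {
    props <- paste0(props, ":hirsh_ratio:R:1")
    tab$hr <- geom$hirshfeld_ratios
    fmt <- c(fmt, "%12.6f")
  }
  if (!is.null(geom$labels)) {
    props <- paste0(props, ":frag:S:1")
    tab$frag <- geom$labels
    fmt <- c(fmt, "%s")
  }
  rows <- vapply(seq_len(n), function(i)
    paste(mapply(function(f, v) sprintf(f, v), fmt, as.list(tab[i, ])),
          collapse = " "), "")
  writeLines(c(as.character(n), trimws(paste(props, comment)), rows), path)
  invisible(path)
}
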