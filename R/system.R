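#' Define a molecular system
#'
#' Creates the closed-shell molecular system object used throughout the
#' package: element symbols, Cartesian coordinates, total charge, optional
#' external point charges (QM/MM style), and the AO / auxiliary basis
#' labels.  Coordinates are stored in Bohr; pass `unit = "angstrom"` for
#' input in Angstrom (1 Angstrom = 1.8897259886 Bohr).
#'
#' @param symbols character vector of element symbols
#' @param coords numeric matrix (n x 3) of positions
#' @param charge total molecular charge (integer)
#' @param multiplicity spin multiplicity; only 1 (closed shell) is supported
#' @param point_charges optional matrix (m x 4): x, y, z, q with positions in
#'   the same unit as `coords` and charges in elementary charge units
#' @param ao_basis AO basis label (`"sto-3g"` or `"dz"`)
#' @param aux_basis auxiliary basis label (`"autoaux"` or `"autoaux-dense"`)
#' @param unit `"bohr"` (default) or `"angstrom"`
#' @return an object of class `less_system`
#' @export
less_system <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                        point_charges = NULL, ao_basis = "dz",
                        aux_basis = "autoaux", unit = c("bohr", "angstrom")) {
  unit <- match.arg(unit)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(symbols) != nrow(coords)) {
    stop("symbols and coords disagree in length")
  }
  if (multiplicity != 1L) {
    stop("only closed-shell systems (multiplicity 1) are supported")
  }
  if (unit == "angstrom") {
    coords <- coords * bohr_per_angstrom
    if (!is.null(point_charges)) {
      point_charges[, 1:3] <- point_charges[, 1:3] * bohr_per_angstrom
    }
  }
  z <- atomic_number(symbols)
  nelec <- sum(z) - charge
  if (nelec %% 2 != 0) {
    stop("odd electron count (", nelec, "); closed-shell systems only")
  }
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (nrow(coords) > 1 && min(d) < 1e-6) stop("two atoms coincide")
  if (!is.null(point_charges)) {
    point_charges <- matrix(as.numeric(point_charges), ncol = 4)
  }
  structure(list(symbols = symbols, coords = coords,
                 charge = as.integer(charge), multiplicity = 1L,
                 point_charges = point_charges, ao_basis = ao_basis,
                 aux_basis = aux_basis, n_electrons = as.integer(nelec)),
            class = "less_system")
}

#' @export
print.less_system <- function(x, ...) {
  cat("<less_system> ", length(x$symbols), " atoms, charge ", x$charge,
      ", ", x$n_electrons, " electrons\n", sep = "")
  cat("  AO basis: ", x$ao_basis, "   aux basis: ", x$aux_basis, "\n", sep = "")
  if (!is.null(x$point_charges)) {
    cat("  external point charges: ", nrow(x$point_charges), "\n", sep = "")
  }
  invisible(x)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ layout: atom count, comment line, then `element x y z` per
#' line in Angstrom.
#'
#' @param path file path
#' @inheritParams less_system
#' @param ... passed on to [less_system()]
#' @return a `less_system`
#' @export
read_xyz <- function(path, charge = 0L, ...) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  body <- lines[3:(2 + n)]
  toks <- strsplit(trimws(body), "\\s+")
  symbols <- vapply(toks, `[[`, "", 1)
  coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  less_system(symbols, coords, charge = charge, unit = "angstrom", ...)
}

#' Write an XYZ geometry file (Angstrom)
#'
#' @param system a `less_system`
#' @param path output path
#' @param comment comment line
#' @export
write_xyz <- function(system, path, comment = "") {
  ang <- system$coords / bohr_per_angstrom
  lines <- c(length(system$symbols), comment,
             sprintf("%-3s %18.10f %18.10f %18.10f", system$symbols,
                     ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
}

#' Read external point charges
#'
#' Four-column text file (x, y, z in Angstrom, charge in e), the layout in
#' which MM charges are conventionally appended after the QM coordinates.
#'
#' @param path file path
#' @return numeric matrix (m x 4) with positions converted to Bohr
#' @export
read_point_charges <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 4) stop("point-charge file must have 4 columns (x y z q)")
  m[, 1:3] <- m[, 1:3] * bohr_per_angstrom
  unname(m)
}
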