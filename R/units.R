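#' Physical constants and unit conversions
#'
#' All internal quantities are in atomic units (Bohr, Hartree).  XYZ input
#' is interpreted as Angstrom; reports convert energies to kcal/mol where
#' stated.
#'
#' @format `bohr_per_angstrom` (1 Angstrom in Bohr) and `kcal_per_hartree`
#'   (1 Hartree in kcal/mol).
#' @export
bohr_per_angstrom <- 1.8897259886

#' @rdname bohr_per_angstrom
#' @export
kcal_per_hartree <- 627.509474

element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17
)

# Bragg-Slater radii (Angstrom) used as radial grid scale parameters
bragg_radii <- c(
  H = 0.35, He = 0.31, Li = 1.45, Be = 1.05, B = 0.85, C = 0.70,
  N = 0.65, O = 0.60, F = 0.50, Ne = 0.38, Na = 1.80, Mg = 1.50,
  Al = 1.25, Si = 1.10, P = 1.00, S = 1.00, Cl = 1.00
)

atomic_number <- function(symbol) {
  z <- element_numbers[symbol]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(z)], collapse = ", "))
  }
  unname(z)
}
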