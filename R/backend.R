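# Integral backend: binds a molecular system to its integral and
# exchange-correlation providers.  The handle is an environment so that
# expensive quantities (integrals, grids) are computed once and cached;
# repeated queries return identical values.

#' Create a backend handle
#'
#' Binds a [less_system()] to the built-in McMurchie-Davidson integral
#' engine and the Becke-grid exchange-correlation evaluator.  All
#' downstream modules (SCF, embedding, basis reduction) only talk to the
#' handle, never to the engine directly.
#'
#' @param system a `less_system`
#' @param grid_level exchange-correlation quadrature grid level 1-3
#'   (radial x angular points per atom grow with the level; level 2 is a
#'   production default, level 3 a fine verification grid)
#' @return an object of class `less_handle`
#' @export
backend_handle <- function(system, grid_level = 2L) {
  stopifnot(inherits(system, "less_system"))
  h <- new.env(parent = emptyenv())
  h$system <- system
  h$ao <- build_shellset(system, "ao")
  h$aux <- build_shellset(system, "aux")
  h$grid_level <- as.integer(grid_level)
  h$cache <- new.env(parent = emptyenv())
  class(h) <- "less_handle"
  h
}

#' @export
print.less_handle <- function(x, ...) {
  cat("<less_handle> ", length(x$system$symbols), " atoms, ",
      x$ao$nbf, " AOs, ", x$aux$nbf, " auxiliary functions\n", sep = "")
  invisible(x)
}

cache_get <- function(handle, key, fn) {
  if (!exists(key, envir = handle$cache, inherits = FALSE)) {
    assign(key, fn(), envir = handle$cache)
  }
  get(key, envir = handle$cache, inherits = FALSE)
}

# all charge centers seen by the electrons: nuclei then point charges
charge_table <- function(system) {
  z <- atomic_number(system$symbols)
  m <- cbind(system$coords, z)
  if (!is.null(system$point_charges)) m <- rbind(m, system$point_charges)
  m
}

#' One-electron integrals
#'
#' Overlap, core Hamiltonian (kinetic + nuclear attraction + external
#' point-charge attraction) and the nuclear repulsion energy (including
#' nucleus-point-charge terms; the point-charge-point-charge self energy is
#' excluded, being a constant of the MM layer).
#'
#' @param handle a backend handle
#' @return list with `S`, `h`, `E_nuc`
#' @export
one_electron <- function(handle) {
  cache_get(handle, "one_electron", function() {
    ct <- charge_table(handle$system)
    ints <- cpp_one_electron(handle$ao, ct)
    ev <- eigen(ints$S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) {
      stop("AO basis '", handle$system$ao_basis,
           "' is numerically linearly dependent (smallest overlap ",
           "eigenvalue ", format(min(ev), digits = 3), ")")
    }
    list(S = ints$S, h = ints$T + ints$V,
         E_nuc = cpp_nuclear_repulsion(ct, length(handle$system$symbols)))
  })
}

#' Density-fitting integrals
#'
#' Three-center integrals (mu nu | P) (packed over mu >= nu pairs) and the
#' two-center Coulomb metric (P | Q) over the auxiliary basis.
#'
#' @param handle a backend handle
#' @return list with `three_center` (npair x naux) and `two_center`
#' @export
df_integrals <- function(handle) {
  cache_get(handle, "df_integrals", function() {
    m2 <- cpp_metric2c(handle$aux)
    ev <- eigen(m2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) {
      stop("auxiliary Coulomb metric is not positive definite; ",
           "review the auxiliary basis '", handle$system$aux_basis, "'")
    }
    list(three_center = cpp_eri3c(handle$ao, handle$aux), two_center = m2)
  })
}

#' Auxiliary-basis overlap matrix
#'
#' Needed by the generalized-Mulliken-charge auxiliary reduction.
#' @param handle a backend handle
#' @export
aux_overlap <- function(handle) {
  cache_get(handle, "aux_overlap", function() cpp_overlap(handle$aux))
}

#' Diagonal four-center integrals
#'
#' The Cauchy-Schwarz diagonals (mu nu | mu nu) as a full AO matrix, used
#' by the local density-fitting domain construction.
#' @param handle a backend handle
#' @export
eri_diagonal <- function(handle) {
  cache_get(handle, "eri_diag", function() cpp_eri_diag(handle$ao))
}

#' Full four-center integral tensor (tiny systems only)
#'
#' Returns (mu nu | lambda sigma) reshaped as an nao^2 x nao^2 matrix.
#' Exists to support brute-force reference calculations in tests; refuses
#' systems beyond 40 AOs.
#' @param handle a backend handle
#' @export
four_center <- function(handle) {
  cache_get(handle, "eri4c", function() cpp_eri4c(handle$ao))
}

grid_params <- list(
  `1` = list(nrad = 35, ntheta = 10),
  `2` = list(nrad = 60, ntheta = 16),
  `3` = list(nrad = 100, ntheta = 24)
)

xc_grid <- function(handle, level = handle$grid_level) {
  key <- paste0("grid", level)
  cache_get(handle, key, function() {
    p <- grid_params[[as.character(level)]]
    if (is.null(p)) stop("grid level must be 1, 2 or 3")
    radii <- bragg_radii[handle$system$symbols] * bohr_per_angstrom
    radii[is.na(radii)] <- 1.0
    cpp_becke_grid(handle$system$coords, unname(radii), p$nrad, p$ntheta)
  })
}

#' Exchange-correlation functionals
#'
#' The functional registry: `"hf"` (pure Hartree-Fock exchange, no XC
#' quadrature), `"pbe"` (GGA), `"pbe0"` (25 % exact exchange + 75 % PBE
#' exchange + PBE correlation).
#'
#' @param name functional name (case-insensitive)
#' @return list with `c_hfx` (exact-exchange weight), `x_scale`, `c_scale`
#'   (weights of PBE exchange / correlation) and `has_xc`
#' @export
functional_info <- function(name) {
  switch(tolower(name),
    hf = list(name = "hf", c_hfx = 1.0, x_scale = 0.0, c_scale = 0.0,
              has_xc = FALSE),
    pbe = list(name = "pbe", c_hfx = 0.0, x_scale = 1.0, c_scale = 1.0,
               has_xc = TRUE),
    pbe0 = list(name = "pbe0", c_hfx = 0.25, x_scale = 0.75, c_scale = 1.0,
                has_xc = TRUE),
    stop("unknown functional '", name, "' (available: hf, pbe, pbe0)")
  )
}

#' Evaluate the exchange-correlation energy and potential
#'
#' For functional `"hf"` returns zero energy and a zero potential.  The
#' density may live on a shell-complete subset of the AO basis (`kept_ao`),
#' in which case the potential is returned in that subset.
#'
#' @param handle a backend handle
#' @param functional functional name
#' @param D symmetric closed-shell AO density matrix
#' @param kept_ao optional 1-based AO function indices the density is
#'   expressed in (default: full basis)
#' @param grid_level override the handle's grid level
#' @return list with `E_xc`, `V_xc`, `n_elec` (density integrated on the
#'   grid, a quadrature quality indicator)
#' @export
xc_eval <- function(handle, functional, D, kept_ao = NULL,
                    grid_level = handle$grid_level) {
  f <- functional_info(functional)
  n <- if (is.null(kept_ao)) handle$ao$nbf else length(kept_ao)
  if (!isTRUE(all.equal(dim(D), c(n, n)))) {
    stop("density dimension does not match the kept AO set")
  }
  if (max(abs(D - t(D))) > 1e-8) stop("density matrix must be symmetric")
  if (!f$has_xc) {
    return(list(E_xc = 0, V_xc = matrix(0, n, n), n_elec = NA_real_))
  }
  keep_shells <- if (is.null(kept_ao)) {
    seq_along(handle$ao$l) - 1L
  } else {
    assert_shell_complete(handle$ao, kept_ao, "kept AO set") - 1L
  }
  g <- xc_grid(handle, grid_level)
  r <- cpp_xc_eval(handle$ao, as.integer(keep_shells), D, g$points,
                   g$weights, f$x_scale, f$c_scale)
  list(E_xc = r$exc, V_xc = r$vxc, n_elec = r$n_elec)
}
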