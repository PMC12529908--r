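# Deterministic closed-shell fixture generators: idealized zig-zag
# alkyl-chain species (quasi-one-dimensional, so the active head group and
# the growing environment tail mimic the geometry regime the embedding
# scheme targets), an SN2 reaction quartet, small pi systems and separated
# dimers.  Geometries use standard bond lengths and tetrahedral angles; no
# optimizer and no random numbers are involved.

.len <- list(CC = 1.54, CH = 1.09, CO_double = 1.21, CO_single = 1.36,
             OH = 0.97, CCl = 1.79, CO_ol = 1.43)

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
}

unit <- function(v) v / sqrt(sum(v^2))

# zig-zag carbon backbone in the xz plane, C1 at origin
chain_backbone <- function(n) {
  th <- acos(-1 / 3) / 2               # half tetrahedral angle
  step <- .len$CC * c(sin(th), 0, cos(th))
  pos <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    s <- step; s[3] <- s[3] * (-1)^(i - 1)
    pos[i + 1, ] <- pos[i, ] + s
  }
  pos
}

# two tetrahedral H positions for a CH2 carbon with bond unit vectors b1, b2
ch2_hydrogens <- function(c_pos, b1, b2) {
  s <- unit(-(b1 + b2))
  p <- unit(pracma_cross(b1, b2))
  h1 <- c_pos + .len$CH * (s / sqrt(3) + sqrt(2 / 3) * p) /
    sqrt(sum((s / sqrt(3) + sqrt(2 / 3) * p)^2))
  h2 <- c_pos + .len$CH * unit(s / sqrt(3) - sqrt(2 / 3) * p)
  rbind(h1, h2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# three tetrahedral H positions for a terminal CH3 with bond unit vector b1
ch3_hydrogens <- function(c_pos, b1) {
  ref <- if (abs(b1[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  p <- unit(pracma_cross(b1, ref))
  q <- unit(pracma_cross(b1, p))
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    c_pos + .len$CH * unit(-b1 / 3 + (2 * sqrt(2) / 3) *
                             (cos(phi) * p + sin(phi) * q))
  }, numeric(3)))
}

chain_skeleton <- function(n_carbons) {
  cc <- chain_backbone(n_carbons)
  sym <- rep("C", n_carbons)
  hyd <- NULL
  for (i in seq_len(n_carbons)) {
    if (i == n_carbons) next           # head group replaces these bonds
    b_next <- unit(cc[i + 1, ] - cc[i, ])
    if (i == 1) {
      hyd <- rbind(hyd, ch3_hydrogens(cc[1, ], b_next))
    } else {
      b_prev <- unit(cc[i - 1, ] - cc[i, ])
      hyd <- rbind(hyd, ch2_hydrogens(cc[i, ], b_prev, b_next))
    }
  }
  list(carbons = cc, hydrogens = hyd)
}

#' Alkyl-chain carboxylic acid / carboxylate fixture pair
#'
#' Builds an idealized n-carbon chain acid and its deprotonated anion on
#' the identical heavy-atom frame.  The head group (carboxyl carbon, both
#' oxygens, the acidic proton where present) plus the alpha carbon form the
#' recommended active set; the alkyl tail is the environment.
#'
#' @param n_carbons chain length, 2 to 12
#' @param ao_basis,aux_basis basis labels for the generated systems
#' @return list with `acid`, `anion` (each a `less_system`),
#'   `active_acid`, `active_anion` (atom index vectors)
#' @export
build_chain_acid <- function(n_carbons, ao_basis = "dz",
                             aux_basis = "autoaux") {
  if (n_carbons < 2 || n_carbons > 12) stop("n_carbons must be in [2, 12]")
  sk <- chain_skeleton(n_carbons)
  cc <- sk$carbons
  n <- n_carbons
  b1 <- unit(cc[n - 1, ] - cc[n, ])    # carboxyl C -> alpha C
  d_eq <- as.vector(rot_y(125) %*% b1)   # C=O direction
  d_oh <- as.vector(rot_y(-115) %*% b1)  # C-OH direction
  o_eq <- cc[n, ] + .len$CO_double * unit(d_eq)
  o_oh <- cc[n, ] + .len$CO_single * unit(d_oh)
  h_ac <- o_oh + .len$OH * unit(as.vector(rot_y(115) %*% -unit(d_oh)))
  coords_acid <- rbind(cc, sk$hydrogens, o_eq, o_oh, h_ac)
  sym_acid <- c(rep("C", n), rep("H", nrow(sk$hydrogens)), "O", "O", "H")
  nat <- nrow(coords_acid)
  acid <- less_system(sym_acid, coords_acid, charge = 0L,
                      ao_basis = ao_basis, aux_basis = aux_basis,
                      unit = "angstrom")
  anion <- less_system(sym_acid[-nat], coords_acid[-nat, , drop = FALSE],
                       charge = -1L, ao_basis = ao_basis,
                       aux_basis = aux_basis, unit = "angstrom")
  active_acid <- c(n, n - 1L, nat - 2L, nat - 1L, nat)
  active_anion <- c(n, n - 1L, nat - 2L, nat - 1L)
  list(acid = acid, anion = anion,
       active_acid = sort(active_acid), active_anion = sort(active_anion))
}

#' SN2 fixture reaction: R-Cl + OH- -> R-OH + Cl-
#'
#' Four closed-shell species on a shared idealized chain frame; the
#' reacting carbon and the leaving / incoming groups are active.
#'
#' @inheritParams build_chain_acid
#' @param n_carbons chain length, 1 to 12
#' @return list of `species` (each: `system`, `coeff`, `active_atoms`),
#'   with stoichiometric coefficients summing the reaction
#'   `chloroalkane + OH- -> alkanol + Cl-`, plus `name`
#' @export
build_sn2_pair <- function(n_carbons, ao_basis = "dz",
                           aux_basis = "autoaux") {
  if (n_carbons < 1 || n_carbons > 12) stop("n_carbons must be in [1, 12]")
  n <- n_carbons
  if (n == 1) {
    ccl <- .len$CCl
    cpos <- matrix(0, 1, 3)
    b_sub <- c(1, 0, 0)                # substituent direction
    hyd <- ch3_hydrogens(cpos[1, ], b_sub)
    sym <- c("C", rep("H", 3))
    frame <- rbind(cpos, hyd)
  } else {
    sk <- chain_skeleton(n + 1)        # reuse: carbon n+1 slot = substituent
    cpos <- sk$carbons[seq_len(n), , drop = FALSE]
    b_sub <- unit(sk$carbons[n + 1, ] - sk$carbons[n, ])
    sym <- c(rep("C", n), rep("H", nrow(sk$hydrogens)))
    frame <- rbind(cpos, sk$hydrogens)
  }
  sub_origin <- frame[if (n == 1) 1 else n, ]
  cl_pos <- sub_origin + .len$CCl * b_sub
  o_pos <- sub_origin + .len$CO_ol * b_sub
  oh_h <- o_pos + .len$OH * unit(as.vector(rot_y(70) %*% b_sub))
  rcl <- less_system(c(sym, "Cl"), rbind(frame, cl_pos), charge = 0L,
                     ao_basis = ao_basis, aux_basis = aux_basis,
                     unit = "angstrom")
  rol <- less_system(c(sym, "O", "H"), rbind(frame, o_pos, oh_h),
                     charge = 0L, ao_basis = ao_basis,
                     aux_basis = aux_basis, unit = "angstrom")
  hydroxide <- less_system(c("O", "H"),
                           rbind(c(0, 0, 0), c(0.97, 0, 0)), charge = -1L,
                           ao_basis = ao_basis, aux_basis = aux_basis,
                           unit = "angstrom")
  chloride <- less_system("Cl", matrix(0, 1, 3), charge = -1L,
                          ao_basis = ao_basis, aux_basis = aux_basis,
                          unit = "angstrom")
  ncar <- if (n == 1) 1L else n
  nfrm <- nrow(frame)
  list(name = sprintf("sn2_c%d", n),
       species = list(
         list(system = rcl, coeff = -1, active_atoms = c(ncar, nfrm + 1L)),
         list(system = hydroxide, coeff = -1, active_atoms = 1:2),
         list(system = rol, coeff = 1,
              active_atoms = c(ncar, nfrm + 1L, nfrm + 2L)),
         list(system = chloride, coeff = 1, active_atoms = 1L)
       ))
}

monomer_geometries <- list(
  h2o = list(symbols = c("O", "H", "H"),
             coords = rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                            c(0, -0.7572, -0.4692))),
  nh3 = list(symbols = c("N", "H", "H", "H"),
             coords = rbind(c(0, 0, 0.1126),
                            c(0, 0.9377, -0.2628),
                            c(0.8121, -0.4689, -0.2628),
                            c(-0.8121, -0.4689, -0.2628))),
  ch4 = list(symbols = c("C", "H", "H", "H", "H"),
             coords = rbind(c(0, 0, 0), c(0.6293, 0.6293, 0.6293),
                            c(-0.6293, -0.6293, 0.6293),
                            c(-0.6293, 0.6293, -0.6293),
                            c(0.6293, -0.6293, -0.6293)))
)

#' Library monomer
#'
#' @param name one of `"h2o"`, `"nh3"`, `"ch4"`
#' @inheritParams build_chain_acid
#' @return a `less_system`
#' @export
fixture_monomer <- function(name, ao_basis = "dz", aux_basis = "autoaux") {
  g <- monomer_geometries[[tolower(name)]]
  if (is.null(g)) stop("unknown monomer '", name, "'")
  less_system(g$symbols, g$coords, ao_basis = ao_basis,
              aux_basis = aux_basis, unit = "angstrom")
}

#' Two well-separated copies of a library monomer
#'
#' The second copy is translated along x by `distance` (Bohr).  Used for
#' separable-limit checks (additive energies, clean active/environment
#' split, distance decay of the fitting domains).
#'
#' @param monomer monomer name, see [fixture_monomer()]
#' @param distance separation in Bohr (> 0)
#' @inheritParams build_chain_acid
#' @return a `less_system`; atoms of monomer 1 come first
#' @export
build_separated_dimer <- function(monomer, distance, ao_basis = "dz",
                                  aux_basis = "autoaux") {
  if (distance <= 0) stop("distance must be positive")
  g <- monomer_geometries[[tolower(monomer)]]
  if (is.null(g)) stop("unknown monomer '", monomer, "'")
  c1 <- g$coords * bohr_per_angstrom
  c2 <- c1
  c2[, 1] <- c2[, 1] + distance
  less_system(rep(g$symbols, 2), rbind(c1, c2), ao_basis = ao_basis,
              aux_basis = aux_basis, unit = "bohr")
}

#' Small pi-system reaction fixture (butadiene + ethene cycloaddition pair)
#'
#' A compact stand-in for large conjugated benchmark reactions: planar
#' s-trans butadiene and ethene as separate reactants.
#'
#' @inheritParams build_chain_acid
#' @return list with `butadiene` and `ethene` systems
#' @export
build_pi_fixture <- function(ao_basis = "dz", aux_basis = "autoaux") {
  buta <- less_system(
    c("C", "C", "C", "C", "H", "H", "H", "H", "H", "H"),
    rbind(c(0.6050, 1.7450, 0), c(0.6050, 0.4050, 0),
          c(-0.6050, -0.4050, 0), c(-0.6050, -1.7450, 0),
          c(1.5420, 2.2920, 0), c(-0.3320, 2.3120, 0),
          c(1.5420, -0.1620, 0), c(-1.5420, 0.1620, 0),
          c(0.3320, -2.3120, 0), c(-1.5420, -2.2920, 0)),
    ao_basis = ao_basis, aux_basis = aux_basis, unit = "angstrom")
  ethe <- less_system(
    c("C", "C", "H", "H", "H", "H"),
    rbind(c(0, 0.6695, 0), c(0, -0.6695, 0),
          c(0.9289, 1.2321, 0), c(-0.9289, 1.2321, 0),
          c(0.9289, -1.2321, 0), c(-0.9289, -1.2321, 0)),
    ao_basis = ao_basis, aux_basis = aux_basis, unit = "angstrom")
  list(butadiene = buta, ethene = ethe)
}
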