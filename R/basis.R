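# Built-in Gaussian basis library and shell-set construction.
#
# Contraction coefficients are stored in the usual convention (they multiply
# normalized primitives); primitive normalization is applied when a shell
# set is built and the contracted functions are renormalized against the
# computed overlap (AO sets) or Coulomb-metric-consistent overlap (aux sets)
# diagonal, so every basis function has unit self-overlap.

sh <- function(l, exps, coefs) list(l = l, exps = exps, coefs = coefs)

basis_sto3g <- list(
  H = list(sh(0, c(3.42525091, 0.62391373, 0.16885540),
              c(0.15432897, 0.53532814, 0.44463454))),
  He = list(sh(0, c(6.36242139, 1.15892300, 0.31364979),
               c(0.15432897, 0.53532814, 0.44463454))),
  C = list(
    sh(0, c(71.6168370, 13.0450960, 3.5305122),
       c(0.15432897, 0.53532814, 0.44463454)),
    sh(0, c(2.9412494, 0.6834831, 0.2222899),
       c(-0.09996723, 0.39951283, 0.70011547)),
    sh(1, c(2.9412494, 0.6834831, 0.2222899),
       c(0.15591627, 0.60768372, 0.39195739))
  ),
  N = list(
    sh(0, c(99.1061690, 18.0523120, 4.8856602),
       c(0.15432897, 0.53532814, 0.44463454)),
    sh(0, c(3.7804559, 0.8784966, 0.2857144),
       c(-0.09996723, 0.39951283, 0.70011547)),
    sh(1, c(3.7804559, 0.8784966, 0.2857144),
       c(0.15591627, 0.60768372, 0.39195739))
  ),
  O = list(
    sh(0, c(130.7093200, 23.8088610, 6.4436083),
       c(0.15432897, 0.53532814, 0.44463454)),
    sh(0, c(5.0331513, 1.1695961, 0.3803890),
       c(-0.09996723, 0.39951283, 0.70011547)),
    sh(1, c(5.0331513, 1.1695961, 0.3803890),
       c(0.15591627, 0.60768372, 0.39195739))
  )
)

# Split-valence double-zeta set ("dz"): 6-31G parameters for H, C, N, O.
# Cl carries an uncontracted even-tempered double-zeta-quality set (no
# third-row split-valence data is bundled); it is internally consistent
# for all fixture comparisons.
et_shells <- function(l, a0, ratio, n) {
  lapply(seq_len(n) - 1L, function(k) sh(l, a0 * ratio^k, 1.0))
}

basis_dz <- list(
  H = list(
    sh(0, c(18.7311370, 2.8253937, 0.6401217),
       c(0.03349460, 0.23472695, 0.81375733)),
    sh(0, 0.1612778, 1.0)
  ),
  C = list(
    sh(0, c(3047.5249, 457.36951, 103.94869, 29.210155, 9.2866630, 3.1639270),
       c(0.0018347, 0.0140373, 0.0688426, 0.2321844, 0.4679413, 0.3623120)),
    sh(0, c(7.8682724, 1.8812885, 0.5442493),
       c(-0.1193324, -0.1608542, 1.1434564)),
    sh(1, c(7.8682724, 1.8812885, 0.5442493),
       c(0.0689991, 0.3164240, 0.7443083)),
    sh(0, 0.1687144, 1.0),
    sh(1, 0.1687144, 1.0)
  ),
  N = list(
    sh(0, c(4173.5110, 627.45790, 142.90210, 40.234330, 12.820210, 4.3904370),
       c(0.0018348, 0.0139950, 0.0685870, 0.2322410, 0.4690700, 0.3604550)),
    sh(0, c(11.626358, 2.7162800, 0.7722180),
       c(-0.1149610, -0.1691180, 1.1458520)),
    sh(1, c(11.626358, 2.7162800, 0.7722180),
       c(0.0675800, 0.3239070, 0.7408950)),
    sh(0, 0.2120313, 1.0),
    sh(1, 0.2120313, 1.0)
  ),
  O = list(
    sh(0, c(5484.6717, 825.23495, 188.04696, 52.964500, 16.897570, 5.7996353),
       c(0.0018311, 0.0139501, 0.0684451, 0.2327143, 0.4701930, 0.3585209)),
    sh(0, c(15.539616, 3.5999336, 1.0137618),
       c(-0.1107775, -0.1480263, 1.1307670)),
    sh(1, c(15.539616, 3.5999336, 1.0137618),
       c(0.0708743, 0.3397528, 0.7271586)),
    sh(0, 0.2700058, 1.0),
    sh(1, 0.2700058, 1.0)
  ),
  Cl = c(
    et_shells(0, 0.09, 3.6, 11),
    et_shells(1, 0.075, 3.6, 8)
  )
)

basis_library <- list(`sto-3g` = basis_sto3g, dz = basis_dz)

prim_norm <- function(a, l) {
  dfact <- c(1, 1, 3)[l + 1]
  (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(dfact)
}

element_basis <- function(basis_name, symbol) {
  lib <- basis_library[[basis_name]]
  if (is.null(lib)) {
    stop("unknown AO basis '", basis_name, "'; available: ",
         paste(names(basis_library), collapse = ", "))
  }
  bs <- lib[[symbol]]
  if (is.null(bs)) {
    stop("basis '", basis_name, "' has no parameters for element ", symbol)
  }
  bs
}

# Even-tempered auxiliary set generated from the AO exponent ranges of an
# element.  `dense` widens and tightens the progression (used by tests that
# need the density-fitting residual to be very small on tiny systems).
autoaux_element <- function(ao_shells, dense = FALSE) {
  ratio <- if (dense) 2.0 else 3.2
  caps <- if (dense) c(16, 12, 8) else c(12, 8, 6)
  exps_by_l <- list(`0` = numeric(), `1` = numeric(), `2` = numeric())
  for (s in ao_shells) {
    key <- as.character(min(s$l, 2))
    exps_by_l[[key]] <- c(exps_by_l[[key]], s$exps)
  }
  all_exps <- unlist(exps_by_l)
  a_min <- min(all_exps)
  a_max_s <- max(all_exps)
  has_p <- length(exps_by_l[["1"]]) > 0
  a_max_p <- if (has_p) max(exps_by_l[["1"]]) else sqrt(a_min * a_max_s)
  a_min_p <- if (has_p) min(exps_by_l[["1"]]) else a_min
  lmax <- if (has_p) 2L else 1L
  ranges <- list(
    c(2 * a_min, 2 * a_max_s),          # L = 0
    c(2 * a_min, 2 * a_max_p),          # L = 1
    c(2 * min(a_min_p, a_min * 4), 2 * a_max_p) # L = 2
  )
  out <- list()
  for (L in 0:lmax) {
    rg <- ranges[[L + 1]]
    n <- min(caps[L + 1], max(2L, ceiling(log(rg[2] / rg[1]) / log(ratio)) + 1L))
    e <- rg[1] * (rg[2] / rg[1])^((seq_len(n) - 1) / (n - 1))
    for (a in e) out[[length(out) + 1L]] <- sh(L, a, 1.0)
  }
  out
}

# Build a flat shell-set structure (the layout consumed by the C++ engine)
# for either the AO or the auxiliary basis of a system.
build_shellset <- function(system, which = c("ao", "aux")) {
  which <- match.arg(which)
  nat <- nrow(system$coords)
  l <- integer(); atom <- integer(); nprim <- integer()
  exps <- numeric(); coefs <- numeric()
  centers <- NULL
  for (ia in seq_len(nat)) {
    sym <- system$symbols[ia]
    if (which == "ao") {
      shells <- element_basis(system$ao_basis, sym)
    } else if (system$aux_basis %in% c("autoaux", "autoaux-dense")) {
      ao_shells <- element_basis(system$ao_basis, sym)
      shells <- autoaux_element(ao_shells,
                                dense = identical(system$aux_basis,
                                                  "autoaux-dense"))
    } else {
      shells <- element_basis(system$aux_basis, sym)
    }
    for (s in shells) {
      l <- c(l, s$l); atom <- c(atom, ia); nprim <- c(nprim, length(s$exps))
      cf <- s$coefs * prim_norm(s$exps, s$l)
      exps <- c(exps, s$exps); coefs <- c(coefs, cf)
      centers <- rbind(centers, system$coords[ia, ])
    }
  }
  nsph <- 2L * l + 1L
  ptr <- cumsum(c(0L, nsph))[seq_along(l)]
  poff <- cumsum(c(0L, nprim))[seq_along(l)]
  ss <- list(l = l, atom = atom, ptr = as.integer(ptr),
             nprim = as.integer(nprim), poff = as.integer(poff),
             exps = exps, coefs = coefs, centers = centers,
             nbf = sum(nsph))
  # renormalize contracted functions to unit self-overlap
  d <- diag(cpp_overlap(ss))
  scale <- 1 / sqrt(d[ss$ptr + 1L])
  rep_scale <- rep(scale, times = ss$nprim)
  ss$coefs <- ss$coefs * rep_scale
  ss
}

#' Shell map of a bound system
#'
#' Returns the per-shell bookkeeping table for the AO or auxiliary basis of
#' a backend handle: parent atom, angular momentum, first (1-based) function
#' index and function count.  Shell completeness of all reduction schemes is
#' defined against this map.
#'
#' @param handle a backend handle from [backend_handle()]
#' @param which `"ao"` or `"aux"`
#' @return data.frame with columns `atom`, `l`, `first`, `count`
#' @export
shell_map <- function(handle, which = c("ao", "aux")) {
  which <- match.arg(which)
  ss <- if (which == "ao") handle$ao else handle$aux
  data.frame(atom = ss$atom, l = ss$l, first = ss$ptr + 1L,
             count = 2L * ss$l + 1L)
}

# map every function index (1-based) to its shell row
function_shell_index <- function(ss) {
  rep(seq_along(ss$l), times = 2L * ss$l + 1L)
}

# expand a set of shell rows to their (sorted) 1-based function indices
shells_to_functions <- function(ss, shell_rows) {
  idx <- integer()
  for (s in sort(unique(shell_rows))) {
    idx <- c(idx, ss$ptr[s] + seq_len(2L * ss$l[s] + 1L))
  }
  sort(idx)
}

# verify that a function index set is shell-complete; returns shell rows
assert_shell_complete <- function(ss, fun_idx, what = "index set") {
  fun_idx <- sort(unique(fun_idx))
  shrows <- unique(function_shell_index(ss)[fun_idx])
  full <- shells_to_functions(ss, shrows)
  if (!identical(as.integer(full), as.integer(fun_idx))) {
    stop(what, " is not shell-complete")
  }
  shrows
}
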