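# Active/environment partitioning and the embedding operators.
#
# The total energy of the hybrid-in-GGA scheme is
#   E = E_LL[D^AB] - E_LL[D^A] + E_HL[Dt^A] + Tr{(Dt^A - D^A) v_emb}
# where v_emb is the low-level two-electron + XC potential difference
# between the full and the active density, added to the high-level core
# Hamiltonian, and orthogonality of the relaxed active orbitals to the
# frozen environment is enforced by the Huzinaga operator
#   H = F - S D^B F - F D^B S
# or by the level shift F + alpha S D^B S.

# Mulliken gross population of each MO on each atom
mo_atom_populations <- function(C, S, ao_atom) {
  SC <- S %*% C
  pops <- C * SC                       # nao x nmo, per-AO contribution
  rowsum(pops, group = ao_atom)        # natom x nmo (atoms in sort order)
}

# Pipek-Mezey localization (Mulliken metric) by Jacobi sweeps
pipek_mezey <- function(C, S, ao_atom, max_sweep = 120, tol = 1e-10) {
  nmo <- ncol(C)
  if (nmo < 2) return(list(C = C, converged = TRUE, sweeps = 0L))
  atoms <- sort(unique(ao_atom))
  converged <- FALSE
  for (sweep in seq_len(max_sweep)) {
    gain_total <- 0
    SC <- S %*% C
    for (i in seq_len(nmo - 1)) for (j in (i + 1):nmo) {
      # per-atom symmetrized Mulliken blocks
      Qii <- Qjj <- Qij <- numeric(length(atoms))
      pii <- C[, i] * SC[, i]
      pjj <- C[, j] * SC[, j]
      pij <- 0.5 * (C[, i] * SC[, j] + C[, j] * SC[, i])
      Qii <- rowsum(pii, ao_atom)[, 1]
      Qjj <- rowsum(pjj, ao_atom)[, 1]
      Qij <- rowsum(pij, ao_atom)[, 1]
      A <- sum(Qij^2 - 0.25 * (Qii - Qjj)^2)
      B <- sum(Qij * (Qii - Qjj))
      if (A^2 + B^2 < 1e-24) next
      gain <- A + sqrt(A^2 + B^2)
      if (gain < tol) next
      gamma <- 0.25 * atan2(B, -A)
      cg <- cos(gamma); sg <- sin(gamma)
      ci <- C[, i]; cj <- C[, j]
      C[, i] <- cg * ci + sg * cj
      C[, j] <- -sg * ci + cg * cj
      si <- SC[, i]; sj <- SC[, j]
      SC[, i] <- cg * si + sg * sj
      SC[, j] <- -sg * si + cg * sj
      gain_total <- gain_total + gain
    }
    if (gain_total < tol * nmo) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("orbital localization stalled; returning the last iterate")
  }
  list(C = C, converged = converged, sweeps = sweep)
}

#' Localize the occupied space and select active orbitals
#'
#' Localizes the converged low-level occupied MOs (Pipek-Mezey, Mulliken
#' metric) and assigns each localized MO to the active set when its summed
#' Mulliken population on the active atoms reaches `tau_sel`; the remainder
#' become the frozen environment.
#'
#' @param low converged full-system low-level `less_scf` state
#' @param handle the backend handle of the low-level run
#' @param active_atoms 1-based atom indices of the active region
#' @param tau_sel selection threshold on the active-atom population of a
#'   localized MO (default 0.4)
#' @return an object of class `less_partition` with `C_A`, `C_B`, `D_A`,
#'   `D_B`, `n_act`, `selection_scores`
#' @export
localize_and_select <- function(low, handle, active_atoms, tau_sel = 0.4) {
  if (!isTRUE(low$converged)) stop("low-level state is not converged")
  nat <- length(handle$system$symbols)
  active_atoms <- sort(unique(as.integer(active_atoms)))
  if (length(active_atoms) == 0 || any(active_atoms < 1) ||
      any(active_atoms > nat)) {
    stop("active_atoms must be a non-empty set of valid atom indices")
  }
  S <- one_electron(handle)$S
  ao_atom <- rep(handle$ao$atom, times = 2L * handle$ao$l + 1L)
  loc <- pipek_mezey(low$C_occ, S, ao_atom)
  pops <- mo_atom_populations(loc$C, S, ao_atom)
  scores <- colSums(pops[active_atoms, , drop = FALSE])
  act <- which(scores >= tau_sel)
  if (length(act) == 0) {
    stop("no occupied MO reaches the selection threshold on the active ",
         "atoms; enlarge the active set or lower tau_sel")
  }
  C_A <- loc$C[, act, drop = FALSE]
  C_B <- loc$C[, -act, drop = FALSE]
  p <- list(active_atoms = active_atoms, C_A = C_A, C_B = C_B,
            D_A = 2 * tcrossprod(C_A), D_B = 2 * tcrossprod(C_B),
            n_act = length(act), selection_scores = scores,
            tau_sel = tau_sel)
  class(p) <- "less_partition"
  p
}

#' @export
print.less_partition <- function(x, ...) {
  cat("<less_partition> ", x$n_act, " active / ",
      ncol(x$C_B), " environment MOs on ",
      length(x$active_atoms), " active atoms\n", sep = "")
  invisible(x)
}

#' Huzinaga operator
#'
#' `H = F - S D^B F - F D^B S`; symmetric, and equal to `F` for an empty
#' environment.  Replaces the Fock matrix in the embedded SCF, enforcing
#' orthogonality of its occupied solutions to the environment orbitals.
#' `D_B` must be idempotent in the overlap metric (`S D_B S D_B = S D_B`,
#' i.e. one orbital per column, `C_B C_B^T`); only then does the
#' active-environment coupling block of `H` vanish.
#'
#' @param F symmetric (high-level) Fock matrix
#' @param D_B frozen environment density, idempotent in the `S` metric
#' @param S overlap in the same basis
#' @export
huzinaga_matrix <- function(F, D_B, S) {
  if (!all(dim(F) == dim(D_B)) || !all(dim(F) == dim(S))) {
    stop("dimension mismatch")
  }
  SDF <- S %*% D_B %*% F
  F - SDF - t(SDF)
}

#' Level-shift projector Fock matrix
#'
#' `F + alpha S D^B S`; pushes solutions overlapping the frozen
#' environment up by `alpha`, approaching the Huzinaga result as
#' `alpha -> Inf`.
#'
#' @inheritParams huzinaga_matrix
#' @param alpha level shift in Hartree (non-negative)
#' @export
projector_fock <- function(F, D_B, S, alpha) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (!all(dim(F) == dim(D_B)) || !all(dim(F) == dim(S))) {
    stop("dimension mismatch")
  }
  P <- S %*% D_B %*% S
  F + alpha * (P + t(P)) / 2
}

#' Embedding potential
#'
#' The fixed one-electron operator added to the high-level core
#' Hamiltonian: the low-level two-electron + exchange-correlation potential
#' of the full density minus that of the active density,
#' `v_emb = (J + V_xc - c_HFx K)[D^AB] - (J + V_xc - c_HFx K)[D^A]`.
#' Independent of the high-level functional.
#'
#' @param handle backend handle
#' @param low_functional the low-level functional name
#' @param D_AB full low-level density
#' @param D_A active-subsystem low-level density
#' @param T full-basis `less_tensors` (defaults to fresh full tensors)
#' @param C_AB,C_A optional occupied coefficients generating the two
#'   densities (speeds up the exchange part for hybrid low levels)
#' @return symmetric matrix `h_emb` on the full AO basis
#' @export
embedding_potential <- function(handle, low_functional, D_AB, D_A,
                                T = NULL, C_AB = NULL, C_A = NULL) {
  f <- functional_info(low_functional)
  if (is.null(T)) T <- build_tensors(handle)
  pot <- function(D, C) {
    v <- build_coulomb(D, T)
    if (f$c_hfx > 0) {
      v <- v + if (!is.null(C)) build_exchange(C, T, f$c_hfx)
               else exchange_from_density(D, T, f$c_hfx)
    }
    if (f$has_xc) v <- v + xc_eval(handle, low_functional, D)$V_xc
    v
  }
  v <- pot(D_AB, C_AB) - pot(D_A, C_A)
  (v + t(v)) / 2
}

#' Embedded high-level SCF
#'
#' Optimizes `n_act` active orbitals with the high-level functional in the
#' (possibly reduced) AO basis, with the environment frozen and
#' orthogonality enforced by the requested operator.
#'
#' @param handle backend handle
#' @param T tensors for the high-level run (carries the kept AO set and any
#'   auxiliary reduction)
#' @param partition a `less_partition` (or the reduced equivalent from
#'   [reorthogonalize()] wrapped by the caller)
#' @param hl_functional high-level functional name
#' @param h_emb embedding potential on the full AO basis
#' @param mode `"huzinaga"` or `"projector"`
#' @param alpha level shift (projector mode, Hartree)
#' @param options SCF options, see [scf_solve()]
#' @return a `less_scf` state for the active subsystem; energy components
#'   refer to the bare subsystem Hamiltonian, with the embedding term kept
#'   out of `E_1e` (it enters the total energy through the first-order
#'   correction in [assemble_energy()])
#' @export
embedded_scf <- function(handle, T, partition, hl_functional, h_emb,
                         mode = c("huzinaga", "projector"), alpha = 1e6,
                         options = list()) {
  mode <- match.arg(mode)
  # occupy by projection onto the starting active orbitals: the embedded
  # run optimizes the state continuously connected to the low-level
  # active space, and plain aufbau oscillates when the embedded gap is
  # small (see scf_solve); callers may still force "aufbau" explicitly
  options <- utils::modifyList(list(occupation = "guess"), options)
  kept <- T$kept_ao
  oe <- one_electron(handle)
  h_red <- oe$h[kept, kept, drop = FALSE]
  v_red <- h_emb[kept, kept, drop = FALSE]
  C_B <- partition$C_B_red
  C_A0 <- partition$C_A_red
  if (is.null(C_B)) {
    # no AO reduction: use the partition blocks directly
    C_B <- partition$C_B
    C_A0 <- partition$C_A
  }
  # S-idempotent environment density (one orbital per column); the factor-2
  # spin-traced density would leave a residual active-environment coupling
  # in the Huzinaga matrix
  D_B <- tcrossprod(C_B)
  project <- if (ncol(C_B) > 0) {
    list(mode = mode, D_B = D_B, alpha = alpha)
  } else NULL
  scf_solve(handle, T, hl_functional, h_eff = h_red + v_red,
            n_occ = partition$n_act, guess = C_A0, options = options,
            project = project, h_energy = h_red)
}

#' Assemble the embedding total energy
#'
#' `E = E_LL[D^AB] - E_LL[D^A] + E_HL[Dt^A] + Tr{(Dt^A - D^A) v_emb}`.
#' The low-level subsystem term is evaluated in the full basis at the
#' partition's active density; the correction trace uses the densities the
#' high-level run actually saw (reduced basis, if AO reduction is active).
#'
#' @param low full-system low-level `less_scf`
#' @param partition the `less_partition` used
#' @param high embedded high-level `less_scf`
#' @param h_emb embedding potential (full basis)
#' @param handle backend handle
#' @param T_ll full-basis tensors of the low-level run
#' @param ll_functional low-level functional name
#' @return object of class `less_energy` with the five energy fields
#' @export
assemble_energy <- function(low, partition, high, h_emb, handle, T_ll,
                            ll_functional) {
  if (!isTRUE(low$converged) || !isTRUE(high$converged)) {
    stop("both SCF states must be converged")
  }
  E_LL_full <- low$E_total
  E_LL_act <- scf_energy(handle, T_ll, ll_functional, partition$D_A,
                         C_occ = partition$C_A)$E_total
  E_HL_act <- high$E_total
  kept <- high$kept_ao
  C_A_ref <- if (!is.null(partition$C_A_red)) partition$C_A_red
             else partition$C_A
  D_A_ref <- 2 * tcrossprod(C_A_ref)
  E_corr <- sum((high$D - D_A_ref) * h_emb[kept, kept, drop = FALSE])
  out <- list(E_LL_full = E_LL_full, E_LL_act = E_LL_act,
              E_HL_act = E_HL_act, E_corr = E_corr,
              E_total = E_LL_full - E_LL_act + E_HL_act + E_corr,
              n_act = partition$n_act, n_env = ncol(partition$C_B))
  class(out) <- "less_energy"
  out
}

#' @export
print.less_energy <- function(x, ...) {
  cat("<less_energy>  (all values in Hartree)\n")
  cat(sprintf("  E_LL[D_AB]  %18.10f\n", x$E_LL_full))
  cat(sprintf("  E_LL[D_A]   %18.10f\n", x$E_LL_act))
  cat(sprintf("  E_HL[Dt_A]  %18.10f\n", x$E_HL_act))
  cat(sprintf("  correction  %18.10f\n", x$E_corr))
  cat(sprintf("  E_total     %18.10f\n", x$E_total))
  cat(sprintf("  active/environment MOs: %d/%d\n", x$n_act, x$n_env))
  invisible(x)
}
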