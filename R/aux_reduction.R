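# The three auxiliary-basis reduction schemes for the high-level run:
# natural auxiliary functions (SVD of the active-MO half-transformed
# three-center integrals), generalized Mulliken charges on fitting
# functions, and local density-fitting shell domains built from Loewdin
# charges plus Cauchy-Schwarz extension.

#' Natural auxiliary functions
#'
#' Builds the Gram matrix `W_PQ = sum_{mu i} J^P_{mu i} J^Q_{mu i}` of the
#' half-transformed integrals `J^P_{mu i} = sum_{Q nu} C^A_{nu i}
#' (mu nu|Q) L_QP`, diagonalizes it, and retains the columns whose singular
#' values (square roots of the eigenvalues) exceed `eps_naf`.  The NAFs are
#' built once from the low-level active orbitals, not per high-level
#' iteration.
#'
#' @param C_A active occupied MO coefficients (full AO basis)
#' @param T full-auxiliary `less_tensors`
#' @param eps_naf retention threshold on the singular values (Hartree)
#' @return object of class `less_naf` with the retained columns `N`
#'   (orthonormal), singular values `sigma`, and `W`
#' @export
naf_build <- function(C_A, T, eps_naf) {
  if (eps_naf < 0) stop("eps_naf must be non-negative")
  if (!is.null(T$naf)) stop("naf_build needs untransformed tensors")
  half <- half_transform(C_A, T)       # (naux_eff) x (n * nocc)
  W <- tcrossprod(half)
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  sigma <- sqrt(pmax(e$values, 0))
  # at a zero threshold the complete (orthogonal) rotation is kept, null
  # space included, so the transformation is exactly unitary
  keep <- if (eps_naf == 0) rep(TRUE, length(sigma)) else sigma > eps_naf
  if (!any(keep)) stop("eps_naf retains no natural auxiliary function")
  out <- list(N = e$vectors[, keep, drop = FALSE], sigma = sigma,
              eps_naf = eps_naf, n_full = T$naux_eff)
  class(out) <- "less_naf"
  out
}

# J^P_{mu i} over the full kept AO set, as matrix naux_eff x (n * nocc)
half_transform <- function(C_A, T) {
  C <- C_A[T$kept_ao, , drop = FALSE]
  nocc <- ncol(C)
  out <- matrix(0, T$naux_eff, T$n * nocc)
  for (si in seq_along(T$kept_shells)) {
    B <- tensor_block(T, si)
    keep <- T$screen_map[[si]]
    nmu <- length(T$shell_fun[[si]])
    half <- matrix(B, nrow = T$naux_eff * nmu) %*% C[keep, , drop = FALSE]
    half <- array(half, c(T$naux_eff, nmu, nocc))
    for (k in seq_len(nmu)) {
      mu <- T$shell_fun[[si]][k]
      out[, mu + T$n * (seq_len(nocc) - 1L)] <- half[, k, ]
    }
  }
  out
}

#' @export
print.less_naf <- function(x, ...) {
  cat(sprintf("<less_naf> %d of %d natural auxiliary functions (eps %g)\n",
              ncol(x$N), x$n_full, x$eps_naf))
  invisible(x)
}

#' Generalized Mulliken charges on auxiliary functions
#'
#' `qhat_P = sum_Pbar N_{P Pbar}^2 S^DF_{PP}` from the retained NAF
#' columns; an auxiliary shell is kept when any of its functions exceeds
#' `eps_mull`, and then the whole shell is kept.
#'
#' @param naf a `less_naf`
#' @param S_df auxiliary-basis overlap matrix
#' @param eps_mull retention threshold
#' @param aux_shell_map shell table of the auxiliary basis
#' @return sorted 1-based indices of the retained auxiliary functions;
#'   the charges are attached as attribute `"qhat"`
#' @export
generalized_mulliken <- function(naf, S_df, eps_mull, aux_shell_map) {
  qhat <- rowSums(naf$N^2) * diag(S_df)
  kept <- tryCatch(select_shells(qhat, eps_mull, aux_shell_map),
                   error = function(e) {
                     stop("eps_mull removes every auxiliary function")
                   })
  attr(kept, "qhat") <- qhat
  kept
}

#' Local density-fitting domains
#'
#' Per localized active MO, atoms carrying a Loewdin charge above
#' `lowdin_cut` form the primary domain; the union domain is extended by
#' Cauchy-Schwarz screening: the auxiliary shells of angular momentum l on
#' atom B are retained when
#' `sqrt(max_{mu in A, nu in B} (mu nu|mu nu)) * sqrt(max_{P in B_l} (P|P))
#'  > eps_dom` for any primary atom A.  The final fitting set is the union
#' over the active MOs, shell complete by construction.
#'
#' @param C_A_loc localized active MO coefficients (full AO basis)
#' @param handle backend handle
#' @param eps_dom domain extension threshold (Hartree)
#' @param lowdin_cut primary-domain Loewdin charge cutoff (default 0.05)
#' @return sorted 1-based indices of the retained auxiliary functions, with
#'   attribute `"domains"` (per-MO primary atom sets)
#' @export
ldf_domains <- function(C_A_loc, handle, eps_dom, lowdin_cut = 0.05) {
  oe <- one_electron(handle)
  nat <- length(handle$system$symbols)
  ao_atom <- rep(handle$ao$atom, times = 2L * handle$ao$l + 1L)
  # Loewdin charges in the full AO basis (reduction independent)
  es <- eigen(oe$S, symmetric = TRUE)
  Sh <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  Cl <- Sh %*% C_A_loc
  lowdin <- rowsum(Cl^2, ao_atom)      # natom x nmo
  primary <- lapply(seq_len(ncol(Cl)), function(i) {
    at <- which(lowdin[, i] > lowdin_cut)
    if (length(at) == 0) at <- which.max(lowdin[, i])
    at
  })
  # Cauchy-Schwarz factors: per atom pair, max (mu nu | mu nu)
  diag4c <- eri_diagonal(handle)
  pair_max <- matrix(0, nat, nat)
  for (A in seq_len(nat)) for (B in seq_len(nat)) {
    pair_max[A, B] <- max(diag4c[ao_atom == A, ao_atom == B])
  }
  # per auxiliary shell: max (P|P)
  m2 <- df_integrals(handle)$two_center
  asm <- shell_map(handle, "aux")
  shell_pp <- vapply(seq_len(nrow(asm)), function(s) {
    idx <- asm$first[s] + seq_len(asm$count[s]) - 1L
    max(diag(m2)[idx])
  }, numeric(1))
  keep_shell <- rep(FALSE, nrow(asm))
  prim_atoms_all <- sort(unique(unlist(primary)))
  for (s in seq_len(nrow(asm))) {
    B <- asm$atom[s]
    if (B %in% prim_atoms_all) { keep_shell[s] <- TRUE; next }
    crit <- sqrt(pair_max[prim_atoms_all, B]) * sqrt(shell_pp[s])
    if (any(crit > eps_dom)) keep_shell[s] <- TRUE
  }
  if (!any(keep_shell)) stop("empty union domain")
  kept <- shells_to_functions(handle$aux, which(keep_shell))
  attr(kept, "domains") <- primary
  kept
}

#' Auxiliary retention report
#'
#' Kept fraction of the fitting basis for a reduction outcome.
#'
#' @param handle backend handle
#' @param kept_aux kept auxiliary function indices (or a `less_naf`)
#' @return retained fraction in percent
#' @export
aux_retention <- function(handle, kept_aux) {
  n <- if (inherits(kept_aux, "less_naf")) ncol(kept_aux$N)
       else length(kept_aux)
  100 * n / handle$aux$nbf
}
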