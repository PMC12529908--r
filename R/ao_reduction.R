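# AO basis truncation for the high-level calculation: net Mulliken
# populations of the active orbitals select the retained functions (shell
# complete), the low-level orbitals are re-orthogonalized in the reduced
# metric, poorly represented environment orbitals are dropped, and the
# retained environment space is projected out of the active orbitals.

#' Net Mulliken population of each AO in the active orbitals
#'
#' `q_mu = sum_i (C^A_{mu i})^2 S_{mu mu}` -- the net (diagonal-only)
#' population, invariant under orthogonal mixing of the active MOs.
#'
#' @param C_A active occupied MO coefficients (full AO basis)
#' @param S AO overlap
#' @return numeric vector of length nAO
#' @export
net_population <- function(C_A, S) {
  rowSums(C_A^2) * diag(S)
}

#' Select the retained AO shells
#'
#' A basis function is significant when `q_mu > eps_ao`; a shell is kept
#' when any of its functions is significant, and then all functions of the
#' shell are kept.
#'
#' @param q net populations from [net_population()]
#' @param eps_ao AO truncation threshold (>= 0)
#' @param shell_map shell table from [shell_map()]
#' @return sorted 1-based indices of the retained AO functions
#' @export
select_shells <- function(q, eps_ao, shell_map) {
  if (eps_ao < 0) stop("eps_ao must be non-negative")
  keep_rows <- integer()
  for (s in seq_len(nrow(shell_map))) {
    idx <- shell_map$first[s] + seq_len(shell_map$count[s]) - 1L
    if (any(q[idx] > eps_ao)) keep_rows <- c(keep_rows, s)
  }
  if (length(keep_rows) == 0) {
    stop("eps_ao removes every AO; the active orbitals are unrepresentable")
  }
  kept <- integer()
  for (s in keep_rows) {
    kept <- c(kept, shell_map$first[s] + seq_len(shell_map$count[s]) - 1L)
  }
  sort(kept)
}

#' Re-orthogonalize the partition in a reduced AO basis
#'
#' Both orbital sets are truncated to the kept AOs and Loewdin-canonically
#' re-orthonormalized (each set separately).  Environment MOs whose MO
#' overlap eigenvalue falls below `tau_drop` cannot be represented in the
#' reduced basis and are removed; an active MO in that situation is a hard
#' error (the truncation threshold is too aggressive).  Finally the
#' retained environment space is projected out of all active orbitals,
#' which are then symmetrically re-orthonormalized.
#'
#' @param C_A,C_B active / environment MO coefficients truncated to the
#'   kept AO rows
#' @param S_red overlap restricted to the kept AOs
#' @param tau_drop environment-MO drop cutoff on the overlap eigenvalues
#'   (default 1e-3: only numerically unrepresentable environment MOs are
#'   removed; dropping substantially representable ones would leave their
#'   density regions unprotected against active-orbital collapse)
#' @return list with `C_A`, `C_B` (orthonormal in `S_red`, mutually
#'   orthogonal) and `dropped_env_count`
#' @export
reorthogonalize <- function(C_A, C_B, S_red, tau_drop = 1e-3) {
  canon <- function(C, what) {
    if (ncol(C) == 0) {
      return(list(C = C, dropped = 0L, eigenvalues = numeric()))
    }
    M <- crossprod(C, S_red %*% C)
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    keep <- e$values >= tau_drop
    if (what == "active" && !all(keep)) {
      stop("an active MO loses too much norm in the reduced basis ",
           "(overlap eigenvalue ", format(min(e$values), digits = 3),
           "); decrease eps_ao")
    }
    Ck <- C %*% e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
    list(C = Ck, dropped = sum(!keep), eigenvalues = e$values)
  }
  a <- canon(C_A, "active")
  b <- canon(C_B, "environment")
  C_Bp <- b$C
  C_Ap <- a$C
  if (ncol(C_Bp) > 0) {
    C_Ap <- C_Ap - C_Bp %*% crossprod(C_Bp, S_red %*% C_Ap)
    M <- crossprod(C_Ap, S_red %*% C_Ap)
    C_Ap <- C_Ap %*% mat_invsqrt(M)
  }
  list(C_A = C_Ap, C_B = C_Bp, dropped_env_count = b$dropped,
       env_eigenvalues = b$eigenvalues)
}

#' Build an AO reduction plan for a partition
#'
#' Convenience wrapper: net populations of the active orbitals, shell
#' selection at `eps_ao`, truncation and re-orthogonalization.  The
#' returned plan carries the reduced orbital blocks (`C_A_red`, `C_B_red`)
#' that the embedded SCF consumes, plus retention bookkeeping for reports.
#'
#' @param handle backend handle
#' @param partition a `less_partition`
#' @param eps_ao AO truncation threshold (default 1e-4)
#' @param tau_drop see [reorthogonalize()]
#' @return an object of class `less_reduction`
#' @export
ao_reduction_plan <- function(handle, partition, eps_ao = 1e-4,
                              tau_drop = 1e-3) {
  S <- one_electron(handle)$S
  q <- net_population(partition$C_A, S)
  sm <- shell_map(handle, "ao")
  kept_ao <- select_shells(q, eps_ao, sm)
  S_red <- S[kept_ao, kept_ao, drop = FALSE]
  ro <- reorthogonalize(partition$C_A[kept_ao, , drop = FALSE],
                        partition$C_B[kept_ao, , drop = FALSE],
                        S_red, tau_drop)
  plan <- list(q = q, kept_ao = kept_ao,
               retention = length(kept_ao) / handle$ao$nbf,
               eps_ao = eps_ao, tau_drop = tau_drop,
               C_A_red = ro$C_A, C_B_red = ro$C_B,
               dropped_env_count = ro$dropped_env_count)
  class(plan) <- "less_reduction"
  plan
}

#' @export
print.less_reduction <- function(x, ...) {
  cat(sprintf(paste0("<less_reduction> eps_ao = %g: %d AOs kept (%.1f%%), ",
                     "%d environment MO(s) dropped\n"),
              x$eps_ao, length(x$kept_ao), 100 * x$retention,
              x$dropped_env_count))
  invisible(x)
}
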