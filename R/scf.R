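# Restricted closed-shell SCF with density fitting, CDIIS acceleration and
# optional embedding operators (Huzinaga or level-shift projector) applied
# to the Fock matrix at every iteration.

default_scf_options <- function() {
  list(tol_grad = 1e-7, tol_e = 1e-9, max_iter = 250, diis_size = 8,
       damping = 0.5, n_damp = 2, occupation = "aufbau")
}

# canonical orthogonalizer X with X^T S X = I
orthogonalizer <- function(S, floor = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > floor
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

apply_fock_operator <- function(F, project, S) {
  if (is.null(project)) return(F)
  if (project$mode == "huzinaga") {
    huzinaga_matrix(F, project$D_B, S)
  } else {
    projector_fock(F, project$D_B, S, project$alpha)
  }
}

#' Solve the restricted SCF equations
#'
#' Density-fitted closed-shell SCF.  The effective core Hamiltonian is
#' supplied by the caller and may already contain embedding contributions;
#' `project` optionally installs an orthogonality operator (Huzinaga or
#' level-shift projector against a frozen environment density) applied to
#' the Fock matrix each iteration.
#'
#' @param handle a backend handle
#' @param T a `less_tensors` object (defines the kept AO set)
#' @param functional functional name (`"hf"`, `"pbe"`, `"pbe0"`)
#' @param h_eff symmetric effective core Hamiltonian on the kept AO set
#' @param n_occ number of doubly occupied MOs to optimize
#' @param guess optional starting MO coefficients (kept AO set x >= n_occ)
#' @param options list overriding [default_scf_options()] entries
#' @param project optional list(mode = "huzinaga"|"projector", D_B, alpha)
#' @param h_energy core Hamiltonian used for the reported energy
#'   components (defaults to `h_eff`); lets embedded solvers report bare
#'   subsystem energies while iterating with the embedding potential
#' @return an object of class `less_scf` with fields `C_occ`, `eps`, `D`,
#'   energy components (`E_total = E_1e + E_J + E_K + E_xc + E_nuc`),
#'   `n_iter`, `converged`, `diis_error`
#' @export
scf_solve <- function(handle, T, functional, h_eff, n_occ, guess = NULL,
                      options = list(), project = NULL, h_energy = h_eff) {
  opt <- utils::modifyList(default_scf_options(), options)
  f <- functional_info(functional)
  oe <- one_electron(handle)
  kept <- T$kept_ao
  S <- oe$S[kept, kept, drop = FALSE]
  n <- T$n
  if (n_occ > n) stop("n_occ exceeds the kept AO dimension")
  if (max(abs(h_eff - t(h_eff))) > 1e-9) stop("h_eff must be symmetric")
  X <- orthogonalizer(S)
  E_nuc <- oe$E_nuc

  # In Huzinaga mode the eigenproblem is solved in the S-orthogonal
  # complement of the frozen environment span (on which the Huzinaga
  # matrix acts identically to the bare Fock matrix); this enforces the
  # orthogonality constraint exactly and keeps sign-flipped environment
  # solutions out of the aufbau.  In projector mode the full space is
  # used and the level shift does the separation; environment-dominated
  # eigenvectors are excluded from the aufbau by their overlap
  # x^T S D_B S x as a safeguard for moderate shifts.
  X_solve <- X
  Penv <- NULL
  if (!is.null(project)) {
    Po <- crossprod(X, S %*% project$D_B %*% (S %*% X))
    if (project$mode == "huzinaga") {
      ep <- eigen((Po + t(Po)) / 2, symmetric = TRUE)
      X_solve <- X %*% ep$vectors[, ep$values < 0.5, drop = FALSE]
    } else {
      Penv <- Po
    }
  }
  # occupation = "guess": among the (complement) eigenvectors, occupy the
  # n_occ with the largest projection onto the initial-guess span.  This
  # targets the solution continuously connected to the low-level active
  # orbitals, which is what an embedded run optimizes; plain aufbau can
  # flip occupations every iteration when the embedded gap is tiny
  # (anionic head groups are the typical case).
  M0 <- NULL
  occupy <- function(F) {
    Fo <- crossprod(X_solve, F %*% X_solve)
    e <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    if (identical(opt$occupation, "guess") && !is.null(M0)) {
      score <- rowSums(crossprod(e$vectors, M0)^2)
      sel <- sort(order(score, decreasing = TRUE)[seq_len(n_occ)])
    } else {
      ord <- order(e$values)             # aufbau: lowest eigenvalues
      if (!is.null(Penv)) {
        ovl <- colSums(e$vectors * (Penv %*% e$vectors))
        ord <- ord[ovl[ord] < 0.5]
      }
      sel <- ord[seq_len(n_occ)]
    }
    C <- X_solve %*% e$vectors[, sel, drop = FALSE]
    list(C = C, eps = e$values[sel])
  }

  if (is.null(guess)) {
    # superposition of atomic densities, scaled to the electron count;
    # the first Fock matrix is built from this density directly
    C <- NULL
    D <- sad_density(handle)[kept, kept, drop = FALSE]
    D <- D * (2 * n_occ / sum(D * S))
  } else {
    C <- guess[, seq_len(n_occ), drop = FALSE]
    # symmetric re-orthonormalization in the current metric
    M <- crossprod(C, S %*% C)
    C <- C %*% mat_invsqrt(M)
    D <- 2 * tcrossprod(C)
    M0 <- crossprod(X_solve, S %*% C)
  }

  diis_F <- list(); diis_e <- list()
  E_old <- Inf; F_old <- NULL
  converged <- FALSE; it <- 0; grad <- Inf
  E_parts <- NULL; eps <- rep(NA_real_, n_occ)

  for (it in seq_len(opt$max_iter)) {
    FJ <- build_coulomb(D, T)
    FK <- if (!is.null(C)) build_exchange(C, T, f$c_hfx)
          else exchange_from_density(D, T, f$c_hfx, S = S)
    xc <- if (f$has_xc) {
      xc_eval(handle, functional, D, kept_ao = kept)
    } else list(E_xc = 0, V_xc = matrix(0, n, n))
    F <- h_eff + FJ + FK + xc$V_xc
    E_parts <- list(E_1e = sum(D * h_energy), E_J = 0.5 * sum(D * FJ),
                    E_K = 0.5 * sum(D * FK), E_xc = xc$E_xc, E_nuc = E_nuc)
    E <- sum(unlist(E_parts))

    Fmod <- apply_fock_operator(F, project, S)
    err <- crossprod(X, (Fmod %*% D %*% S - S %*% D %*% Fmod) %*% X)
    grad <- max(abs(err))
    if (abs(E - E_old) < opt$tol_e && grad < opt$tol_grad && it > 1) {
      converged <- TRUE
      E_old <- E
      break
    }
    E_old <- E

    # CDIIS on the modified Fock matrix
    diis_F[[length(diis_F) + 1]] <- Fmod
    diis_e[[length(diis_e) + 1]] <- err
    if (length(diis_F) > opt$diis_size) {
      diis_F <- diis_F[-1]; diis_e <- diis_e[-1]
    }
    # prune the oldest entries until the DIIS system is well conditioned
    while (length(diis_F) >= 2) {
      nd <- length(diis_F)
      B <- matrix(0, nd, nd)
      for (i in seq_len(nd)) for (j in seq_len(nd)) {
        B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      }
      A <- rbind(cbind(B / max(B), -1), c(rep(-1, nd), 0))
      if (rcond(A) > 1e-13) break
      diis_F <- diis_F[-1]; diis_e <- diis_e[-1]
    }
    nd <- length(diis_F)
    if (nd >= 2) {
      cf <- solve(A, c(rep(0, nd), -1))[seq_len(nd)]
      Fuse <- Reduce(`+`, Map(`*`, diis_F, cf))
    } else if (!is.null(F_old) && it <= opt$n_damp + 1) {
      Fuse <- (1 - opt$damping) * Fmod + opt$damping * F_old
    } else {
      Fuse <- Fmod
    }
    F_old <- Fmod

    sol <- occupy(Fuse)
    C <- sol$C; eps <- sol$eps
    D <- 2 * tcrossprod(C)
  }
  if (!converged) {
    warning(sprintf("SCF did not converge in %d iterations (|dE| grad %.2e)",
                    it, grad))
  }
  state <- c(list(C_occ = C, eps = eps, D = D,
                  E_total = sum(unlist(E_parts))),
             E_parts,
             list(n_iter = it, converged = converged, diis_error = grad,
                  functional = functional, n_occ = n_occ, kept_ao = kept))
  class(state) <- "less_scf"
  state
}

mat_invsqrt <- function(M, floor = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) < floor) {
    stop("matrix is numerically singular in mat_invsqrt")
  }
  e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
}

#' @export
print.less_scf <- function(x, ...) {
  cat(sprintf("<less_scf> %s, E_total = %.10f Eh (%s in %d iterations)\n",
              x$functional, x$E_total,
              if (x$converged) "converged" else "NOT CONVERGED", x$n_iter))
  cat(sprintf("  E_1e %.8f  E_J %.8f  E_K %.8f  E_xc %.8f  E_nuc %.8f\n",
              x$E_1e, x$E_J, x$E_K, x$E_xc, x$E_nuc))
  invisible(x)
}

#' Evaluate the SCF energy functional at a fixed density
#'
#' Computes `Tr(D h) + E_J[D] + E_K[D] + E_xc[D] + E_nuc` without any
#' orbital optimization.  Used for the subsystem terms of the embedding
#' energy expression and by finite-difference tests.
#'
#' @param handle backend handle
#' @param T tensors (kept AO set must match `D`)
#' @param functional functional name
#' @param D closed-shell density
#' @param h core Hamiltonian (defaults to the bare one on the kept set)
#' @param C_occ optional occupied coefficients generating `D` (avoids a
#'   density factorization for the exchange part)
#' @return list of energy components and their sum `E_total`
#' @export
scf_energy <- function(handle, T, functional, D, h = NULL, C_occ = NULL) {
  f <- functional_info(functional)
  oe <- one_electron(handle)
  kept <- T$kept_ao
  if (is.null(h)) h <- oe$h[kept, kept, drop = FALSE]
  FJ <- build_coulomb(D, T)
  FK <- if (f$c_hfx == 0) matrix(0, T$n, T$n)
        else if (!is.null(C_occ)) build_exchange(C_occ, T, f$c_hfx)
        else exchange_from_density(D, T, f$c_hfx,
                                   S = oe$S[kept, kept, drop = FALSE])
  E_xc <- if (f$has_xc) xc_eval(handle, functional, D, kept_ao = kept)$E_xc
          else 0
  parts <- list(E_1e = sum(D * h), E_J = 0.5 * sum(D * FJ),
                E_K = 0.5 * sum(D * FK), E_xc = E_xc, E_nuc = oe$E_nuc)
  c(parts, list(E_total = sum(unlist(parts))))
}

#' Write / read an SCF checkpoint
#'
#' Serializes the SCF state together with tensor metadata (kept index sets,
#' mode, thresholds) so a subsequent high-level run can restart from the
#' low-level result.  Stored as an RDS container.
#'
#' @param state a `less_scf`
#' @param T the `less_tensors` the state was solved with (metadata only)
#' @param path file path
#' @export
write_checkpoint <- function(state, T, path) {
  meta <- list(kept_ao = T$kept_ao, kept_aux = T$kept_aux,
               naux_eff = T$naux_eff, mode = T$mode,
               screen_threshold = T$screen_threshold)
  saveRDS(list(state = unclass(state), tensor_meta = meta), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  class(x$state) <- "less_scf"
  x
}
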