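# Density-fitting tensor plumbing.
#
# The transformed three-center integrals J^P_{mu nu} = sum_Q (mu nu|Q) L_QP
# (L the triangular factor with (P|Q)^{-1} = L L^T) are either stored whole
# in an in-core shellwise layout -- P fastest, mu restricted to its shell,
# nu slowest, with (nu, shell) blocks whose J^S_nu = max_{mu in S} max_P
# |J^P_{mu nu}| falls below the screening threshold absent -- or produced
# blockwise on the fly in integral-direct mode.

pair_index <- function(mu, nu) {
  # 1-based packed lower-triangle index for mu >= nu (vectors allowed)
  m <- pmax(mu, nu) - 1L
  n <- pmin(mu, nu) - 1L
  m * (m + 1L) / 2L + n + 1L
}

# triangular factor of the inverse metric: (P|Q)^{-1} = L L^T
metric_factor <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, diag(nrow(M)))) # upper-triangular L = U^{-1}
  }
  # eigendecomposition fallback with eigenvalue floor
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > 1e-10
  e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]),
                                           sum(keep))
}

#' Build density-fitting tensors
#'
#' Prepares the fitted three-center integrals for Fock assembly, over a
#' shell-complete subset of the AO basis (`kept_ao`), and either a
#' shell-complete subset of the auxiliary basis (`kept_aux`), a natural
#' auxiliary function transformation (`naf`, from [naf_build()]), or the
#' full auxiliary set.
#'
#' @param handle a backend handle
#' @param kept_ao 1-based AO function indices (default all); must be
#'   shell-complete
#' @param kept_aux 1-based auxiliary function indices (default all); must
#'   be shell-complete; mutually exclusive with `naf`
#' @param naf an `less_naf` object (retained NAF columns)
#' @param mode `"incore"` (store transformed integrals shellwise with
#'   screening) or `"direct"` (re-derive the shell blocks at every Fock
#'   build)
#' @param screen_threshold in-core screening threshold on the shellwise
#'   integral maxima (Eh); 0 stores every block
#' @param memory_budget in-core storage budget in bytes
#' @return an object of class `less_tensors`
#' @export
build_tensors <- function(handle, kept_ao = NULL, kept_aux = NULL, naf = NULL,
                          mode = c("incore", "direct"),
                          screen_threshold = 1e-10, memory_budget = 4e9) {
  mode <- match.arg(mode)
  if (!is.null(kept_aux) && !is.null(naf)) {
    stop("kept_aux and naf are mutually exclusive")
  }
  df <- df_integrals(handle)
  nao <- handle$ao$nbf
  naux <- handle$aux$nbf
  if (is.null(kept_ao)) kept_ao <- seq_len(nao)
  kept_ao <- sort(unique(as.integer(kept_ao)))
  kept_shells <- assert_shell_complete(handle$ao, kept_ao, "kept_ao")
  if (is.null(kept_aux) && is.null(naf)) kept_aux_eff <- seq_len(naux)
  else kept_aux_eff <- kept_aux
  if (!is.null(kept_aux_eff)) {
    kept_aux_eff <- sort(unique(as.integer(kept_aux_eff)))
    assert_shell_complete(handle$aux, kept_aux_eff, "kept_aux")
  }
  # combined auxiliary transform: columns of the effective fitting space
  if (is.null(naf)) {
    L <- metric_factor(df$two_center[kept_aux_eff, kept_aux_eff,
                                     drop = FALSE])
    trans <- L
    aux_cols <- kept_aux_eff
  } else {
    Lfull <- metric_factor(df$two_center)
    trans <- Lfull %*% naf$N
    aux_cols <- seq_len(naux)
    L <- Lfull
  }
  T <- new.env(parent = emptyenv())
  T$handle <- handle
  T$kept_ao <- kept_ao
  T$kept_shells <- kept_shells
  T$kept_aux <- if (is.null(naf)) kept_aux_eff else NULL
  T$naf <- naf
  T$L <- L
  T$trans <- trans
  T$aux_cols <- aux_cols
  T$naux_eff <- ncol(trans)
  T$mode <- mode
  T$screen_threshold <- screen_threshold
  T$n <- length(kept_ao)

  # per kept shell: local mu indices into kept_ao
  shl <- handle$ao
  T$shell_fun <- lapply(kept_shells, function(s) {
    match(shl$ptr[s] + seq_len(2L * shl$l[s] + 1L), kept_ao)
  })

  # screening map (Eq 17 quantities), computed from the transformed
  # integrals in both modes so the two modes represent the same object
  blocks <- vector("list", length(kept_shells))
  screen <- vector("list", length(kept_shells))
  bytes <- 0
  for (si in seq_along(kept_shells)) {
    B <- tensor_raw_block(T, si)        # naux_eff x (nmu * n)
    nmu <- length(T$shell_fun[[si]])
    arr <- array(B, c(T$naux_eff, nmu, T$n))
    jnu <- apply(abs(arr), 3, max)      # J^S_nu over kept nu
    keep_nu <- if (screen_threshold <= 0) seq_len(T$n) else
      which(jnu >= screen_threshold)
    screen[[si]] <- keep_nu
    if (mode == "incore") {
      blk <- matrix(arr[, , keep_nu, drop = FALSE],
                    nrow = T$naux_eff)
      bytes <- bytes + as.numeric(object.size(blk))
      if (bytes > memory_budget) {
        stop(sprintf(paste0("in-core storage exceeds the memory budget ",
                            "(needs > %.0f bytes, budget %.0f); ",
                            "use mode = 'direct'"), bytes, memory_budget))
      }
      blocks[[si]] <- blk
    }
  }
  T$screen_map <- screen
  T$blocks <- if (mode == "incore") blocks else NULL
  class(T) <- "less_tensors"
  T
}

# transformed integral block for kept shell si: naux_eff x (nmu * n_kept),
# nu slowest, mu (within shell) middle, P fastest -- straight from the raw
# packed three-center integrals
tensor_raw_block <- function(T, si) {
  df <- df_integrals(T$handle)
  mu <- T$kept_ao[T$shell_fun[[si]]]
  rows <- pair_index(rep(mu, times = T$n),
                     rep(T$kept_ao, each = length(mu)))
  raw <- df$three_center[rows, T$aux_cols, drop = FALSE]
  t(raw %*% T$trans)
}

# screened block retrieval honouring the storage mode
tensor_block <- function(T, si) {
  if (T$mode == "incore") {
    return(T$blocks[[si]])
  }
  nmu <- length(T$shell_fun[[si]])
  arr <- array(tensor_raw_block(T, si), c(T$naux_eff, nmu, T$n))
  matrix(arr[, , T$screen_map[[si]], drop = FALSE], nrow = T$naux_eff)
}

#' @export
print.less_tensors <- function(x, ...) {
  cat("<less_tensors> mode ", x$mode, ": ", x$n, " kept AOs, ",
      x$naux_eff, " effective fitting functions\n", sep = "")
  invisible(x)
}

check_density_index <- function(D, T) {
  if (!isTRUE(all.equal(dim(D), c(T$n, T$n)))) {
    stop("density dimension does not match the tensor kept-AO set")
  }
}

#' Coulomb matrix from fitted integrals
#'
#' Two-step shellwise assembly: `X_P = sum_{mu nu} D_{mu nu} J^P_{mu nu}`
#' followed by `F^J_{mu nu} = sum_P X_P J^P_{mu nu}`.
#'
#' @param D symmetric density on the kept AO set
#' @param T a `less_tensors` object
#' @return the Coulomb matrix on the kept AO set
#' @export
build_coulomb <- function(D, T) {
  check_density_index(D, T)
  X <- numeric(T$naux_eff)
  for (si in seq_along(T$kept_shells)) {
    B <- tensor_block(T, si)
    keep <- T$screen_map[[si]]
    Dsub <- D[T$shell_fun[[si]], keep, drop = FALSE]
    X <- X + as.vector(B %*% as.vector(Dsub))
  }
  FJ <- matrix(0, T$n, T$n)
  for (si in seq_along(T$kept_shells)) {
    B <- tensor_block(T, si)
    keep <- T$screen_map[[si]]
    contrib <- matrix(crossprod(B, X), nrow = length(T$shell_fun[[si]]))
    FJ[T$shell_fun[[si]], keep] <- FJ[T$shell_fun[[si]], keep] + contrib
  }
  (FJ + t(FJ)) / 2
}

#' Exact-exchange matrix from fitted integrals
#'
#' Half-transformation `J^P_{mu i} = sum_nu C_{nu i} J^P_{mu nu}` followed
#' by `F^K_{mu nu} = -c_HFx sum_{i P} J^P_{mu i} J^P_{nu i}`.  The MO index
#' runs over the columns of `C_occ` only, which for embedded calculations
#' are the active orbitals.
#'
#' @param C_occ occupied MO coefficients on the kept AO set
#' @param T a `less_tensors` object
#' @param c_hfx exact-exchange weight in `[0, 1]`
#' @return the (negative semidefinite) scaled exchange matrix
#' @export
build_exchange <- function(C_occ, T, c_hfx) {
  if (c_hfx < 0 || c_hfx > 1) stop("c_hfx must lie in [0, 1]")
  if (nrow(C_occ) != T$n) {
    stop("C_occ dimension does not match the tensor kept-AO set")
  }
  nocc <- ncol(C_occ)
  if (c_hfx == 0 || nocc == 0) return(matrix(0, T$n, T$n))
  G <- matrix(0, T$naux_eff * nocc, T$n)
  for (si in seq_along(T$kept_shells)) {
    B <- tensor_block(T, si)
    keep <- T$screen_map[[si]]
    nmu <- length(T$shell_fun[[si]])
    half <- matrix(B, nrow = T$naux_eff * nmu) %*%
      C_occ[keep, , drop = FALSE]                  # (P, mu) x i
    half <- aperm(array(half, c(T$naux_eff, nmu, nocc)), c(1, 3, 2))
    G[, T$shell_fun[[si]]] <- matrix(half, ncol = nmu)
  }
  -c_hfx * crossprod(G)
}

# exchange-type matrix of an arbitrary closed-shell density:
# K(D) = -(c/2) sum_P J^P D J^P, via an occupied factorization of D
exchange_from_density <- function(D, T, c_hfx, S = NULL) {
  if (c_hfx == 0) return(matrix(0, T$n, T$n))
  if (is.null(S)) S <- one_electron(T$handle)$S[T$kept_ao, T$kept_ao]
  C <- density_factor(D, S)
  build_exchange(C, T, c_hfx)
}

# factor a positive-semidefinite closed-shell density, D/2 = C C^T with
# occupation weights absorbed into the columns, by diagonalizing
# S^(1/2) (D/2) S^(1/2); exact for idempotent and fractional densities
density_factor <- function(D, S) {
  es <- eigen(S, symmetric = TRUE)
  Sh <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  Shm <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  M <- Sh %*% (D / 2) %*% Sh
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  occ <- em$values > 1e-6
  Shm %*% em$vectors[, occ, drop = FALSE] %*%
    diag(sqrt(em$values[occ]), sum(occ))
}
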