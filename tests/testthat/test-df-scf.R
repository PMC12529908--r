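# Density-fitted SCF engine: four-center and dense-DF oracles, storage
# modes, screening, energy bookkeeping, variationality.

test_that("He and H2 RHF match the dense four-center and dense-DF oracles", {
  cases <- list(
    list(sys = less_system("He", matrix(0, 1, 3), ao_basis = "sto-3g",
                           aux_basis = "autoaux-dense"),
         basis = oracle_basis(matrix(0, 1, 3), sto3g_he$exps,
                              sto3g_he$coefs),
         charges = matrix(c(0, 0, 0, 2), 1, 4), n_occ = 1, E_nuc = 0),
    list(sys = h2_system(1.4), basis = h2_oracle_basis(1.4),
         charges = cbind(rbind(c(0, 0, 0), c(0, 0, 1.4)), 1), n_occ = 1,
         E_nuc = 1 / 1.4)
  )
  for (cs in cases) {
    h <- backend_handle(cs$sys)
    oe <- one_electron(h)
    T <- build_tensors(h)
    st <- scf_solve(h, T, "hf", oe$h, cs$n_occ)
    # brute-force four-center oracle
    ref <- oracle_one_electron(cs$basis, cs$charges)
    g4 <- oracle_eri(cs$basis)
    hf4 <- oracle_rhf(ref$h, ref$S, g4, cs$n_occ, cs$E_nuc)
    # dense-DF oracle: same RHF driver on the explicitly fitted tensor
    df <- df_integrals(h)
    n <- h$ao$nbf
    L <- lessemb:::metric_factor(df$two_center)
    J3 <- df$three_center %*% L
    gfit <- array(0, c(n, n, n, n))
    for (m in 1:n) for (v in 1:n) for (l in 1:n) for (s in 1:n) {
      gfit[m, v, l, s] <- sum(J3[lessemb:::pair_index(m, v), ] *
                                J3[lessemb:::pair_index(l, s), ])
    }
    hfdf <- oracle_rhf(ref$h, ref$S, gfit, cs$n_occ, cs$E_nuc)
    df_residual <- max(abs(gfit - g4))
    expect_lt(abs(st$E_total - hf4$E), 10 * df_residual + 1e-10)
    expect_equal(st$E_total, hfdf$E, tolerance = 1e-10)
    # Fock pieces against the dense-DF tensor at the converged density
    FJ <- build_coulomb(st$D, T)
    FK <- build_exchange(st$C_occ, T, 1)
    FJd <- FKd <- matrix(0, n, n)
    for (m in 1:n) for (v in 1:n) {
      FJd[m, v] <- sum(gfit[m, v, , ] * st$D)
      FKd[m, v] <- -0.5 * sum(gfit[m, , , v] * t(st$D))
    }
    expect_lt(max(abs(FJ - FJd)), 1e-12)
    expect_lt(max(abs(FK - FKd)), 1e-12)
  }
})

test_that("in-core and integral-direct modes represent the same object", {
  w <- fixture_monomer("h2o", ao_basis = "sto-3g")
  h <- backend_handle(w)
  oe <- one_electron(h)
  Ti <- build_tensors(h, mode = "incore")
  Td <- build_tensors(h, mode = "direct")
  set.seed(3)
  D <- crossprod(matrix(rnorm(49), 7, 7)); D <- (D + t(D)) / 2
  expect_lt(max(abs(build_coulomb(D, Ti) - build_coulomb(D, Td))), 1e-12)
  C <- matrix(rnorm(21), 7, 3)
  expect_lt(max(abs(build_exchange(C, Ti, 0.25) -
                      build_exchange(C, Td, 0.25))), 1e-12)
  si <- scf_solve(h, Ti, "hf", oe$h, 5)
  sd <- scf_solve(h, Td, "hf", oe$h, 5)
  expect_lt(abs(si$E_total - sd$E_total), 1e-10)
})

test_that("Eq-17 screening: zero threshold keeps all blocks, 1e-10 is inert", {
  w <- fixture_monomer("h2o", ao_basis = "sto-3g")
  h <- backend_handle(w)
  oe <- one_electron(h)
  T0 <- build_tensors(h, screen_threshold = 0)
  expect_true(all(vapply(T0$screen_map, length, 1L) == T0$n))
  Ts <- build_tensors(h, screen_threshold = 1e-10)
  e0 <- scf_solve(h, T0, "hf", oe$h, 5)$E_total
  es <- scf_solve(h, Ts, "hf", oe$h, 5)$E_total
  expect_lt(abs(e0 - es), 1e-8)
})

test_that("in-core mode reports an informative error on a tiny budget", {
  h <- backend_handle(fixture_monomer("h2o", ao_basis = "sto-3g"))
  expect_error(build_tensors(h, mode = "incore", memory_budget = 1e3),
               "direct")
})

test_that("identity reduction reproduces the plain transformed integrals", {
  h <- backend_handle(fixture_monomer("h2o", ao_basis = "sto-3g"))
  df <- df_integrals(h)
  T <- build_tensors(h, kept_aux = seq_len(h$aux$nbf))
  L <- lessemb:::metric_factor(df$two_center)
  # shell block 1 against a direct contraction over the full sets
  B <- lessemb:::tensor_block(T, 1)
  mu <- T$kept_ao[T$shell_fun[[1]]]
  rows <- lessemb:::pair_index(rep(mu, times = T$n),
                               rep(T$kept_ao, each = length(mu)))
  ref <- t(df$three_center[rows, ] %*% L)
  expect_lt(max(abs(B - matrix(ref, nrow = T$naux_eff))), 1e-13)
})

test_that("converged states conserve particle number and orthonormality", {
  w <- fixture_monomer("h2o", ao_basis = "dz")
  h <- backend_handle(w, grid_level = 1)
  oe <- one_electron(h)
  T <- build_tensors(h)
  for (f in c("hf", "pbe")) {
    st <- scf_solve(h, T, f, oe$h, 5)
    expect_true(st$converged)
    expect_equal(sum(st$D * oe$S), 10, tolerance = 1e-8)
    expect_lt(max(abs(crossprod(st$C_occ, oe$S %*% st$C_occ) - diag(5))),
              1e-8)
    expect_equal(st$E_total,
                 st$E_1e + st$E_J + st$E_K + st$E_xc + st$E_nuc,
                 tolerance = 1e-12)
  }
})

test_that("exact exchange enters PBE0 but not PBE", {
  w <- fixture_monomer("h2o", ao_basis = "sto-3g")
  h <- backend_handle(w, grid_level = 1)
  oe <- one_electron(h)
  T <- build_tensors(h)
  spbe <- scf_solve(h, T, "pbe", oe$h, 5)
  spbe0 <- scf_solve(h, T, "pbe0", oe$h, 5)
  expect_equal(spbe$E_K, 0)
  expect_lt(spbe0$E_K, 0)
})

test_that("the fitted Coulomb energy is positive semidefinite in D", {
  h <- backend_handle(fixture_monomer("h2o", ao_basis = "sto-3g"))
  T <- build_tensors(h)
  for (seed in 1:5) {
    set.seed(seed)
    D <- matrix(rnorm(49), 7, 7); D <- D + t(D)
    expect_gte(0.5 * sum(D * build_coulomb(D, T)), -1e-12)
  }
})

test_that("exchange is additive over occupied columns and validates c_HFx", {
  h <- backend_handle(fixture_monomer("h2o", ao_basis = "sto-3g"))
  T <- build_tensors(h)
  set.seed(11)
  C <- matrix(rnorm(14), 7, 2)
  K2 <- build_exchange(C, T, 1)
  K3 <- build_exchange(cbind(C, C[, 2]), T, 1)
  K1 <- build_exchange(C[, 2, drop = FALSE], T, 1)
  expect_lt(max(abs(K3 - K2 - K1)), 1e-12)
  expect_equal(max(abs(build_exchange(C, T, 0))), 0)
  expect_error(build_exchange(C, T, 1.5), "c_hfx")
})

test_that("the converged SCF is variational under orbital rotations", {
  # subset auxiliary reduction keeps the energy functional exactly
  # variational: numerical orbital-rotation gradients vanish
  w <- fixture_monomer("h2o", ao_basis = "sto-3g")
  h <- backend_handle(w)
  oe <- one_electron(h)
  kept_aux <- lessemb:::shells_to_functions(
    h$aux, seq(1, nrow(shell_map(h, "aux")), 2))
  T <- build_tensors(h, kept_aux = kept_aux)
  st <- scf_solve(h, T, "hf", oe$h, 5,
                  options = list(tol_grad = 1e-9, tol_e = 1e-12))
  X <- lessemb:::orthogonalizer(oe$S)
  Call <- cbind(st$C_occ, X[, 1:2])  # two arbitrary virtual directions
  Call[, 6:7] <- Call[, 6:7] -
    st$C_occ %*% crossprod(st$C_occ, oe$S %*% Call[, 6:7])
  energy_at <- function(theta, iocc, ivirt) {
    C <- st$C_occ
    vir <- Call[, ivirt] / sqrt(sum(Call[, ivirt] * (oe$S %*% Call[, ivirt])))
    C[, iocc] <- cos(theta) * C[, iocc] + sin(theta) * vir
    D <- 2 * tcrossprod(C)
    scf_energy(h, T, "hf", D, C_occ = C)$E_total
  }
  for (iocc in c(1, 5)) {
    g <- (energy_at(1e-3, iocc, 6) - energy_at(-1e-3, iocc, 6)) / 2e-3
    expect_lt(abs(g), 1e-5)
  }
})
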