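# Partitioning, embedding operators and the embedded SCF.

dimer_case <- function(distance = 6, grid_level = 1) {
  sys <- build_separated_dimer("h2o", distance, ao_basis = "sto-3g")
  h <- backend_handle(sys, grid_level = grid_level)
  oe <- one_electron(h)
  T <- build_tensors(h)
  list(sys = sys, h = h, oe = oe, T = T)
}

embed_once <- function(cc, ll, hl, active, mode = "huzinaga", alpha = 1e6,
                       scf = list()) {
  low <- scf_solve(cc$h, cc$T, ll, cc$oe$h, cc$sys$n_electrons / 2,
                   options = scf)
  part <- localize_and_select(low, cc$h, active)
  h_emb <- embedding_potential(cc$h, ll, low$D, part$D_A, T = cc$T,
                               C_AB = low$C_occ, C_A = part$C_A)
  st <- embedded_scf(cc$h, cc$T, part, hl, h_emb, mode = mode,
                     alpha = alpha, options = scf)
  list(low = low, part = part, h_emb = h_emb, high = st,
       energy = assemble_energy(low, part, st, h_emb, cc$h, cc$T, ll))
}

test_that("same-level embedding reproduces the full SCF energy", {
  cc <- dimer_case()
  for (f in c("hf", "pbe")) {
    r <- embed_once(cc, f, f, active = 1:3)
    expect_lt(abs(r$energy$E_total - r$energy$E_LL_full), 1e-8)
    expect_lt(max(abs(r$high$D - 2 * tcrossprod(r$part$C_A))), 1e-6)
    expect_lt(abs(r$energy$E_corr), 5e-8)  # O(SCF residual) around zero
  }
})

test_that("localization/selection: full-system and separable limits", {
  cc <- dimer_case(50)
  low <- scf_solve(cc$h, cc$T, "hf", cc$oe$h, 10)
  pall <- localize_and_select(low, cc$h, 1:6)
  expect_equal(pall$n_act, 10)
  expect_equal(ncol(pall$C_B), 0)
  p1 <- localize_and_select(low, cc$h, 1:3)
  expect_equal(p1$n_act, 5)
  # partition invariants
  S <- cc$oe$S
  expect_lt(max(abs(crossprod(p1$C_A, S %*% p1$C_B))), 1e-8)
  expect_lt(max(abs(p1$D_A + p1$D_B - low$D)), 1e-7)
  expect_error(localize_and_select(low, cc$h, integer()), "active")
})

test_that("selection agrees with a direct per-MO Mulliken tabulation", {
  w <- fixture_monomer("h2o", ao_basis = "sto-3g")
  h <- backend_handle(w)
  oe <- one_electron(h)
  T <- build_tensors(h)
  low <- scf_solve(h, T, "hf", oe$h, 5)
  part <- localize_and_select(low, h, active_atoms = 2:3, tau_sel = 0.4)
  # independent tabulation: gross Mulliken population of each localized MO
  # (localized orbitals recovered as the union of the partition blocks)
  Cloc <- cbind(part$C_A, part$C_B)
  ao_atom <- rep(h$ao$atom, times = 2L * h$ao$l + 1L)
  n_act_direct <- 0
  for (i in seq_len(ncol(Cloc))) {
    pop <- 0
    for (mu in which(ao_atom %in% 2:3)) {
      pop <- pop + Cloc[mu, i] * sum(oe$S[mu, ] * Cloc[, i])
    }
    if (pop >= 0.4) n_act_direct <- n_act_direct + 1
  }
  expect_equal(part$n_act, n_act_direct)
  expect_gt(part$n_act, 0)
})

test_that("Huzinaga matrix: empty environment and 2x2 algebra", {
  F <- matrix(c(1, 0.2, 0.2, 2), 2, 2)
  S <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_identical(huzinaga_matrix(F, matrix(0, 2, 2), S), F)
  # idempotent-in-S density from a normalized vector b
  b <- c(1, 1) / sqrt(sum(c(1, 1) * (S %*% c(1, 1))))
  DB <- tcrossprod(b)
  expect_lt(max(abs(S %*% DB %*% S %*% DB - S %*% DB)), 1e-12)
  H <- huzinaga_matrix(S, DB, S)
  expect_lt(max(abs(H - (S - 2 * S %*% DB %*% S))), 1e-12)
  expect_error(huzinaga_matrix(F, matrix(0, 3, 3), S), "dimension")
})

test_that("environment block decouples at the converged embedded state", {
  cc <- dimer_case()
  r <- embed_once(cc, "pbe", "pbe0", active = 1:3)
  S <- cc$oe$S
  DB <- tcrossprod(r$part$C_B)
  FJ <- build_coulomb(r$high$D, cc$T)
  FK <- build_exchange(r$high$C_occ, cc$T, 0.25)
  Vxc <- xc_eval(cc$h, "pbe0", r$high$D)$V_xc
  F <- cc$oe$h + r$h_emb + FJ + FK + Vxc
  H <- huzinaga_matrix(F, DB, S)
  expect_lt(max(abs(crossprod(r$part$C_B, H %*% r$high$C_occ))), 1e-7)
  expect_lt(max(abs(crossprod(r$high$C_occ, S %*% r$part$C_B))), 1e-7)
  expect_equal(sum(r$high$D * S), 2 * r$part$n_act, tolerance = 1e-8)
})

test_that("projector operator: identity limits and convergence to Huzinaga", {
  F <- matrix(c(1, 0.2, 0.2, 2), 2, 2)
  S <- diag(2)
  DB <- diag(c(1, 0))
  expect_identical(projector_fock(F, DB, S, 0), F)
  expect_identical(projector_fock(F, matrix(0, 2, 2), S, 5), F)
  expect_error(projector_fock(F, DB, S, -1), "alpha")
  cc <- dimer_case(5)
  tight <- list(tol_grad = 1e-9, tol_e = 1e-12)
  rh <- embed_once(cc, "hf", "hf", 1:3, scf = tight)
  errs <- vapply(c(1e3, 1e4, 1e5), function(a) {
    rp <- embed_once(cc, "hf", "hf", 1:3, mode = "projector", alpha = a,
                     scf = tight)
    abs(rp$energy$E_total - rh$energy$E_total)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the embedding potential is a true first-order potential", {
  cc <- dimer_case()
  low <- scf_solve(cc$h, cc$T, "pbe", cc$oe$h, 10)
  part <- localize_and_select(low, cc$h, 1:3)
  h0 <- embedding_potential(cc$h, "pbe", low$D, low$D, T = cc$T,
                            C_AB = low$C_occ, C_A = low$C_occ)
  expect_lt(max(abs(h0)), 1e-10)
  h_emb <- embedding_potential(cc$h, "pbe", low$D, part$D_A, T = cc$T,
                               C_AB = low$C_occ, C_A = part$C_A)
  expect_symmetric(h_emb)
  # finite-difference: Tr(dD v) matches the change of the two-electron
  # low-level energy around D_A to first order
  e2 <- function(D) {
    p <- scf_energy(cc$h, cc$T, "pbe", D)
    p$E_J + p$E_K + p$E_xc
  }
  # perturb within the active occupied span so D_A +- dD stays a valid
  # (non-negative) density and the low-density grid cutoff is never
  # crossed asymmetrically
  u <- part$C_A %*% c(0.6, 0.5, 0.4, 0.3, 0.2)
  dD <- 1e-4 * tcrossprod(u)
  fd <- (e2(low$D + dD) - e2(low$D - dD)) / 2 -
    (e2(part$D_A + dD) - e2(part$D_A - dD)) / 2
  expect_equal(fd, sum(h_emb * dD), tolerance = 1e-5)
})

test_that("reaction energies are robust to enlarging the active set", {
  fx <- build_chain_acid(2, ao_basis = "sto-3g")
  cfg_head <- less_config(eps_ao = NULL, grid_level = 1)
  dE <- function(active_acid, active_anion) {
    ra <- run_embedding(fx$acid, active_acid, cfg_head)
    rn <- run_embedding(fx$anion, active_anion, cfg_head)
    rn$energy$E_total - ra$energy$E_total
  }
  d_head <- dE(fx$active_acid, fx$active_anion)
  d_all <- dE(seq_along(fx$acid$symbols), seq_along(fx$anion$symbols))
  expect_lt(abs(d_head - d_all) * kcal_per_hartree, 1)
})

test_that("E_total is invariant under unitary mixing of environment MOs", {
  cc <- dimer_case()
  r <- embed_once(cc, "pbe", "pbe0", active = 1:3)
  set.seed(9)
  nB <- ncol(r$part$C_B)
  Q <- qr.Q(qr(matrix(rnorm(nB * nB), nB)))
  part2 <- r$part
  part2$C_B <- r$part$C_B %*% Q
  st2 <- embedded_scf(cc$h, cc$T, part2, "pbe0", r$h_emb)
  e2 <- assemble_energy(r$low, part2, st2, r$h_emb, cc$h, cc$T, "pbe")
  expect_equal(e2$E_total, r$energy$E_total, tolerance = 1e-9)
})

test_that("assemble_energy identities hold by construction", {
  cc <- dimer_case()
  r <- embed_once(cc, "pbe", "pbe", active = 1:3)
  e <- r$energy
  expect_equal(e$E_total,
               e$E_LL_full - e$E_LL_act + e$E_HL_act + e$E_corr,
               tolerance = 1e-13)
  expect_equal(e$n_act + e$n_env, 10)
})
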