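# The three auxiliary-basis reduction schemes.

h2o_low <- function(basis = "sto-3g") {
  w <- fixture_monomer("h2o", ao_basis = basis)
  h <- backend_handle(w)
  oe <- one_electron(h)
  T <- build_tensors(h)
  low <- scf_solve(h, T, "hf", oe$h, 5)
  part <- localize_and_select(low, h, 2:3)
  list(h = h, oe = oe, T = T, low = low, part = part)
}

test_that("NAF: Gram structure, dense oracle, and the complete-rotation limit", {
  cc <- h2o_low()
  naf <- naf_build(cc$part$C_A, cc$T, eps_naf = 0)
  expect_lt(max(abs(crossprod(naf$N) - diag(ncol(naf$N)))), 1e-10)
  expect_true(all(diff(naf$sigma) <= 1e-12))   # sorted descending
  # dense Gram oracle: W assembled independently from the raw integrals
  df <- df_integrals(cc$h)
  L <- lessemb:::metric_factor(df$two_center)
  n <- cc$h$ao$nbf; naux <- cc$h$aux$nbf
  C <- cc$part$C_A
  J <- array(0, c(n, ncol(C), naux))
  for (m in seq_len(n)) for (i in seq_len(ncol(C))) {
    acc <- numeric(naux)
    for (v in seq_len(n)) {
      acc <- acc + C[v, i] * df$three_center[lessemb:::pair_index(m, v), ]
    }
    J[m, i, ] <- as.vector(acc %*% L)
  }
  W <- matrix(0, naux, naux)
  for (m in seq_len(n)) for (i in seq_len(ncol(C))) {
    W <- W + tcrossprod(J[m, i, ])
  }
  expect_lt(max(abs(sort(naf$sigma^2) -
                      sort(pmax(eigen(W, symmetric = TRUE)$values, 0)))),
            1e-10)
  expect_gte(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # complete rotation: transformed Coulomb/exchange equal untransformed
  Tn <- build_tensors(cc$h, naf = naf)
  FJ0 <- build_coulomb(cc$low$D, cc$T)
  FJn <- build_coulomb(cc$low$D, Tn)
  expect_lt(max(abs(FJ0 - FJn)), 1e-10)
  FK0 <- build_exchange(cc$part$C_A, cc$T, 1)
  FKn <- build_exchange(cc$part$C_A, Tn, 1)
  expect_lt(max(abs(FK0 - FKn)), 1e-10)
  expect_error(naf_build(cc$part$C_A, cc$T, -1), "non-negative")
})

test_that("generalized Mulliken charges: orthogonal limit and monotonicity", {
  cc <- h2o_low()
  S_df <- aux_overlap(cc$h)
  asm <- shell_map(cc$h, "aux")
  naf_full <- naf_build(cc$part$C_A, cc$T, eps_naf = 0)
  kept <- generalized_mulliken(naf_full, S_df, eps_mull = 0, aux_shell_map = asm)
  qhat <- attr(kept, "qhat")
  if (ncol(naf_full$N) == nrow(naf_full$N)) {
    # square orthogonal N: qhat reduces to the overlap diagonal
    expect_lt(max(abs(qhat - diag(S_df))), 1e-10)
  }
  naf <- naf_build(cc$part$C_A, cc$T, eps_naf = 5e-4)
  ks <- lapply(c(0.05, 0.3, 0.6), function(e) {
    generalized_mulliken(naf, S_df, e, asm)
  })
  expect_true(all(diff(vapply(ks, length, 1L)) <= 0))
  for (i in 1:2) expect_true(all(ks[[i + 1]] %in% ks[[i]]))
})

test_that("LDF domains: single atom, vacuous threshold, distance decay", {
  he <- less_system("He", matrix(0, 1, 3), ao_basis = "sto-3g")
  hh <- backend_handle(he)
  oeh <- one_electron(hh)
  Th <- build_tensors(hh)
  lowh <- scf_solve(hh, Th, "hf", oeh$h, 1)
  kd <- ldf_domains(lowh$C_occ, hh, eps_dom = 2.0)
  expect_equal(as.integer(kd), seq_len(hh$aux$nbf))

  # vacuous threshold within one molecule (every Cauchy-Schwarz factor
  # is strictly positive there)
  cc <- h2o_low()
  kv <- ldf_domains(cc$part$C_A, cc$h, eps_dom = 1e-12)
  expect_equal(as.integer(kv), seq_len(cc$h$aux$nbf))

  sys <- build_separated_dimer("h2o", 25, ao_basis = "sto-3g")
  h <- backend_handle(sys)
  oe <- one_electron(h)
  T <- build_tensors(h)
  low <- scf_solve(h, T, "hf", oe$h, 10)
  part <- localize_and_select(low, h, 1:3)
  k2 <- ldf_domains(part$C_A, h, eps_dom = 2.0)
  aux_atom <- rep(h$aux$atom, times = 2L * h$aux$l + 1L)
  expect_true(all(aux_atom[k2] <= 3))   # no monomer-2 shells retained
  # decay matches the directly computed Cauchy-Schwarz factors: the
  # largest cross-fragment (mu nu | mu nu) is itself tiny
  d4 <- eri_diagonal(h)
  ao_atom <- rep(h$ao$atom, times = 2L * h$ao$l + 1L)
  cross <- max(d4[ao_atom <= 3, ao_atom > 3])
  expect_lt(sqrt(cross) * sqrt(max(diag(df_integrals(h)$two_center))), 2.0)
})

test_that("all three schemes recover the unreduced result as eps -> 0", {
  cc <- h2o_low()
  e_ref <- scf_solve(cc$h, cc$T, "hf", cc$oe$h, 5)$E_total
  naf <- naf_build(cc$part$C_A, cc$T, 0)
  e_naf <- scf_solve(cc$h, build_tensors(cc$h, naf = naf), "hf",
                     cc$oe$h, 5)$E_total
  expect_lt(abs(e_naf - e_ref), 1e-8)
  km <- generalized_mulliken(naf, aux_overlap(cc$h), 0,
                             shell_map(cc$h, "aux"))
  e_m <- scf_solve(cc$h, build_tensors(cc$h, kept_aux = km), "hf",
                   cc$oe$h, 5)$E_total
  expect_lt(abs(e_m - e_ref), 1e-10)
  kl <- ldf_domains(cc$part$C_A, cc$h, 1e-12)
  e_l <- scf_solve(cc$h, build_tensors(cc$h, kept_aux = kl), "hf",
                   cc$oe$h, 5)$E_total
  expect_lt(abs(e_l - e_ref), 1e-10)
})

test_that("recommended thresholds give sub-0.1 kcal/mol reaction errors", {
  # quasi-1D acid deprotonation at double-zeta, embedded PBE0-in-PBE,
  # errors vs the AO-reduction-only internal reference
  fx <- build_chain_acid(3, ao_basis = "dz")
  cfg <- less_config(eps_ao = 1e-4, grid_level = 1)
  dE <- function(c) {
    ra <- run_embedding(fx$acid, fx$active_acid, c)
    rn <- run_embedding(fx$anion, fx$active_anion, c)
    list(d = rn$energy$E_total - ra$energy$E_total,
         ret = (ra$aux_retention + rn$aux_retention) / 2)
  }
  ref <- dE(cfg)
  errs <- numeric(); rets <- numeric()
  for (sc in c("naf", "mulliken", "ldf")) {
    c2 <- cfg; c2$aux_scheme <- sc
    r <- dE(c2)
    errs[[sc]] <- abs(r$d - ref$d) * kcal_per_hartree
    rets[[sc]] <- r$ret
  }
  expect_lt(max(errs), 0.1)
  # compression ordering: NAF compresses hardest
  expect_lt(rets[["naf"]], rets[["mulliken"]])
  expect_lt(rets[["naf"]], rets[["ldf"]])
})
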