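# Net-Mulliken AO truncation, shell completion, Loewdin
# re-orthogonalization and environment-MO dropping.

test_that("net populations match a brute-force loop and are rotation invariant", {
  w <- fixture_monomer("h2o", ao_basis = "sto-3g")
  h <- backend_handle(w)
  oe <- one_electron(h)
  T <- build_tensors(h)
  low <- scf_solve(h, T, "hf", oe$h, 5)
  part <- localize_and_select(low, h, 2:3)
  q <- net_population(part$C_A, oe$S)
  qref <- numeric(h$ao$nbf)
  for (mu in seq_len(h$ao$nbf)) {
    for (i in seq_len(ncol(part$C_A))) {
      qref[mu] <- qref[mu] + part$C_A[mu, i]^2 * oe$S[mu, mu]
    }
  }
  expect_lt(max(abs(q - qref)), 1e-14)
  set.seed(2)
  n <- ncol(part$C_A)
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  expect_lt(max(abs(net_population(part$C_A %*% Q, oe$S) - q)), 1e-13)
  # localized unit-vector limit in an orthonormal basis
  qa <- net_population(diag(4)[, 2, drop = FALSE], diag(4))
  expect_equal(qa, c(0, 1, 0, 0))
})

test_that("shell selection keeps whole shells, errors on empty sets, nests", {
  h <- backend_handle(fixture_monomer("h2o", ao_basis = "dz"))
  sm <- shell_map(h, "ao")
  set.seed(4)
  q <- runif(h$ao$nbf)
  expect_equal(select_shells(q, 0, sm), seq_len(h$ao$nbf))
  expect_error(select_shells(q, max(q) + 1, sm), "unrepresentable")
  expect_error(select_shells(q, -1, sm), "non-negative")
  eps_grid <- c(1e-4, 1e-2, 0.3, 0.8)
  kept <- lapply(eps_grid, select_shells, q = q, shell_map = sm)
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
  # shell completeness: every p shell contributes 0 or 3 functions
  fs <- lessemb:::function_shell_index(h$ao)
  for (k in kept) {
    tab <- table(fs[k])
    expect_true(all(tab == sm$count[as.integer(names(tab))]))
  }
})

test_that("re-orthogonalization: identity limit and the orthogonality pattern", {
  cc <- build_separated_dimer("h2o", 12, ao_basis = "sto-3g")
  h <- backend_handle(cc)
  oe <- one_electron(h)
  T <- build_tensors(h)
  low <- scf_solve(h, T, "hf", oe$h, 10)
  part <- localize_and_select(low, h, 1:3)
  # all AOs kept: nothing dropped, spans preserved
  ro <- reorthogonalize(part$C_A, part$C_B, oe$S)
  expect_equal(ro$dropped_env_count, 0L)
  expect_lt(max(abs(crossprod(ro$C_A, oe$S %*% ro$C_A) - diag(5))), 1e-10)
  expect_lt(max(abs(crossprod(ro$C_B, oe$S %*% ro$C_B) - diag(5))), 1e-10)
  expect_lt(max(abs(crossprod(ro$C_A, oe$S %*% ro$C_B))), 1e-10)
  PD <- tcrossprod(ro$C_A) - tcrossprod(part$C_A)
  expect_lt(max(abs(PD)), 1e-8)   # same span up to unitary mixing
})

test_that("far-separated environment MOs are dropped; active ones error", {
  cc <- build_separated_dimer("h2o", 50, ao_basis = "sto-3g")
  h <- backend_handle(cc)
  oe <- one_electron(h)
  T <- build_tensors(h)
  low <- scf_solve(h, T, "hf", oe$h, 10)
  part <- localize_and_select(low, h, 1:3)
  q <- net_population(part$C_A, oe$S)
  kept <- select_shells(q, 1e-4, shell_map(h, "ao"))
  ao_atom <- rep(h$ao$atom, times = 2L * h$ao$l + 1L)
  expect_true(all(ao_atom[kept] <= 3))  # only monomer-1 AOs survive
  S_red <- oe$S[kept, kept]
  ro <- reorthogonalize(part$C_A[kept, , drop = FALSE],
                        part$C_B[kept, , drop = FALSE], S_red)
  expect_equal(ro$dropped_env_count, 5L)
  expect_equal(ncol(ro$C_A), 5)         # active electron count preserved
  # active MOs truncated to the wrong fragment must be rejected
  wrong <- setdiff(seq_len(h$ao$nbf), kept)
  expect_error(
    reorthogonalize(part$C_A[wrong, , drop = FALSE],
                    part$C_B[wrong, , drop = FALSE],
                    oe$S[wrong, wrong]),
    "eps_ao")
})

test_that("AO retention decreases monotonically with eps_ao", {
  fx <- build_chain_acid(3, ao_basis = "sto-3g")
  h <- backend_handle(fx$acid, grid_level = 1)
  oe <- one_electron(h)
  T <- build_tensors(h)
  low <- scf_solve(h, T, "hf", oe$h, fx$acid$n_electrons / 2)
  part <- localize_and_select(low, h, fx$active_acid)
  rets <- vapply(c(1e-8, 1e-4, 1e-2), function(e) {
    ao_reduction_plan(h, part, eps_ao = e)$retention
  }, numeric(1))
  expect_true(all(diff(rets) <= 0))
})
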