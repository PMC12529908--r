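# Integral backend: normalization, symmetry, point charges, closed-form
# oracles, relabeling invariance, determinism, failure modes.

test_that("AO functions are normalized and one-electron matrices symmetric", {
  for (sys in list(less_system("He", matrix(0, 1, 3), ao_basis = "sto-3g"),
                   fixture_monomer("h2o", ao_basis = "dz"))) {
    h <- backend_handle(sys)
    oe <- one_electron(h)
    expect_lt(max(abs(diag(oe$S) - 1)), 1e-10)
    expect_symmetric(oe$S)
    expect_symmetric(oe$h)
    expect_gt(min(eigen(oe$S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("an empty point-charge list leaves h unchanged, a real one not", {
  w0 <- fixture_monomer("h2o", ao_basis = "sto-3g")
  w1 <- w0
  w1$point_charges <- matrix(numeric(0), 0, 4)
  h0 <- one_electron(backend_handle(w0))
  h1 <- one_electron(backend_handle(w1))
  expect_identical(h0$h, h1$h)
  expect_identical(h0$E_nuc, h1$E_nuc)
  w2 <- w0
  w2$point_charges <- matrix(c(0, 0, 10, -0.5), 1, 4)
  h2 <- one_electron(backend_handle(w2))
  expect_gt(max(abs(h2$h - h0$h)), 1e-4)
  expect_false(isTRUE(all.equal(h2$E_nuc, h0$E_nuc)))
})

test_that("H2 one-electron integrals match the closed-form s-Gaussian oracle", {
  sys <- h2_system(1.4)
  oe <- one_electron(backend_handle(sys))
  ob <- h2_oracle_basis(1.4)
  charges <- cbind(rbind(c(0, 0, 0), c(0, 0, 1.4)), 1)
  ref <- oracle_one_electron(ob, charges)
  expect_lt(max(abs(oe$S - ref$S)), 1e-10)
  expect_lt(max(abs(oe$h - ref$h)), 1e-10)
  expect_equal(oe$E_nuc, 1 / 1.4, tolerance = 1e-12)
})

test_that("integrals are invariant under atom relabeling", {
  w <- fixture_monomer("h2o", ao_basis = "dz")
  wp <- less_system(w$symbols[c(2, 3, 1)], w$coords[c(2, 3, 1), ],
                    ao_basis = "dz")
  h <- backend_handle(w)
  hp <- backend_handle(wp)
  # map functions of h onto hp through the per-atom shell structure
  ao_atom <- rep(h$ao$atom, times = 2L * h$ao$l + 1L)
  ao_atom_p <- rep(hp$ao$atom, times = 2L * hp$ao$l + 1L)
  perm <- unlist(lapply(c(2, 3, 1), function(a) which(ao_atom == a)))
  S <- one_electron(h)$S
  Sp <- one_electron(hp)$S
  expect_lt(max(abs(Sp - S[perm, perm])), 1e-12)
  expect_equal(one_electron(hp)$E_nuc, one_electron(h)$E_nuc,
               tolerance = 1e-12)
})

test_that("near-linear dependence raises a diagnostic naming the basis", {
  sys <- less_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1e-5)),
                     ao_basis = "sto-3g", unit = "bohr")
  expect_error(one_electron(backend_handle(sys)), "sto-3g")
})

test_that("repeated backend queries return identical values", {
  h <- backend_handle(fixture_monomer("h2o", ao_basis = "sto-3g"))
  a <- one_electron(h); b <- one_electron(h)
  expect_identical(a$S, b$S)
  d1 <- df_integrals(h); d2 <- df_integrals(h)
  expect_identical(d1$three_center, d2$three_center)
})

test_that("DF metric is SPD and the fit reproduces four-center integrals", {
  sys <- h2_system(1.4, aux = "autoaux-dense")
  h <- backend_handle(sys)
  df <- df_integrals(h)
  expect_symmetric(df$two_center)
  expect_gt(min(eigen(df$two_center, only.values = TRUE)$values), 0)
  g4 <- array(four_center(h), c(2, 2, 2, 2))
  L <- lessemb:::metric_factor(df$two_center)
  J3 <- df$three_center %*% L
  pk <- function(m, n) lessemb:::pair_index(m, n)
  resid <- 0
  for (m in 1:2) for (n in 1:2) for (l in 1:2) for (s in 1:2) {
    fit <- sum(J3[pk(m, n), ] * J3[pk(l, s), ])
    resid <- max(resid, abs(fit - g4[m, n, l, s]))
  }
  expect_lt(resid, 2e-4)   # dense even-tempered fitting residual
  # coarser auxiliary set has a larger residual (DF residual shrinks
  # as the fitting set is enlarged)
  hc <- backend_handle(h2_system(1.4, aux = "autoaux"))
  dfc <- df_integrals(hc)
  Lc <- lessemb:::metric_factor(dfc$two_center)
  J3c <- dfc$three_center %*% Lc
  residc <- abs(sum(J3c[pk(1, 2), ]^2) - g4[1, 2, 1, 2])
  expect_gt(residc, resid / 10)
})

test_that("xc_eval: HF is zero, empty density is zero, PBE is grid stable", {
  h <- backend_handle(h2_system(1.4))
  n <- h$ao$nbf
  D <- diag(0.5, n)
  z <- xc_eval(h, "hf", D)
  expect_equal(z$E_xc, 0)
  expect_equal(max(abs(z$V_xc)), 0)
  expect_equal(xc_eval(h, "pbe", matrix(0, n, n))$E_xc, 0)
  oe <- one_electron(h)
  T <- build_tensors(h)
  st <- scf_solve(h, T, "pbe", oe$h, 1)
  e2 <- xc_eval(h, "pbe", st$D, grid_level = 2)$E_xc
  e3 <- xc_eval(h, "pbe", st$D, grid_level = 3)$E_xc
  expect_lt(abs(e2 - e3), 1e-8)
})

test_that("the XC potential is the functional derivative of the energy", {
  h <- backend_handle(h2_system(1.4))
  oe <- one_electron(h)
  T <- build_tensors(h)
  st <- scf_solve(h, T, "pbe", oe$h, 1)
  x <- xc_eval(h, "pbe", st$D, grid_level = 2)
  set.seed(7)
  dD <- matrix(rnorm(4), 2, 2) * 1e-5
  dD <- dD + t(dD)
  ep <- xc_eval(h, "pbe", st$D + dD, grid_level = 2)$E_xc
  em <- xc_eval(h, "pbe", st$D - dD, grid_level = 2)$E_xc
  expect_equal((ep - em) / 2, sum(x$V_xc * dD), tolerance = 1e-6)
})

test_that("rotating a molecule leaves its SCF energy unchanged", {
  # exercises the p-shell integral pathways under a nontrivial rotation
  w <- fixture_monomer("h2o", ao_basis = "sto-3g")
  th <- 0.7; ph <- 0.3
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
       matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  wr <- less_system(w$symbols, w$coords %*% t(R), ao_basis = "sto-3g")
  e1 <- scf_solve(backend_handle(w), T = build_tensors(backend_handle(w)),
                  "hf", one_electron(backend_handle(w))$h, 5)
  hr <- backend_handle(wr)
  e2 <- scf_solve(hr, build_tensors(hr), "hf", one_electron(hr)$h, 5)
  expect_equal(e1$E_total, e2$E_total, tolerance = 1e-9)
})
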