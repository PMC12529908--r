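# Independent closed-form oracles for s-type Gaussian systems and a dense
# brute-force RHF solver.  Everything here is plain R built from textbook
# formulas (Boys F0 via erf); none of it touches the package's integral
# engine, so it can certify that engine on tiny systems.

erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1

boys0 <- function(t) ifelse(t < 1e-12, 1 - t / 3,
                            0.5 * sqrt(pi / t) * erf_(sqrt(t)))

# an s-only basis: list of functions, each list(center = xyz Bohr,
# exps, coefs) with coefs for unnormalized primitives
oracle_normalize <- function(basis) {
  for (i in seq_along(basis)) {
    b <- basis[[i]]
    s <- 0
    for (k in seq_along(b$exps)) for (l in seq_along(b$exps)) {
      p <- b$exps[k] + b$exps[l]
      s <- s + b$coefs[k] * b$coefs[l] * (pi / p)^1.5
    }
    basis[[i]]$coefs <- b$coefs / sqrt(s)
  }
  basis
}

# package-convention contracted functions (coefs on normalized primitives)
oracle_basis <- function(centers, exps, coefs) {
  basis <- lapply(seq_len(nrow(centers)), function(i) {
    list(center = centers[i, ], exps = exps,
         coefs = coefs * (2 * exps / pi)^0.75)
  })
  oracle_normalize(basis)
}

oracle_one_electron <- function(basis, charges) {
  n <- length(basis)
  S <- T <- V <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a <- basis[[i]]; b <- basis[[j]]
    for (k in seq_along(a$exps)) for (l in seq_along(b$exps)) {
      p <- a$exps[k] + b$exps[l]
      mu <- a$exps[k] * b$exps[l] / p
      R2 <- sum((a$center - b$center)^2)
      c <- a$coefs[k] * b$coefs[l]
      s <- (pi / p)^1.5 * exp(-mu * R2)
      S[i, j] <- S[i, j] + c * s
      T[i, j] <- T[i, j] + c * mu * (3 - 2 * mu * R2) * s
      P <- (a$exps[k] * a$center + b$exps[l] * b$center) / p
      for (q in seq_len(nrow(charges))) {
        t <- p * sum((P - charges[q, 1:3])^2)
        V[i, j] <- V[i, j] - c * charges[q, 4] * (2 * pi / p) *
          exp(-mu * R2) * boys0(t)
      }
    }
  }
  list(S = S, h = T + V)
}

oracle_eri <- function(basis) {
  n <- length(basis)
  g <- array(0, c(n, n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
    a <- basis[[i]]; b <- basis[[j]]; cc <- basis[[k]]; d <- basis[[l]]
    v <- 0
    for (ka in seq_along(a$exps)) for (kb in seq_along(b$exps)) {
      p <- a$exps[ka] + b$exps[kb]
      mup <- a$exps[ka] * b$exps[kb] / p
      Rab2 <- sum((a$center - b$center)^2)
      P <- (a$exps[ka] * a$center + b$exps[kb] * b$center) / p
      for (kc in seq_along(cc$exps)) for (kd in seq_along(d$exps)) {
        q <- cc$exps[kc] + d$exps[kd]
        muq <- cc$exps[kc] * d$exps[kd] / q
        Rcd2 <- sum((cc$center - d$center)^2)
        Q <- (cc$exps[kc] * cc$center + d$exps[kd] * d$center) / q
        al <- p * q / (p + q)
        v <- v + a$coefs[ka] * b$coefs[kb] * cc$coefs[kc] * d$coefs[kd] *
          2 * pi^2.5 / (p * q * sqrt(p + q)) *
          exp(-mup * Rab2 - muq * Rcd2) * boys0(al * sum((P - Q)^2))
      }
    }
    g[i, j, k, l] <- v
  }
  g
}

# dense closed-shell RHF on an explicit (possibly fitted) ERI tensor
oracle_rhf <- function(h, S, g, n_occ, E_nuc = 0, max_iter = 200) {
  n <- nrow(h)
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  D <- matrix(0, n, n)
  E_old <- Inf
  for (it in seq_len(max_iter)) {
    G <- matrix(0, n, n)
    for (m in 1:n) for (v in 1:n) {
      G[m, v] <- sum(g[m, v, , ] * D) - 0.5 * sum(g[m, , , v] * t(D))
    }
    F <- h + G
    E <- sum(D * (h + 0.5 * G)) + E_nuc
    e <- eigen(crossprod(X, F %*% X), symmetric = TRUE)
    sel <- order(e$values)[seq_len(n_occ)]
    C <- X %*% e$vectors[, sel, drop = FALSE]
    Dn <- 2 * tcrossprod(C)
    if (abs(E - E_old) < 1e-12 && max(abs(Dn - D)) < 1e-9) {
      return(list(E = E, D = Dn, C = C))
    }
    D <- Dn
    E_old <- E
  }
  list(E = E, D = D, C = C)
}

# package's STO-3G hydrogen/helium parameters (shared data, independent math)
sto3g_h <- list(exps = c(3.42525091, 0.62391373, 0.16885540),
                coefs = c(0.15432897, 0.53532814, 0.44463454))
sto3g_he <- list(exps = c(6.36242139, 1.15892300, 0.31364979),
                 coefs = c(0.15432897, 0.53532814, 0.44463454))

h2_system <- function(R = 1.4, aux = "autoaux-dense") {
  less_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, R)),
              ao_basis = "sto-3g", aux_basis = aux, unit = "bohr")
}

h2_oracle_basis <- function(R = 1.4) {
  oracle_basis(rbind(c(0, 0, 0), c(0, 0, R)), sto3g_h$exps, sto3g_h$coefs)
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
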