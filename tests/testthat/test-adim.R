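test_that("the dipole field tensor has its closed axial form", {
  for (r in c(1, 2.5, 10)) {
    t_ax <- field_tensor(c(0, 0, r), c(0, 0, 0))
    expect_equal(t_ax, diag(c(-1, -1, 2)) / r^3, tolerance = 1e-12)
  }
  set.seed(5)
  for (k in 1:10) {
    a <- rnorm(3, sd = 4); b <- rnorm(3, sd = 4)
    tt <- field_tensor(a, b)
    expect_equal(sum(diag(tt)), 0, tolerance = 1e-12)   # traceless
    expect_equal(tt, t(tt), tolerance = 1e-12)          # symmetric
    expect_equal(tt, field_tensor(b, a), tolerance = 1e-12)
  }
  expect_error(field_tensor(c(0, 0, 0), c(0, 0, 0)), "1e-6 bohr")
})

test_that("T mu matches the finite-difference dipole field", {
  ## the field of a point dipole is the limit of two opposite charges;
  ## field_from_charges provides the independent route
  set.seed(12)
  for (k in 1:5) {
    src <- rnorm(3, sd = 3)
    obs <- src + rnorm(3, sd = 5) + c(4, 0, 0)
    mu <- rnorm(3)
    d <- 1e-4
    sep <- d * mu / sqrt(sum(mu^2))
    qmag <- sqrt(sum(mu^2)) / d
    f_fd <- field_from_charges(obs, c(qmag, -qmag),
                               rbind(src + sep / 2, src - sep / 2))
    f_t <- as.vector(field_tensor(obs, src) %*% mu)
    expect_equal(f_t, f_fd, tolerance = 1e-6)
  }
})

test_that("damping vanishes at long range and suppresses short range", {
  t1 <- field_tensor(c(0, 0, 50), c(0, 0, 0))
  ## u = 2.6 * 50 / 1 = 130 >> 40: damped == undamped to 1e-10
  d1 <- thole_damp(t1, 50, diag(3), diag(3), b = 2.6)
  expect_lt(max(abs(d1 - t1)) / max(abs(t1)), 1e-10)

  ## short range: the damped tensor goes to zero (no catastrophe),
  ## linearly in r
  m <- vapply(c(1e-2, 1e-3, 1e-4), function(r) {
    tr <- field_tensor(c(0, 0, r), c(0, 0, 0))
    max(abs(thole_damp(tr, r, diag(3), diag(3), b = 2.6)))
  }, 0)
  expect_true(all(diff(m) < 0))
  expect_lt(m[3], 1e-3)
  expect_equal(m[1] / m[2], 10, tolerance = 0.05)   # asymptotically linear in r

  ## zero-polarizability sites are exempt from damping
  expect_equal(thole_damp(t1, 50, 0, diag(3), b = 2.6), t1)
})

test_that("screening factors are monotone in the scaled distance", {
  u <- seq(0, 20, by = 0.05)
  s_exp <- blockpol:::screen_exp(u)
  s_drude <- blockpol:::screen_drude(u)
  expect_true(all(diff(s_exp) > 0))
  expect_true(all(diff(s_drude) > 0))
  expect_equal(s_exp[1], 0)
  expect_lt(abs(s_exp[length(u)] - 1), 1e-4)
  ## the alternative schemes are distinct and "none" is the identity
  tt <- field_tensor(c(0, 0, 2), c(0, 0, 0))
  expect_false(isTRUE(all.equal(
    thole_damp(tt, 2, diag(3), diag(3), scheme = "exp"),
    thole_damp(tt, 2, diag(3), diag(3), scheme = "drude_exp"))))
  expect_identical(thole_damp(tt, 2, diag(3), diag(3), scheme = "none"), tt)
})

test_that("induction without neighbours reduces to alpha times the field", {
  sys1 <- polarizable_system(matrix(c(0, 0, 0), 1), list(diag(3) * 10),
                             external_field = c(0.01, 0, 0))
  expect_equal(solve_induced(sys1)$induced[1, ], c(0.1, 0, 0),
               tolerance = 1e-12)

  ## full intra-molecular exclusion kills all coupling
  set.seed(9)
  pos <- matrix(rnorm(12, sd = 3), 4, 3)
  alphas <- replicate(4, random_spd(), simplify = FALSE)
  ff <- matrix(rnorm(12, sd = 0.02), 4, 3)
  sys <- polarizable_system(pos, alphas, molecule_id = rep("m", 4),
                            external_field = ff,
                            mu0 = matrix(rnorm(12), 4, 3))
  got <- solve_induced(sys)$induced
  want <- t(vapply(1:4, function(i) as.vector(alphas[[i]] %*% ff[i, ]),
                   numeric(3)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("solver matches the explicit supermatrix inversion", {
  set.seed(23)
  for (n in 2:5) {
    pos <- matrix(rnorm(3 * n, sd = 4), n, 3)
    pos <- pos + 2 * seq_len(n)                 # spread sites out
    alphas <- replicate(n, random_spd(), simplify = FALSE)
    mu0 <- matrix(rnorm(3 * n, sd = 0.4), n, 3)
    ff <- matrix(rnorm(3 * n, sd = 0.02), n, 3)
    sys <- polarizable_system(pos, alphas, mu0 = mu0,
                              external_field = ff)
    got <- solve_induced(sys)$induced

    tt <- oracle_supermatrix(pos, alphas, seq_len(n))
    a_big <- matrix(0, 3 * n, 3 * n)
    for (i in seq_len(n))
      a_big[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <- alphas[[i]]
    rhs <- a_big %*% (as.vector(t(ff)) + tt %*% as.vector(t(mu0)))
    mu_oracle <- solve(diag(3 * n) - a_big %*% tt, rhs)
    expect_lt(max(abs(as.vector(t(got)) - mu_oracle)), 1e-10)

    ## and via damped fixed-point iteration (fully independent route)
    mu_it <- matrix(0, n, 3)
    for (it in 1:400) {
      fld <- matrix(as.vector(tt %*% as.vector(t(mu0 + mu_it))),
                    n, 3, byrow = TRUE) + ff
      mu_new <- t(vapply(seq_len(n), function(i)
        as.vector(alphas[[i]] %*% fld[i, ]), numeric(3)))
      if (max(abs(mu_new - mu_it)) < 1e-14) break
      mu_it <- mu_new
    }
    expect_lt(max(abs(got - mu_it)), 1e-9)
  }
})

test_that("relay row sums match the explicit inversion and the response", {
  set.seed(29)
  n <- 4
  pos <- matrix(rnorm(3 * n, sd = 5), n, 3) + 3 * seq_len(n)
  alphas <- replicate(n, random_spd(), simplify = FALSE)
  sys <- polarizable_system(pos, alphas)
  got <- corrected_polarizabilities(sys)

  ## explicit relay
  tt <- oracle_supermatrix(pos, alphas, seq_len(n))
  a_inv <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n))
    a_inv[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <- solve(alphas[[i]])
  b_mat <- solve(a_inv - tt)
  total_oracle <- matrix(0, 3, 3)
  for (i in seq_len(n)) for (j in seq_len(n))
    total_oracle <- total_oracle +
      b_mat[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
  expect_lt(max(abs(got$total - total_oracle)), 1e-10)

  ## response route: total alpha = d(sum mu)/dF under a uniform field
  h <- 1e-5
  resp <- matrix(0, 3, 3)
  for (k in 1:3) {
    fplus <- matrix(0, n, 3); fplus[, k] <- h
    mup <- solve_induced(polarizable_system(pos, alphas,
                                            external_field = fplus))
    mum <- solve_induced(polarizable_system(pos, alphas,
                                            external_field = -fplus))
    resp[, k] <- colSums(mup$induced - mum$induced) / (2 * h)
  }
  expect_equal(resp, got$total, tolerance = 1e-6)
})

test_that("two interacting isotropic sites recover the closed form", {
  ## alpha = 1 at r = 10, undamped: alpha_par = 2/(1 - 2/r^3),
  ## alpha_perp = 2/(1 + 1/r^3)
  sys <- polarizable_system(rbind(c(0, 0, 0), c(0, 0, 10)),
                            list(diag(3), diag(3)))
  got <- corrected_polarizabilities(sys, damping = "none")
  a_par <- 2 / (1 - 2 / 1000)
  a_perp <- 2 / (1 + 1 / 1000)
  expect_equal(got$total[3, 3], a_par, tolerance = 1e-10)
  expect_equal(got$total[1, 1], a_perp, tolerance = 1e-10)
  expect_equal(got$total[2, 2], a_perp, tolerance = 1e-10)
  expect_equal(a_par, 2.004008, tolerance = 1e-6)
  expect_equal(a_perp, 1.998002, tolerance = 1e-6)
})

test_that("distant sites decouple", {
  set.seed(41)
  alphas <- replicate(3, random_spd(), simplify = FALSE)
  pos <- matrix(rnorm(9, sd = 2), 3, 3)
  near <- corrected_polarizabilities(
    polarizable_system(pos + 10 * seq_len(3), alphas))
  far <- corrected_polarizabilities(
    polarizable_system(pos + 1000 * seq_len(3), alphas))
  orig <- Reduce(`+`, alphas)
  expect_lt(max(abs(far$total - orig)), 1e-6)
  expect_gt(max(abs(near$total - orig)), max(abs(far$total - orig)))

  ## a remote isotropic ion adds its own polarizability and nothing else
  sysi <- polarizable_system(rbind(pos, c(500, 500, 500)),
                             c(alphas, list(diag(3) * 0.3)))
  with_ion <- corrected_polarizabilities(sysi)
  base <- corrected_polarizabilities(polarizable_system(pos, alphas))
  expect_equal(with_ion$total, base$total + diag(3) * 0.3,
               tolerance = 1e-6)
})

test_that("results are invariant under site permutation", {
  set.seed(43)
  n <- 5
  pos <- matrix(rnorm(3 * n, sd = 6), n, 3)
  alphas <- replicate(n, random_spd(), simplify = FALSE)
  mu0 <- matrix(rnorm(3 * n, sd = 0.3), n, 3)
  perm <- sample(n)
  s1 <- polarizable_system(pos, alphas, mu0 = mu0)
  s2 <- polarizable_system(pos[perm, ], alphas[perm], mu0 = mu0[perm, ])
  expect_equal(colSums(solve_induced(s1)$induced),
               colSums(solve_induced(s2)$induced), tolerance = 1e-10)
  expect_equal(corrected_polarizabilities(s1)$total,
               corrected_polarizabilities(s2)$total, tolerance = 1e-10)
})

test_that("close contacts stay solvable under damping", {
  sys <- polarizable_system(rbind(c(0, 0, 0), c(0, 0, 0.5)),
                            list(diag(3) * 10, diag(3) * 10))
  expect_no_error(solve_induced(sys, b = 2.6))
  expect_no_error(corrected_polarizabilities(sys, b = 2.6))
  total <- corrected_polarizabilities(sys, b = 2.6)$total
  expect_true(all(is.finite(total)))
})

test_that("zero-polarizability sites pass through the relay untouched", {
  set.seed(47)
  alphas <- list(random_spd(), diag(3) * 0, random_spd())
  pos <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 6, 0))
  got <- corrected_polarizabilities(polarizable_system(pos, alphas))
  expect_equal(got$per_site[[2]], diag(3) * 0)
  expect_true(all(is.finite(got$total)))
})

test_that("permanent dipoles only matter when enabled", {
  set.seed(53)
  pos <- rbind(c(0, 0, 0), c(6, 0, 0))
  alphas <- list(diag(3) * 4, diag(3) * 4)
  mu0 <- rbind(c(1, 0, 0), c(0, 1, 0))
  sys <- polarizable_system(pos, alphas, mu0 = mu0)
  on_ <- solve_induced(sys, include_permanent_dipoles = TRUE)$induced
  off <- solve_induced(sys, include_permanent_dipoles = FALSE)$induced
  expect_true(max(abs(on_)) > 0)
  expect_equal(max(abs(off)), 0)
})
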