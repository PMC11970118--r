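## Applequist dipole interaction model with Thole-style damping: mutual
## induction among point polarizable sites through the dipole field tensor,
## with intra-molecular pairs excluded (their interactions are already part
## of the database entries).  Environment-corrected per-site polarizabilities
## come from row sums of the relay matrix B = (A^-1 - T)^-1.

#' Dipole-dipole field tensor
#'
#' T = (3 rhat rhat' - I) / r^3 for two sites (atomic units, bohr^-3).
#' Symmetric and traceless.
#'
#' @param r_a,r_b site positions, bohr.
#' @return 3x3 matrix.
#' @export
field_tensor <- function(r_a, r_b) {
  d <- r_a - r_b
  r <- vnorm(d)
  if (r < 1e-6) stop("coincident sites: |r| < 1e-6 bohr in field tensor")
  rh <- d / r
  (3 * tcrossprod(rh) - diag(3)) / r^3
}

## scalar screening factors S(u); S -> 1 as u -> infinity.  For small u the
## direct 1 - (...)exp(-u) form loses all precision to cancellation, so the
## exact series remainders are used there:
## 1 - (1+u+u^2/2+u^3/6) e^-u = e^-u * sum_{k>=4} u^k/k!
## 1 - (1+u/2) e^-u        = e^-u * (expm1(u) - u/2)
screen_exp <- function(u) {
  out <- numeric(length(u))
  small <- u < 1
  if (any(small)) {
    k <- 4:12
    out[small] <- exp(-u[small]) *
      vapply(u[small], function(x) sum(x^k / factorial(k)), 0)
  }
  if (any(!small)) {
    ub <- u[!small]
    out[!small] <- 1 - (1 + ub + ub^2 / 2 + ub^3 / 6) * exp(-ub)
  }
  out
}
screen_drude <- function(u) exp(-u) * (expm1(u) - u / 2)

#' Thole-damped dipole field tensor
#'
#' Screens the dipole-dipole tensor at short range to avoid the polarization
#' catastrophe, using the scaled distance u = b * r /
#' (alpha_iso_a * alpha_iso_b)^(1/6).  The default `"exp"` scheme multiplies
#' T by S(u) = 1 - (1 + u + u^2/2 + u^3/6) exp(-u), which tends to 1 at
#' large separation and suppresses the tensor to zero as r -> 0.
#' `"drude_exp"` uses S(u) = 1 - (1 + u/2) exp(-u) (the screening of Drude
#' polarizable force fields); `"thole_linear"` applies the piecewise-linear
#' lambda3/lambda5 factors; `"none"` returns T unchanged.  If either site
#' has zero isotropic polarizability (a bare point charge site), no damping
#' is applied.
#'
#' @param t_ab undamped tensor from [field_tensor()].
#' @param r intersite distance, bohr.
#' @param alpha_a,alpha_b site polarizabilities (3x3 matrices or isotropic
#'   scalars), bohr^3.
#' @param b dimensionless damping parameter (default 2.6).
#' @param scheme damping scheme.
#' @return damped 3x3 tensor.
#' @export
thole_damp <- function(t_ab, r, alpha_a, alpha_b, b = 2.6,
                       scheme = c("exp", "drude_exp", "thole_linear",
                                  "none")) {
  scheme <- match.arg(scheme)
  stopifnot(b > 0, r > 0)
  if (scheme == "none") return(t_ab)
  iso <- function(a) if (is.matrix(a)) sum(diag(a)) / 3 else a[1L]
  ia <- iso(alpha_a); ib <- iso(alpha_b)
  if (ia <= 0 || ib <= 0) return(t_ab)
  u <- b * r / (ia * ib)^(1 / 6)
  switch(scheme,
         exp = screen_exp(u) * t_ab,
         drude_exp = screen_drude(u) * t_ab,
         thole_linear = {
           if (u >= 1) t_ab
           else {
             l3 <- 4 * u^3 - 3 * u^4
             l5 <- u^4
             rr <- (t_ab * r^3 + diag(3)) / 3    # rhat rhat'
             (3 * l5 * rr - l3 * diag(3)) / r^3
           }
         })
}

#' Build a polarizable system of interaction sites
#'
#' Sites sharing a `molecule_id` do not interact (their mutual response is
#' already folded into the database entries); everything else couples
#' through the damped dipole tensor.
#'
#' @param positions matrix (n x 3), bohr.
#' @param alphas list of n 3x3 polarizability tensors, bohr^3.
#' @param mu0 matrix (n x 3) of permanent dipoles, e*bohr (default zero).
#' @param molecule_id character/integer vector of length n.
#' @param external_field matrix (n x 3) of external fields at the sites,
#'   Eh/(e*bohr) (default zero).
#' @param site_id optional site labels.
#' @return object of class `polarizable_system`.
#' @export
polarizable_system <- function(positions, alphas, mu0 = NULL,
                               molecule_id = NULL, external_field = NULL,
                               site_id = NULL) {
  positions <- matrix(positions, ncol = 3L)
  n <- nrow(positions)
  stopifnot(length(alphas) == n)
  for (i in seq_len(n)) {
    a <- alphas[[i]]
    if (length(a) == 1L) alphas[[i]] <- diag(3) * as.numeric(a)
    else {
      stopifnot(all(dim(a) == c(3L, 3L)))
      if (asym_norm(a) > 1e-8 * max(1, max(abs(a))))
        stop("site ", i, ": polarizability tensor is not symmetric")
    }
  }
  if (is.null(mu0)) mu0 <- matrix(0, n, 3L) else mu0 <- matrix(mu0, ncol = 3L)
  if (is.null(external_field)) external_field <- matrix(0, n, 3L)
  else external_field <- matrix(external_field, ncol = 3L)
  if (is.null(molecule_id)) molecule_id <- seq_len(n)
  if (is.null(site_id)) site_id <- as.character(seq_len(n))
  stopifnot(nrow(mu0) == n, nrow(external_field) == n,
            length(molecule_id) == n, length(site_id) == n)
  structure(list(positions = positions, alphas = alphas, mu0 = mu0,
                 molecule_id = molecule_id,
                 external_field = external_field, site_id = site_id),
            class = "polarizable_system")
}

#' @export
print.polarizable_system <- function(x, ...) {
  cat("polarizable_system:", nrow(x$positions), "sites,",
      length(unique(x$molecule_id)), "molecules\n")
  invisible(x)
}

## 3n x 3n damped interaction supermatrix; zero blocks on the diagonal and
## for excluded (same-molecule) pairs
interaction_matrix <- function(sys, b = 2.6, scheme = "exp") {
  n <- nrow(sys$positions)
  t_big <- matrix(0, 3L * n, 3L * n)
  if (n < 2L) return(t_big)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (identical(sys$molecule_id[i], sys$molecule_id[j])) next
      tij <- field_tensor(sys$positions[i, ], sys$positions[j, ])
      r <- vnorm(sys$positions[i, ] - sys$positions[j, ])
      tij <- thole_damp(tij, r, sys$alphas[[i]], sys$alphas[[j]], b = b,
                        scheme = scheme)
      ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
      t_big[ii, jj] <- tij
      t_big[jj, ii] <- t(tij)                  # tij is symmetric
    }
  }
  t_big
}

block_diag_alphas <- function(alphas) {
  n <- length(alphas)
  a_big <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n)) {
    ii <- (3L * i - 2L):(3L * i)
    a_big[ii, ii] <- alphas[[i]]
  }
  a_big
}

## one-inversion path used by the pipeline: the relay matrix
## B = (A^-1 - T)^-1 yields both the induced dipoles
## (mu_ind = B (F_ext + T mu0)) and the corrected tensors (row-block sums
## of B).  Requires all site tensors invertible; callers with zero-alpha
## sites use the generic functions instead.
run_adim <- function(sys, b = 2.6, damping = "exp",
                     include_permanent_dipoles = TRUE) {
  n <- nrow(sys$positions)
  if (!all(vapply(sys$alphas, function(a) max(abs(a)) > 0, TRUE)))
    return(list(
      induced = solve_induced(sys, b, damping,
                              include_permanent_dipoles)$induced,
      corrected = corrected_polarizabilities(sys, b, damping)))
  t_big <- interaction_matrix(sys, b = b, scheme = damping)
  a_inv <- matrix(0, 3L * n, 3L * n)
  for (k in seq_len(n)) {
    kk <- (3L * k - 2L):(3L * k)
    a_inv[kk, kk] <- solve(sys$alphas[[k]])
  }
  b_mat <- tryCatch(solve(a_inv - t_big),
                    error = function(e)
                      stop("singular relay matrix (polarization ",
                           "catastrophe despite damping); increase the ",
                           "Thole b parameter or check the geometry",
                           call. = FALSE))
  rhs <- as.vector(t(sys$external_field))
  if (include_permanent_dipoles)
    rhs <- rhs + as.vector(t_big %*% as.vector(t(sys$mu0)))
  induced <- matrix(b_mat %*% rhs, ncol = 3L, byrow = TRUE)
  per_site <- vector("list", n)
  for (k in seq_len(n)) {
    kk <- (3L * k - 2L):(3L * k)
    row_sum <- matrix(0, 3L, 3L)
    for (l in seq_len(n)) {
      ll <- (3L * l - 2L):(3L * l)
      row_sum <- row_sum + b_mat[kk, ll]
    }
    per_site[[k]] <- row_sum
  }
  total <- Reduce(`+`, per_site)
  if (asym_norm(total) > 1e-8 * max(1, max(abs(total))))
    stop("corrected total polarizability asymmetric beyond tolerance")
  list(induced = induced,
       corrected = list(per_site = per_site, total = sym_part(total)))
}

#' Solve the mutual-induction equations
#'
#' Each site's dipole responds to the external field plus the fields of all
#' non-excluded neighbours' dipoles (permanent mu0 and induced alike):
#' mu_ind = alpha (F_ext + T (mu0 + mu_ind)).  Solved directly as
#' (I - alpha T) mu_ind = alpha (F_ext + T mu0).
#'
#' @param sys a `polarizable_system`.
#' @param b Thole damping parameter (default 2.6).
#' @param damping damping scheme (see [thole_damp()]).
#' @param include_permanent_dipoles should permanent dipoles act as field
#'   sources for the other sites (default TRUE)?
#' @return list with `induced` (n x 3 matrix of induced dipoles, e*bohr)
#'   and `total` (mu0 + induced).
#' @export
solve_induced <- function(sys, b = 2.6, damping = "exp",
                          include_permanent_dipoles = TRUE) {
  n <- nrow(sys$positions)
  t_big <- interaction_matrix(sys, b = b, scheme = damping)
  a_big <- block_diag_alphas(sys$alphas)
  rhs_field <- as.vector(t(sys$external_field))
  if (include_permanent_dipoles)
    rhs_field <- rhs_field + as.vector(t_big %*% as.vector(t(sys$mu0)))
  lhs <- diag(3L * n) - a_big %*% t_big
  mu_ind <- tryCatch(solve(lhs, a_big %*% rhs_field),
                     error = function(e)
                       stop("singular induction system (polarization ",
                            "catastrophe despite damping); increase the ",
                            "Thole b parameter or check the geometry",
                            call. = FALSE))
  induced <- matrix(mu_ind, ncol = 3L, byrow = TRUE)
  ## residual of the fixed-point form, relative
  res <- lhs %*% mu_ind - a_big %*% rhs_field
  scale <- max(1e-30, vnorm(a_big %*% rhs_field))
  if (vnorm(res) / scale > 1e-10)
    warning("induction solve residual above 1e-10 (relative)")
  list(induced = induced, total = sys$mu0 + induced)
}

#' Environment-corrected polarizabilities from the relay matrix
#'
#' Builds the relay matrix B = (A^-1 - T)^-1 with A the block-diagonal of
#' the site tensors and T the damped, exclusion-aware interaction matrix.
#' The corrected polarizability of site i is the row sum over 3x3 blocks
#' sum_j B_ij; the system polarizability is the grand sum.  Sites with a
#' zero tensor cannot enter A^-1; they are removed from the relay and
#' reported with their (zero) tensor uncorrected.
#'
#' @inheritParams solve_induced
#' @return list with `per_site` (list of n corrected 3x3 tensors) and
#'   `total` (3x3, symmetrized; asymmetry above 1e-8 is an error).
#' @export
corrected_polarizabilities <- function(sys, b = 2.6, damping = "exp") {
  n <- nrow(sys$positions)
  live <- vapply(sys$alphas, function(a) max(abs(a)) > 0, TRUE)
  idx <- which(live)
  per_site <- sys$alphas                        # zero-alpha sites pass through
  if (length(idx) > 0L) {
    sub <- polarizable_system(sys$positions[idx, , drop = FALSE],
                              sys$alphas[idx],
                              molecule_id = sys$molecule_id[idx],
                              site_id = sys$site_id[idx])
    m <- length(idx)
    t_big <- interaction_matrix(sub, b = b, scheme = damping)
    a_inv <- matrix(0, 3L * m, 3L * m)
    for (k in seq_len(m)) {
      kk <- (3L * k - 2L):(3L * k)
      a_inv[kk, kk] <- solve(sub$alphas[[k]])
    }
    b_mat <- tryCatch(solve(a_inv - t_big),
                      error = function(e)
                        stop("singular relay matrix (polarization ",
                             "catastrophe despite damping); increase the ",
                             "Thole b parameter or check the geometry",
                             call. = FALSE))
    for (k in seq_len(m)) {
      kk <- (3L * k - 2L):(3L * k)
      row_sum <- matrix(0, 3L, 3L)
      for (l in seq_len(m)) {
        ll <- (3L * l - 2L):(3L * l)
        row_sum <- row_sum + b_mat[kk, ll]
      }
      per_site[[idx[k]]] <- row_sum
    }
  }
  total <- Reduce(`+`, per_site, accumulate = FALSE)
  if (asym_norm(total) > 1e-8 * max(1, max(abs(total))))
    stop("corrected total polarizability asymmetric beyond tolerance")
  total <- sym_part(total)
  list(per_site = per_site, total = total)
}
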