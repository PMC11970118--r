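## Electrostatics: charge dipole moment of the ionizable-site charges,
## point-charge electric fields, and the field correction of the stored
## ("core") block dipoles.  All quantities in atomic units; positions in
## bohr.

#' Charge dipole moment of a set of point charges
#'
#' Computed as Q+ times the vector R from the centre of negative charge to
#' the centre of positive charge, mu = Q+ * (sum(q+ r+)/Q+ -
#' sum(|q-| r-)/Q-).  For a neutral set this equals sum(q_i r_i) and is
#' origin independent; a neutrality warning is issued when |sum q| exceeds
#' 0.01 e.  Neutralized sites must be excluded by the caller.
#'
#' @param q numeric vector of charges, e.
#' @param pos matrix (n x 3) of positions, bohr.
#' @param neutrality_tol warn when |sum q| exceeds this (e).  The pipeline
#'   relaxes it: neutralizing a terminal group removes its fractional
#'   compensating charge, so the *applied* charge set is legitimately
#'   non-neutral there even though the physical system (zwitterion plus
#'   ions) stays neutral.
#' @return dipole 3-vector, e*bohr; the zero vector for an empty set.
#' @export
charge_dipole <- function(q, pos, neutrality_tol = 0.01) {
  if (length(q) == 0L) return(c(0, 0, 0))
  pos <- matrix(pos, ncol = 3L)
  stopifnot(nrow(pos) == length(q))
  net <- sum(q)
  if (abs(net) > neutrality_tol)
    warning(sprintf("charge set is not neutral (net %+.4f e); %s", net,
                    "the charge dipole is origin dependent"))
  pl <- q > 0; mn <- q < 0
  if (any(pl) && any(mn)) {
    qp <- sum(q[pl]); qm <- sum(-q[mn])
    cp <- colSums(q[pl] * pos[pl, , drop = FALSE]) / qp
    cm <- colSums(-q[mn] * pos[mn, , drop = FALSE]) / qm
    qp * (cp - cm)
  } else {
    as.vector(colSums(q * pos))
  }
}

#' Electric field of point charges at a point
#'
#' F = sum_i q_i / |r_i|^2 * rhat_i with rhat_i the unit vector from charge
#' i towards the evaluation point (atomic units, no 4*pi*eps0).
#'
#' @param point 3-vector, bohr.
#' @param q charges, e.
#' @param pos matrix (n x 3) of charge positions, bohr.
#' @return field 3-vector, Eh/(e*bohr).
#' @export
field_from_charges <- function(point, q, pos) {
  if (length(q) == 0L) return(c(0, 0, 0))
  pos <- matrix(pos, ncol = 3L)
  dx <- sweep(-pos, 2L, point, FUN = "+")       # point - pos
  r <- sqrt(rowSums(dx * dx))
  if (any(r < 0.1))
    stop("field evaluation point within 0.1 bohr of a charge ",
         "(unphysical overlap)")
  as.vector(colSums(q / r^3 * dx))
}

#' Field-correct the core (block) dipole moments
#'
#' mu_block = mu0_block + alpha_block %*% F_block for each block.  Fields
#' must include the charges of neutralized residues and of bound ions; the
#' block polarizability tensors themselves are never modified by charges.
#'
#' @param mu0 matrix (n x 3) of initial block dipoles, e*bohr.
#' @param alphas list of n 3x3 block polarizability tensors, bohr^3.
#' @param fields matrix (n x 3) of total fields at the block centres,
#'   Eh/(e*bohr).
#' @return matrix (n x 3) of corrected dipoles.
#' @export
correct_core_dipoles <- function(mu0, alphas, fields) {
  mu0 <- matrix(mu0, ncol = 3L)
  fields <- matrix(fields, ncol = 3L)
  stopifnot(nrow(mu0) == length(alphas), nrow(fields) == length(alphas))
  out <- mu0
  for (i in seq_along(alphas))
    out[i, ] <- mu0[i, ] + as.vector(alphas[[i]] %*% fields[i, ])
  out
}
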