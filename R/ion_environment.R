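## Ion environment: distance-criterion detection of coordinated Na+/Cl-,
## neutralization bookkeeping for the charge dipole, the inflated
## minimum-volume enclosing ellipsoid water cutoff, and the 70-member
## NaCl pair-configuration enumerator with its naming scheme.

.cl_binding_groups <- c("LYS", "ARG", "NTER")   # via H...Cl distance
.na_binding_groups <- c("ASP", "GLU", "CTER")   # via O...Na distance

#' Detect ions coordinated to ionizable residues
#'
#' A Cl- is bound when its minimum distance to any hydrogen of a basic
#' ionizable block (LYS, ARG, NTER) is within `cl_threshold` (default
#' 2.5 angstrom, the H-Cl bond criterion); an Na+ is bound when within
#' `na_threshold` (default 3.5 angstrom, O-Na) of any oxygen of an acidic
#' block (ASP, GLU, CTER).  Each ion binds at most one residue and each
#' residue at most one ion; conflicts are resolved greedily by smallest
#' distance, ties broken by residue order then ion order.
#'
#' @param structure a `protein_structure`.
#' @param env_sites environment-site data frame from [read_structure()].
#' @param cl_threshold,na_threshold binding thresholds, angstrom.
#' @return data frame of bindings: `ion` (row index into `env_sites`),
#'   `ion_kind`, `block_id`, `group`, `distance` (angstrom).
#' @export
detect_bound_ions <- function(structure, env_sites, cl_threshold = 2.5,
                              na_threshold = 3.5) {
  empty <- data.frame(ion = integer(), ion_kind = character(),
                      block_id = character(), group = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  ions <- which(env_sites$kind %in% c("NA", "CL"))
  sites <- structure$ionizable_sites
  if (length(ions) == 0L || nrow(sites) == 0L) return(empty)

  cand <- list()
  for (s in seq_len(nrow(sites))) {
    grp <- sites$group[s]
    blk <- block_by_id(structure, sites$block_id[s])
    if (grp %in% .cl_binding_groups) {
      want_kind <- "CL"; thr <- cl_threshold
      sel <- blk$atoms$element %in% c("H", "D")
    } else if (grp %in% .na_binding_groups) {
      want_kind <- "NA"; thr <- na_threshold
      sel <- blk$atoms$element == "O"
    } else next                                  # HIS, TYR, CYS: no rule
    if (!any(sel)) next
    axyz <- as.matrix(blk$atoms[sel, c("x", "y", "z")])
    for (i in ions) {
      if (env_sites$kind[i] != want_kind) next
      d2 <- (axyz[, 1L] - env_sites$x[i])^2 +
            (axyz[, 2L] - env_sites$y[i])^2 +
            (axyz[, 3L] - env_sites$z[i])^2
      dmin <- sqrt(min(d2))
      if (dmin <= thr)
        cand[[length(cand) + 1L]] <-
          data.frame(ion = i, ion_kind = want_kind,
                     block_id = sites$block_id[s], group = grp,
                     site_order = s, distance = dmin,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$distance, cand$site_order, cand$ion), ,
               drop = FALSE]
  used_ion <- integer(); used_site <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$ion[i] %in% used_ion || cand$block_id[i] %in% used_site) next
    keep[i] <- TRUE
    used_ion <- c(used_ion, cand$ion[i])
    used_site <- c(used_site, cand$block_id[i])
  }
  out <- cand[keep, c("ion", "ion_kind", "block_id", "group", "distance"),
              drop = FALSE]
  out <- out[order(out$ion), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Neutralize ion-bound charge sites
#'
#' Residues coordinated to an ion are flagged `neutralized = TRUE`: they are
#' excluded from the charge dipole moment but keep their charge as a field
#' source for the core-dipole correction (as does the bound ion itself).
#'
#' @param charge_sites data frame from [assign_charges()].
#' @param bindings data frame from [detect_bound_ions()].
#' @return `charge_sites` with updated `neutralized` flags.
#' @export
neutralize <- function(charge_sites, bindings) {
  if (nrow(bindings) == 0L || nrow(charge_sites) == 0L)
    return(charge_sites)
  charge_sites$neutralized <-
    charge_sites$neutralized | charge_sites$block_id %in% bindings$block_id
  charge_sites
}

## Khachiyan-type minimum-volume enclosing ellipsoid:
## returns centre c and shape A with (x - c)' A (x - c) <= 1.
## First-order iteration on the dual D-optimal design problem, accelerated
## with Wolfe-Atwood away steps (linear convergence, so the 1e-6 tolerance
## is reachable) and periodic Harman-Pronzato elimination of points that
## provably cannot support the optimum.
mvee <- function(points, tol = 1e-6, maxit = 100000L) {
  p <- unique(as.matrix(points))
  n <- nrow(p); d <- ncol(p)
  k <- d + 1
  q <- t(cbind(p, 1))                           # k x n
  u <- rep(1 / n, n)
  for (it in seq_len(maxit)) {
    x <- q %*% (u * t(q))
    m <- colSums(q * solve(x, q))
    jp <- which.max(m)
    eps <- m[jp] / k - 1                        # relative optimality gap
    if (eps < tol) break
    sup <- which(u > 1e-12)
    jm <- sup[which.min(m[sup])]
    if (m[jp] - k >= k - m[jm]) {               # regular (add) step
      j <- jp
      lam <- (m[j] - k) / (k * (m[j] - 1))
    } else {                                    # away (drop) step
      j <- jm
      lam <- max((m[j] - k) / (k * (m[j] - 1)), -u[j] / (1 - u[j]))
    }
    u <- (1 - lam) * u
    u[j] <- u[j] + lam
    u[u < 0] <- 0
    if (it %% 50L == 0L && eps < 1) {
      thr <- k * (1 + eps / 2 - sqrt(eps * (4 + eps - 4 / k)) / 2)
      keep <- m >= thr
      if (!all(keep) && sum(keep) > k) {
        q <- q[, keep, drop = FALSE]
        p <- p[keep, , drop = FALSE]
        u <- u[keep] / sum(u[keep])
      }
    }
  }
  centre <- as.vector(t(p) %*% u)
  a <- solve(t(p) %*% (u * p) - tcrossprod(centre)) / d
  list(centre = centre, shape = sym_part(a))
}

## grow each semi-axis of (x-c)' A (x-c) <= 1 by `margin`
inflate_ellipsoid <- function(ell, margin) {
  e <- eigen(ell$shape, symmetric = TRUE)
  semi <- 1 / sqrt(pmax(e$values, 1e-300)) + margin
  shape <- e$vectors %*% diag(1 / semi^2) %*% t(e$vectors)
  list(centre = ell$centre, shape = sym_part(shape))
}

in_ellipsoid <- function(ell, xyz) {
  dx <- sweep(as.matrix(xyz), 2L, ell$centre)
  rowSums((dx %*% ell$shape) * dx) <= 1
}

#' Trim environment waters by an inflated enclosing ellipsoid
#'
#' Fits the minimum-volume enclosing ellipsoid of the protein atoms
#' (Khachiyan algorithm, tolerance 1e-6), grows each semi-axis by `cutoff`
#' and keeps only waters inside it.  Ions are always kept, wherever they
#' are, to preserve charge balance.  Degenerate (coplanar) geometries fall
#' back to a sphere around the centroid.
#'
#' @param structure a `protein_structure`.
#' @param env_sites environment-site data frame.
#' @param cutoff margin in angstrom (default 8).
#' @return filtered `env_sites`.
#' @export
ellipsoid_cutoff <- function(structure, env_sites, cutoff = 8) {
  stopifnot(cutoff >= 0)
  wat <- env_sites$kind == "WATER"
  if (!any(wat)) return(env_sites)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  ell <- tryCatch(mvee(xyz), error = function(e) NULL)
  wxyz <- as.matrix(env_sites[wat, c("x", "y", "z")])
  if (is.null(ell)) {
    centre <- colMeans(xyz)
    rad <- sqrt(max(rowSums(sweep(xyz, 2L, centre)^2))) + cutoff
    keep_w <- sqrt(rowSums(sweep(wxyz, 2L, centre)^2)) <= rad
  } else {
    keep_w <- in_ellipsoid(inflate_ellipsoid(ell, cutoff), wxyz)
  }
  keep <- !wat
  keep[which(wat)[keep_w]] <- TRUE
  out <- env_sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.na_letters <- c("A", "B", "C", "D")
.cl_letters <- c("X", "Y", "Z", "W")            # canonical order, not A-Z

#' Name an ion configuration
#'
#' Six-character code: the sorted Na+ site letters (A-D) padded with "-" to
#' width 3, then the sorted Cl- site letters (X, Y, Z, W order) likewise.
#' The empty configuration is "standard"; the full one is "ABCDXYZW".
#'
#' @param na_sites subset of A/B/C/D.
#' @param cl_sites subset of X/Y/Z/W (same size as `na_sites`: ions come in
#'   pairs).
#' @return the configuration name.
#' @export
config_name <- function(na_sites, cl_sites) {
  if (!all(na_sites %in% .na_letters) || !all(cl_sites %in% .cl_letters))
    stop("invalid site letters")
  na_sites <- .na_letters[sort(match(na_sites, .na_letters))]
  cl_sites <- .cl_letters[sort(match(cl_sites, .cl_letters))]
  if (length(na_sites) != length(cl_sites))
    stop("ions come in pairs: |na_sites| must equal |cl_sites|")
  k <- length(na_sites)
  if (k == 0L) return("standard")
  if (k == 4L) return("ABCDXYZW")
  pad <- function(x) formatC(paste(x, collapse = ""), width = -3,
                             flag = "-")
  out <- paste0(pad(na_sites), pad(cl_sites))
  gsub(" ", "-", out)
}

subsets_of <- function(letters_, k) {
  if (k == 0L) return(list(character()))
  cmb <- utils::combn(seq_along(letters_), k)
  lapply(seq_len(ncol(cmb)), function(j) letters_[cmb[, j]])
}

#' Enumerate the 70 NaCl pair configurations
#'
#' All pairs (S+, S-) with S+ a subset of {A,B,C,D}, S- a subset of
#' {X,Y,Z,W} and |S+| = |S-| (ions are added in charge-balancing pairs):
#' 1 + 16 + 36 + 16 + 1 = 70 configurations.  Numbered 1 (standard) to 70
#' (ABCDXYZW), lexicographically within each pair-count class.
#'
#' @return data frame with `number`, `name`, `n_pairs`, `na_sites`,
#'   `cl_sites` (the site strings, e.g. `"AC"` / `"ZW"`).
#' @export
enumerate_configurations <- function() {
  rows <- list()
  for (k in 0:4) {
    na_subs <- subsets_of(.na_letters, k)
    cl_subs <- subsets_of(.cl_letters, k)
    for (na in na_subs) for (cl in cl_subs) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = config_name(na, cl), n_pairs = k,
        na_sites = paste(na, collapse = ""),
        cl_sites = paste(cl, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$number <- seq_len(nrow(out))
  out[, c("number", "name", "n_pairs", "na_sites", "cl_sites")]
}
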