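## Block property database: per-block dipole vectors and polarizability
## tensors in a local anchor-atom frame, stored as JSON.  The shipped
## database is synthetic (seeded), standing in for real per-fragment
## entries; it exercises the full vector/tensor pathway without pretending
## to carry measured values.

## default isotropic polarizabilities for environment sites, bohr^3
.default_env_alpha <- c(`NA` = 0.3, CL = 30.0, WATER = 9.8)

db_schema_version <- "1"

#' Construct a block database object
#'
#' @param entries named list of entries; each entry has `dipole_local`
#'   (3-vector, e*bohr), `polarizability_local` (3x3 symmetric, bohr^3) and
#'   `frame_atoms` (3 distinct atom names anchoring the local frame).
#' @param metadata named list; `units` defaults to `"au"`.
#' @return object of class `block_db`.
#' @export
block_db <- function(entries, metadata = list()) {
  metadata$units <- if (is.null(metadata$units)) "au" else metadata$units
  metadata$version <- if (is.null(metadata$version)) db_schema_version else
    metadata$version
  db <- structure(list(metadata = metadata, entries = entries),
                  class = "block_db")
  validate_db(db)
  db
}

validate_db <- function(db) {
  if (anyDuplicated(names(db$entries)))
    stop("duplicate db_key in block database")
  for (key in names(db$entries)) {
    e <- db$entries[[key]]
    if (length(e$dipole_local) != 3L || !all(is.finite(e$dipole_local)))
      stop("entry '", key, "': dipole_local must be a finite 3-vector")
    a <- e$polarizability_local
    if (!is.matrix(a) || !all(dim(a) == c(3L, 3L)) || !all(is.finite(a)))
      stop("entry '", key, "': polarizability_local must be a finite 3x3 matrix")
    if (asym_norm(a) > 1e-9 * max(1, max(abs(a))))
      stop("entry '", key, "': polarizability tensor is not symmetric")
    ev <- eigen(sym_part(a), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9 * max(1, max(abs(ev))))
      stop("entry '", key, "': polarizability tensor has negative eigenvalues")
    fa <- e$frame_atoms
    if (length(fa) != 3L || anyDuplicated(fa))
      stop("entry '", key, "': frame_atoms must be 3 distinct atom names")
  }
  invisible(db)
}

#' @export
print.block_db <- function(x, ...) {
  cat("block_db:", length(x$entries), "entries (units:",
      x$metadata$units, ")\n")
  invisible(x)
}

#' Save a block database as JSON
#'
#' UTF-8 JSON with sorted keys and 12 significant digits; saving, loading
#' and saving again reproduces the file byte-for-byte.
#'
#' @param db a `block_db`.
#' @param path output path.
#' @export
save_db <- function(db, path) {
  keys <- sort(names(db$entries))
  ser <- list(
    metadata = db$metadata,
    entries = stats::setNames(lapply(keys, function(k) {
      e <- db$entries[[k]]
      list(dipole_local = signif(as.numeric(e$dipole_local), 12),
           polarizability_local =
             unname(apply(signif(e$polarizability_local, 12), 1L, as.list,
                          simplify = FALSE)),
           frame_atoms = as.character(e$frame_atoms))
    }), keys))
  json <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a block database from JSON
#'
#' @param path JSON file written by [save_db()] (schema:
#'   `{"metadata": {...}, "entries": {key: {"dipole_local": [3],
#'   "polarizability_local": [[3x3]], "frame_atoms": [3]}}}`).
#' @return a `block_db`.
#' @export
load_db <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = TRUE)
  if (is.null(raw$entries))
    stop("block database file has no 'entries' object")
  entries <- lapply(names(raw$entries), function(k) {
    e <- raw$entries[[k]]
    a <- e$polarizability_local
    if (is.list(a)) a <- do.call(rbind, lapply(a, unlist))
    list(dipole_local = as.numeric(e$dipole_local),
         polarizability_local = matrix(as.numeric(a), 3L, 3L, byrow = FALSE),
         frame_atoms = as.character(e$frame_atoms))
  })
  names(entries) <- names(raw$entries)
  md <- as.list(raw$metadata)
  block_db(entries, md)
}

## heavy-atom counts per block kind, from the fixture templates
block_heavy_count <- function(resname, kind) {
  switch(kind,
         backbone = 4L,                       # N, CA, C, O
         NTER = 1L,                           # N (hydrogens Z=1 not counted)
         CTER = 3L,                           # C, O, OXT
         sidechain = {
           tpl <- .sidechain_templates[[resname]]
           if (is.null(tpl)) 3L else length(tpl$heavy)
         })
}

block_frame_atoms <- function(resname, kind) {
  switch(kind,
         backbone = c("N", "CA", "C"),
         NTER = c("N", "H1", "H2"),
         CTER = c("C", "O", "OXT"),
         sidechain = {
           tpl <- .sidechain_templates[[resname]]
           nms <- c(names(tpl$heavy), names(tpl$hydro))
           nms[1:3]
         })
}

## SPD tensor with mean eigenvalue `iso` and relative eigenvalue spread
## controlled by `anisotropy_frac` in [0, 1)
random_spd_tensor <- function(iso, anisotropy_frac) {
  u <- stats::runif(3L, -1, 1)
  u <- u - mean(u)
  mx <- max(abs(u))
  if (mx > 0) u <- u / mx
  ev <- iso * (1 + anisotropy_frac * u)
  r <- random_rotation()
  sym_part(r %*% diag(ev) %*% t(r))
}

#' Synthesize a seeded block database
#'
#' One entry per (residue, block kind) plus NTER/CTER.  Tensors are
#' symmetric positive definite with trace/3 equal to `base_iso` times the
#' block's heavy-atom count; eigenvalue spread is set by `anisotropy_frac`.
#' Dipoles point along the block's first local frame axis with magnitude
#' drawn from U(0.5, 2) e*bohr.  Fully reproducible from `seed`.
#'
#' @param residues residue names to cover (default: all fixture-supported
#'   residues).
#' @param seed integer seed.
#' @param base_iso isotropic polarizability per heavy atom, bohr^3
#'   (default 11, a typical in-molecule heavy-atom scale).
#' @param anisotropy_frac relative eigenvalue spread in `[0, 1)`.
#' @return a `block_db`.
#' @export
synthesize_db <- function(residues = fixture_residues(), seed = 1L,
                          base_iso = 11, anisotropy_frac = 0.3) {
  stopifnot(base_iso > 0, anisotropy_frac >= 0, anisotropy_frac < 1)
  keys <- c(unlist(lapply(residues, function(r) {
    k <- paste0(r, ".backbone")
    if (r != "GLY") k <- c(k, paste0(r, ".sidechain"))
    k
  })), "NTER", "CTER")
  entries <- with_seed(seed, {
    out <- list()
    for (key in keys) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      if (key %in% c("NTER", "CTER")) {
        resname <- key; kind <- key
      } else {
        resname <- parts[1L]; kind <- parts[2L]
      }
      nh <- block_heavy_count(resname, kind)
      alpha <- random_spd_tensor(base_iso * nh, anisotropy_frac)
      mag <- stats::runif(1L, 0.5, 2.0)
      out[[key]] <- list(dipole_local = c(mag, 0, 0),
                         polarizability_local = alpha,
                         frame_atoms = block_frame_atoms(resname, kind))
    }
    out
  })
  block_db(entries, metadata = list(units = "au", version = db_schema_version,
                                    seed = seed, base_iso = base_iso,
                                    anisotropy_frac = anisotropy_frac,
                                    synthetic = TRUE))
}

## Gram-Schmidt frame from three points: axis1 = p1->p2; axis2 the
## orthogonalized in-plane component of p1->p3; axis3 completes right-handed.
frame_rotation <- function(p1, p2, p3) {
  e1 <- unitv(p2 - p1)
  v <- p3 - p1
  w <- v - sum(v * e1) * e1
  if (vnorm(w) < 1e-8 * max(1, vnorm(v)))
    stop("collinear frame atoms: cannot build a local frame")
  e2 <- unitv(w)
  m <- cbind(e1, e2, cross3(e1, e2))
  dimnames(m) <- NULL
  m
}

#' Place a database entry onto a building block
#'
#' Rotates the entry's local dipole and polarizability into the global frame
#' using a Gram-Schmidt frame built from the block's three anchor atoms
#' (axis 1 along atom1 -> atom2, axis 2 perpendicular within the
#' atom1/2/3 plane).  Rotation preserves tensor eigenvalues.
#'
#' @param entry a database entry (element of `block_db$entries`).
#' @param block a building block from [decompose_blocks()].
#' @param frame_atoms optional override of the entry's anchor atom names.
#' @return list with `dipole` (3-vector, e*bohr) and `alpha` (3x3, bohr^3)
#'   in the global frame.
#' @export
place_entry <- function(entry, block, frame_atoms = NULL) {
  fa <- if (is.null(frame_atoms)) entry$frame_atoms else frame_atoms
  nm <- trimws(block$atoms$elety)
  idx <- match(fa, nm)
  if (anyNA(idx))
    stop("block ", block$block_id, " is missing frame atom(s): ",
         paste(fa[is.na(idx)], collapse = ", "))
  xyz <- as.matrix(block$atoms[idx, c("x", "y", "z")])
  r <- frame_rotation(xyz[1L, ], xyz[2L, ], xyz[3L, ])
  list(dipole = as.vector(r %*% entry$dipole_local),
       alpha = sym_part(r %*% entry$polarizability_local %*% t(r)))
}

## fallback anchors for blocks lacking the generic frame atoms (the two
## terminal-residue backbone blocks): first three non-collinear atoms.
fallback_frame_atoms <- function(block) {
  nm <- trimws(block$atoms$elety)
  xyz <- as.matrix(block$atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 3L) stop("block ", block$block_id, " has fewer than 3 atoms")
  for (k in 3:n) {
    v1 <- xyz[2L, ] - xyz[1L, ]
    v2 <- xyz[k, ] - xyz[1L, ]
    if (vnorm(cross3(v1, v2)) > 1e-6)
      return(nm[c(1L, 2L, k)])
  }
  stop("block ", block$block_id, " is collinear; cannot anchor a frame")
}
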