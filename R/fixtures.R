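## Synthetic structure fixtures: ideal-geometry poly-peptides with hydrogens,
## built from internal coordinates (NeRF placement, alpha-helical phi/psi),
## with optional coordinated Na+/Cl- ions and a deterministic water shell.
## Geometry is toy-scale-realistic (bond lengths/angles near canonical
## values; side chains laid out procedurally), not a force-field minimum.

## ideal backbone internal coordinates (angstrom / degrees)
.bb_geo <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5, phi = -57, psi = -47, omega = 180)

## hydrogen offset directions in a local frame, ~1.0 angstrom
.hoff1 <- c(0.33, 0.94, 0.00)
.hoff2 <- c(0.33, -0.47, 0.82)
.hoff3 <- c(0.33, -0.47, -0.82)

## side-chain templates: heavy-atom offsets from CA in the residue's local
## (d, p1, p2) frame, and hydrogens attached to named parents.
.sidechain_templates <- list(
  GLY = list(heavy = list(), hydro = list()),
  ALA = list(
    heavy = list(CB = c(1.2, 0.9, 0.0)),
    hydro = list(HB1 = list("CB", .hoff1), HB2 = list("CB", .hoff2),
                 HB3 = list("CB", .hoff3))),
  SER = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), OG = c(2.4, 1.0, 0.3)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HG = list("OG", .hoff1))),
  CYS = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), SG = c(2.6, 1.1, 0.3)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HG = list("SG", .hoff1))),
  THR = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), OG1 = c(2.3, 1.6, 0.2),
                 CG2 = c(2.0, 0.4, 1.3)),
    hydro = list(HB = list("CB", .hoff3), HG1 = list("OG1", .hoff1),
                 HG21 = list("CG2", .hoff1), HG22 = list("CG2", .hoff2),
                 HG23 = list("CG2", .hoff3))),
  VAL = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG1 = c(2.3, 1.6, 0.2),
                 CG2 = c(2.0, 0.4, 1.3)),
    hydro = list(HB = list("CB", .hoff3),
                 HG11 = list("CG1", .hoff1), HG12 = list("CG1", .hoff2),
                 HG13 = list("CG1", .hoff3), HG21 = list("CG2", .hoff1),
                 HG22 = list("CG2", .hoff2), HG23 = list("CG2", .hoff3))),
  ASP = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 OD1 = c(3.1, 1.8, 0.2), OD2 = c(3.3, -0.3, 0.2)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3))),
  ASN = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 OD1 = c(3.1, 1.8, 0.2), ND2 = c(3.3, -0.3, 0.2)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HD21 = list("ND2", .hoff1), HD22 = list("ND2", .hoff3))),
  GLU = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 CD = c(3.8, 0.9, 0.3), OE1 = c(4.4, 1.9, 0.3),
                 OE2 = c(4.6, -0.1, 0.3)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HG1 = list("CG", .hoff2), HG2 = list("CG", .hoff3))),
  GLN = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 CD = c(3.8, 0.9, 0.3), OE1 = c(4.4, 1.9, 0.3),
                 NE2 = c(4.6, -0.1, 0.3)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HG1 = list("CG", .hoff2), HG2 = list("CG", .hoff3),
                 HE21 = list("NE2", .hoff1), HE22 = list("NE2", .hoff3))),
  LYS = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 CD = c(3.8, 1.0, 0.2), CE = c(5.1, 0.8, 0.3),
                 NZ = c(6.3, 1.1, 0.3)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HG1 = list("CG", .hoff2), HG2 = list("CG", .hoff3),
                 HD1 = list("CD", .hoff2), HD2 = list("CD", .hoff3),
                 HE1 = list("CE", .hoff2), HE2 = list("CE", .hoff3),
                 HZ1 = list("NZ", .hoff1), HZ2 = list("NZ", .hoff2),
                 HZ3 = list("NZ", .hoff3))),
  ARG = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 CD = c(3.8, 1.0, 0.2), NE = c(5.0, 0.8, 0.3),
                 CZ = c(6.3, 1.0, 0.3), NH1 = c(7.0, 1.9, 0.3),
                 NH2 = c(7.0, 0.0, 0.4)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HG1 = list("CG", .hoff2), HG2 = list("CG", .hoff3),
                 HD1 = list("CD", .hoff2), HD2 = list("CD", .hoff3),
                 HE = list("NE", c(0.0, -0.9, 0.44)),
                 HH11 = list("NH1", .hoff1), HH12 = list("NH1", .hoff2),
                 HH21 = list("NH2", c(0.33, -0.94, 0.0)),
                 HH22 = list("NH2", .hoff3))),
  HIS = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 ND1 = c(3.3, 1.7, 0.2), CD2 = c(3.4, -0.4, 0.3),
                 CE1 = c(4.6, 1.4, 0.3), NE2 = c(4.7, 0.1, 0.3)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HD1 = list("ND1", c(0.0, 0.95, -0.31)),
                 HD2 = list("CD2", c(0.1, -0.95, 0.3)),
                 HE1 = list("CE1", c(0.8, 0.6, 0.0)),
                 HE2 = list("NE2", c(0.8, -0.5, 0.33)))),
  TYR = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 CD1 = c(3.2, 1.8, 0.2), CD2 = c(3.3, -0.4, 0.3),
                 CE1 = c(4.5, 1.9, 0.3), CE2 = c(4.6, -0.3, 0.3),
                 CZ = c(5.3, 0.8, 0.3), OH = c(6.7, 0.9, 0.4)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HD1 = list("CD1", c(0.0, 0.98, -0.2)),
                 HD2 = list("CD2", c(0.0, -0.98, 0.2)),
                 HE1 = list("CE1", c(0.0, 0.98, -0.2)),
                 HE2 = list("CE2", c(0.0, -0.98, 0.2)),
                 HH = list("OH", .hoff1))),
  PHE = list(
    heavy = list(CB = c(1.2, 0.9, 0.0), CG = c(2.5, 0.7, 0.2),
                 CD1 = c(3.2, 1.8, 0.2), CD2 = c(3.3, -0.4, 0.3),
                 CE1 = c(4.5, 1.9, 0.3), CE2 = c(4.6, -0.3, 0.3),
                 CZ = c(5.3, 0.8, 0.3)),
    hydro = list(HB1 = list("CB", .hoff2), HB2 = list("CB", .hoff3),
                 HD1 = list("CD1", c(0.0, 0.98, -0.2)),
                 HD2 = list("CD2", c(0.0, -0.98, 0.2)),
                 HE1 = list("CE1", c(0.0, 0.98, -0.2)),
                 HE2 = list("CE2", c(0.0, -0.98, 0.2)),
                 HZ = list("CZ", c(0.9, 0.2, 0.4))))
)

fixture_residues <- function() names(.sidechain_templates)

## NeRF: place atom D given A-B-C, bond r = |CD|, angle theta = D-C-B,
## dihedral chi = D-C-B-A (degrees).
place_atom <- function(a, b, c_, r, theta, chi) {
  theta <- theta * pi / 180
  chi <- chi * pi / 180
  bc <- unitv(c_ - b)
  n <- unitv(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi),
         r * sin(theta) * sin(chi))
  c_ + as.vector(m %*% d)
}

## local side-chain frame at a residue: d points away from the backbone
sidechain_frame <- function(n, ca, c_) {
  d <- unitv(ca - (n + c_) / 2)
  v <- n - c_
  p1 <- unitv(v - sum(v * d) * d)
  p2 <- cross3(d, p1)
  list(d = d, p1 = p1, p2 = p2)
}

frame_point <- function(origin, fr, off) {
  origin + off[1L] * fr$d + off[2L] * fr$p1 + off[3L] * fr$p2
}

element_of_name <- function(name) {
  e2 <- substr(name, 1L, 2L)
  if (e2 %in% c("NA", "CL")) return(e2)
  substr(name, 1L, 1L)
}

pdb_atom_line <- function(type, serial, name, resn, chain, resno, xyz, elem) {
  namef <- if (nchar(name) < 4L) paste0(" ", formatC(name, width = -3)) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, namef, "", resn, chain, resno, "",
          xyz[1L], xyz[2L], xyz[3L], 1.00, 0.00, elem)
}

## build one chain; returns list(atoms = data.frame, anchors = list per
## residue with N/CA/C coordinates and side-chain frame)
build_chain <- function(sequence, chain = "A", origin = c(0, 0, 0)) {
  g <- .bb_geo
  n_res <- length(sequence)
  N <- CA <- C <- vector("list", n_res)
  N[[1L]] <- origin
  CA[[1L]] <- origin + c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[[1L]] <- CA[[1L]] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)[-1L]) {
    N[[i]] <- place_atom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                         g$c_n, g$ang_ca_c_n, g$psi)
    CA[[i]] <- place_atom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                          g$n_ca, g$ang_c_n_ca, g$omega)
    C[[i]] <- place_atom(C[[i - 1L]], N[[i]], CA[[i]],
                         g$ca_c, g$ang_n_ca_c, g$phi)
  }
  rows <- list()
  add <- function(name, resn, resno, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resn = resn, chain = chain, resno = resno,
      x = xyz[1L], y = xyz[2L], z = xyz[3L],
      elem = element_of_name(name), het = FALSE, stringsAsFactors = FALSE)
  }
  frames <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    resn <- sequence[i]
    tpl <- .sidechain_templates[[resn]]
    if (is.null(tpl))
      stop("no fixture template for residue '", resn, "'")
    fr <- sidechain_frame(N[[i]], CA[[i]], C[[i]])
    frames[[i]] <- fr
    add("N", resn, i, N[[i]])
    if (i == 1L) {
      u1 <- unitv(N[[1L]] - CA[[1L]])
      b1 <- unitv(fr$p1 - sum(fr$p1 * u1) * u1)
      b2 <- cross3(u1, b1)
      for (k in 1:3) {
        th <- 2 * pi * k / 3
        dk <- unitv(0.40 * u1 + 0.92 * (cos(th) * b1 + sin(th) * b2))
        add(paste0("H", k), resn, i, N[[1L]] + 1.0 * dk)
      }
    } else {
      hdir <- unitv(unitv(N[[i]] - C[[i - 1L]]) + unitv(N[[i]] - CA[[i]]))
      add("H", resn, i, N[[i]] + 1.0 * hdir)
    }
    add("CA", resn, i, CA[[i]])
    ## HA along the remaining tetrahedral direction
    ha_dir <- -(unitv(N[[i]] - CA[[i]]) + unitv(C[[i]] - CA[[i]]) + fr$d)
    if (resn == "GLY") {
      add("HA1", resn, i, CA[[i]] + 1.09 * unitv(ha_dir))
      add("HA2", resn, i, CA[[i]] + 1.09 * fr$d)
    } else {
      add("HA", resn, i, CA[[i]] + 1.09 * unitv(ha_dir))
    }
    ## side chain
    heavy_pos <- list()
    for (hn in names(tpl$heavy)) {
      p <- frame_point(CA[[i]], fr, tpl$heavy[[hn]])
      heavy_pos[[hn]] <- p
      add(hn, resn, i, p)
    }
    for (hn in names(tpl$hydro)) {
      spec <- tpl$hydro[[hn]]
      parent <- heavy_pos[[spec[[1L]]]]
      add(hn, resn, i, frame_point(parent, fr, spec[[2L]]))
    }
    add("C", resn, i, C[[i]])
    if (i < n_res) {
      o <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                      g$psi + 180)
      add("O", resn, i, o)
    } else {
      add("O", resn, i, place_atom(N[[i]], CA[[i]], C[[i]], 1.25, 117,
                                   g$psi + 180))
      add("OXT", resn, i, place_atom(N[[i]], CA[[i]], C[[i]], 1.25, 117,
                                     g$psi))
    }
  }
  list(atoms = do.call(rbind, rows),
       anchors = list(N = N, CA = CA, C = C, frames = frames))
}

## saltbox default: the glucagon-like ionizable composition (3 ASP, 2 ARG,
## 1 LYS, 1 HIS, 2 TYR plus the termini), with the basic groups near the N
## terminus and the acidic ones near the C terminus so the charge centroids
## separate along the helix
default_fixture_sequence <- function(kind, n_residues) {
  s <- rep("ALA", n_residues)
  if (kind == "saltbox") {
    if (n_residues < 14L)
      stop("saltbox fixtures need at least 14 residues")
    s[c(2L, 4L)] <- "ARG"
    s[3L] <- "HIS"
    s[c(5L, 7L)] <- "TYR"
    s[6L] <- "LYS"
    s[c(n_residues - 5L, n_residues - 3L, n_residues - 1L)] <- "ASP"
  }
  s
}

## ion placed `dist` angstrom beyond `atom` along the direction away from
## `inner` (so it sits outside the group, not inside the helix)
place_ion_beyond <- function(atom_xyz, inner_xyz, dist) {
  atom_xyz + dist * unitv(atom_xyz - inner_xyz)
}

#' Generate a toy peptide PDB fixture
#'
#' Builds an ideal-geometry alpha-helical poly-peptide (phi = -57, psi = -47)
#' with all hydrogens, as PDB text.  `kind = "dimer"` produces two identical
#' chains A and B; `kind = "saltbox"` uses an ionizable sequence (2 ARG +
#' 1 LYS near the N terminus, 3 ASP near the C terminus, ALA elsewhere) and
#' coordinates one Na+ at each carboxylate group (3 ASP + CTER) plus one Cl-
#' at each basic group (LYS, 2 ARG, NTER), at the given distances.  Waters
#' (single O sites) are scattered deterministically in a shell around the
#' peptide.
#'
#' @param kind one of `"helix"`, `"dimer"`, `"saltbox"`.
#' @param n_residues number of residues per chain (>= 2).
#' @param seed integer seed controlling water placement.
#' @param sequence optional character vector of 3-letter residue names
#'   (length `n_residues`) overriding the default sequence.
#' @param n_waters number of water O sites to scatter (default 0).
#' @param na_dist,cl_dist ion placement distances in angstrom from the
#'   carboxylate O / basic-group H (defaults 2.3 and 2.1, inside the 3.5 and
#'   2.5 angstrom binding thresholds).
#' @return PDB-format text (single string).
#' @export
make_fixture <- function(kind = c("helix", "dimer", "saltbox"),
                         n_residues = 10L, seed = 1L, sequence = NULL,
                         n_waters = 0L, na_dist = 2.3, cl_dist = 2.1) {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 2L)
  if (is.null(sequence)) sequence <- default_fixture_sequence(kind, n_residues)
  stopifnot(length(sequence) == n_residues)

  chains <- list(build_chain(sequence, chain = "A"))
  if (kind == "dimer")
    chains[[2L]] <- build_chain(sequence, chain = "B",
                                origin = c(0, 18, 0))
  atoms <- do.call(rbind, lapply(chains, `[[`, "atoms"))

  het <- list()
  add_het <- function(name, resn, xyz) {
    het[[length(het) + 1L]] <<- data.frame(
      name = name, resn = resn, chain = "A",
      resno = 900L + length(het), x = xyz[1L], y = xyz[2L], z = xyz[3L],
      elem = element_of_name(name), het = TRUE, stringsAsFactors = FALSE)
  }
  if (kind == "saltbox") {
    a <- atoms
    grab <- function(resno, name) {
      r <- a[a$resno == resno & a$name == name & !a$het, ]
      c(r$x[1L], r$y[1L], r$z[1L])
    }
    ## Na+ beside each ASP carboxylate and the CTER
    asp_res <- which(sequence == "ASP")
    for (r in asp_res)
      add_het("NA", "NA", place_ion_beyond(grab(r, "OD1"), grab(r, "CG"),
                                           na_dist))
    add_het("NA", "NA", place_ion_beyond(grab(n_residues, "OXT"),
                                         grab(n_residues, "C"), na_dist))
    ## Cl- beside each basic-group hydrogen
    lys_res <- which(sequence == "LYS")
    for (r in lys_res)
      add_het("CL", "CL", place_ion_beyond(grab(r, "HZ1"), grab(r, "NZ"),
                                           cl_dist))
    arg_res <- which(sequence == "ARG")
    for (r in arg_res)
      add_het("CL", "CL", place_ion_beyond(grab(r, "HH11"), grab(r, "NH1"),
                                           cl_dist))
    add_het("CL", "CL", place_ion_beyond(grab(1L, "H1"), grab(1L, "N"),
                                         cl_dist))
  }
  if (n_waters > 0L) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    with_seed(seed, {
      for (w in seq_len(n_waters)) {
        i <- sample.int(nrow(xyz), 1L)
        dir <- unitv(stats::rnorm(3L))
        d <- stats::runif(1L, 2.8, 5.5)
        add_het("O", "HOH", xyz[i, ] + d * dir)
      }
    })
  }

  lines <- character()
  serial <- 0L
  for (ch in chains) {
    ca <- ch$atoms
    for (i in seq_len(nrow(ca))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("ATOM", serial, ca$name[i],
                                      ca$resn[i], ca$chain[i], ca$resno[i],
                                      c(ca$x[i], ca$y[i], ca$z[i]),
                                      ca$elem[i]))
    }
    lines <- c(lines, "TER")
  }
  if (length(het) > 0L) {
    hd <- do.call(rbind, het)
    for (i in seq_len(nrow(hd))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("HETATM", serial, hd$name[i],
                                      hd$resn[i], hd$chain[i], hd$resno[i],
                                      c(hd$x[i], hd$y[i], hd$z[i]),
                                      hd$elem[i]))
    }
  }
  paste(c(lines, "END", ""), collapse = "\n")
}
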