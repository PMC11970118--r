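## Structure model: read protonated PDB structures, decompose residues into
## building blocks (backbone / side chain / terminal groups), locate
## atomic-number-weighted charge centres and classify ionizable groups.

.element_z <- c(H = 1, D = 1, HE = 2, LI = 3, B = 5, C = 6, N = 7, O = 8,
                F = 9, `NA` = 11, MG = 12, P = 15, S = 16, CL = 17, K = 19,
                CA = 20, MN = 25, FE = 26, CO = 27, NI = 28, CU = 29,
                ZN = 30, SE = 34, BR = 35, I = 53)

.standard_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.water_names <- c("HOH", "TIP3", "TIP", "WAT", "SOL")

## side-chain ionizable groups; terminals handled separately
.acidic_sidechains <- c("ASP", "GLU", "CYS", "TYR")
.basic_sidechains  <- c("ARG", "LYS", "HIS")

## PDB atom names forming the generic backbone unit
.backbone_names <- c("N", "H", "HN", "CA", "HA", "HA1", "HA2", "HA3",
                     "C", "O")
.nter_h_names <- c("H", "HN", "H1", "H2", "H3", "HT1", "HT2", "HT3")
.cter_names   <- c("C", "O", "OXT", "OT1", "OT2")

element_from_atom <- function(elety, elesy = NA_character_) {
  sy <- toupper(trimws(elesy))
  if (!is.na(sy) && nzchar(sy) && sy %in% names(.element_z)) return(sy)
  nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(elety)))
  if (nm %in% c("NA", "CL", "MG", "ZN", "FE", "BR", "SE"))
    return(nm)
  e1 <- substr(nm, 1L, 1L)
  if (e1 %in% names(.element_z)) return(e1)
  stop("cannot infer element for atom name '", elety, "'")
}

#' Atomic-number-weighted centre of a building block
#'
#' The point charge of an ionizable group is placed at the block's centre of
#' "mass" with masses replaced by atomic numbers: sum(Z_i r_i) / sum(Z_i).
#'
#' @param block a building block as produced by [decompose_blocks()] (a list
#'   with an `atoms` data frame holding `x`, `y`, `z` and `znum` columns).
#' @return numeric 3-vector, angstrom.
#' @export
charge_centre <- function(block) {
  a <- block$atoms
  stopifnot(nrow(a) >= 1L)
  w <- a$znum
  c(sum(w * a$x), sum(w * a$y), sum(w * a$z)) / sum(w)
}

block_coords <- function(block) {
  as.matrix(block$atoms[, c("x", "y", "z")])
}

#' Decompose protein residues into building blocks
#'
#' Each residue contributes one backbone block (N, H, CA, HA, C, O) and, for
#' all residues except glycine, one side-chain block with the remaining
#' atoms.  The first residue of a chain loses its N and amine hydrogens to a
#' dedicated NTER (-NH3+) block; the last residue loses C, O and OXT to a
#' CTER (-COO-) block.  Every atom lands in exactly one block.
#'
#' @param atoms data frame of protein atoms with columns `elety`, `resid`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `element`, `znum`.
#' @return list of blocks; each block is a list with `block_id`,
#'   `residue_name`, `kind` (one of `"backbone"`, `"sidechain"`, `"NTER"`,
#'   `"CTER"`), `db_key`, `atoms` (data frame) and `charge_centre`.
#' @export
decompose_blocks <- function(atoms) {
  blocks <- list()
  for (ch in unique(atoms$chain)) {
    ca <- atoms[atoms$chain == ch, , drop = FALSE]
    rid <- paste(ca$resno, ca$insert)
    rkeys <- unique(rid)                      # file order within the chain
    first_key <- rkeys[1L]
    last_key <- rkeys[length(rkeys)]
    nter_atoms <- cter_atoms <- NULL
    nter_res <- cter_res <- NULL
    for (rk in rkeys) {
      ra <- ca[rid == rk, , drop = FALSE]
      resname <- ra$resid[1L]
      if (!resname %in% .standard_residues)
        stop("unknown residue name '", resname, "' at ", ch, " ", rk)
      nm <- toupper(trimws(ra$elety))
      take_nter <- rk == first_key & (nm == "N" | nm %in% .nter_h_names)
      take_cter <- rk == last_key & nm %in% .cter_names
      is_bb <- nm %in% .backbone_names & !take_nter & !take_cter
      if (any(take_nter)) {
        nter_atoms <- ra[take_nter, , drop = FALSE]
        nter_res <- resname
      }
      if (any(take_cter)) {
        cter_atoms <- ra[take_cter, , drop = FALSE]
        cter_res <- resname
      }
      bb <- ra[is_bb, , drop = FALSE]
      sc <- ra[!is_bb & !take_nter & !take_cter, , drop = FALSE]
      mk <- function(kind, at, key) {
        list(block_id = sprintf("%s:%s:%s", ch, gsub(" ", "", rk), kind),
             residue_name = resname, kind = kind, chain = ch,
             resno = ra$resno[1L], db_key = key, atoms = at)
      }
      if (nrow(bb) > 0L)
        blocks[[length(blocks) + 1L]] <-
          mk("backbone", bb, paste0(resname, ".backbone"))
      if (nrow(sc) > 0L) {
        if (resname == "GLY")
          stop("unassignable atoms in GLY ", ch, " ", rk, ": ",
               paste(trimws(sc$elety), collapse = ", "))
        blocks[[length(blocks) + 1L]] <-
          mk("sidechain", sc, paste0(resname, ".sidechain"))
      }
      if (rk == first_key && !is.null(nter_atoms)) {
        b <- mk("NTER", nter_atoms, "NTER")
        b$block_id <- sprintf("%s:%s:NTER", ch, gsub(" ", "", rk))
        blocks[[length(blocks) + 1L]] <- b
      }
      if (rk == last_key && !is.null(cter_atoms)) {
        b <- mk("CTER", cter_atoms, "CTER")
        b$block_id <- sprintf("%s:%s:CTER", ch, gsub(" ", "", rk))
        blocks[[length(blocks) + 1L]] <- b
      }
    }
    if (is.null(nter_atoms))
      stop("chain ", ch, ": no N-terminal amine atoms found")
    if (is.null(cter_atoms))
      stop("chain ", ch, ": no C-terminal carboxylate atoms found")
  }
  for (i in seq_along(blocks))
    blocks[[i]]$charge_centre <- charge_centre(blocks[[i]])
  blocks
}

classify_ionizable <- function(blocks) {
  out <- list()
  for (b in blocks) {
    grp <- NULL
    if (b$kind == "sidechain" &&
        b$residue_name %in% c(.acidic_sidechains, .basic_sidechains))
      grp <- b$residue_name
    else if (b$kind %in% c("NTER", "CTER"))
      grp <- b$kind
    if (!is.null(grp))
      out[[length(out) + 1L]] <-
        data.frame(block_id = b$block_id, group = grp,
                   chain = b$chain, resno = b$resno,
                   stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(block_id = character(), group = character(),
                      chain = character(), resno = integer()))
  do.call(rbind, out)
}

## the polar hydrogens each basic group needs for the H...Cl- criterion
.basic_h_patterns <- c(LYS = "^HZ", ARG = "^(HE$|HH)", HIS = "^(HD1|HE2)$",
                       NTER = "^(H[123]?|HT[123]|HN)$")

check_ionizable_hydrogens <- function(blocks, ionizable) {
  idx <- ionizable$group %in% names(.basic_h_patterns)
  bmap <- stats::setNames(seq_along(blocks),
                          vapply(blocks, `[[`, "", "block_id"))
  for (i in which(idx)) {
    b <- blocks[[bmap[[ionizable$block_id[i]]]]]
    pat <- .basic_h_patterns[[ionizable$group[i]]]
    has_h <- b$atoms$element %in% c("H", "D") &
      grepl(pat, trimws(b$atoms$elety))
    if (!any(has_h))
      stop("missing hydrogens on ionizable group ", ionizable$group[i],
           " (", b$chain, " ", b$resno,
           "): protonated input is required for H-Cl distance checks")
  }
  invisible(TRUE)
}

#' Read a protonated protein structure and its environment sites
#'
#' Parses PDB text (or a file path), keeps the highest-occupancy alternate
#' conformer, decomposes the protein into building blocks and collects
#' HETATM Na+, Cl- and water records as environment sites.  Waters are
#' represented by a single site at their oxygen.
#'
#' @param pdb PDB-format text (single string or character vector of lines)
#'   or a path to a PDB file.
#' @return list with components `structure` (class `protein_structure`:
#'   `atoms`, `blocks`, `ionizable_sites`, `sequence`) and `env_sites`
#'   (data frame with `kind` in NA/CL/WATER, `x`, `y`, `z` angstrom,
#'   `charge` in e).
#' @export
read_structure <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  }
  p <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- p$atom
  at$elety <- trimws(at$elety)
  at$resid <- trimws(at$resid)
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  ## keep highest-occupancy altloc per atom slot (ties: first record)
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
    ix[which.max(at$o[ix])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  elem <- mapply(element_from_atom, at$elety, at$elesy, USE.NAMES = FALSE)
  at$element <- elem
  at$znum <- unname(.element_z[elem])
  if (anyNA(at$znum))
    stop("unknown element in PDB input")

  is_ion <- at$type == "HETATM" &
    (at$resid %in% c("NA", "SOD") | at$resid %in% c("CL", "CLA"))
  is_wat <- at$resid %in% .water_names
  is_protein <- !is_ion & !is_wat

  prot <- at[is_protein, , drop = FALSE]
  ## deterministic ordering: chain, then residue file order is preserved
  prot <- prot[order(prot$chain, prot$resno, prot$insert, prot$eleno), ,
               drop = FALSE]
  blocks <- decompose_blocks(prot)
  ionizable <- classify_ionizable(blocks)
  check_ionizable_hydrogens(blocks, ionizable)

  seq_tab <- unique(prot[, c("chain", "resno", "insert", "resid")])

  env <- data.frame(kind = character(), x = numeric(), y = numeric(),
                    z = numeric(), charge = numeric(),
                    stringsAsFactors = FALSE)
  if (any(is_ion)) {
    io <- at[is_ion, , drop = FALSE]
    na_ion <- io$resid %in% c("NA", "SOD") | io$element == "NA"
    env <- rbind(env, data.frame(
      kind = ifelse(na_ion, "NA", "CL"),
      x = io$x, y = io$y, z = io$z,
      charge = ifelse(na_ion, 1, -1), stringsAsFactors = FALSE))
  }
  if (any(is_wat)) {
    wa <- at[is_wat & at$element == "O", , drop = FALSE]
    if (nrow(wa) > 0L)
      env <- rbind(env, data.frame(kind = "WATER", x = wa$x, y = wa$y,
                                   z = wa$z, charge = 0,
                                   stringsAsFactors = FALSE))
  }
  rownames(env) <- NULL

  structure_out <- structure(
    list(atoms = prot, blocks = blocks, ionizable_sites = ionizable,
         sequence = seq_tab),
    class = "protein_structure")
  list(structure = structure_out, env_sites = env)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$sequence), "residues,",
      length(x$blocks), "blocks,", nrow(x$ionizable_sites),
      "ionizable groups\n")
  invisible(x)
}

block_by_id <- function(structure, block_id) {
  ids <- vapply(structure$blocks, `[[`, "", "block_id")
  i <- match(block_id, ids)
  if (is.na(i)) stop("no block with id '", block_id, "'")
  structure$blocks[[i]]
}
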