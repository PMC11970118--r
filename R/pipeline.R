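## Pipeline: orchestrates the full prediction in the fixed order
## (1) pH charges + ion neutralization -> charge dipole, (2) point-charge
## field correction of the core dipoles, (3) ellipsoid water cutoff,
## (4) dipole-interaction-model environment correction, (5) totals.

#' Run configuration
#'
#' @param ph working pH (default 7.3).
#' @param mode `"charged"` (pH charges on ionizable groups) or `"standard"`
#'   (zwitterion reference, no backbone charges).
#' @param thole_b Thole damping parameter (default 2.6).
#' @param damping damping scheme, see [thole_damp()].
#' @param cutoff ellipsoid inflation margin for waters, angstrom
#'   (default 8).
#' @param cl_threshold,na_threshold ion binding thresholds, angstrom
#'   (defaults 2.5 and 3.5).
#' @param na_alpha,cl_alpha,water_alpha isotropic polarizabilities of
#'   environment sites, bohr^3 (defaults 0.3, 30, 9.8).
#' @param include_permanent_dipoles permanent block dipoles act as field
#'   sources in the induction solve (default TRUE).
#' @param include_far_ion_fields unbound ions also contribute to the
#'   stage-2 charge fields (default TRUE); they are polarizable sites in
#'   stage 4 regardless.
#' @param pka_table pKa table override.
#' @return list of class `run_config`.
#' @export
run_config <- function(ph = 7.3, mode = c("charged", "standard"),
                       thole_b = 2.6, damping = "exp", cutoff = 8,
                       cl_threshold = 2.5, na_threshold = 3.5,
                       na_alpha = 0.3, cl_alpha = 30, water_alpha = 9.8,
                       include_permanent_dipoles = TRUE,
                       include_far_ion_fields = TRUE,
                       pka_table = default_pka_table()) {
  mode <- match.arg(mode)
  stopifnot(thole_b > 0, cutoff >= 0, cl_threshold > 0, na_threshold > 0,
            na_alpha >= 0, cl_alpha >= 0, water_alpha >= 0)
  structure(list(ph = ph, mode = mode, thole_b = thole_b,
                 damping = damping, cutoff = cutoff,
                 cl_threshold = cl_threshold, na_threshold = na_threshold,
                 na_alpha = na_alpha, cl_alpha = cl_alpha,
                 water_alpha = water_alpha,
                 include_permanent_dipoles = include_permanent_dipoles,
                 include_far_ion_fields = include_far_ion_fields,
                 pka_table = pka_table),
            class = "run_config")
}

env_alpha_for <- function(kind, config) {
  switch(kind,
         `NA` = config$na_alpha,
         CL = config$cl_alpha,
         WATER = config$water_alpha,
         stop("unknown environment site kind '", kind, "'"))
}

## place every block's database entry; terminal-residue backbone blocks may
## lack the generic (N, CA, C) anchors and fall back to their first three
## non-collinear atoms.
place_all_blocks <- function(blocks, db) {
  lapply(blocks, function(blk) {
    entry <- db$entries[[blk$db_key]]
    if (is.null(entry))
      stop("block database has no entry for key '", blk$db_key, "'")
    nm <- trimws(blk$atoms$elety)
    fa <- if (all(entry$frame_atoms %in% nm)) entry$frame_atoms
          else fallback_frame_atoms(blk)
    place_entry(entry, blk, frame_atoms = fa)
  })
}

#' Predict dipole moment and polarizability of a structure
#'
#' Full prediction: block decomposition and database lookup, pH charges
#' (with ion neutralization) and the charge dipole, point-charge field
#' correction of the core dipoles, ellipsoid water cutoff, and the damped
#' dipole-interaction-model correction over protein blocks plus environment
#' sites (intra-protein pairs excluded).  The reported total dipole is
#' mu_charge + mu_core (exact additivity); the reported polarizability sums
#' the corrected tensors of the protein blocks and any bound ions.
#'
#' @param pdb PDB text/path, or the list returned by [read_structure()].
#' @param db a `block_db`.
#' @param config a [run_config()].
#' @return a `property_report` (see [property_report()]).
#' @export
run_prediction <- function(pdb, db, config = run_config()) {
  parsed <- if (is.list(pdb) && !is.null(pdb$structure)) pdb
            else read_structure(pdb)
  structure_ <- parsed$structure
  env <- parsed$env_sites
  blocks <- structure_$blocks
  placed <- place_all_blocks(blocks, db)
  centres_ang <- t(vapply(blocks, `[[`, numeric(3L), "charge_centre"))
  centres <- ang2bohr(centres_ang)
  mu0 <- t(vapply(placed, `[[`, numeric(3L), "dipole"))
  alphas <- lapply(placed, `[[`, "alpha")

  ## stage 1: charges and neutralization
  charges <- assign_charges(structure_, pka_table = config$pka_table,
                            ph = config$ph, mode = config$mode)
  bindings <- detect_bound_ions(structure_, env,
                                cl_threshold = config$cl_threshold,
                                na_threshold = config$na_threshold)
  charges <- neutralize(charges, bindings)
  active <- charges[!charges$neutralized, , drop = FALSE]
  ## Q+*R is origin independent even when terminal neutralization leaves
  ## the applied charges slightly unbalanced; the physical system
  ## (zwitterion reference + ion pairs) is neutral, so no warning here.
  mu_charge <- charge_dipole(active$q,
                             ang2bohr(as.matrix(active[, c("x", "y", "z")])),
                             neutrality_tol = Inf)

  ## stage 2: core-dipole field correction; sources are ALL residue charges
  ## (neutralized included) plus ion charges
  src_q <- charges$q
  src_pos <- ang2bohr(as.matrix(charges[, c("x", "y", "z")]))
  src_block <- charges$block_id
  ions <- env[env$kind %in% c("NA", "CL"), , drop = FALSE]
  if (nrow(ions) > 0L) {
    ion_rows <- as.integer(rownames(env))[env$kind %in% c("NA", "CL")]
    ion_rows <- which(env$kind %in% c("NA", "CL"))
    use_ion <- if (config$include_far_ion_fields) rep(TRUE, nrow(ions))
               else ion_rows %in% bindings$ion
    if (any(use_ion)) {
      src_q <- c(src_q, ions$charge[use_ion])
      src_pos <- rbind(src_pos,
                       ang2bohr(as.matrix(ions[use_ion, c("x", "y", "z")])))
      src_block <- c(src_block, rep(NA_character_, sum(use_ion)))
    }
  }
  fields <- matrix(0, length(blocks), 3L)
  if (length(src_q) > 0L) {
    block_ids <- vapply(blocks, `[[`, "", "block_id")
    for (i in seq_along(blocks)) {
      sel <- is.na(src_block) | src_block != block_ids[i]   # not own charge
      if (any(sel))
        fields[i, ] <- field_from_charges(centres[i, ], src_q[sel],
                                          src_pos[sel, , drop = FALSE])
    }
  }
  mu_corrected <- correct_core_dipoles(mu0, alphas, fields)

  ## stage 3: ellipsoid cutoff on waters (ions all kept)
  env_kept <- ellipsoid_cutoff(structure_, env, cutoff = config$cutoff)

  ## stage 4: dipole interaction model over blocks + environment sites
  n_b <- length(blocks)
  n_e <- nrow(env_kept)
  pos_all <- rbind(centres,
                   ang2bohr(as.matrix(env_kept[, c("x", "y", "z")])))
  alphas_all <- c(alphas,
                  lapply(seq_len(n_e), function(i)
                    diag(3) * env_alpha_for(env_kept$kind[i], config)))
  mu0_all <- rbind(mu_corrected, matrix(0, n_e, 3L))
  env_ids <- sprintf("env%d", seq_len(n_e))
  mol_id <- c(rep("protein", n_b), env_ids)
  sys <- polarizable_system(pos_all, alphas_all, mu0 = mu0_all,
                            molecule_id = mol_id,
                            site_id = c(vapply(blocks, `[[`, "", "block_id"),
                                        env_ids))
  adim <- run_adim(sys, b = config$thole_b, damping = config$damping,
                   include_permanent_dipoles =
                     config$include_permanent_dipoles)
  corr <- adim$corrected

  ## stage 5: totals. Dipole: protein blocks only; polarizability: protein
  ## blocks + bound ions (the coordinated compound).
  mu_blocks <- (mu0_all + adim$induced)[seq_len(n_b), , drop = FALSE]
  mu_core <- colSums(mu_blocks)
  alpha_sel <- corr$per_site[seq_len(n_b)]
  if (n_e > 0L && nrow(bindings) > 0L) {
    kept_ion_pos <- as.matrix(env_kept[, c("x", "y", "z")])
    for (bi in seq_len(nrow(bindings))) {
      orig <- bindings$ion[bi]
      hit <- which(env_kept$kind == env$kind[orig] &
                   abs(env_kept$x - env$x[orig]) < 1e-9 &
                   abs(env_kept$y - env$y[orig]) < 1e-9 &
                   abs(env_kept$z - env$z[orig]) < 1e-9)
      if (length(hit) == 1L)
        alpha_sel <- c(alpha_sel, corr$per_site[n_b + hit])
    }
  }
  alpha_total <- sym_part(Reduce(`+`, alpha_sel))

  per_block <- data.frame(
    block_id = vapply(blocks, `[[`, "", "block_id"),
    residue = vapply(blocks, `[[`, "", "residue_name"),
    kind = vapply(blocks, `[[`, "", "kind"),
    mu_x = mu_blocks[, 1L], mu_y = mu_blocks[, 2L], mu_z = mu_blocks[, 3L],
    alpha_iso = vapply(corr$per_site[seq_len(n_b)],
                       function(a) sum(diag(a)) / 3, 0),
    stringsAsFactors = FALSE)

  property_report(mu_charge = mu_charge, mu_core = mu_core,
                  alpha_total = alpha_total, per_block = per_block,
                  config = config,
                  counts = list(blocks = n_b,
                                charges = nrow(charges),
                                bound_ions = nrow(bindings),
                                env_sites = n_e))
}

#' Sweep the 70 NaCl ion-pair configurations
#'
#' The input structure must carry all eight coordinated ions (4 Na+ bound to
#' the ASP/CTER sites, 4 Cl- bound to the LYS/ARG/NTER sites).  Sites are
#' lettered in residue order: negative sites A-D (ASP by residue number,
#' then CTER), positive sites X, Y, Z, W (LYS, then ARG, then NTER).  Each
#' configuration keeps only its subset of ions and reruns the prediction;
#' waters are always retained.
#'
#' @param pdb PDB text/path or parsed structure with the 8 placed ions.
#' @param db a `block_db`.
#' @param config a [run_config()].
#' @return data frame with one row per configuration: `number`, `name`,
#'   `n_pairs`, `mu_x`, `mu_y`, `mu_z`, `mu_abs`, `alpha_iso`,
#'   `alpha_aniso`, `a11`, `a22`, `a33` (ascending eigenvalues).
#' @export
sweep_configurations <- function(pdb, db, config = run_config()) {
  parsed <- if (is.list(pdb) && !is.null(pdb$structure)) pdb
            else read_structure(pdb)
  structure_ <- parsed$structure
  env <- parsed$env_sites
  bindings <- detect_bound_ions(structure_, env,
                                cl_threshold = config$cl_threshold,
                                na_threshold = config$na_threshold)
  site_letter <- assign_site_letters(structure_, bindings)
  ion_letter <- rep(NA_character_, nrow(env))
  ion_letter[bindings$ion] <- site_letter[bindings$block_id]
  if (sum(ion_letter %in% .na_letters) != 4L ||
      sum(ion_letter %in% .cl_letters) != 4L)
    stop("sweep input must have all 8 ions bound ",
         "(4 Na+ at A-D, 4 Cl- at X/Y/Z/W); found ",
         sum(!is.na(ion_letter)))
  configs <- enumerate_configurations()
  rows <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    want <- c(strsplit(configs$na_sites[i], "")[[1L]],
              strsplit(configs$cl_sites[i], "")[[1L]])
    keep <- env$kind == "WATER" |
      (!is.na(ion_letter) & ion_letter %in% want)
    sub_env <- env[keep, , drop = FALSE]
    rownames(sub_env) <- NULL
    rep_i <- run_prediction(list(structure = structure_,
                                 env_sites = sub_env), db, config)
    ev <- sort(eigen(rep_i$alpha_total, symmetric = TRUE,
                     only.values = TRUE)$values)
    rows[[i]] <- data.frame(
      number = configs$number[i], name = configs$name[i],
      n_pairs = configs$n_pairs[i],
      mu_x = rep_i$mu_total[1L], mu_y = rep_i$mu_total[2L],
      mu_z = rep_i$mu_total[3L], mu_abs = vnorm(rep_i$mu_total),
      alpha_iso = rep_i$alpha_iso, alpha_aniso = rep_i$alpha_aniso,
      a11 = ev[1L], a22 = ev[2L], a33 = ev[3L],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## letter the 8 canonical sites in residue order
assign_site_letters <- function(structure_, bindings) {
  ion <- structure_$ionizable_sites
  neg <- ion[ion$group %in% c("ASP", "GLU"), , drop = FALSE]
  neg <- neg[order(neg$chain, neg$resno), , drop = FALSE]
  neg_ids <- c(neg$block_id, ion$block_id[ion$group == "CTER"])
  pos_ids <- c(ion$block_id[ion$group == "LYS"][
                 order(ion$resno[ion$group == "LYS"])],
               ion$block_id[ion$group == "ARG"][
                 order(ion$resno[ion$group == "ARG"])],
               ion$block_id[ion$group == "NTER"])
  letters_ <- c(stats::setNames(.na_letters[seq_along(neg_ids)], neg_ids),
                stats::setNames(.cl_letters[seq_along(pos_ids)], pos_ids))
  letters_
}
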