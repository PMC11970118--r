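## Henderson-Hasselbalch protonation: fractional charges at a given pH,
## terminal-group compensating charges relative to the zwitterion reference,
## net charge and isoelectric-point solver.

## chemical class of each ionizable group (true titration behaviour)
.group_class <- c(ASP = "acidic", GLU = "acidic", CYS = "acidic",
                  TYR = "acidic", CTER = "acidic",
                  ARG = "basic", LYS = "basic", HIS = "basic",
                  NTER = "basic")

#' Default pKa table for ionizable groups
#'
#' Built-in values: GLU/ASP 4.4, CYS 8.5, TYR 10.1 (acidic); ARG 12.5,
#' LYS 10.6, HIS 6.6 (basic); CTER 4.0 and NTER 8.0.  The `table_sign`
#' column records the bookkeeping sign convention for the terminal groups
#' (CTER "+", NTER "-"): database entries are built for the zwitterion, so
#' terminal charges enter as compensations relative to +1/-1, giving them a
#' counter-intuitive sign.  The `class` column keeps the true chemical
#' behaviour used for titration and the isoelectric point.
#'
#' @return data frame with columns `group`, `class`, `pka`, `table_sign`.
#' @export
default_pka_table <- function() {
  data.frame(
    group = c("GLU", "ASP", "CYS", "TYR", "ARG", "LYS", "HIS",
              "CTER", "NTER"),
    class = c("acidic", "acidic", "acidic", "acidic", "basic", "basic",
              "basic", "acidic", "basic"),
    pka = c(4.4, 4.4, 8.5, 10.1, 12.5, 10.6, 6.6, 4.0, 8.0),
    table_sign = c("-", "-", "-", "-", "+", "+", "+", "+", "-"),
    stringsAsFactors = FALSE)
}

pka_of <- function(group, pka_table) {
  i <- match(group, pka_table$group)
  if (is.na(i)) stop("unknown ionizable group '", group, "'")
  pka_table$pka[i]
}

#' Henderson-Hasselbalch fractional charge
#'
#' Ionized fraction of a titratable group: acidic groups carry
#' q = -1 / (1 + 10^(pKa - pH)), basic groups q = +1 / (1 + 10^(pH - pKa)).
#' At pH = pKa the magnitude is exactly 0.5.
#'
#' @param group ionizable group name (ASP, GLU, CYS, TYR, ARG, LYS, HIS,
#'   CTER, NTER).
#' @param pka pKa value; if missing, taken from `pka_table`.
#' @param ph solution pH.
#' @param pka_table pKa table (see [default_pka_table()]).
#' @return signed fractional charge in (-1, 0) or (0, 1), units of e.
#' @export
henderson_charge <- function(group, pka = NULL, ph,
                             pka_table = default_pka_table()) {
  cls <- unname(.group_class[group])
  if (is.na(cls)) stop("unknown ionizable group '", group, "'")
  if (is.null(pka)) pka <- pka_of(group, pka_table)
  stopifnot(is.finite(pka), is.finite(ph))
  if (cls == "acidic") -1 / (1 + 10^(pka - ph)) else 1 / (1 + 10^(ph - pka))
}

#' Compensating charge for a terminal group
#'
#' Database entries assume the zwitterion (-NH3+ / -COO-), so terminal
#' charges are applied as compensations relative to that reference:
#' q_applied = q_effective - q_zwitterion with q_zwitterion = +1 for NTER
#' and -1 for CTER.  An NTER with effective charge +0.6 therefore receives
#' an applied charge of -0.4.
#'
#' @param group `"NTER"` or `"CTER"`.
#' @param q_effective the Henderson-Hasselbalch charge of the terminal at
#'   the working pH (chemical sign convention).
#' @return applied (compensating) charge, e.
#' @export
terminal_compensation <- function(group, q_effective) {
  if (!group %in% c("NTER", "CTER"))
    stop("terminal_compensation applies only to NTER/CTER, got '",
         group, "'")
  q_zwit <- if (group == "NTER") 1 else -1
  q_effective - q_zwit
}

#' Assign point charges to ionizable groups
#'
#' One charge site per ionizable group, placed at the group's block charge
#' centre (atomic-number-weighted).  Terminal groups use the compensation
#' rule of [terminal_compensation()].  In `"standard"` mode (the zwitterion
#' reference with no ions) no charges are added at all.
#'
#' @param structure a `protein_structure` from [read_structure()].
#' @param pka_table pKa table.
#' @param ph working pH (default 7.3).
#' @param mode `"charged"` or `"standard"`.
#' @return data frame of charge sites: `block_id`, `group`, `x`, `y`, `z`
#'   (angstrom), `q` (e), `neutralized` (logical).
#' @export
assign_charges <- function(structure, pka_table = default_pka_table(),
                           ph = 7.3, mode = c("charged", "standard")) {
  mode <- match.arg(mode)
  empty <- data.frame(block_id = character(), group = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      q = numeric(), neutralized = logical(),
                      stringsAsFactors = FALSE)
  if (mode == "standard") return(empty)
  ion <- structure$ionizable_sites
  if (nrow(ion) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(ion)), function(i) {
    grp <- ion$group[i]
    q_eff <- henderson_charge(grp, ph = ph, pka_table = pka_table)
    q <- if (grp %in% c("NTER", "CTER")) terminal_compensation(grp, q_eff)
         else q_eff
    cc <- block_by_id(structure, ion$block_id[i])$charge_centre
    data.frame(block_id = ion$block_id[i], group = grp,
               x = cc[1L], y = cc[2L], z = cc[3L], q = q,
               neutralized = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Net Henderson-Hasselbalch charge of a composition
#'
#' Sums the fractional charges of a multiset of ionizable groups using true
#' chemical signs (terminals included as ordinary acidic/basic groups, not
#' the zwitterion-compensation bookkeeping).
#'
#' @param ph solution pH.
#' @param composition character vector of group names, one element per
#'   group instance (repeats allowed).
#' @param pka_table pKa table.
#' @return total charge, e.
#' @export
net_charge <- function(ph, composition, pka_table = default_pka_table()) {
  if (length(composition) == 0L) return(0)
  sum(vapply(composition, henderson_charge, 0, ph = ph,
             pka_table = pka_table, pka = NULL))
}

#' Isoelectric point by bisection
#'
#' Solves net_charge(pH) = 0 on [0, 14].  The net charge is strictly
#' decreasing in pH, so the root is unique.
#'
#' @param composition character vector of ionizable group names (needs at
#'   least one acidic and one basic group for a sign change).
#' @param pka_table pKa table.
#' @param tol bisection tolerance on |net charge| (default 1e-9).
#' @return the isoelectric pH.
#' @export
isoelectric_point <- function(composition,
                              pka_table = default_pka_table(),
                              tol = 1e-9) {
  lo <- 0; hi <- 14
  f_lo <- net_charge(lo, composition, pka_table)
  f_hi <- net_charge(hi, composition, pka_table)
  if (f_lo < 0 || f_hi > 0)
    stop("net charge does not change sign on [0, 14]; ",
         "composition needs both acidic and basic groups")
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    f_mid <- net_charge(mid, composition, pka_table)
    if (abs(f_mid) < tol) return(mid)
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Ionizable composition of a structure
#'
#' Convenience accessor: the multiset of ionizable group names (including
#' NTER/CTER) of a parsed structure, as used by [net_charge()] and
#' [isoelectric_point()].
#'
#' @param structure a `protein_structure`.
#' @return character vector of group names.
#' @export
ionizable_composition <- function(structure) {
  structure$ionizable_sites$group
}
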