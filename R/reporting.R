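## Reporting: scalar summaries (isotropic polarizability, anisotropy,
## dipole deviations), the property-report container and its JSON/TSV
## serialization.

#' Isotropic polarizability
#'
#' alpha_iso = Tr(alpha) / 3; invariant under rotation.
#'
#' @param alpha 3x3 symmetric tensor, bohr^3.
#' @return scalar, bohr^3.
#' @export
isotropic_polarizability <- function(alpha) {
  stopifnot(is.matrix(alpha), all(dim(alpha) == c(3L, 3L)))
  sum(diag(alpha)) / 3
}

#' Polarizability anisotropy
#'
#' The first anisotropy invariant over the eigenvalues a1, a2, a3:
#' sqrt(((a1-a2)^2 + (a2-a3)^2 + (a3-a1)^2) / 2).  Zero iff the tensor is
#' isotropic; invariant under rotation.
#'
#' @param alpha 3x3 symmetric tensor, bohr^3.
#' @return scalar, bohr^3.
#' @export
polarizability_anisotropy <- function(alpha) {
  stopifnot(is.matrix(alpha), all(dim(alpha) == c(3L, 3L)))
  ev <- eigen(sym_part(alpha), symmetric = TRUE, only.values = TRUE)$values
  sqrt(((ev[1L] - ev[2L])^2 + (ev[2L] - ev[3L])^2 +
        (ev[3L] - ev[1L])^2) / 2)
}

#' Magnitude and angular deviation between two dipole vectors
#'
#' @param mu_a,mu_b nonzero 3-vectors (the second is the reference for the
#'   percent magnitude deviation).
#' @return named numeric: `percent_magnitude` = 100 * ||a|-|b|| / |b| and
#'   `angle_degrees` in [0, 180].
#' @export
dipole_deviation <- function(mu_a, mu_b) {
  na <- vnorm(mu_a); nb <- vnorm(mu_b)
  if (na == 0 || nb == 0)
    stop("dipole_deviation is undefined for zero vectors")
  cosang <- max(-1, min(1, sum(mu_a * mu_b) / (na * nb)))
  c(percent_magnitude = 100 * abs(na - nb) / nb,
    angle_degrees = acos(cosang) * 180 / pi)
}

#' Construct a property report
#'
#' The total dipole is the exact sum of the charge and core components.
#'
#' @param mu_charge,mu_core dipole components, e*bohr.
#' @param alpha_total 3x3 polarizability tensor, bohr^3.
#' @param per_block data frame of per-block corrected properties.
#' @param config the `run_config` used (echoed as provenance).
#' @param counts named list of stage counts (blocks, charges, bound ions,
#'   environment sites).
#' @return object of class `property_report` with fields `mu_charge`,
#'   `mu_core`, `mu_total`, `alpha_total`, `alpha_iso`, `alpha_aniso`,
#'   `alpha_eigen` (ascending), `per_block`, `provenance`.
#' @export
property_report <- function(mu_charge, mu_core, alpha_total,
                            per_block = NULL, config = NULL,
                            counts = NULL) {
  mu_total <- mu_charge + mu_core
  ev <- sort(eigen(sym_part(alpha_total), symmetric = TRUE,
                   only.values = TRUE)$values)
  prov <- list(package_version = as.character(utils::packageVersion("blockpol")),
               counts = counts)
  if (!is.null(config))
    prov$config <- config[setdiff(names(config), "pka_table")]
  structure(list(mu_charge = mu_charge, mu_core = mu_core,
                 mu_total = mu_total, alpha_total = alpha_total,
                 alpha_iso = isotropic_polarizability(alpha_total),
                 alpha_aniso = polarizability_anisotropy(alpha_total),
                 alpha_eigen = ev, per_block = per_block,
                 provenance = prov),
            class = "property_report")
}

#' @export
print.property_report <- function(x, digits = 4, ...) {
  fmt <- function(v) paste(format(round(v, digits), trim = TRUE),
                           collapse = ", ")
  cat("property_report (atomic units)\n")
  cat("  mu_charge: (", fmt(x$mu_charge), ")  |mu_charge| =",
      format(round(vnorm(x$mu_charge), digits)), "\n")
  cat("  mu_core:   (", fmt(x$mu_core), ")  |mu_core|  =",
      format(round(vnorm(x$mu_core), digits)), "\n")
  cat("  mu_total:  (", fmt(x$mu_total), ")  |mu_total| =",
      format(round(vnorm(x$mu_total), digits)), "\n")
  cat("  alpha_iso =", format(round(x$alpha_iso, digits)),
      "  alpha_aniso =", format(round(x$alpha_aniso, digits)), "\n")
  cat("  alpha eigenvalues:", fmt(x$alpha_eigen), "\n")
  invisible(x)
}

#' Write a property report as JSON
#'
#' @param report a `property_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  ser <- list(
    schema_version = "1",
    mu_charge = report$mu_charge, mu_core = report$mu_core,
    mu_total = report$mu_total,
    mu_abs = vnorm(report$mu_total),
    alpha_total = unname(apply(report$alpha_total, 1L, as.list,
                               simplify = FALSE)),
    alpha_iso = report$alpha_iso, alpha_aniso = report$alpha_aniso,
    alpha_eigen = report$alpha_eigen,
    per_block = report$per_block,
    provenance = report$provenance)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a configuration sweep as TSV
#'
#' @param sweep data frame from [sweep_configurations()].
#' @param path output path.
#' @export
write_sweep_tsv <- function(sweep, path) {
  utils::write.table(sweep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
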