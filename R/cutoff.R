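#' Assign charge groups to a configuration
#'
#' One charge group per molecule, the convention for water (each SPC/E
#' molecule is a neutral group). The group reference point is the
#' geometric centre of the member atoms.
#'
#' @param config An `md_config`.
#' @return The configuration with `group_id` set to the molecule map, plus
#'   an attribute `group_charge` with the per-group net charges.
#' @export
assign_charge_groups <- function(config) {
  if (any(config$mol_id <= 0)) stop("every atom must belong to a molecule")
  config$group_id <- config$mol_id
  attr(config, "group_charge") <- as.numeric(tapply(config$charge, config$group_id, sum))
  config
}

#' Geometric centres of the charge groups
#'
#' Minimum-image-aware geometric centre of each group's member atoms (so
#' molecules wrapped across the periodic boundary are handled correctly).
#'
#' @param config An `md_config`.
#' @return An n_groups x 3 matrix of reference points (nm).
#' @export
group_centres <- function(config) {
  cpp_group_centres(config$positions, config$box, config$group_id)
}

#' Build an interaction pair list under an atom- or group-based cut-off
#'
#' Atom-based: every pair of atoms in different groups whose minimum-image
#' distance is within `r_c` (closed ball). Group-based: every atom pair of
#' every pair of groups whose geometric-centre distance is within `r_c` --
#' all-or-nothing per group pair, so no partial dipoles are cut. Intra-group
#' pairs are never listed. The list is ordered lexicographically, and the
#' linked-cell and brute-force paths return identical lists.
#'
#' @param config An `md_config`.
#' @param r_c List cut-off radius (nm); at most half the minimum box edge.
#' @param scheme `"atom"` or `"group"`.
#' @param method `"cell"` (linked cells, falling back to the double loop
#'   when the box holds fewer than 3 cells per edge) or `"brute"`.
#' @return An object of class `pairlist_ips`: a list with `pairs` (n x 2
#'   integer matrix, 1-based atom indices), `scheme`, `r_c`, `minimum_image`.
#' @export
build_pairlist <- function(config, r_c, scheme = c("group", "atom"),
                           method = c("cell", "brute")) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  if (r_c > min(config$box) / 2 + 1e-12)
    stop(sprintf("r_c = %g nm exceeds half the minimum box edge (%g nm): minimum image ambiguous",
                 r_c, min(config$box) / 2))
  pairs <- cpp_pairlist(config$positions, config$box, config$group_id, r_c,
                        if (scheme == "atom") 0L else 1L, method == "cell")
  structure(list(pairs = pairs, scheme = scheme, r_c = r_c,
                 minimum_image = TRUE),
            class = "pairlist_ips")
}

#' @export
print.pairlist_ips <- function(x, ...) {
  cat(sprintf("pairlist: %d atom pairs, %s-based cut-off at %g nm\n",
              nrow(x$pairs), x$scheme, x$r_c))
  invisible(x)
}

#' Truncated non-bonded energy and forces from a tabulated potential
#'
#' Sums the tabulated electrostatic and LJ interactions over the listed
#' pairs at their minimum-image distances. Energies and forces come from
#' cubic Hermite interpolation of the table's value and derivative
#' columns, so the forces are the exact negative gradient of the
#' interpolated energy. Interaction columns are clamped to exactly zero
#' beyond their cut-off radii (`r_c` for electrostatics, `r_c_lj` for LJ),
#' independent of the list radius.
#'
#' @param config An `md_config`.
#' @param pairlist A [build_pairlist()] result.
#' @param table A `pair_table`.
#' @return A list with `e_elec`, `e_lj` (kJ/mol) and `forces` (N x 3,
#'   kJ/mol/nm).
#' @export
nonbonded_energy_forces <- function(config, pairlist, table) {
  stopifnot(inherits(pairlist, "pairlist_ips"), inherits(table, "pair_table"))
  cpp_nonbonded(config$positions, config$box, pairlist$pairs, config$charge,
                config$c6, config$c12, as_kernel_table(table), .coul)
}
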