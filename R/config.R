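#' Construct an MD configuration
#'
#' The shared container for a periodic simulation snapshot: an orthorhombic
#' box, per-atom positions (and optionally velocities), and the molecule
#' and charge-group index maps plus per-atom parameters.
#'
#' @param box Numeric length-3 box edges (nm).
#' @param positions N x 3 matrix of positions (nm).
#' @param velocities Optional N x 3 matrix (nm/ps).
#' @param mol_id Integer vector: molecule index per atom (1-based).
#' @param group_id Integer vector: charge-group index per atom; defaults to
#'   `mol_id` (one group per molecule).
#' @param atom_name Character vector of atom names (e.g. "OW", "HW1").
#' @param mass,charge Per-atom masses (u) and charges (e).
#' @param c6,c12 Per-atom LJ coefficients; pair values are combined
#'   geometrically, so a single-site model stores \eqn{4\epsilon\sigma^6}
#'   and \eqn{4\epsilon\sigma^{12}} on the LJ-carrying atom and 0 elsewhere.
#' @return An object of class `md_config`.
#' @export
md_config <- function(box, positions, velocities = NULL, mol_id, group_id = mol_id,
                      atom_name = NULL, mass, charge, c6 = NULL, c12 = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(length(box) == 3, ncol(positions) == 3,
            length(mol_id) == n, length(group_id) == n,
            length(mass) == n, length(charge) == n)
  if (is.null(c6)) c6 <- numeric(n)
  if (is.null(c12)) c12 <- numeric(n)
  if (is.null(atom_name)) atom_name <- rep("X", n)
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(nrow(velocities) == n, ncol(velocities) == 3)
  }
  structure(list(box = as.numeric(box), positions = positions,
                 velocities = velocities, mol_id = as.integer(mol_id),
                 group_id = as.integer(group_id), atom_name = atom_name,
                 mass = as.numeric(mass), charge = as.numeric(charge),
                 c6 = as.numeric(c6), c12 = as.numeric(c12)),
            class = "md_config")
}

#' @export
print.md_config <- function(x, ...) {
  cat(sprintf("md_config: %d atoms, %d molecules, box %.4f x %.4f x %.4f nm\n",
              nrow(x$positions), max(x$mol_id), x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  net charge %.3g e, velocities: %s\n", sum(x$charge),
              ifelse(is.null(x$velocities), "absent", "present")))
  invisible(x)
}

#' Number of atoms / molecules in a configuration
#' @param config An `md_config`.
#' @return Integer count.
#' @export
n_atoms <- function(config) nrow(config$positions)

#' @rdname n_atoms
#' @export
n_molecules <- function(config) max(config$mol_id)

#' Build an all-water configuration from oxygen sites and rotations
#'
#' Internal workhorse shared by the system builders: expands one rigid
#' SPC/E molecule per oxygen site.
#' @noRd
waters_from_sites <- function(sites, rotations, box, model = water_model()) {
  n <- nrow(sites)
  pos <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    pos[(3 * i - 2):(3 * i), ] <- water_geometry(model, sites[i, ], rotations[[i]])
  }
  md_config(
    box = box, positions = pos,
    mol_id = rep(seq_len(n), each = 3),
    atom_name = rep(c("OW", "HW1", "HW2"), n),
    mass = rep(c(model$mass_O, model$mass_H, model$mass_H), n),
    charge = rep(c(model$q_O, model$q_H, model$q_H), n),
    c6 = rep(c(model$c6, 0, 0), n),
    c12 = rep(c(model$c12, 0, 0), n)
  )
}

# uniformly random rotation matrix from a unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Initial velocities at a target temperature with the centre-of-mass
#' motion removed, followed by a RATTLE projection so that rigid-molecule
#' constraints are satisfied, and a rescale to the exact target kinetic
#' temperature for the constrained degree-of-freedom count.
#'
#' @param config An `md_config`.
#' @param temperature Target temperature (K).
#' @param seed Integer seed (recorded; the draw is deterministic given it).
#' @return The configuration with a `velocities` field set.
#' @export
init_velocities <- function(config, temperature, seed) {
  set.seed(seed)
  n <- n_atoms(config)
  sd <- sqrt(.kB * temperature / config$mass)
  vel <- matrix(stats::rnorm(3 * n), n, 3) * sd
  # remove centre-of-mass momentum
  p <- colSums(vel * config$mass)
  vel <- sweep(vel, 2, p / sum(config$mass))
  # project out constraint-violating components
  cons <- water_constraints(config)
  if (nrow(cons$index) > 0) {
    res <- cpp_rattle(config$positions, vel, cons$index, cons$d0,
                      1 / config$mass, config$box, 1e-12, 500)
    vel <- res$velocities
  }
  ndof <- count_dof(config)
  ke <- 0.5 * sum(config$mass * rowSums(vel^2))
  t_now <- 2 * ke / (ndof * .kB)
  vel <- vel * sqrt(temperature / t_now)
  config$velocities <- vel
  attr(config, "velocity_seed") <- seed
  config
}

#' Rigid-water constraint list of a configuration
#'
#' Three distance constraints (O-H, O-H, H-H) for every 3-atom molecule;
#' molecules with any other size contribute none.
#'
#' @param config An `md_config`.
#' @param model Water geometry source.
#' @return A list with `index` (n x 2 integer matrix of atom indices) and
#'   `d0` (target distances, nm).
#' @export
water_constraints <- function(config, model = water_model()) {
  idx <- NULL
  d0 <- NULL
  mols <- split(seq_len(n_atoms(config)), config$mol_id)
  for (at in mols) {
    if (length(at) != 3) next
    idx <- rbind(idx, c(at[1], at[2]), c(at[1], at[3]), c(at[2], at[3]))
    d0 <- c(d0, model$d_OH, model$d_OH, model$d_HH)
  }
  if (is.null(idx)) idx <- matrix(integer(0), 0, 2)
  list(index = idx, d0 = as.numeric(d0))
}

#' Count the independent degrees of freedom of a configuration
#'
#' \eqn{3N - N_{constraints} - 3}: three per atom, minus one per rigid
#' distance constraint, minus three for the removed centre-of-mass motion.
#' For a pure rigid-water system this is \eqn{6 N_{mol} - 3}.
#'
#' @param config An `md_config`.
#' @return Integer degree-of-freedom count.
#' @export
count_dof <- function(config) {
  cons <- water_constraints(config)
  3 * n_atoms(config) - nrow(cons$index) - 3
}

#' Instantaneous kinetic temperature
#' @param config An `md_config` with velocities.
#' @return Temperature in K for the constrained degree-of-freedom count.
#' @export
kinetic_temperature <- function(config) {
  stopifnot(!is.null(config$velocities))
  ke <- 0.5 * sum(config$mass * rowSums(config$velocities^2))
  2 * ke / (count_dof(config) * .kB)
}

#' Mass density of a configuration
#' @param config An `md_config`.
#' @return Density in g/cm^3.
#' @export
mass_density <- function(config) {
  sum(config$mass) * .mass_conv / prod(config$box)
}
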