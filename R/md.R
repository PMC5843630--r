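#' Force-field specifications for the MD engine
#'
#' `table_forces()` runs the dynamics on a tabulated pair potential under
#' an atom- or group-based cut-off; the pair list is rebuilt every step at
#' the list radius (by default the pseudo cut-off radius when the table
#' has one, else the electrostatic cut-off). `ewald_forces()` runs on the
#' direct Ewald reference with analytic plain-truncated LJ.
#'
#' @param table A `pair_table`.
#' @param scheme `"group"` or `"atom"`.
#' @param r_list Pair-list radius (nm).
#' @return A force-field specification list consumed by
#'   [run_simulation()] and [velocity_verlet_step()].
#' @export
table_forces <- function(table, scheme = c("group", "atom"), r_list = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(r_list)) {
    p <- attr(table, "pseudo_r_c")
    r_list <- if (is.na(p)) attr(table, "r_c") else p
  }
  tab <- table
  structure(list(type = 0L, table = as_kernel_table(table),
                 scheme = if (scheme == "atom") 0L else 1L,
                 scheme_name = scheme, r_list = r_list, coul = .coul,
                 method_id = attr(table, "method_id"),
                 static_energy = function(config) ips_static_energy(config, tab)),
            class = "ips_forcefield")
}

#' @rdname table_forces
#' @param params An [select_ewald_params()] object.
#' @param r_c_lj LJ truncation radius (nm) for the Ewald runs.
#' @export
ewald_forces <- function(params, r_c_lj) {
  structure(list(type = 1L, alpha = params$alpha, rcut = params$real_cutoff,
                 kmax = as.integer(params$kmax), rc_lj = r_c_lj, coul = .coul,
                 method_id = "Ewald", scheme_name = "atom"),
            class = "ips_forcefield")
}

#' Non-bonded energy and forces of a configuration under a force field
#'
#' @param config An `md_config`.
#' @param forces A force-field specification.
#' @return List with `e_elec`, `e_lj`, `forces`.
#' @export
energy_forces <- function(config, forces) {
  stopifnot(inherits(forces, "ips_forcefield"))
  cpp_energy_forces(config$positions, config$box, config$charge, config$c6,
                    config$c12, config$group_id, config$mol_id, unclass(forces))
}

#' Apply SHAKE position constraints
#'
#' Iteratively corrects post-drift positions so that every constrained
#' distance matches its target within the relative tolerance, using
#' constraint directions from the pre-drift reference positions. The
#' correction displacements are along the reference constraint directions
#' and, with mass weighting, conserve each molecule's centre of mass.
#'
#' @param positions_before N x 3 reference (pre-drift) positions.
#' @param positions_after N x 3 positions to correct.
#' @param constraints A list with `index` (n x 2) and `d0` (nm), as from
#'   [water_constraints()].
#' @param masses Per-atom masses (u).
#' @param box Box edges (nm).
#' @param rel_tol Relative distance tolerance (default 1e-6).
#' @param dt When given, the velocity correction
#'   `(corrected - uncorrected)/dt` is returned as well.
#' @return List with `positions`, `iterations`, and (when `dt` is given)
#'   `velocity_correction`.
#' @export
apply_shake <- function(positions_before, positions_after, constraints, masses,
                        box, rel_tol = 1e-6, dt = NULL) {
  res <- cpp_shake(as.matrix(positions_before), as.matrix(positions_after),
                   constraints$index, constraints$d0, 1 / masses,
                   as.numeric(box), rel_tol, 500L)
  if (!is.null(dt))
    res$velocity_correction <- (res$positions - positions_after) / dt
  res
}

#' Single-chain Nose-Hoover thermostat update
#'
#' One explicit update of the friction variable \eqn{\xi} with thermostat
#' mass \eqn{Q = N_f k_B T \tau^2}: the velocity scale
#' \eqn{s = e^{-\xi\,dt}} is evaluated at the current \eqn{\xi}, then
#' \eqn{\xi} integrates \eqn{\dot\xi = (2K - N_f k_B T)/Q} with the scaled
#' kinetic energy. At the fixed point (kinetic temperature at target,
#' \eqn{\xi = 0}) both the scale and \eqn{\xi} are unchanged.
#' [run_simulation()] applies a time-symmetric splitting of this same
#' update around the velocity-Verlet kicks.
#'
#' @param state List with `xi`, `tau` (ps), `target` (K).
#' @param kinetic_energy Current kinetic energy (kJ/mol).
#' @param dof Degree-of-freedom count entering \eqn{N_f}.
#' @param dt Time step (ps).
#' @return List with updated `state` and the velocity `scale`.
#' @export
nose_hoover_update <- function(state, kinetic_energy, dof, dt) {
  stopifnot(state$tau > 0)
  nf_kT <- dof * .kB * state$target
  Q <- nf_kT * state$tau^2
  scale <- exp(-state$xi * dt)
  K <- kinetic_energy * scale^2
  state$xi <- state$xi + dt * (2 * K - nf_kT) / Q
  list(state = state, scale = scale)
}

#' Run a molecular dynamics simulation
#'
#' Velocity-Verlet integration with SHAKE applied after the drift (with
#' the matching velocity correction) and a RATTLE velocity stage after the
#' second kick; NVT runs wrap the step in symmetric single-chain
#' Nose-Hoover half-updates. The non-bonded pair list is rebuilt every
#' step. Deterministic: identical inputs (and seed, when velocities are
#' drawn) give bit-identical trajectories.
#'
#' @param config An `md_config`; if it has no velocities they are drawn
#'   from a Maxwell-Boltzmann distribution at `temperature` using `seed`.
#' @param forces A force-field specification ([table_forces()] /
#'   [ewald_forces()]).
#' @param ensemble `"nvt"` or `"nve"`.
#' @param n_steps Number of integration steps (0 returns the input state
#'   as a one-frame trajectory).
#' @param dt Time step in ps (default 0.002 = 2 fs).
#' @param stride Frame recording stride in steps.
#' @param temperature Target temperature (K) for NVT and velocity drawing.
#' @param tau Nose-Hoover coupling time constant (ps, default 0.04).
#' @param seed Seed for velocity initialization when needed.
#' @param shake_tol SHAKE relative tolerance (default 1e-6).
#' @return An object of class `md_trajectory`: list with `frames`
#'   (N x 3 x n_frames array, nm), `frame_time` (ps), per-step `traces`
#'   (data frame: time, e_elec, e_lj, kinetic, t_kin, xi, px, py, pz),
#'   `box`, atom metadata, and `config` (the final state with velocities).
#' @export
run_simulation <- function(config, forces, ensemble = c("nvt", "nve"), n_steps,
                           dt = 0.002, stride = 10L, temperature = 298.15,
                           tau = 0.04, seed = NULL, shake_tol = 1e-6) {
  ensemble <- match.arg(ensemble)
  stopifnot(inherits(forces, "ips_forcefield"))
  if (forces$type == 0L && forces$r_list > min(config$box) / 2 + 1e-12)
    stop(sprintf("pair-list radius %g nm exceeds half the minimum box edge (%g nm)",
                 forces$r_list, min(config$box) / 2))
  if (is.null(config$velocities)) {
    if (is.null(seed)) stop("config has no velocities: provide a seed to draw them")
    config <- init_velocities(config, temperature, seed)
  }
  cons <- water_constraints(config)
  ndof <- count_dof(config)
  res <- cpp_md_run(config$positions, config$velocities, config$box,
                    config$mass, config$charge, config$c6, config$c12,
                    config$group_id, config$mol_id, cons$index, cons$d0,
                    unclass(forces), dt, as.integer(n_steps),
                    as.integer(max(1L, stride)), ensemble == "nvt",
                    temperature, tau, ndof, shake_tol, .kB)
  # constant self/excluded image energy of the IPS method (zero for Ewald,
  # whose self and exclusion terms are part of the summation itself)
  e_static <- if (forces$type == 0L && !is.null(forces$static_energy))
    forces$static_energy(config) else 0
  traces <- data.frame(time = res$time, e_elec = res$e_elec + e_static,
                       e_lj = res$e_lj,
                       kinetic = res$kinetic,
                       t_kin = 2 * res$kinetic / (ndof * .kB),
                       xi = res$xi,
                       px = res$momentum[, 1], py = res$momentum[, 2],
                       pz = res$momentum[, 3])
  final <- config
  final$positions <- res$positions
  final$velocities <- res$velocities
  structure(list(frames = res$frames,
                 frame_time = res$time[seq(1, n_steps + 1, by = max(1L, stride))],
                 traces = traces, box = config$box,
                 atom_name = config$atom_name, mol_id = config$mol_id,
                 group_id = config$group_id, mass = config$mass,
                 charge = config$charge, dt = dt,
                 stride = as.integer(max(1L, stride)),
                 ensemble = ensemble, method_id = forces$method_id,
                 scheme = forces$scheme_name, ndof = ndof, config = final),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  nf <- dim(x$frames)[3]
  cat(sprintf("md_trajectory: %s/%s, %s, %d frames over %.3f ps, %d atoms\n",
              x$method_id, x$scheme, toupper(x$ensemble), nf,
              x$frame_time[nf], dim(x$frames)[1]))
  cat(sprintf("  mean T_kin = %.2f K, mean E_pot = %.2f kJ/mol\n",
              mean(x$traces$t_kin), mean(x$traces$e_elec + x$traces$e_lj)))
  invisible(x)
}

#' Advance a configuration by one velocity-Verlet step
#'
#' One NVE step of the same integrator used by [run_simulation()] (SHAKE
#' after the drift, RATTLE after the second kick).
#'
#' @inheritParams run_simulation
#' @return The updated `md_config`.
#' @export
velocity_verlet_step <- function(config, forces, dt = 0.002, shake_tol = 1e-6) {
  traj <- run_simulation(config, forces, ensemble = "nve", n_steps = 1,
                         dt = dt, stride = 1L, shake_tol = shake_tol)
  traj$config
}

#' Build a trajectory object from explicit frames
#'
#' Wraps a list of configurations (or an N x 3 x F array plus a template
#' configuration) as an `md_trajectory`, so that the observable estimators
#' can be driven by hand-constructed or synthetic data.
#'
#' @param frames List of N x 3 position matrices, or an N x 3 x F array.
#' @param config Template `md_config` supplying box and atom metadata.
#' @param times Frame time stamps (ps).
#' @return An `md_trajectory`.
#' @export
trajectory_from_frames <- function(frames, config, times = NULL) {
  if (is.list(frames)) {
    arr <- array(0, c(nrow(frames[[1]]), 3, length(frames)))
    for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
    frames <- arr
  }
  nf <- dim(frames)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  structure(list(frames = frames, frame_time = times, traces = NULL,
                 box = config$box, atom_name = config$atom_name,
                 mol_id = config$mol_id, group_id = config$group_id,
                 mass = config$mass, charge = config$charge,
                 dt = if (nf > 1) times[2] - times[1] else 1, stride = 1L,
                 ensemble = "none", method_id = "external", scheme = "none",
                 ndof = NA, config = config),
            class = "md_trajectory")
}
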