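#' Experiment configuration profiles
#'
#' `desk_profile()` is the default reduced-scale condition set used
#' throughout the package: 125 bulk waters at 0.997 g/cm^3 (box edge
#' 1.554 nm), electrostatic cut-off 0.7 nm (below half the box edge), LJ
#' cut-off 0.55 nm, 2 fs steps, Nose-Hoover NVT at 298.15 K with
#' tau = 0.04 ps. `paper_profile()` is the full-scale bulk condition set
#' (6192 molecules, LJ cut-off 1.2664 nm, electrostatic cut-offs
#' 1.2--2.8 nm, ns-scale runs); constructing it emits a warning since such
#' runs take orders of magnitude longer than the desk profile.
#'
#' @param method One of `"IPSn"`, `"IPSp"`, `"LIPS5th"`, `"LIPSSW"`,
#'   `"Ewald"`.
#' @param scheme `"group"` or `"atom"`.
#' @param r_c Electrostatic cut-off (nm).
#' @param pseudo_r_c Optional pseudo cut-off radius for group-based runs.
#' @param seed Integer seed.
#' @return An experiment configuration list.
#' @export
desk_profile <- function(method = "LIPS5th", scheme = "group", r_c = 0.7,
                         pseudo_r_c = NULL, seed = 1) {
  list(method = method, scheme = scheme, r_c = r_c, pseudo_r_c = pseudo_r_c,
       r_c_lj = 0.55, n_molecules = 125, density = 0.997,
       temperature = 298.15, tau = 0.04, dt = 0.002,
       equil_steps = 7500L, prod_steps = 15000L, stride = 20L,
       ewald_tolerance = 1e-5, seed = seed)
}

#' @rdname desk_profile
#' @export
paper_profile <- function(method = "LIPS5th", scheme = "group", r_c = 1.2,
                          pseudo_r_c = NULL, seed = 1) {
  warning("paper-scale profile: 6192 molecules and ns-scale runs take orders of magnitude longer than the desk profile")
  list(method = method, scheme = scheme, r_c = r_c, pseudo_r_c = pseudo_r_c,
       r_c_lj = 1.2664, n_molecules = 6192, density = 0.997,
       temperature = 298.15, tau = 0.04, dt = 0.002,
       equil_steps = 500000L, prod_steps = 500000L, stride = 500L,
       ewald_tolerance = 1e-6, seed = seed)
}

#' Build the force field of an experiment configuration
#'
#' @param config Experiment configuration list.
#' @param box Box edges (nm), used for the Ewald parameter selection.
#' @return An `ips_forcefield`.
#' @export
experiment_forcefield <- function(config, box) {
  if (identical(config$method, "Ewald")) {
    pars <- select_ewald_params(box, config$ewald_tolerance %||% 1e-5)
    return(ewald_forces(pars, r_c_lj = config$r_c_lj))
  }
  pot <- solve_ips_coefficients(boundary_spec(config$method), config$r_c)
  r_list <- config$pseudo_r_c %||% config$r_c
  tab <- write_table(pot, spacing = 5e-4, r_max = r_list,
                     pseudo_r_c = config$pseudo_r_c, r_c_lj = config$r_c_lj)
  table_forces(tab, scheme = config$scheme, r_list = r_list)
}

#' Run one truncation-method experiment end to end
#'
#' Builds the system, tabulates the method (or selects Ewald parameters),
#' equilibrates under NVT, runs the production segment, and computes the
#' observable suite. Deterministic under the configuration's seed.
#'
#' @param config An experiment configuration ([desk_profile()] or a list
#'   with the same fields).
#' @param outdir Optional directory: final configuration (GRO), observable
#'   CSVs and a summary table are written there.
#' @param observables Which radial observables to compute.
#' @return A result bundle: list with `config`, `trajectory` (production),
#'   `summary` (mean potential energy per molecule with 5-block standard
#'   error, mean kinetic temperature, self-diffusion coefficient) and
#'   `observables` (list of series).
#' @export
run_experiment <- function(config, outdir = NULL,
                           observables = c("g_r", "G_k", "h_OO")) {
  t0 <- proc.time()["elapsed"]
  stage <- function(what, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("experiment stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s/%s] %-12s %7.1f s", config$method, config$scheme, what,
                    proc.time()["elapsed"] - t0))
    res
  }
  cfg <- stage("build", {
    sys <- build_bulk(config$n_molecules, config$density, seed = config$seed)
    init_velocities(assign_charge_groups(sys), config$temperature,
                    seed = config$seed + 1L)
  })
  ff <- stage("tabulate", experiment_forcefield(config, cfg$box))
  eq <- stage("equilibrate",
              run_simulation(cfg, ff, "nvt", config$equil_steps, dt = config$dt,
                             stride = config$equil_steps,
                             temperature = config$temperature, tau = config$tau))
  pr <- stage("run",
              run_simulation(eq$config, ff, "nvt", config$prod_steps,
                             dt = config$dt, stride = config$stride,
                             temperature = config$temperature, tau = config$tau))
  obs <- stage("analyze", {
    out <- list()
    dr <- 0.002
    if ("g_r" %in% observables) out$g_r <- rdf(pr, dr = dr)
    if ("G_k" %in% observables) out$G_k <- kirkwood_gk(pr, dr = dr)
    if ("h_OO" %in% observables) out$h_OO <- dipole_ordering_hoo(pr, dr = dr)
    out
  })
  epot <- (pr$traces$e_elec + pr$traces$e_lj) / config$n_molecules
  bl <- block_stats(epot, 5)
  diff_est <- tryCatch(self_diffusion(pr), error = function(e) list(D = NA))
  summary <- list(method = config$method, scheme = config$scheme,
                  r_c = config$r_c, n = config$n_molecules,
                  e_pot_per_mol = bl$mean, e_pot_se = bl$se,
                  t_kin_mean = mean(pr$traces$t_kin),
                  D = diff_est$D)
  bundle <- list(config = config, trajectory = pr, summary = summary,
                 observables = obs)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_gro(pr$config, file.path(outdir, "final.gro"),
              title = sprintf("%s-%s final frame", config$method, config$scheme))
    for (nm in names(obs))
      write_observable(obs[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       extra = c(method = config$method, scheme = config$scheme,
                                 r_c = as.character(config$r_c)))
    utils::write.csv(as.data.frame(summary), file.path(outdir, "summary.csv"),
                     row.names = FALSE)
  }
  bundle
}

#' Block-averaged mean and standard error
#'
#' Splits a correlated series into `nblocks` contiguous blocks and uses
#' the spread of the block means as the error estimate.
#'
#' @param x Numeric series.
#' @param nblocks Number of blocks (default 5).
#' @return List with `mean`, `se`, `block_means`.
#' @export
block_stats <- function(x, nblocks = 5) {
  n <- length(x)
  idx <- cut(seq_len(n), nblocks, labels = FALSE)
  bm <- as.numeric(tapply(x, idx, mean))
  list(mean = mean(x), se = stats::sd(bm) / sqrt(nblocks), block_means = bm)
}

#' Compare a method bundle to the Ewald reference bundle
#'
#' Per-observable deviation statistics between two [run_experiment()]
#' bundles on the same system: potential-energy offset with combined
#' block-error bars, maximum Kirkwood-factor deviation and its location,
#' and the self-diffusion ratio.
#'
#' @param bundle Result bundle of the method under test.
#' @param reference Result bundle of the reference (typically Ewald).
#' @return A list with `energy_offset`, `energy_se` (combined),
#'   `within_error_bars` (offset within 2 combined SE),
#'   `gk_max_dev`, `gk_max_dev_r`, `d_ratio`.
#' @export
compare_to_reference <- function(bundle, reference) {
  if (bundle$summary$n != reference$summary$n)
    stop("bundles were run on different systems (molecule counts differ)")
  de <- bundle$summary$e_pot_per_mol - reference$summary$e_pot_per_mol
  se <- sqrt(bundle$summary$e_pot_se^2 + reference$summary$e_pot_se^2)
  out <- list(energy_offset = de, energy_se = se,
              within_error_bars = abs(de) <= 2 * se,
              gk_max_dev = NA_real_, gk_max_dev_r = NA_real_,
              d_ratio = bundle$summary$D / reference$summary$D)
  if (!is.null(bundle$observables$G_k) && !is.null(reference$observables$G_k)) {
    g1 <- bundle$observables$G_k
    g2 <- reference$observables$G_k
    m <- min(nrow(g1), nrow(g2))
    dev <- abs(g1$value[1:m] - g2$value[1:m])
    out$gk_max_dev <- max(dev)
    out$gk_max_dev_r <- g1$bin_centre[which.max(dev)]
  }
  out
}
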