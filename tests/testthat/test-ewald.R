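# rock-salt lattice of +-1e point charges in a unit cube (4 ion pairs)
rock_salt <- function() {
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 0.5
  q <- ifelse(rowSums(g / 0.5) %% 2 == 0, 1, -1)
  md_config(box = c(1, 1, 1), positions = g, mol_id = 1:8,
            mass = rep(1, 8), charge = q)
}

test_that("Madelung energy matches the direct-sum oracle", {
  # independent oracle: Evjen-weighted direct lattice sum for the rock-salt
  # Madelung constant (fractional weights on the boundary of each shell)
  evjen_madelung <- function(nshell) {
    idx <- -nshell:nshell
    g <- expand.grid(i = idx, j = idx, k = idx)
    g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
    w <- (ifelse(abs(g$i) == nshell, 0.5, 1) *
          ifelse(abs(g$j) == nshell, 0.5, 1) *
          ifelse(abs(g$k) == nshell, 0.5, 1))
    sum(w * (-1)^(abs(g$i) + abs(g$j) + abs(g$k)) /
          sqrt(g$i^2 + g$j^2 + g$k^2))
  }
  M <- -evjen_madelung(8)          # ~1.747565 at 8 shells
  cfg <- rock_salt()
  res <- ewald_energy_forces(cfg, select_ewald_params(cfg$box, 1e-8))
  # energy per ion pair = -M * coulomb_factor / d0 with d0 = 0.5 nm
  got_M <- -res$energy / 4 / physical_constants()$coulomb_factor * 0.5
  expect_equal(got_M, M, tolerance = 1e-4)
})

test_that("Ewald forces are the gradient of the Ewald energy", {
  cfg <- two_waters(0.32, rot2 = ipswater:::random_rotation())
  pars <- select_ewald_params(cfg$box, 1e-7)
  res <- ewald_energy_forces(cfg, pars)
  h <- 2e-6
  for (atom in c(1, 5)) for (dim in 1:3) {
    cp <- cfg; cp$positions[atom, dim] <- cp$positions[atom, dim] + h
    cm <- cfg; cm$positions[atom, dim] <- cm$positions[atom, dim] - h
    num <- -(ewald_energy_forces(cp, pars)$energy -
               ewald_energy_forces(cm, pars)$energy) / (2 * h)
    expect_equal(res$forces[atom, dim], num,
                 tolerance = 1e-5 * max(1, abs(num)))
  }
})

test_that("energy is invariant under rigid translation and alpha choice", {
  cfg <- water_box(16, seed = 3)
  pars <- select_ewald_params(cfg$box, 1e-7)
  e0 <- ewald_energy_forces(cfg, pars)
  shifted <- cfg
  shifted$positions <- sweep(cfg$positions, 2, c(0.371, -0.82, 1.9), `+`)
  e1 <- ewald_energy_forces(shifted, pars)
  expect_equal(e1$energy, e0$energy, tolerance = 1e-9)
  # Newton's third law
  expect_lt(max(abs(colSums(e0$forces))), 1e-9 * max(abs(e0$forces)))
  # alpha +-20 % at cut-offs generous enough that every alpha in the range
  # meets the truncation tolerance (erfc tail at 0.8 alpha, k tail at 1.2)
  rcut <- min(cfg$box) / 2
  alpha0 <- 5.5 / rcut / 0.8
  kmax0 <- as.integer(ceiling(2 * 1.2 * alpha0 * sqrt(-log(1e-10)) *
                                max(cfg$box) / (2 * pi)))
  eref <- ewald_energy_forces(cfg, list(alpha = alpha0, real_cutoff = rcut,
                                        kmax = kmax0))
  for (fac in c(0.8, 1.2)) {
    alt <- list(alpha = alpha0 * fac, real_cutoff = rcut, kmax = kmax0)
    ealt <- ewald_energy_forces(cfg, alt)
    expect_equal(ealt$energy, eref$energy, tolerance = 1e-6)
  }
})

test_that("parameter selection tightens monotonically with tolerance", {
  box <- c(2, 2, 2)
  p6 <- select_ewald_params(box, 1e-6)
  p8 <- select_ewald_params(box, 1e-8)
  expect_gte(p8$kmax, p6$kmax)
  expect_gte(p8$real_cutoff, p6$real_cutoff)
  cfg <- water_box(64, seed = 6)
  e6 <- ewald_energy_forces(cfg, select_ewald_params(cfg$box, 1e-6))$energy
  e8 <- ewald_energy_forces(cfg, select_ewald_params(cfg$box, 1e-8))$energy
  expect_lt(abs(e6 - e8) / 64, 1e-4)
})

test_that("a single molecule's intramolecular electrostatics is excluded", {
  wm <- water_model()
  one <- function(L) {
    p <- ipswater:::water_geometry(wm, rep(L / 2, 3))
    md_config(box = rep(L, 3), positions = p, mol_id = c(1, 1, 1),
              atom_name = c("OW", "HW1", "HW2"),
              mass = c(wm$mass_O, wm$mass_H, wm$mass_H),
              charge = c(wm$q_O, wm$q_H, wm$q_H))
  }
  e3 <- ewald_energy_forces(one(3), select_ewald_params(c(3, 3, 3), 1e-7))$energy
  e5 <- ewald_energy_forces(one(5), select_ewald_params(c(5, 5, 5), 1e-7))$energy
  expect_lt(abs(e3), 0.1)           # only the image self-interaction remains
  expect_lt(abs(e5), abs(e3))       # and it vanishes with box size
})

test_that("non-neutral systems are rejected", {
  cfg <- md_config(box = c(2, 2, 2), positions = matrix(c(1, 1, 1), 1),
                   mol_id = 1L, mass = 1, charge = 1)
  expect_error(ewald_energy_forces(cfg, select_ewald_params(c(2, 2, 2), 1e-6)),
               "net charge")
})
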