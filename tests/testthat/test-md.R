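test_that("SHAKE restores constrained distances and conserves the centre of mass", {
  wm <- water_model()
  cfg <- two_waters(1.0)
  cons <- water_constraints(cfg)
  # already satisfied: nothing to do
  res0 <- apply_shake(cfg$positions, cfg$positions, cons, cfg$mass, cfg$box)
  expect_identical(res0$iterations, 0L)
  expect_equal(res0$positions, cfg$positions)
  # stretch one O-H bond by 5 %
  bad <- cfg$positions
  bad[2, ] <- bad[1, ] + (bad[2, ] - bad[1, ]) * 1.05
  res <- apply_shake(cfg$positions, bad, cons, cfg$mass, cfg$box,
                     rel_tol = 1e-6, dt = 0.002)
  d <- sqrt(sum((res$positions[2, ] - res$positions[1, ])^2))
  expect_equal(d, wm$d_OH, tolerance = 1e-6)
  expect_gt(res$iterations, 0)
  # mass-weighted corrections leave the molecular centre of mass in place
  m <- cfg$mass[1:3]
  com_before <- colSums(bad[1:3, ] * m) / sum(m)
  com_after <- colSums(res$positions[1:3, ] * m) / sum(m)
  expect_equal(com_after, com_before, tolerance = 1e-12)
  # correction displacement lies along the reference constraint direction
  dir <- (cfg$positions[2, ] - cfg$positions[1, ])
  dir <- dir / sqrt(sum(dir^2))
  # (the two other constraints couple in, so alignment is near-exact only)
  mv <- res$positions[2, ] - bad[2, ]
  expect_equal(abs(sum(mv * dir)), sqrt(sum(mv^2)), tolerance = 1e-3)
  expect_equal(dim(res$velocity_correction), dim(bad))
})

test_that("zero forces give uniform straight-line motion", {
  pos <- rbind(c(1, 1, 1), c(2, 2, 2))
  vel <- rbind(c(0.1, 0, -0.05), c(0, 0.2, 0))
  cfg <- lj_atoms(pos, c(5, 5, 5), vel)
  cfg$c6[] <- 0; cfg$c12[] <- 0   # no interactions at all
  pot <- solve_ips_coefficients(boundary_spec("IPSn"), 1.0)
  ff <- table_forces(write_table(pot, r_c_lj = 1.0), "atom")
  tr <- run_simulation(cfg, ff, "nve", n_steps = 50, dt = 0.002, stride = 50)
  expect_equal(tr$config$positions, pos + 50 * 0.002 * vel, tolerance = 1e-12)
  expect_equal(tr$config$velocities, vel, tolerance = 1e-12)
})

test_that("an LJ dimer conserves energy to 1e-4 relative over 10 ps", {
  pos <- rbind(c(2, 2, 2), c(2.38, 2, 2))   # near the LJ minimum
  cfg <- lj_atoms(pos, c(6, 6, 6), matrix(0, 2, 3))
  pot <- solve_ips_coefficients(boundary_spec("IPSn"), 2.0)
  ff <- table_forces(write_table(pot, r_c_lj = 2.0), "atom")
  tr <- run_simulation(cfg, ff, "nve", n_steps = 5000, dt = 0.002, stride = 500)
  E <- tr$traces$kinetic + tr$traces$e_lj
  expect_lt(diff(range(E)), 1e-4 * abs(mean(E)))
})

test_that("unconstrained dynamics is time reversible", {
  set.seed(5)
  bb <- build_bulk(27, seed = 8)
  pos <- bb$positions[seq(1, 81, by = 3), ]  # O sites
  cfg <- lj_atoms(pos, bb$box, matrix(rnorm(81, sd = 0.1), 27, 3))
  pot <- solve_ips_coefficients(boundary_spec("IPSn"), 0.45)
  ff <- table_forces(write_table(pot, r_c_lj = 0.45), "atom")
  fwd <- run_simulation(cfg, ff, "nve", n_steps = 100, stride = 100)
  back_cfg <- fwd$config
  back_cfg$velocities <- -back_cfg$velocities
  back <- run_simulation(back_cfg, ff, "nve", n_steps = 100, stride = 100)
  expect_equal(back$config$positions, cfg$positions, tolerance = 1e-8)
  expect_equal(-back$config$velocities, cfg$velocities, tolerance = 1e-8)
})

test_that("Nose-Hoover update has the correct fixed point and scale", {
  state <- list(xi = 0, tau = 0.04, target = 298.15)
  dof <- 100
  k_target <- 0.5 * dof * physical_constants()$kB * 298.15
  at_target <- nose_hoover_update(state, k_target, dof, 0.002)
  expect_equal(at_target$state$xi, 0)        # dxi/dt = 0 at the fixed point
  expect_equal(at_target$scale, 1)           # no rescale when xi = 0
  hot <- nose_hoover_update(state, 2 * k_target, dof, 0.002)
  expect_gt(hot$state$xi, 0)                 # heats the friction when too hot
  drag <- nose_hoover_update(list(xi = 1, tau = 0.04, target = 298.15),
                             k_target, dof, 0.002)
  expect_lt(drag$scale, 1)                   # positive friction damps
})

test_that("trajectories are deterministic and constraints hold at every frame", {
  cfg <- water_box(27, seed = 21)
  pot <- solve_ips_coefficients(boundary_spec("LIPS5th"), 0.42)
  tab <- write_table(pot, spacing = 5e-4, r_c_lj = 0.4)
  ff <- table_forces(tab, "group")
  t1 <- run_simulation(cfg, ff, "nvt", n_steps = 200, stride = 40)
  t2 <- run_simulation(cfg, ff, "nvt", n_steps = 200, stride = 40)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$traces, t2$traces)
  wm <- water_model()
  for (f in seq_len(dim(t1$frames)[3])) {
    p <- t1$frames[, , f]
    for (m in 0:26) {
      o <- 3 * m + 1
      expect_equal(sqrt(sum((p[o + 1, ] - p[o, ])^2)), wm$d_OH, tolerance = 2e-6)
      expect_equal(sqrt(sum((p[o + 2, ] - p[o + 1, ])^2)), wm$d_HH, tolerance = 2e-6)
    }
  }
})

test_that("a zero-step run returns the input configuration as one frame", {
  cfg <- water_box(8, seed = 14)
  pot <- solve_ips_coefficients(boundary_spec("IPSn"), 0.3)
  ff <- table_forces(write_table(pot, spacing = 1e-3, r_c_lj = 0.3), "group")
  tr <- run_simulation(cfg, ff, "nve", n_steps = 0, stride = 1)
  expect_equal(dim(tr$frames)[3], 1)
  expect_equal(tr$frames[, , 1], unname(cfg$positions))
})

test_that("NVE conserves linear momentum and NVT regulates temperature", {
  cfg <- water_box(27, seed = 33)
  pot <- solve_ips_coefficients(boundary_spec("LIPSSW"), 0.42)
  tab <- write_table(pot, spacing = 5e-4, r_c_lj = 0.4)
  ff <- table_forces(tab, "group")
  nve <- run_simulation(cfg, ff, "nve", n_steps = 500, stride = 100)
  p0 <- unlist(nve$traces[1, c("px", "py", "pz")])
  pscale <- sqrt(sum(cfg$mass) * physical_constants()$kB * 300 * sum(cfg$mass))
  expect_lt(max(abs(as.matrix(nve$traces[, c("px", "py", "pz")]) -
                      matrix(p0, nrow(nve$traces), 3, byrow = TRUE))),
            1e-9 * pscale)
  nvt <- run_simulation(cfg, ff, "nvt", n_steps = 3000, stride = 500,
                        temperature = 298.15, tau = 0.04)
  late <- nvt$traces$t_kin[1500:3001]
  expect_lt(abs(mean(late) - 298.15), 15)   # coarse regulation check
})

test_that("velocity drawing hits the target kinetic temperature exactly", {
  cfg <- build_bulk(27, seed = 3)
  cfg <- init_velocities(assign_charge_groups(cfg), 250, seed = 77)
  expect_equal(kinetic_temperature(cfg), 250, tolerance = 1e-10)
  expect_equal(count_dof(cfg), 6 * 27 - 3)
  expect_lt(max(abs(colSums(cfg$velocities * cfg$mass))), 1e-10)
})
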