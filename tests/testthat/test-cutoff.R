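test_that("charge groups are one neutral group per water", {
  cfg <- build_bulk(125, seed = 4)
  cfg <- assign_charge_groups(cfg)
  expect_equal(max(cfg$group_id), 125)
  expect_true(all(table(cfg$group_id) == 3))
  expect_true(all(abs(attr(cfg, "group_charge")) < 1e-12))
  # SPC/E charge arithmetic: -0.8476 + 2 * 0.4238 = 0 exactly
  wm <- water_model()
  expect_identical(wm$q_O + 2 * wm$q_H, 0)
})

test_that("group reference point is the geometric centre of the members", {
  cfg <- two_waters(1.0)
  cent <- group_centres(cfg)
  expect_equal(cent[1, ], colMeans(cfg$positions[1:3, ]), tolerance = 1e-12)
  expect_equal(cent[2, ], colMeans(cfg$positions[4:6, ]), tolerance = 1e-12)
})

test_that("scheme semantics: all-or-nothing group pairs vs atom pairs", {
  r_c <- 0.40
  # two 3-atom groups whose members reach toward each other: centre distance
  # slightly beyond r_c but the closest atom pair well inside it
  make_pair <- function(D) {
    a <- rbind(c(1.00, 1, 1), c(1.12, 1, 1), c(0.88, 1, 1))  # centre (1,1,1)
    b <- rbind(c(1 + D, 1, 1), c(1 + D - 0.12, 1, 1), c(1 + D + 0.12, 1, 1))
    assign_charge_groups(md_config(
      box = c(4, 4, 4), positions = rbind(a, b), mol_id = rep(1:2, each = 3),
      mass = rep(1, 6), charge = rep(0, 6)))
  }
  cfg <- make_pair(r_c + 0.01)
  dmat <- ref_pair_distances(cfg$positions, cfg$box)
  cross <- dmat[dmat[, 1] <= 3 & dmat[, 2] > 3, ]
  expect_true(any(cross[, 3] < r_c))   # fixture sanity: an atom pair is inside
  pg <- build_pairlist(cfg, r_c, "group")
  pa <- build_pairlist(cfg, r_c, "atom")
  expect_equal(nrow(pg$pairs), 0)
  expect_gt(nrow(pa$pairs), 0)
  # centres just inside: the full 9-pair block appears even for far atom pairs
  cfg2 <- make_pair(r_c - 0.01)
  expect_equal(nrow(build_pairlist(cfg2, r_c, "group")$pairs), 9)
})

test_that("no intra-group pairs are ever listed", {
  cfg <- water_box(27, seed = 9)
  for (scheme in c("atom", "group")) {
    pl <- build_pairlist(cfg, 0.45, scheme)
    gi <- cfg$group_id[pl$pairs[, 1]]
    gj <- cfg$group_id[pl$pairs[, 2]]
    expect_true(all(gi != gj))
  }
})

test_that("cell-list, brute-force and R reference pair lists agree", {
  set.seed(31)
  for (rep in 1:3) {
    cfg <- build_bulk(50, seed = rep + 40)
    cfg <- assign_charge_groups(cfg)
    r_c <- 0.30   # small enough that the box holds >= 3 cells per edge
    for (scheme in c("atom", "group")) {
      cell <- build_pairlist(cfg, r_c, scheme, method = "cell")$pairs
      brute <- build_pairlist(cfg, r_c, scheme, method = "brute")$pairs
      expect_identical(cell, brute)
      ref <- ref_pairlist(cfg$positions, cfg$box, cfg$group_id, r_c, scheme)
      expect_equal(unname(brute), unname(ref))
    }
  }
})

test_that("group scheme truncates in complete group-pair blocks", {
  cfg <- water_box(64, seed = 12)
  pl <- build_pairlist(cfg, 0.5, "group")
  key <- paste(cfg$group_id[pl$pairs[, 1]], cfg$group_id[pl$pairs[, 2]])
  expect_true(all(table(key) == 9))
})

test_that("tabulated pair energies match direct evaluation", {
  pot <- solve_ips_coefficients(boundary_spec("LIPS5th"), 0.6)
  tab <- write_table(pot, spacing = 5e-4, r_c_lj = 0.5)
  d <- 0.437123
  cfg <- md_config(box = c(3, 3, 3), positions = rbind(c(1, 1, 1), c(1 + d, 1, 1)),
                   mol_id = 1:2, mass = c(1, 1), charge = c(0.8, -0.3))
  pl <- build_pairlist(cfg, 0.6, "atom")
  got <- nonbonded_energy_forces(cfg, pl, tab)
  want <- evaluate_pair(pot, d, 0.8 * -0.3)
  expect_equal(got$e_elec, want$energy, tolerance = 1e-6)
  expect_equal(got$forces[2, 1], want$force, tolerance = 1e-6)
})

test_that("empty pair lists give zero energies and forces", {
  cfg <- two_waters(2.0)
  pl <- build_pairlist(cfg, 0.5, "group")
  pot <- solve_ips_coefficients(boundary_spec("IPSn"), 0.5)
  tab <- write_table(pot, spacing = 1e-3, r_c_lj = 0.5)
  res <- nonbonded_energy_forces(cfg, pl, tab)
  expect_equal(res$e_elec, 0)
  expect_equal(res$e_lj, 0)
  expect_true(all(res$forces == 0))
})

test_that("overlapping pairs below the table start raise an error", {
  pot <- solve_ips_coefficients(boundary_spec("IPSn"), 0.5)
  tab <- write_table(pot, spacing = 1e-3, r_c_lj = 0.5)
  cfg <- md_config(box = c(3, 3, 3),
                   positions = rbind(c(1, 1, 1), c(1.001, 1, 1)),
                   mol_id = 1:2, mass = c(1, 1), charge = c(1, 1))
  pl <- build_pairlist(cfg, 0.5, "atom")
  expect_error(nonbonded_energy_forces(cfg, pl, tab), "overlap")
})

test_that("group cut-off with a pseudo radius equals atom cut-off at r_c", {
  r_c <- 0.45
  pot <- solve_ips_coefficients(boundary_spec("IPSn"), r_c)
  tab <- write_table(pot, spacing = 5e-4, pseudo_r_c = r_c + 0.2, r_c_lj = 0.4)
  for (s in 1:20) {
    cfg <- assign_charge_groups(build_bulk(100, seed = 100 + s))
    pg <- build_pairlist(cfg, r_c + 0.2, "group")
    pa <- build_pairlist(cfg, r_c, "atom")
    eg <- nonbonded_energy_forces(cfg, pg, tab)
    ea <- nonbonded_energy_forces(cfg, pa, tab)
    expect_equal(eg$e_elec, ea$e_elec, tolerance = 1e-12)
    expect_equal(eg$e_lj, ea$e_lj, tolerance = 1e-12)
    expect_equal(eg$forces, ea$forces, tolerance = 1e-12)
  }
})

test_that("pair-list radius beyond the minimum image is rejected", {
  cfg <- water_box(27, seed = 2)
  expect_error(build_pairlist(cfg, min(cfg$box), "atom"), "half")
})
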