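# Shared fixtures and independent reference implementations used as oracles.
# Everything here is deliberately written from scratch (plain R, brute
# force) so that it exercises none of the package's computational paths.

min_image_ref <- function(d, box) d - box * round(d / box)

# Independent closed-form derivatives of u(r) = 1/r + (1/r_c) sum c_k (r/r_c)^(2k):
# d^m (1/r) = (-1)^m m! r^-(m+1); polynomial terms differentiated term-wise.
ref_total_derivative <- function(coef, r_c, r, m) {
  inv <- (-1)^m * factorial(m) / r^(m + 1)
  poly <- 0
  for (k in seq_along(coef) - 1) {
    p <- 2 * k
    if (m > p) next
    fac <- if (m == 0) 1 else prod(seq(p, p - m + 1))
    poly <- poly + coef[k + 1] * fac * (r / r_c)^(p - m) / r_c^m
  }
  inv + poly / r_c
}

# Brute-force O(N^2) minimum-image pair distances of a point set
ref_pair_distances <- function(pos, box) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- min_image_ref(pos[j, ] - pos[i, ], box)
    out <- rbind(out, c(i, j, sqrt(sum(d^2))))
  }
  out
}

# Brute-force pair list (atom or group scheme) as a sorted two-column matrix
ref_pairlist <- function(pos, box, group_id, r_c, scheme) {
  n <- nrow(pos)
  pairs <- NULL
  if (scheme == "atom") {
    pd <- ref_pair_distances(pos, box)
    keep <- pd[, 3] <= r_c & group_id[pd[, 1]] != group_id[pd[, 2]]
    pairs <- pd[keep, 1:2, drop = FALSE]
  } else {
    gs <- sort(unique(group_id))
    cent <- t(vapply(gs, function(g) {
      m <- which(group_id == g)
      a0 <- pos[m[1], ]
      a0 + colMeans(do.call(rbind, lapply(m, function(a)
        min_image_ref(pos[a, ] - a0, box))))
    }, numeric(3)))
    for (a in seq_along(gs)[-length(gs)]) for (b in (a + 1):length(gs)) {
      d <- min_image_ref(cent[b, ] - cent[a, ], box)
      if (sqrt(sum(d^2)) <= r_c) {
        for (i in which(group_id == gs[a])) for (j in which(group_id == gs[b]))
          pairs <- rbind(pairs, sort(c(i, j)))
      }
    }
  }
  if (is.null(pairs)) return(matrix(integer(0), 0, 2))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  unname(pairs)
}

# A bulk water fixture with velocities and charge groups assigned
water_box <- function(n, seed = 1, temperature = 298.15) {
  cfg <- build_bulk(n, seed = seed)
  init_velocities(assign_charge_groups(cfg), temperature, seed + 1000L)
}

# Two waters with oxygens separated by `d` along x, orientations given as
# rotation matrices; box large enough that minimum image is trivial
two_waters <- function(d, box = c(4, 4, 4), rot1 = diag(3), rot2 = diag(3)) {
  wm <- water_model()
  p1 <- ipswater:::water_geometry(wm, c(1, 1, 1), rot1)
  p2 <- ipswater:::water_geometry(wm, c(1 + d, 1, 1), rot2)
  cfg <- md_config(
    box = box, positions = rbind(p1, p2), mol_id = rep(1:2, each = 3),
    atom_name = rep(c("OW", "HW1", "HW2"), 2),
    mass = rep(c(wm$mass_O, wm$mass_H, wm$mass_H), 2),
    charge = rep(c(wm$q_O, wm$q_H, wm$q_H), 2),
    c6 = rep(c(wm$c6, 0, 0), 2), c12 = rep(c(wm$c12, 0, 0), 2))
  assign_charge_groups(cfg)
}

# Lennard-Jones atoms (single-atom molecules, no charge)
lj_atoms <- function(pos, box, vel = NULL) {
  wm <- water_model()
  n <- nrow(pos)
  md_config(box = box, positions = pos, velocities = vel, mol_id = seq_len(n),
            atom_name = rep("AR", n), mass = rep(39.948, n),
            charge = numeric(n), c6 = rep(wm$c6, n), c12 = rep(wm$c12, n))
}

# Waters on a loose grid with chosen orientations (all parallel by default)
oriented_waters <- function(n_side, spacing, rot = NULL, seed = NULL,
                            box = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_side^3
  g <- as.matrix(expand.grid(x = 0:(n_side - 1), y = 0:(n_side - 1),
                             z = 0:(n_side - 1))) * spacing + spacing / 2
  if (is.null(box)) box <- rep(n_side * spacing, 3)
  rots <- lapply(seq_len(n), function(i)
    if (is.null(rot)) ipswater:::random_rotation() else rot)
  cfg <- ipswater:::waters_from_sites(g, rots, box = box)
  assign_charge_groups(cfg)
}

# total energy trace per molecule of a trajectory
total_energy_per_mol <- function(traj) {
  n <- length(unique(traj$mol_id))
  (traj$traces$kinetic + traj$traces$e_elec + traj$traces$e_lj) / n
}

# drift: |linear trend| of the total energy over the run, per molecule
energy_drift <- function(traj) {
  e <- total_energy_per_mol(traj)
  t <- traj$traces$time
  abs(unname(coef(stats::lm(e ~ t))[2])) * (max(t) - min(t))
}
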