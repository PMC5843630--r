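#' Binned observable series
#'
#' Common container for binned radial or axial statistics: a data frame
#' with columns `bin_centre` (nm), `value`, `count`, plus attributes
#' `observable`, `bin_width` and `frames`.
#' @noRd
observable_series <- function(bin_centre, value, count, observable, bin_width,
                              frames) {
  out <- data.frame(bin_centre = bin_centre, value = value, count = count)
  attr(out, "observable") <- observable
  attr(out, "bin_width") <- bin_width
  attr(out, "frames") <- frames
  class(out) <- c("observable_series", "data.frame")
  out
}

#' Write an observable series as CSV
#'
#' One file per observable: `#`-prefixed metadata header (bin width,
#' number of frames, observable id, free-form extra fields), then
#' `bin_centre,value,count` rows.
#'
#' @param series An observable series.
#' @param file Output path.
#' @param extra Named character vector of additional metadata.
#' @return `file`, invisibly.
#' @export
write_observable <- function(series, file, extra = NULL) {
  hdr <- c(sprintf("# observable=%s", attr(series, "observable")),
           sprintf("# bin_width=%g", attr(series, "bin_width")),
           sprintf("# frames=%d", attr(series, "frames")))
  if (!is.null(extra)) hdr <- c(hdr, sprintf("# %s=%s", names(extra), extra))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(file)
}

# Oxygen (molecular reference site) indices of a trajectory: the O atom of
# each 3-atom molecule, else each molecule's first atom.
reference_sites <- function(traj) {
  first <- !duplicated(traj$mol_id)
  ox <- startsWith(traj$atom_name, "O")
  mols <- unique(traj$mol_id)
  vapply(mols, function(m) {
    cand <- which(traj$mol_id == m & ox)
    if (length(cand) > 0) cand[1] else which(traj$mol_id == m)[1]
  }, integer(1))
}

#' Molecular dipole unit vectors of one frame
#'
#' SPC/E dipoles point along the H-H bisector away from the oxygen; the
#' returned vectors are normalized (and minimum-image safe for wrapped
#' molecules).
#'
#' @param traj An `md_trajectory` of 3-site waters.
#' @param frame Frame index.
#' @return List with `u` (n_mol x 3 unit dipoles) and `ref` (n_mol x 3
#'   oxygen positions, nm).
#' @export
molecular_dipoles <- function(traj, frame = 1) {
  pos <- traj$frames[, , frame]
  box <- traj$box
  mols <- unique(traj$mol_id)
  u <- ref <- matrix(0, length(mols), 3)
  for (k in seq_along(mols)) {
    at <- which(traj$mol_id == mols[k])
    stopifnot(length(at) == 3)
    o <- at[startsWith(traj$atom_name[at], "O")][1]
    hs <- setdiff(at, o)
    d1 <- min_image_r(pos[hs[1], ] - pos[o, ], box)
    d2 <- min_image_r(pos[hs[2], ] - pos[o, ], box)
    v <- d1 + d2
    u[k, ] <- v / sqrt(sum(v^2))
    ref[k, ] <- pos[o, ]
  }
  list(u = u, ref = ref)
}

min_image_r <- function(d, box) d - box * round(d / box)

#' Self-diffusion coefficient by the Einstein relation
#'
#' Unwraps the molecular reference sites across the periodic boundary by
#' accumulating per-frame minimum-image displacements, computes the
#' particle-averaged mean-squared displacement over multiple time origins,
#' and fits \eqn{D = \mathrm{slope}/6} by least squares on the stated lag
#' window. The log-log slope of the MSD over the window is returned as a
#' regime diagnostic (1 for diffusive motion, 2 for ballistic).
#'
#' @param traj An `md_trajectory`.
#' @param fit_window Length-2 lag-time window (ps) for the linear fit;
#'   default the central 20--80 % of the available lags.
#' @param origin_stride Time-origin spacing in frames (default: a tenth of
#'   the window length).
#' @return List with `D` (nm^2/ps; multiply by 1e3 for 1e-9 m^2/s),
#'   `slope`, `intercept`, `r_squared`, `exponent` (log-log diagnostic),
#'   `diffusive` (logical flag), and the `msd` data frame (`lag` ps,
#'   `msd` nm^2).
#' @export
self_diffusion <- function(traj, fit_window = NULL, origin_stride = NULL) {
  sites <- reference_sites(traj)
  sub <- traj$frames[sites, , , drop = FALSE]
  un <- cpp_unwrap_arr(sub, traj$box)
  nf <- dim(un)[3]
  if (nf < 3) stop("trajectory too short for a diffusion estimate")
  dtf <- traj$frame_time[2] - traj$frame_time[1]
  tmax <- traj$frame_time[nf] - traj$frame_time[1]
  if (is.null(fit_window)) fit_window <- c(0.2, 0.8) * tmax
  if (fit_window[2] > tmax)
    stop("fit window extends beyond the trajectory length")
  lag_max <- min(nf - 1, ceiling(fit_window[2] / dtf))
  lags <- seq_len(lag_max)
  if (is.null(origin_stride))
    origin_stride <- max(1L, floor((fit_window[2] - fit_window[1]) / dtf / 10))
  msd <- vapply(lags, function(L) {
    orig <- seq(1, nf - L, by = origin_stride)
    m <- 0
    for (o in orig) {
      d <- un[, , o + L] - un[, , o]
      m <- m + mean(rowSums(d^2))
    }
    m / length(orig)
  }, numeric(1))
  lag_t <- lags * dtf
  inw <- lag_t >= fit_window[1] & lag_t <= fit_window[2]
  if (sum(inw) < 2) stop("fit window contains fewer than two MSD points")
  fit <- stats::lm(msd[inw] ~ lag_t[inw])
  sl <- unname(stats::coef(fit)[2])
  pos_ok <- msd[inw] > 0
  expo <- if (sum(pos_ok) >= 2 && sl != 0) {
    unname(stats::coef(stats::lm(log(msd[inw][pos_ok]) ~ log(lag_t[inw][pos_ok])))[2])
  } else NA_real_
  list(D = sl / 6, slope = sl, intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, exponent = expo,
       diffusive = is.finite(expo) && abs(expo - 1) < 0.3,
       msd = data.frame(lag = lag_t, msd = msd))
}

#' Radial distribution function
#'
#' \eqn{g(r) = V / (4\pi r^2 \Delta r\, N(N-1)) \langle \sum_i n_i(r)\rangle}
#' over the molecular reference sites (O-O for water), frame-averaged,
#' with \eqn{r} evaluated at the bin centre.
#'
#' @param traj An `md_trajectory`.
#' @param dr Bin width (nm, default 0.002).
#' @param r_max Histogram range (default half the minimum box edge).
#' @return An observable series (`bin_centre` nm, `value` = g, `count` =
#'   accumulated ordered-pair count).
#' @export
rdf <- function(traj, dr = 0.002, r_max = NULL) {
  if (dr <= 0) stop("dr must be positive")
  if (is.null(r_max)) r_max <- min(traj$box) / 2
  if (r_max > min(traj$box) / 2 + 1e-12)
    stop("r_max exceeds half the minimum box edge")
  sites <- reference_sites(traj)
  if (length(sites) < 2) stop("selection is empty or has a single site")
  nbins <- floor(r_max / dr)
  nf <- dim(traj$frames)[3]
  counts <- numeric(nbins)
  for (f in seq_len(nf)) {
    b <- cpp_pair_bins(traj$frames[sites, , f], matrix(0, 1, 1), traj$box,
                       dr, nbins, FALSE)
    counts <- counts + 2 * b$counts   # ordered pairs
  }
  N <- length(sites)
  V <- prod(traj$box)
  rc <- (seq_len(nbins) - 0.5) * dr
  g <- V / (4 * pi * rc^2 * dr * N * (N - 1)) * counts / nf
  observable_series(rc, g, counts, "g_r", dr, nf)
}

#' Distance-dependent Kirkwood factor
#'
#' \eqn{G_k(r) = (1/N)\langle \sum_i \mathbf{u}_i \cdot \sum_{j, r_{ij}<r}
#' \mathbf{u}_j\rangle}, cumulative in \eqn{r} with the self term included,
#' so \eqn{G_k \to 1} as \eqn{r \to 0^+}. The `bin_centre` column holds the
#' upper edge of each cumulative shell.
#'
#' @param traj An `md_trajectory` of waters.
#' @param dr Bin width (nm, default 0.002).
#' @param r_max Range (default half the minimum box edge).
#' @return An observable series.
#' @export
kirkwood_gk <- function(traj, dr = 0.002, r_max = NULL) {
  if (is.null(r_max)) r_max <- min(traj$box) / 2
  nbins <- floor(r_max / dr)
  nf <- dim(traj$frames)[3]
  acc <- numeric(nbins)
  N <- length(unique(traj$mol_id))
  for (f in seq_len(nf)) {
    dip <- molecular_dipoles(traj, f)
    b <- cpp_pair_bins(dip$ref, dip$u, traj$box, dr, nbins, TRUE)
    acc <- acc + cumsum(b$dots)
  }
  gk <- 1 + 2 * acc / (N * nf)
  observable_series(seq_len(nbins) * dr, gk, rep(nf, nbins), "G_k", dr, nf)
}

#' Radial dipole-ordering function
#'
#' \eqn{h_{OO}(r) = 3 g_{OO}(r) \langle\cos\theta(r)\rangle} with the
#' shell-wise orientation average
#' \eqn{\langle\cos\theta(r)\rangle = (1/N)\langle\sum_i (1/n_i(r))
#' \sum_j \mathbf{u}_i\cdot\mathbf{u}_j\rangle}; molecules with an empty
#' shell (\eqn{n_i(r)=0}) contribute zero. Both factors are computed on
#' the same bins.
#'
#' @inheritParams kirkwood_gk
#' @return An observable series; attributes `g_oo` and `cos_theta` carry
#'   the two factors.
#' @export
dipole_ordering_hoo <- function(traj, dr = 0.002, r_max = NULL) {
  if (is.null(r_max)) r_max <- min(traj$box) / 2
  nbins <- floor(r_max / dr)
  nf <- dim(traj$frames)[3]
  N <- length(unique(traj$mol_id))
  counts <- coshell <- numeric(nbins)
  for (f in seq_len(nf)) {
    dip <- molecular_dipoles(traj, f)
    b <- cpp_pair_bins(dip$ref, dip$u, traj$box, dr, nbins, TRUE)
    counts <- counts + 2 * b$counts
    coshell <- coshell + b$coshell
  }
  V <- prod(traj$box)
  rc <- (seq_len(nbins) - 0.5) * dr
  g <- V / (4 * pi * rc^2 * dr * N * (N - 1)) * counts / nf
  cosr <- coshell / (N * nf)
  out <- observable_series(rc, 3 * g * cosr, counts, "h_OO", dr, nf)
  attr(out, "g_oo") <- g
  attr(out, "cos_theta") <- cosr
  out
}

#' Mass and charge density profiles along a surface normal
#'
#' Per-bin frame-averaged mass density (g/cm^3) and charge density
#' (e/nm^3) along the stated axis, with positions wrapped into the box.
#'
#' @param traj An `md_trajectory` (slab geometry for interface analyses).
#' @param dz Bin width (nm, default 0.02).
#' @param axis `"z"` (default), `"y"` or `"x"`.
#' @return List of two observable series, `mass` and `charge`.
#' @export
density_profiles <- function(traj, dz = 0.02, axis = "z") {
  if (dz <= 0) stop("dz must be positive")
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  L <- traj$box[ax]
  area <- prod(traj$box[-ax])
  nbins <- max(1L, floor(L / dz + 0.5))
  dz_eff <- L / nbins
  nf <- dim(traj$frames)[3]
  m_acc <- q_acc <- numeric(nbins)
  for (f in seq_len(nf)) {
    z <- traj$frames[, ax, f]
    z <- z - L * floor(z / L)
    b <- pmin(nbins, floor(z / dz_eff) + 1)
    m_acc <- m_acc + as.numeric(tapply(traj$mass, factor(b, levels = 1:nbins),
                                       sum, default = 0))
    q_acc <- q_acc + as.numeric(tapply(traj$charge, factor(b, levels = 1:nbins),
                                       sum, default = 0))
  }
  vol <- area * dz_eff
  zc <- (seq_len(nbins) - 0.5) * dz_eff
  mass <- observable_series(zc, m_acc / nf / vol * .mass_conv, m_acc / nf,
                            "rho_mass", dz_eff, nf)
  charge <- observable_series(zc, q_acc / nf / vol, q_acc / nf,
                              "rho_charge", dz_eff, nf)
  list(mass = mass, charge = charge)
}

#' Electrostatic potential profile from a charge density profile
#'
#' Double integration of the Poisson equation along the surface normal:
#' \eqn{\psi(z) - \psi(0) = -(1/\epsilon_0)\int_0^z\int_0^{z'}
#' \rho_c(z'')\,dz''\,dz'} by cumulative trapezoids. The zero of the
#' potential is anchored to the vacuum: by default the bin with the lowest
#' mass density (when a mass profile is supplied), else \eqn{z = 0}.
#'
#' @param charge_profile Observable series of charge density (e/nm^3)
#'   covering the full box edge.
#' @param mass_profile Optional mass-density series used to locate the
#'   vacuum anchor bin.
#' @return An observable series of \eqn{\psi(z)} in kJ/mol/e (divide by
#'   96.485 for volts).
#' @export
electrostatic_potential_profile <- function(charge_profile, mass_profile = NULL) {
  z <- charge_profile$bin_centre
  rho <- charge_profile$value
  dz <- attr(charge_profile, "bin_width")
  eps0 <- physical_constants()$vacuum_permittivity
  ctrap <- function(y) {  # cumulative trapezoid from the first point
    c(0, cumsum((y[-1] + y[-length(y)]) / 2)) * dz
  }
  field <- ctrap(rho)          # integral of rho_c
  psi <- -ctrap(field) / eps0  # double integral
  anchor <- if (!is.null(mass_profile)) which.min(mass_profile$value)[1] else 1L
  psi <- psi - psi[anchor]
  observable_series(z, psi, charge_profile$count, "psi_z", dz,
                    attr(charge_profile, "frames"))
}
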