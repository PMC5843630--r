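#' Build a bulk SPC/E water box
#'
#' Places `n` rigid water molecules on a jittered cubic lattice with
#' uniformly random orientations inside a cubic periodic box whose edge is
#' set by the target mass density, \eqn{L = (n\,m_w/\rho)^{1/3}}. The
#' jitter amplitude is capped so that no two oxygens can come closer than
#' 0.25 nm; the construction is deterministic under a fixed seed. The
#' lattice is a starting structure only: equilibration burns in the liquid
#' structure.
#'
#' @param n Number of molecules.
#' @param density Target mass density in g/cm^3 (default 0.997).
#' @param seed Integer seed.
#' @param jitter Requested lattice jitter amplitude (nm, per axis).
#' @param model Water model.
#' @return An `md_config` of `3n` atoms (no velocities).
#' @examples
#' cfg <- build_bulk(27, seed = 1)
#' mass_density(cfg)
#' @export
build_bulk <- function(n, density = 0.997, seed = 1, jitter = 0.015,
                       model = water_model()) {
  if (density <= 0) stop("density must be positive")
  vol <- n * model$mass * .mass_conv / density
  L <- vol^(1 / 3)
  n_side <- ceiling(n^(1 / 3))
  a <- L / n_side
  if (a <= 0.252) stop("density too high: lattice spacing leaves no room for overlap removal")
  set.seed(seed)
  grid <- as.matrix(expand.grid(x = 0:(n_side - 1), y = 0:(n_side - 1),
                                z = 0:(n_side - 1)))
  pick <- if (nrow(grid) > n) sort(sample(nrow(grid), n)) else seq_len(n)
  jit <- min(jitter, max(0, (a - 0.252) / (2 * sqrt(3))))
  sites <- (grid[pick, , drop = FALSE] + 0.5) * a +
    matrix(stats::runif(3 * n, -jit, jit), n, 3)
  rots <- replicate(n, random_rotation(), simplify = FALSE)
  cfg <- waters_from_sites(sites, rots, box = c(L, L, L), model = model)
  check_min_oo(cfg)
  attr(cfg, "seed") <- seed
  cfg
}

#' Build a water-vapour slab configuration
#'
#' A liquid slab of `n` molecules at the given bulk density, centred along
#' the slab axis of an elongated periodic box, with vacuum on both sides.
#' The slab thickness follows from the bulk density and the tangential box
#' area, \eqn{h = n\,m_w/(\rho L_x L_y)}.
#'
#' @param n Number of molecules (0 gives an empty, still valid, box).
#' @param box Length-3 box edges (nm); the `axis` edge must exceed the slab
#'   thickness.
#' @param density Liquid density used for the slab interior (g/cm^3).
#' @param axis Slab normal: `"z"` (default), `"y"` or `"x"`.
#' @param seed Integer seed.
#' @param jitter Lattice jitter amplitude (nm).
#' @param model Water model.
#' @return An `md_config`; the slab thickness is stored in attribute
#'   `slab_thickness`.
#' @export
build_slab <- function(n, box, density = 0.997, axis = "z", seed = 1,
                       jitter = 0.015, model = water_model()) {
  stopifnot(length(box) == 3)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  if (n == 0) {
    cfg <- md_config(box = box, positions = matrix(0, 0, 3),
                     mol_id = integer(0), mass = numeric(0), charge = numeric(0))
    attr(cfg, "slab_thickness") <- 0
    return(cfg)
  }
  tang <- setdiff(1:3, ax)
  h <- n * model$mass * .mass_conv / (density * box[tang[1]] * box[tang[2]])
  if (h >= box[ax]) stop("slab thickness exceeds the box edge along the slab axis; no vacuum left")
  set.seed(seed)
  a0 <- (box[tang[1]] * box[tang[2]] * h / n)^(1 / 3)
  nd <- c(0, 0, 0)
  nd[tang[1]] <- ceiling(box[tang[1]] / a0)
  nd[tang[2]] <- ceiling(box[tang[2]] / a0)
  nd[ax] <- ceiling(n / (nd[tang[1]] * nd[tang[2]]))
  sp <- c(0, 0, 0)
  sp[tang] <- box[tang] / nd[tang]
  sp[ax] <- h / nd[ax]
  if (min(sp) <= 0.252) stop("density too high: lattice spacing leaves no room for overlap removal")
  grid <- as.matrix(expand.grid(x = 0:(nd[1] - 1), y = 0:(nd[2] - 1),
                                z = 0:(nd[3] - 1)))
  pick <- if (nrow(grid) > n) sort(sample(nrow(grid), n)) else seq_len(n)
  jit <- min(jitter, max(0, (min(sp) - 0.252) / (2 * sqrt(3))))
  sites <- sweep((grid[pick, , drop = FALSE] + 0.5), 2, sp, `*`) +
    matrix(stats::runif(3 * n, -jit, jit), n, 3)
  sites[, ax] <- sites[, ax] + (box[ax] - h) / 2  # centre the slab
  rots <- replicate(n, random_rotation(), simplify = FALSE)
  cfg <- waters_from_sites(sites, rots, box = box, model = model)
  check_min_oo(cfg)
  attr(cfg, "seed") <- seed
  attr(cfg, "slab_thickness") <- h
  cfg
}

# enforce the minimum intermolecular O-O distance guarantee of the builders
check_min_oo <- function(cfg, dmin = 0.25) {
  ox <- cfg$atom_name == "OW"
  if (sum(ox) < 2) return(invisible(TRUE))
  pl <- cpp_pairlist(cfg$positions[ox, , drop = FALSE], cfg$box,
                     seq_len(sum(ox)), dmin, 0L, TRUE)
  if (nrow(pl) > 0)
    stop(sprintf("overlap removal failed: %d O-O pairs closer than %g nm", nrow(pl), dmin))
  invisible(TRUE)
}

#' Build a system from a recipe list
#'
#' Recipes are plain lists (typically read from YAML with
#' [yaml::read_yaml()]): fields `geometry` ("bulk" or "slab"),
#' `n_molecules`, `density`, `seed`, and for slabs `box` and `axis`.
#'
#' @param recipe A recipe list.
#' @return An `md_config`.
#' @export
build_system <- function(recipe) {
  geom <- match.arg(recipe$geometry, c("bulk", "slab"))
  if (geom == "bulk") {
    build_bulk(n = recipe$n_molecules,
               density = recipe$density %||% 0.997,
               seed = recipe$seed %||% 1)
  } else {
    build_slab(n = recipe$n_molecules, box = unlist(recipe$box),
               density = recipe$density %||% 0.997,
               axis = recipe$axis %||% "z",
               seed = recipe$seed %||% 1)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
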