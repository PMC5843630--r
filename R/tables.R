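#' Tabulate an IPS pair potential in the GROMACS table dialect
#'
#' Samples the electrostatic pair function \eqn{1/r + \varphi(r)} and the
#' plain-truncated dispersion (\eqn{-r^{-6}}) and repulsion (\eqn{r^{-12}})
#' kernels on a uniform grid, in the seven-column layout `r, f, -f', g,
#' -g', h, -h'` used for tabulated interaction functions: the simulation
#' multiplies `f` by \eqn{f_{coul} q_i q_j} and `g`, `h` by the combined
#' LJ coefficients \eqn{c_6}, \eqn{c_{12}}. All interaction columns are
#' exactly zero beyond their cut-off; with a pseudo cut-off radius
#' \eqn{r_c^* > r_c} the rows on \eqn{(r_c, r_c^*]} are therefore zero,
#' which is what makes group-based truncation at list radius \eqn{r_c^*}
#' numerically identical to atom-based truncation at \eqn{r_c}.
#'
#' @param pot An [`ips_potential`][solve_ips_coefficients()].
#' @param lj LJ parameter source (a [water_model()] or a list with
#'   `sigma_OO`); sets the default LJ cut-off `r_c_lj`.
#' @param spacing Grid spacing in nm (default 0.0005; a warning is issued
#'   above 0.002 where cubic interpolation error becomes noticeable).
#' @param r_max Last grid point (nm); must be at least `r_c` (and at least
#'   `pseudo_r_c` when given).
#' @param pseudo_r_c Optional pseudo cut-off radius \eqn{r_c^* \ge r_c}.
#' @param r_c_lj LJ truncation radius (default `min(4 sigma, r_c)`).
#' @param lj_shift When `TRUE`, the dispersion and repulsion columns are
#'   shifted to zero at `r_c_lj` (cut-and-shifted LJ). The default is
#'   plain truncation; the shift removes the energy jump a pair suffers
#'   when crossing the LJ cut-off, which at reduced cut-off radii
#'   dominates microcanonical energy drift and would mask the
#'   electrostatic boundary behaviour under study.
#' @param r_min First grid point (nm, default 0.002; excludes the
#'   singularity at the origin).
#' @param file Optional path; when given the table is also written as a
#'   whitespace-separated text file with one header comment line.
#' @return An object of class `pair_table`: a data frame with columns
#'   `r, f, fprime, g, gprime, h, hprime` (`*prime` columns hold the
#'   negative derivative) and attributes `method_id`, `r_c`, `pseudo_r_c`,
#'   `r_c_lj`, `spacing`.
#' @export
write_table <- function(pot, lj = water_model(), spacing = 0.0005, r_max = NULL,
                        pseudo_r_c = NULL, r_c_lj = NULL, lj_shift = FALSE,
                        r_min = 0.002, file = NULL) {
  stopifnot(inherits(pot, "ips_potential"))
  if (spacing <= 0) stop("spacing must be positive")
  if (spacing > 0.002)
    warning("table spacing coarser than 0.002 nm: cubic interpolation error may be significant")
  if (!is.null(pseudo_r_c)) {
    if (pseudo_r_c < pot$r_c) stop("pseudo_r_c must be >= r_c")
    if (is.null(r_max)) r_max <- pseudo_r_c
    if (r_max < pseudo_r_c) stop("r_max must be >= pseudo_r_c")
  }
  if (is.null(r_max)) r_max <- pot$r_c
  if (r_max < pot$r_c) stop("r_max must be >= r_c")
  if (is.null(r_c_lj)) r_c_lj <- min(4 * lj$sigma_OO, pot$r_c)

  r <- seq(r_min, r_max + spacing / 2, by = spacing)
  el <- r <= pot$r_c
  f <- fp <- numeric(length(r))
  f[el] <- 1 / r[el] + .phi(pot, r[el])
  fp[el] <- 1 / r[el]^2 - .phi_deriv(pot, r[el])
  in_lj <- r <= r_c_lj
  g <- gp <- h <- hp <- numeric(length(r))
  g_shift <- if (lj_shift) 1 / r_c_lj^6 else 0
  h_shift <- if (lj_shift) -1 / r_c_lj^12 else 0
  g[in_lj] <- -1 / r[in_lj]^6 + g_shift
  gp[in_lj] <- -6 / r[in_lj]^7
  h[in_lj] <- 1 / r[in_lj]^12 + h_shift
  hp[in_lj] <- 12 / r[in_lj]^13

  tab <- data.frame(r = r, f = f, fprime = fp, g = g, gprime = gp, h = h, hprime = hp)
  attr(tab, "method_id") <- pot$method_id
  attr(tab, "coefficients") <- pot$coefficients
  attr(tab, "r_c") <- pot$r_c
  attr(tab, "pseudo_r_c") <- if (is.null(pseudo_r_c)) NA_real_ else pseudo_r_c
  attr(tab, "r_c_lj") <- r_c_lj
  attr(tab, "spacing") <- spacing
  class(tab) <- c("pair_table", "data.frame")
  if (!is.null(file)) {
    hdr <- sprintf("# ipswater table method=%s r_c=%.17g pseudo_r_c=%.17g r_c_lj=%.17g coef=%s",
                   pot$method_id, pot$r_c,
                   if (is.null(pseudo_r_c)) NA_real_ else pseudo_r_c, r_c_lj,
                   paste(sprintf("%.17g", pot$coefficients), collapse = ","))
    lines <- c(hdr, vapply(seq_len(nrow(tab)), function(i) {
      paste(sprintf("%.17e", unlist(tab[i, ])), collapse = " ")
    }, character(1)))
    writeLines(lines, file)
  }
  tab
}

#' Read a tabulated pair potential written by [write_table()]
#'
#' @param file Path to the table file.
#' @return A `pair_table` object.
#' @export
read_table <- function(file) {
  lines <- readLines(file)
  hdr <- lines[1]
  get_field <- function(name) {
    m <- regmatches(hdr, regexpr(paste0(name, "=[^ ]+"), hdr))
    sub(paste0(name, "="), "", m)
  }
  vals <- utils::read.table(text = lines[-1], col.names =
    c("r", "f", "fprime", "g", "gprime", "h", "hprime"))
  attr(vals, "method_id") <- get_field("method")
  cf <- get_field("coef")
  if (length(cf) == 1)
    attr(vals, "coefficients") <- as.numeric(strsplit(cf, ",")[[1]])
  attr(vals, "r_c") <- as.numeric(get_field("r_c"))
  attr(vals, "pseudo_r_c") <- as.numeric(get_field("pseudo_r_c"))
  attr(vals, "r_c_lj") <- as.numeric(get_field("r_c_lj"))
  attr(vals, "spacing") <- vals$r[2] - vals$r[1]
  class(vals) <- c("pair_table", "data.frame")
  vals
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("pair_table: %s, r_c = %g nm, pseudo_r_c = %s, r_c_lj = %g nm\n",
              attr(x, "method_id"), attr(x, "r_c"),
              ifelse(is.na(attr(x, "pseudo_r_c")), "none",
                     sprintf("%g nm", attr(x, "pseudo_r_c"))),
              attr(x, "r_c_lj")))
  cat(sprintf("  %d rows, r in [%g, %g] nm, spacing %g nm\n",
              nrow(x), x$r[1], x$r[nrow(x)], attr(x, "spacing")))
  invisible(x)
}

# table in the flat layout the C++ kernels consume
as_kernel_table <- function(tab) {
  stopifnot(inherits(tab, "pair_table"))
  list(Vf = tab$f, Ff = tab$fprime, Vg = tab$g, Fg = tab$gprime,
       Vh = tab$h, Fh = tab$hprime, r0 = tab$r[1], dr = attr(tab, "spacing"),
       rc_elec = attr(tab, "r_c"), rc_lj = attr(tab, "r_c_lj"))
}
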