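#' Cut-off boundary conditions of the IPS potential family
#'
#' The isotropic periodic sum (IPS) family replaces the long-range tail of
#' the Coulomb interaction by an image term \eqn{\varphi(r; r_c)} that
#' represents isotropically distributed periodic images inside a local
#' sphere of radius \eqn{r_c}. The members of the family differ in which
#' derivative orders of the total pair potential
#' \eqn{u(r) = 1/r + \varphi(r; r_c)} are forced to vanish at the cut-off
#' boundary:
#' \describe{
#'   \item{IPSn}{value and first derivative only (orders 0, 1); adequate for
#'     non-polar systems but leaves higher-order boundary discontinuities
#'     that group-based truncation of polar molecules exposes.}
#'   \item{IPSp}{the counter-charge boundary assumption for polar systems,
#'     realized as vanishing orders 0 through 3.}
#'   \item{LIPS5th}{linear-combination IPS with a fifth-order boundary
#'     condition: orders 0 through 5 vanish.}
#'   \item{LIPSSW}{the periodic reaction-field member of the LIPS family:
#'     orders 0 through 5 vanish and the quadratic term of the image
#'     polynomial is pinned to the conducting reaction-field value 1/2.}
#' }
#'
#' @param method One of `"IPSn"`, `"IPSp"`, `"LIPS5th"`, `"LIPSSW"`.
#' @param vanish_orders,basis_degree Override the derivative orders forced
#'   to zero at \eqn{r_c} and the degree of the even-polynomial basis for
#'   \eqn{\varphi} in \eqn{s = r/r_c}. Defaults are the per-method values
#'   above with the lowest consistent basis degree.
#' @return An object of class `boundary_spec` with fields `method_id`,
#'   `vanish_orders`, `basis_degree` and `extra_constraints` (a list of
#'   `list(k, value)` pinning polynomial coefficients).
#' @examples
#' boundary_spec("LIPS5th")
#' @export
boundary_spec <- function(method = c("IPSn", "IPSp", "LIPS5th", "LIPSSW"),
                          vanish_orders = NULL, basis_degree = NULL) {
  method <- match.arg(method)
  defaults <- list(
    IPSn    = list(orders = 0:1, extra = list()),
    IPSp    = list(orders = 0:3, extra = list()),
    LIPS5th = list(orders = 0:5, extra = list()),
    LIPSSW  = list(orders = 0:5, extra = list(list(k = 1, value = 0.5)))
  )
  d <- defaults[[method]]
  if (is.null(vanish_orders)) vanish_orders <- d$orders
  vanish_orders <- sort(unique(as.integer(vanish_orders)))
  if (length(vanish_orders) == 0 || vanish_orders[1] != 0)
    stop("vanish_orders must be non-empty and include 0 (energy continuity at r_c)")
  n_cond <- length(vanish_orders) + length(d$extra)
  if (is.null(basis_degree)) basis_degree <- 2 * (n_cond - 1)
  basis_degree <- as.integer(basis_degree)
  if (basis_degree %% 2 != 0) stop("basis_degree must be even")
  if (basis_degree < max(vanish_orders))
    stop("basis_degree must be at least max(vanish_orders)")
  structure(list(method_id = method, vanish_orders = vanish_orders,
                 basis_degree = basis_degree, extra_constraints = d$extra),
            class = "boundary_spec")
}

#' @export
print.boundary_spec <- function(x, ...) {
  cat(sprintf("IPS boundary-condition spec: %s\n", x$method_id))
  cat(sprintf("  derivative orders vanishing at r_c: %s\n",
              paste(x$vanish_orders, collapse = ", ")))
  cat(sprintf("  even-polynomial basis degree in r/r_c: %d\n", x$basis_degree))
  if (length(x$extra_constraints))
    for (ec in x$extra_constraints)
      cat(sprintf("  pinned coefficient: c[s^%d] = %g\n", 2 * ec$k, ec$value))
  invisible(x)
}

# falling factorial (2k)(2k-1)...(2k-m+1); equals 1 for m = 0
.falling <- function(twok, m) {
  if (m == 0) return(1)
  if (m > twok) return(0)
  prod(seq(twok, twok - m + 1))
}

#' Solve the boundary-condition system for an IPS image term
#'
#' Constructs the image term \eqn{\varphi(r; r_c) = (1/r_c)\sum_k c_k
#' (r/r_c)^{2k}} of the total electrostatic pair potential
#' \eqn{u(r) = 1/r + \varphi(r)} by solving the linear system that forces
#' the derivative orders named in the spec to vanish at \eqn{r = r_c}.
#' The reduced coefficients \eqn{c_k} depend only on the spec, not on
#' \eqn{r_c}; the dimensional image term scales as \eqn{1/r_c}.
#'
#' @param spec A [boundary_spec()].
#' @param r_c Cut-off radius in nm (> 0).
#' @return An object of class `ips_potential` with fields `method_id`,
#'   `r_c`, `coefficients` (reduced coefficients \eqn{c_k} of
#'   \eqn{(r/r_c)^{2k}}, \eqn{k = 0, 1, \dots}), and the originating `spec`.
#' @examples
#' pot <- solve_ips_coefficients(boundary_spec("IPSn"), r_c = 1.2)
#' evaluate_pair(pot, r = 1.2, qq = 1)$energy  # 0 at the boundary
#' @export
solve_ips_coefficients <- function(spec, r_c) {
  stopifnot(inherits(spec, "boundary_spec"))
  if (!is.numeric(r_c) || length(r_c) != 1 || r_c <= 0) stop("r_c must be a positive length")
  ks <- 0:(spec$basis_degree / 2)
  n_unknown <- length(ks)
  orders <- spec$vanish_orders
  n_cond <- length(orders) + length(spec$extra_constraints)
  if (n_unknown > n_cond)
    stop(sprintf("underdetermined system: %d coefficients but only %d conditions; reduce basis_degree",
                 n_unknown, n_cond))
  # condition rows: sum_k c_k * falling(2k, m) = -(-1)^m m!  (from d^m/dr^m 1/r)
  A <- matrix(0, n_cond, n_unknown)
  b <- numeric(n_cond)
  for (i in seq_along(orders)) {
    m <- orders[i]
    A[i, ] <- vapply(ks, function(k) .falling(2 * k, m), numeric(1))
    b[i] <- -(-1)^m * factorial(m)
  }
  for (j in seq_along(spec$extra_constraints)) {
    ec <- spec$extra_constraints[[j]]
    row <- length(orders) + j
    A[row, ec$k + 1] <- 1
    b[row] <- ec$value
  }
  qr_A <- qr(A)
  if (qr_A$rank < n_unknown) {
    stop(sprintf("singular boundary-condition system for %s: conditions on orders {%s} conflict at basis degree %d",
                 spec$method_id, paste(orders, collapse = ","), spec$basis_degree))
  }
  coef <- qr.coef(qr_A, b)
  resid <- A %*% coef - b
  if (max(abs(resid)) > 1e-9)
    stop(sprintf("inconsistent overdetermined boundary system (max residual %g): basis_degree %d too small for orders {%s}",
                 max(abs(resid)), spec$basis_degree, paste(orders, collapse = ",")))
  structure(list(method_id = spec$method_id, r_c = r_c,
                 coefficients = as.numeric(coef), spec = spec),
            class = "ips_potential")
}

#' @export
print.ips_potential <- function(x, ...) {
  cat(sprintf("%s electrostatic pair potential, r_c = %g nm\n", x$method_id, x$r_c))
  cat("  u(r) = 1/r + (1/r_c) sum_k c_k (r/r_c)^(2k), c_k =\n")
  cat("   ", paste(sprintf("%.10g", x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

# image term phi(r) and its radial derivative (dimensional, 1/nm units)
.phi <- function(pot, r) {
  s <- r / pot$r_c
  out <- 0
  for (k in seq_along(pot$coefficients)) out <- out + pot$coefficients[k] * s^(2 * (k - 1))
  out / pot$r_c
}

.phi_deriv <- function(pot, r) {
  s <- r / pot$r_c
  out <- 0
  for (k in seq_along(pot$coefficients)) {
    p <- 2 * (k - 1)
    if (p > 0) out <- out + pot$coefficients[k] * p * s^(p - 1)
  }
  out / pot$r_c^2
}

#' Evaluate an IPS pair potential
#'
#' Energy and scalar force of a charge pair under the given IPS potential:
#' \eqn{E(r) = f_{coul}\, q_iq_j\, [1/r + \varphi(r)]} for \eqn{r \le r_c}
#' and exactly 0 beyond; the force is \eqn{-dE/dr}.
#'
#' @param pot An `ips_potential`.
#' @param r Distance(s) in nm, > 0.
#' @param qq Charge product \eqn{q_i q_j} in e\eqn{^2}.
#' @return A list with numeric vectors `energy` (kJ/mol) and `force`
#'   (kJ/mol/nm, positive = repulsive).
#' @export
evaluate_pair <- function(pot, r, qq) {
  stopifnot(inherits(pot, "ips_potential"))
  if (any(r <= 0)) stop("r must be positive (r = 0 is a domain error)")
  if (!all(is.finite(qq))) stop("qq must be finite")
  inside <- r <= pot$r_c
  energy <- force <- numeric(length(r))
  if (any(inside)) {
    ri <- r[inside]
    energy[inside] <- .coul * qq * (1 / ri + .phi(pot, ri))
    force[inside] <- .coul * qq * (1 / ri^2 - .phi_deriv(pot, ri))
  }
  list(energy = energy, force = force)
}

#' Static self- and excluded-pair image energy of an IPS method
#'
#' The image term \eqn{\varphi} represents periodic images of every charge
#' in the local region, including a charge's own images
#' (\eqn{\tfrac12 q_i^2 \varphi(0)} per charge, with
#' \eqn{\varphi(0) = c_0/r_c}) and the images of intramolecular partners
#' whose direct interaction is excluded
#' (\eqn{q_i q_j \varphi(r_{ij})} per excluded pair). For rigid molecules
#' these are constants: they exert no force, but they differ between IPS
#' variants (through \eqn{c_0} and the low-order coefficients) and must be
#' included when comparing absolute electrostatic energies against a
#' self-consistent reference such as Ewald summation.
#'
#' @param config An `md_config` with charge groups assigned (intra-group
#'   pairs are the excluded set).
#' @param pot An `ips_potential`, or a `pair_table` carrying its
#'   coefficients.
#' @return Static image energy in kJ/mol.
#' @export
ips_static_energy <- function(config, pot) {
  if (inherits(pot, "pair_table")) {
    pot <- structure(list(method_id = attr(pot, "method_id"),
                          r_c = attr(pot, "r_c"),
                          coefficients = attr(pot, "coefficients")),
                     class = "ips_potential")
  }
  if (is.null(pot$coefficients)) return(0)
  e_self <- 0.5 * sum(config$charge^2) * pot$coefficients[1] / pot$r_c
  e_excl <- 0
  for (at in split(seq_len(n_atoms(config)), config$group_id)) {
    if (length(at) < 2) next
    for (a in seq_along(at)[-length(at)]) for (b in (a + 1):length(at)) {
      i <- at[a]; j <- at[b]
      d <- config$positions[j, ] - config$positions[i, ]
      d <- d - config$box * round(d / config$box)
      e_excl <- e_excl + config$charge[i] * config$charge[j] *
        .phi(pot, sqrt(sum(d^2)))
    }
  }
  .coul * (e_self + e_excl)
}

#' Finite-difference check of the cut-off boundary conditions
#'
#' Reports the magnitude of the derivatives \eqn{d^k u/dr^k} of the total
#' pair potential at \eqn{r = r_c} for orders 0..`max_order`, estimated by
#' central finite differences, and flags any order the potential's spec
#' requires to vanish whose magnitude exceeds `tol` times the magnitude of
#' the same derivative at \eqn{r_c/2}.
#'
#' High-order central differences amplify round-off roughly as
#' \eqn{2^k \epsilon / h^k}, so the step is widened with the order and each
#' estimate is Richardson-extrapolated; the flag compares the estimate both
#' against `tol` times the reference scale and against the observed
#' extrapolation error, so that a condition is only reported as violated
#' when the signal exceeds what finite differences can resolve.
#'
#' @param pot An `ips_potential`.
#' @param max_order Highest derivative order to report (default 6).
#' @param tol Relative tolerance for the vanishing check (default 1e-6).
#' @return A data frame with columns `order`, `value_at_rc`,
#'   `value_at_half_rc` (the reference scale), `fd_error` (Richardson error
#'   estimate), `required_zero`, `ok`.
#' @export
verify_boundary <- function(pot, max_order = 6, tol = 1e-6) {
  stopifnot(inherits(pot, "ips_potential"))
  u <- function(r) 1 / r + .phi(pot, r)  # reduced (qq-independent) total potential
  fd_raw <- function(r0, k, step) {
    if (k == 0) return(u(r0))
    j <- 0:k
    w <- (-1)^j * choose(k, j)
    sum(w * u(r0 + (k / 2 - j) * step)) / step^k
  }
  fd <- function(r0, k) {
    # step widened with order to balance truncation against round-off
    step <- pot$r_c * .Machine$double.eps^(1 / (k + 4))
    a <- fd_raw(r0, k, step)
    b <- fd_raw(r0, k, step / 2)
    val <- (4 * b - a) / 3  # Richardson, O(step^4)
    c(val, abs(b - a))
  }
  orders <- 0:max_order
  at_rc <- t(vapply(orders, function(k) fd(pot$r_c, k), numeric(2)))
  at_half <- vapply(orders, function(k) fd(pot$r_c / 2, k)[1], numeric(1))
  required <- orders %in% pot$spec$vanish_orders
  scale <- pmax(abs(at_half), 1e-12)
  ok <- !required | abs(at_rc[, 1]) <= pmax(tol * scale, 5 * at_rc[, 2])
  data.frame(order = orders, value_at_rc = at_rc[, 1], value_at_half_rc = at_half,
             fd_error = at_rc[, 2], required_zero = required, ok = ok)
}

#' Closed-form derivatives of the total IPS pair potential
#'
#' Exact derivatives \eqn{d^k u/dr^k} of \eqn{u(r) = 1/r + \varphi(r)} at a
#' point, from the closed forms \eqn{d^k r^{-1} = (-1)^k k!\, r^{-(k+1)}}
#' and term-wise differentiation of the image polynomial.
#'
#' @param pot An `ips_potential`.
#' @param r Evaluation point (nm).
#' @param orders Integer vector of derivative orders.
#' @return Numeric vector of derivative values (reduced units, no charge
#'   prefactor), one per order.
#' @export
ips_derivatives <- function(pot, r, orders) {
  vapply(orders, function(m) {
    inv <- (-1)^m * factorial(m) / r^(m + 1)
    ks <- seq_along(pot$coefficients) - 1
    poly <- sum(vapply(ks, function(k) {
      p <- 2 * k
      if (m > p) return(0)
      pot$coefficients[k + 1] * .falling(p, m) * (r / pot$r_c)^(p - m) / pot$r_c^m
    }, numeric(1))) / pot$r_c
    inv + poly
  }, numeric(1))
}
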