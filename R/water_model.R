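#' The rigid SPC/E water model
#'
#' Geometry, point charges, Lennard-Jones parameters and masses of the
#' extended simple point charge (SPC/E) water model: O-H bond length
#' 0.1 nm, H-O-H angle 109.47 degrees, charges \eqn{q_O = -0.8476} e and
#' \eqn{q_H = +0.4238} e, and a single LJ site on the oxygen with
#' \eqn{\sigma_{OO} = 0.3166} nm, \eqn{\epsilon_{OO} = 0.650} kJ/mol.
#' The molecule is charge neutral, and 4.0 LJ length units correspond to
#' 1.2664 nm (the conventional LJ cut-off of the model).
#'
#' @return An object of class `water_model`: a list with fields
#'   `d_OH` (nm), `angle_HOH` (degrees), `d_HH` (nm), `q_O`, `q_H` (e),
#'   `sigma_OO` (nm), `epsilon_OO` (kJ/mol), `mass_O`, `mass_H` (u),
#'   `mass` (molecular mass, g/mol), and derived LJ coefficients
#'   `c6` (\eqn{4\epsilon\sigma^6}) and `c12` (\eqn{4\epsilon\sigma^{12}}).
#' @examples
#' wm <- water_model()
#' wm$q_O + 2 * wm$q_H     # net molecular charge: 0
#' 4.0 * wm$sigma_OO       # LJ cut-off, 1.2664 nm
#' @export
water_model <- function() {
  m <- list(
    d_OH = 0.1,
    angle_HOH = 109.47,
    q_O = -0.8476,
    q_H = 0.4238,
    sigma_OO = 0.3166,
    epsilon_OO = 0.650,
    mass_O = 15.9994,
    mass_H = 1.008
  )
  m$d_HH <- 2 * m$d_OH * sin(m$angle_HOH / 2 * pi / 180)
  m$mass <- m$mass_O + 2 * m$mass_H
  m$c6 <- 4 * m$epsilon_OO * m$sigma_OO^6
  m$c12 <- 4 * m$epsilon_OO * m$sigma_OO^12
  class(m) <- "water_model"
  m
}

#' @export
print.water_model <- function(x, ...) {
  cat("SPC/E water model\n")
  cat(sprintf("  d(O-H) = %.4f nm, angle(H-O-H) = %.2f deg, d(H-H) = %.5f nm\n",
              x$d_OH, x$angle_HOH, x$d_HH))
  cat(sprintf("  q_O = %.4f e, q_H = %+.4f e (net %g e)\n",
              x$q_O, x$q_H, x$q_O + 2 * x$q_H))
  cat(sprintf("  LJ: sigma_OO = %.4f nm, epsilon_OO = %.3f kJ/mol\n",
              x$sigma_OO, x$epsilon_OO))
  invisible(x)
}

# Atom positions of one water molecule (rows O, H, H) with the oxygen at
# `origin` and orientation given by a 3x3 rotation matrix.
water_geometry <- function(model = water_model(), origin = c(0, 0, 0),
                           rotation = diag(3)) {
  half <- model$angle_HOH / 2 * pi / 180
  local <- rbind(
    c(0, 0, 0),
    c(model$d_OH * sin(half), 0, model$d_OH * cos(half)),
    c(-model$d_OH * sin(half), 0, model$d_OH * cos(half))
  )
  t(rotation %*% t(local)) + matrix(origin, 3, 3, byrow = TRUE)
}
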