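## Spatial part of rank-2 anisotropic interactions under MAS.
##
## Frames and conventions (ZYZ, active rotations throughout):
##   PAS --(tensor Euler angles)--> molecule --(crystallite Euler
##   angles {alpha, beta, gamma})--> rotor --(spinning at the magic
##   angle)--> lab.
## The crystallite gamma angle is the outermost rotation, i.e. a rotation
## about the rotor axis, so regular gamma sampling tiles the rotor phase.

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rot_y <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)

## ZYZ active rotation matrix R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma)
euler_rot <- function(alpha, beta, gamma) rot_z(alpha) %*% rot_y(beta) %*% rot_z(gamma)

#' Cartesian tensor of a dipolar coupling in the molecule frame
#'
#' `b * (3 e e^T - I) / 2` for unit internuclear axis `e`; its lab-frame zz
#' component is the familiar `b * (3 cos^2 theta - 1) / 2`.
#'
#' @param b_hz Dipolar coupling constant in Hz (sign retained).
#' @param axis Unit internuclear vector in the molecule frame.
#' @return A symmetric traceless 3x3 matrix (Hz).
#' @export
dip_tensor <- function(b_hz, axis) {
  e <- axis / sqrt(sum(axis^2))
  b_hz * (3 * tcrossprod(e) - diag(3)) / 2
}

#' Cartesian tensor of a CSA in the molecule frame (Haeberlen convention)
#'
#' Principal values of the traceless part are `(-delta (1 + eta) / 2,
#' -delta (1 - eta) / 2, delta)`; the tensor is rotated from its PAS into
#' the molecule frame by ZYZ active Euler angles.
#'
#' @param aniso_ppm Anisotropy delta (zz principal value of the traceless
#'   part) in ppm.
#' @param eta Asymmetry in `[0, 1]`.
#' @param alpha,beta,gamma PAS-to-molecule Euler angles in radians.
#' @return A symmetric traceless 3x3 matrix (ppm).
#' @export
csa_tensor <- function(aniso_ppm, eta = 0, alpha = 0, beta = 0, gamma = 0) {
  p <- c(-aniso_ppm * (1 + eta) / 2, -aniso_ppm * (1 - eta) / 2, aniso_ppm)
  R <- euler_rot(alpha, beta, gamma)
  R %*% diag(p) %*% t(R)
}

#' MAS Fourier coefficients of a rank-2 anisotropy
#'
#' For a traceless symmetric molecule-frame tensor `T` and a crystallite
#' orientation, the lab-frame zz component under spinning at the magic angle
#' is a five-term Fourier series
#' \deqn{f(t) = \omega_0 + \sum_{m \in \{-2,-1,1,2\}} \omega_m e^{i m \omega_r t}.}
#' The static term \eqn{\omega_0} vanishes for any traceless tensor because
#' \eqn{P_2(\cos\theta_m) = 0} at the magic angle.
#'
#' @param tensor A 3x3 symmetric traceless matrix in the molecule frame
#'   (from [dip_tensor()] or [csa_tensor()]), or a one-row dipolar coupling
#'   table as returned by [dipolar_from_geometry()] (the motional scale is
#'   *not* applied here).
#' @param orientation Named list/row with crystallite Euler angles `alpha`,
#'   `beta`, `gamma` (radians).
#' @return List with `static` (the m = 0 term), `omega_m` (complex, named
#'   `"-2", "-1", "1", "2"`) and `cos_sin` (`c(a0, a1c, b1s, a2c, b2s)` of
#'   the equivalent real series), all in the units of `tensor`.
#' @export
#' @examples
#' cf <- mas_fourier_coefficients(dip_tensor(-2120, c(0, 0, 1)),
#'                                list(alpha = 0.3, beta = 1.1, gamma = 0.2))
#' abs(cf$static) < 1e-10   # magic-angle cancellation
mas_fourier_coefficients <- function(tensor, orientation) {
  if (is.data.frame(tensor))
    tensor <- dip_tensor(tensor$b_hz[1],
                         c(tensor$ax[1], tensor$ay[1], tensor$az[1]))
  cs <- .mas_cos_sin(tensor, orientation$alpha, orientation$beta,
                     orientation$gamma)
  om <- c(complex(real = cs[4] / 2, imaginary = cs[5] / 2),
          complex(real = cs[2] / 2, imaginary = cs[3] / 2),
          complex(real = cs[2] / 2, imaginary = -cs[3] / 2),
          complex(real = cs[4] / 2, imaginary = -cs[5] / 2))
  names(om) <- c("-2", "-1", "1", "2")
  list(static = cs[1], omega_m = om, cos_sin = cs)
}

## Real cos/sin coefficients (a0, a1, b1, a2, b2) of the lab zz component:
## f(t) = a0 + a1 cos(wr t) + b1 sin(wr t) + a2 cos(2 wr t) + b2 sin(2 wr t)
## Crystallite gamma is the outermost rotation (about the rotor axis), so a
## gamma increment is equivalent to a rotor-phase offset.
.mas_cos_sin <- function(tensor, alpha, beta, gamma) {
  R <- rot_z(gamma) %*% rot_y(beta) %*% rot_z(alpha)
  Tr <- R %*% tensor %*% t(R)
  s <- sin(.magic_angle); c <- cos(.magic_angle)
  c(s^2 * (Tr[1, 1] + Tr[2, 2]) / 2 + c^2 * Tr[3, 3],
    -2 * s * c * Tr[1, 3],
    2 * s * c * Tr[2, 3],
    s^2 * (Tr[1, 1] - Tr[2, 2]) / 2,
    -s^2 * Tr[1, 2])
}
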