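## Shared fixtures for the test suite (built in code; nothing downloaded).

## A two-carbon system with J coupling, optional dipolar coupling and
## configurable shifts (ppm).
two_carbon <- function(J = 33, dipolar = TRUE, shifts = c(50, 20),
                       aniso = c(0, 0), eta = c(0, 0)) {
  dip <- if (dipolar)
    dipolar_from_geometry("13C", "13C", 1.53,
                          axis = c(0.2, 0.5, sqrt(1 - 0.29)))
  spin_system(c("13C", "13C"), c("CA", "CB"),
              shift = data.frame(iso_ppm = shifts, aniso_ppm = aniso,
                                 eta = eta),
              j = data.frame(i = 1L, j = 2L, J_hz = J),
              dipolar = dip, name = "two_carbon")
}

## Two carbons with identical shifts on the carrier and J only: the ideal
## isotropic-mixing limit, where any (or no) RF leaves H = 2 pi J I.S.
ideal_j_pair <- function(J = 33, carrier = 38)
  spin_system(c("13C", "13C"), c("CA", "CB"),
              shift = data.frame(iso_ppm = c(carrier, carrier)),
              j = data.frame(i = 1L, j = 2L, J_hz = J),
              name = "ideal_j_pair")

## A zero-amplitude rotor-synchronous "program": free evolution.
free_program <- function(nu_r)
  spinmix:::new_sequence_program("free",
    data.frame(duration_s = 1 / nu_r, amp_hz = 0, phase_rad = 0), nu_r)

single_orientation <- function(alpha = 0.4, beta = 1.1, gamma = 0.3)
  powder_set("explicit",
             angles = data.frame(alpha = alpha, beta = beta, gamma = gamma))

tiny_powder <- function(n_ab = 21, n_gamma = 3) powder_set("zcw", n_ab, n_gamma)

## Random traceless symmetric 3x3 tensor
random_tensor <- function() {
  A <- matrix(runif(9, -1, 1), 3, 3)
  S <- (A + t(A)) / 2
  S - diag(3) * sum(diag(S)) / 3
}

## Independent brute-force evaluation of the lab zz component of a
## molecule-frame tensor under MAS: rotates the tensor with explicitly
## composed Cartesian matrices (crystallite, then rotor phase, then the
## magic-angle tilt) and reads the lab zz element.
brute_force_zz <- function(tensor, orientation, nu_r, t) {
  rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  ry <- function(b) rbind(c(cos(b), 0, sin(b)), c(0, 1, 0),
                          c(-sin(b), 0, cos(b)))
  thm <- acos(1 / sqrt(3))
  Rcr <- rz(orientation$gamma) %*% ry(orientation$beta) %*%
    rz(orientation$alpha)
  vapply(t, function(tt) {
    Rlab <- ry(thm) %*% rz(2 * pi * nu_r * tt) %*% Rcr
    (Rlab %*% tensor %*% t(Rlab))[3, 3]
  }, numeric(1))
}
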