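## Spin-1/2 operator algebra on the 2^L product basis.
##
## Basis convention: state index p (1-based) has bit (i-1) of (p-1) equal to
## 0 for spin i in |alpha> (m = +1/2) and 1 for |beta> (m = -1/2); spin 1 is
## the fastest-varying factor. The same convention is used in the compiled
## propagator.

.pauli <- local({
  Ix <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  Iy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  Iz <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
  list(Ix = Ix, Iy = Iy, Iz = Iz, I2 = diag(2))
})

#' Single-spin product operator matrix
#'
#' Embeds a 2x2 single-spin operator (`"Ix"`, `"Iy"`, `"Iz"`) for spin `i`
#' into the `2^L` product space.
#'
#' @param L Number of spins.
#' @param i Spin index (1-based).
#' @param which One of `"Ix"`, `"Iy"`, `"Iz"`.
#' @return A complex `2^L x 2^L` matrix.
#' @export
spin_op <- function(L, i, which = c("Ix", "Iy", "Iz")) {
  which <- match.arg(which)
  M <- .pauli[[which]]
  left <- diag(2^(L - i)) + 0i
  right <- diag(2^(i - 1)) + 0i
  kronecker(left, kronecker(M, right))
}

## mz eigenvalue of spin i for every basis state (vector of +-1/2)
mz_vector <- function(L, i) {
  p <- 0:(2^L - 1)
  ifelse(bitwAnd(p, bitwShiftL(1L, i - 1L)) > 0L, -0.5, 0.5)
}

## Two-spin operators used by the secular Hamiltonian
pair_op <- function(L, i, j, which = c("zz", "flipflop", "dot")) {
  which <- match.arg(which)
  Izi <- spin_op(L, i, "Iz"); Izj <- spin_op(L, j, "Iz")
  if (which == "zz") return(Izi %*% Izj)
  Ixi <- spin_op(L, i, "Ix"); Ixj <- spin_op(L, j, "Ix")
  Iyi <- spin_op(L, i, "Iy"); Iyj <- spin_op(L, j, "Iy")
  ff <- Ixi %*% Ixj + Iyi %*% Iyj
  if (which == "flipflop") ff else Izi %*% Izj + ff
}
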