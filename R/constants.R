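#' @useDynLib spinmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx optimize runif setNames
#' @importFrom utils modifyList read.table write.table
NULL

## Physical constants (CODATA 2018)
.mu0 <- 4e-7 * pi          # vacuum permeability, T m / A
.hbar <- 1.054571817e-34   # reduced Planck constant, J s
.magic_angle <- acos(1 / sqrt(3))

## Gyromagnetic ratios, rad s^-1 T^-1
.gammas <- c(
  "1H"  = 267.52218744e6,
  "13C" = 67.2828e6,
  "15N" = -27.126e6
)

#' Supported isotopes and their gyromagnetic ratios
#'
#' @return Named numeric vector of gyromagnetic ratios in rad s^-1 T^-1 for
#'   the spin-1/2 isotopes the simulator supports (`1H`, `13C`, `15N`).
#' @export
#' @examples
#' isotope_gammas()["13C"] / isotope_gammas()["1H"]  # ~0.2515
isotope_gammas <- function() .gammas

gamma_of <- function(isotope) {
  g <- .gammas[isotope]
  if (any(is.na(g))) {
    stop("unknown isotope(s): ", paste(unique(isotope[is.na(g)]), collapse = ", "),
         "; supported: ", paste(names(.gammas), collapse = ", "))
  }
  unname(g)
}

## Larmor frequency (MHz, absolute value) of `isotope` on a magnet whose
## proton frequency is `proton_mhz`.
larmor_mhz <- function(isotope, proton_mhz) {
  abs(gamma_of(isotope)) / .gammas[["1H"]] * proton_mhz
}
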