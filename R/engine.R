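#' Simulation configuration
#'
#' Bundles the static field, spinning rate, carrier position, powder set and
#' integration controls used by [propagate()] and the scan drivers.
#'
#' @param b0_proton_mhz Static field expressed as the proton Larmor
#'   frequency in MHz (e.g. 600 for 14.1 T, 800 for 18.8 T); it sets every
#'   ppm-to-Hz conversion.
#' @param nu_r MAS frequency in Hz.
#' @param carrier_ppm 13C carrier position in ppm (default 38, the middle of
#'   the aliphatic band).
#' @param powder An [powder_set()] orientation set.
#' @param steps_per_rotor_period Integration sub-steps per rotor period
#'   (>= 32; default 32). Each RF segment is subdivided so that no sub-step
#'   exceeds `min(segment, tau_R / steps_per_rotor_period)`.
#' @param max_mixing_time Longest mixing time of interest in s (default
#'   0.05).
#' @param tau_grid Optional explicit mixing-time grid (s, nonnegative,
#'   increasing). Defaults to multiples of the program cycle up to
#'   `max_mixing_time`.
#' @param proton_carrier_ppm 1H carrier in ppm; defaults to the mean proton
#'   shift of the simulated system (on-resonance per spin group).
#' @param dream_mode Initial/detection convention for DREAM: the adiabatic
#'   sweep spin-locks the 13C coherence, so by default source and
#'   destination operators point along the instantaneous effective field at
#'   t = 0 and t = tau respectively (`"effective_field"`), reporting signed
#'   efficiencies; `"iz"` uses longitudinal operators for comparison.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(b0_proton_mhz, nu_r, carrier_ppm = 38,
                       powder = powder_set("repulsion", 168L, 11L),
                       steps_per_rotor_period = 32L,
                       max_mixing_time = 0.05, tau_grid = NULL,
                       proton_carrier_ppm = NULL,
                       dream_mode = c("effective_field", "iz")) {
  steps_per_rotor_period <- as.integer(steps_per_rotor_period)
  if (steps_per_rotor_period < 32L)
    stop("steps_per_rotor_period must be >= 32")
  if (nu_r <= 0) stop("nu_r must be positive")
  if (b0_proton_mhz <= 0) stop("b0_proton_mhz must be positive")
  if (!is.null(tau_grid)) {
    if (any(tau_grid < 0)) stop("tau_grid must be nonnegative")
    if (is.unsorted(tau_grid, strictly = TRUE))
      stop("tau_grid must be strictly increasing")
  }
  structure(
    list(b0_proton_mhz = b0_proton_mhz, nu_r = nu_r,
         carrier_ppm = carrier_ppm, powder = powder,
         steps_per_rotor_period = steps_per_rotor_period,
         max_mixing_time = max_mixing_time, tau_grid = tau_grid,
         proton_carrier_ppm = proton_carrier_ppm,
         dream_mode = match.arg(dream_mode)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> B0 = %g MHz (1H), nu_r = %g kHz, carrier %g ppm, %d crystallites, %d steps/rotor period\n",
              x$b0_proton_mhz, x$nu_r / 1e3, x$carrier_ppm,
              nrow(x$powder), x$steps_per_rotor_period))
  invisible(x)
}

## Larmor frequency in MHz (= Hz per ppm) for every spin of a system.
.larmor_mhz_per_spin <- function(sys, config)
  vapply(sys$isotope, larmor_mhz, numeric(1), proton_mhz = config$b0_proton_mhz)

## Per-spin carrier in ppm: 13C channel carrier from the config; 1H carrier
## on resonance with the mean proton shift; other isotopes on resonance.
.carrier_ppm_per_spin <- function(sys, config) {
  ref <- numeric(n_spins(sys))
  isC <- sys$isotope == "13C"
  ref[isC] <- config$carrier_ppm
  isH <- sys$isotope == "1H"
  if (any(isH))
    ref[isH] <- config$proton_carrier_ppm %||% mean(sys$shift$iso_ppm[isH])
  other <- !isC & !isH
  if (any(other)) ref[other] <- sys$shift$iso_ppm[other]
  ref
}

## Orientation-independent part of the engine input.
.prep_system <- function(sys, config) {
  L <- n_spins(sys)
  nu0 <- .larmor_mhz_per_spin(sys, config)          # Hz per ppm
  ref <- .carrier_ppm_per_spin(sys, config)
  wz <- 2 * pi * (sys$shift$iso_ppm - ref) * nu0    # rad/s offsets
  csa_T <- lapply(seq_len(L), function(i)
    csa_tensor(sys$shift$aniso_ppm[i], sys$shift$eta[i],
               sys$shift$alpha[i], sys$shift$beta[i], sys$shift$gamma[i]) *
      nu0[i])                                       # Hz
  dip_T <- lapply(seq_len(nrow(sys$dipolar)), function(k) {
    d <- sys$dipolar[k, ]
    dip_tensor(d$b_hz * d$scale, c(d$ax, d$ay, d$az))  # Hz, motional scale applied
  })
  ## couplings: combine J and dipolar per unordered pair
  keys <- function(tab) paste(tab$i, tab$j)
  pk <- union(keys(sys$j), keys(sys$dipolar))
  pairs <- do.call(rbind, lapply(pk, function(k) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    data.frame(i = ij[1], j = ij[2])
  }))
  homo <- sys$isotope[pairs$i] == sys$isotope[pairs$j]
  Jhz <- numeric(length(pk))
  m <- match(keys(sys$j), pk); Jhz[m] <- sys$j$J_hz
  dip_idx <- match(keys(sys$dipolar), pk)
  pair_dipT <- vector("list", length(pk))
  pair_dipT[dip_idx] <- dip_T
  ## zz_static: homonuclear J contributes 2*pi*J (from 2piJ I.S);
  ## heteronuclear weak-coupling J contributes 2*pi*J as well (2piJ IzSz).
  zz_static <- 2 * pi * Jhz
  ff_static <- ifelse(homo, pi * Jhz, 0)
  list(L = L, wz = wz, csa_T = csa_T, pairs = pairs, homo = homo,
       zz_static = zz_static, ff_static = ff_static, pair_dipT = pair_dipT,
       rf_mask = sys$isotope == "13C")
}

## Orientation-dependent Fourier coefficients (rad/s).
## Returns list(csa = L x 5, dip = npair x 5).
.prep_orientation <- function(prep, orientation) {
  a <- orientation$alpha; b <- orientation$beta; g <- orientation$gamma
  csa <- t(vapply(prep$csa_T, function(T)
    if (all(T == 0)) numeric(5) else 2 * pi * .mas_cos_sin(T, a, b, g),
    numeric(5)))
  dip <- t(vapply(prep$pair_dipT, function(T)
    if (is.null(T)) numeric(5) else 2 * pi * .mas_cos_sin(T, a, b, g),
    numeric(5)))
  list(csa = csa, dip = dip)
}

#' Secular rotating-frame Hamiltonian at a time point
#'
#' Assembles the full Hamiltonian matrix (angular-frequency units, rad/s)
#' for one crystallite orientation at time `t` under an RF segment:
#' isotropic offsets relative to the carrier, the time-dependent CSA as
#' `Iz` terms, homonuclear dipolar couplings as
#' `omega_D(t) (2 IzSz - (I+S- + I-S+)/2)`, heteronuclear dipolar couplings
#' as `omega_D(t) 2 IzSz`, homonuclear J as `2 pi J (I . S)`, heteronuclear
#' J in the weak-coupling form `2 pi J IzSz`, and the RF field
#' `2 pi nu_1 (Ix cos(phi) + Iy sin(phi))` summed over the 13C spins.
#'
#' This dense-matrix builder is the engine's reference path, used for
#' validation and small systems; production propagation uses an equivalent
#' compiled split-operator backend.
#'
#' @param sys A [spin_system()].
#' @param config A [sim_config()].
#' @param orientation Named list/row with `alpha`, `beta`, `gamma`.
#' @param t Time in s (defines the rotor phase).
#' @param rf_segment Named list/row with `amp_hz` and `phase_rad` (a zero
#'   amplitude means free evolution).
#' @return A Hermitian complex matrix of dimension `2^L`.
#' @export
hamiltonian <- function(sys, config, orientation, t,
                        rf_segment = list(amp_hz = 0, phase_rad = 0)) {
  prep <- .prep_system(sys, config)
  cf <- .prep_orientation(prep, orientation)
  L <- prep$L; D <- 2^L
  wr_t <- 2 * pi * config$nu_r * t
  ev <- function(c5) c5[1] + c5[2] * cos(wr_t) + c5[3] * sin(wr_t) +
    c5[4] * cos(2 * wr_t) + c5[5] * sin(2 * wr_t)
  H <- matrix(0 + 0i, D, D)
  for (i in seq_len(L)) {
    w <- prep$wz[i] + ev(cf$csa[i, ])
    if (w != 0) H <- H + w * spin_op(L, i, "Iz")
  }
  for (k in seq_len(nrow(prep$pairs))) {
    i <- prep$pairs$i[k]; j <- prep$pairs$j[k]
    wd <- ev(cf$dip[k, ])
    zz <- prep$zz_static[k] + 2 * wd
    ff <- prep$ff_static[k] - (if (prep$homo[k]) wd / 2 else 0)
    if (zz != 0) H <- H + zz * pair_op(L, i, j, "zz")
    if (ff != 0) H <- H + ff * 2 * pair_op(L, i, j, "flipflop")
  }
  amp <- rf_segment$amp_hz
  if (amp > 0) {
    w1 <- 2 * pi * amp; ph <- rf_segment$phase_rad
    for (i in which(prep$rf_mask))
      H <- H + w1 * (cos(ph) * spin_op(L, i, "Ix") +
                     sin(ph) * spin_op(L, i, "Iy"))
  }
  H
}

## Dense reference propagator: midpoint-Hamiltonian eigendecomposition per
## sub-step (same sub-step rule as the compiled backend). Slow; used to
## validate the split-operator path in the test suite.
.propagate_reference <- function(sys, config, orientation, segments, t0 = 0) {
  L <- n_spins(sys); D <- 2^L
  dt_max <- 1 / config$nu_r / config$steps_per_rotor_period
  U <- diag(D) + 0i
  t <- t0
  for (s in seq_len(nrow(segments))) {
    dur <- segments[s, 1]
    n_sub <- max(1L, ceiling(dur / dt_max - 1e-12))
    dt <- dur / n_sub
    for (k in seq_len(n_sub)) {
      tm <- t + (k - 0.5) * dt
      H <- hamiltonian(sys, config, orientation, tm,
                       list(amp_hz = segments[s, 2],
                            phase_rad = segments[s, 3]))
      e <- eigen(H, symmetric = TRUE)
      Us <- e$vectors %*% (exp(-1i * e$values * dt) * Conj(t(e$vectors)))
      U <- Us %*% U
    }
    t <- t + dur
  }
  U
}
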