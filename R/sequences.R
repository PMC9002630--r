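#' RF programs for homonuclear 13C mixing schemes
#'
#' A `sequence_program` is an ordered table of piecewise-constant RF segments
#' (duration in s, amplitude nu_1 in Hz, phase in radians) on the 13C
#' channel, together with the cycle duration and rotor-synchronization
#' metadata. One "cycle" is the shortest self-contained repeating unit of
#' the scheme (including its phase supercycle); mixing times are realized by
#' repeating cycles.
#'
#' @name sequence_program
NULL

new_sequence_program <- function(name, segments, nu_r, params = list(),
                                 cyclic = TRUE, phase0 = 0) {
  segments$phase_rad <- (segments$phase_rad + phase0) %% (2 * pi)
  cycle <- sum(segments$duration_s)
  tau_r <- 1 / nu_r
  rotor_sync <- cyclic && abs(cycle / tau_r - round(cycle / tau_r)) <
    1e-9 * max(1, cycle / tau_r)
  prog <- structure(
    list(name = name, segments = segments, cycle_s = cycle,
         rotor_synchronous = rotor_sync, cyclic = cyclic,
         nu_r = nu_r, params = params),
    class = "sequence_program")
  validate_sequence_program(prog)
  prog
}

validate_sequence_program <- function(prog) {
  seg <- prog$segments
  if (any(seg$duration_s <= 0)) stop("segment durations must be positive")
  if (any(seg$amp_hz < 0)) stop("segment amplitudes must be >= 0")
  if (abs(sum(seg$duration_s) - prog$cycle_s) > 1e-12 * prog$cycle_s)
    stop("cycle duration must equal the sum of segment durations")
  if (prog$rotor_synchronous) {
    ratio <- prog$cycle_s * prog$nu_r
    if (abs(ratio - round(ratio)) > 1e-9 * max(1, ratio))
      stop("rotor-synchronous cycle must span an integer number of rotor periods")
  }
  invisible(prog)
}

#' @export
print.sequence_program <- function(x, ...) {
  cat(sprintf("<sequence_program> %s: %d segment(s), cycle %.6g us (%.6g rotor periods)%s\n",
              x$name, nrow(x$segments), x$cycle_s * 1e6,
              x$cycle_s * x$nu_r,
              if (x$rotor_synchronous) ", rotor-synchronous" else ""))
  invisible(x)
}

## Expand a composite-pulse flip/phase element into segments at amplitude nu1.
composite_segments <- function(flip_deg, phase_rad, nu1) {
  data.frame(duration_s = flip_deg / 360 / nu1,
             amp_hz = nu1, phase_rad = phase_rad)
}

#' TOBSY C9(1, n) symmetry sequence with POST elements
#'
#' Nine POST composite elements (90, 360, 270 degree pulses; the middle
#' pulse phase-inverted) are distributed over `n` rotor periods, with the
#' overall phase of element `j` incremented by `2*pi*j/9`. The symmetry
#' class requires `n = 9p +/- 3` and fixes the RF amplitude through
#' `nu_1 = (2 * 9 / n) * nu_r`, making large `n` attractive at fast MAS.
#'
#' @param n Number of rotor periods per cycle; must satisfy `n = 9p +/- 3`
#'   (e.g. 21, 24, 30, 33, 39, 48).
#' @param nu_r MAS frequency in Hz.
#' @param phase0 Global phase offset in radians (default 0).
#' @return A `sequence_program` (27 segments, cycle `n / nu_r`).
#' @export
#' @examples
#' p <- tobsy_c9(48, 94500)
#' p$params$nu1_hz            # 2*9/48 * 94500
tobsy_c9 <- function(n, nu_r, phase0 = 0) {
  n <- as.integer(n)
  if (nu_r <= 0) stop("nu_r must be positive")
  if (!(n %% 9L) %in% c(3L, 6L))
    stop("TOBSY C9(1,n) requires n = 9p ± 3 (got n = ", n, ")")
  nu1 <- 2 * 9 / n * nu_r
  segs <- do.call(rbind, lapply(0:8, function(jj) {
    phi <- 2 * pi * jj / 9
    composite_segments(c(90, 360, 270), c(phi, phi + pi, phi), nu1)
  }))
  new_sequence_program(sprintf("tobsy_c9_%d", n), segs, nu_r,
                       params = list(N = 9L, nu = 1L, n = n, nu1_hz = nu1),
                       phase0 = phase0)
}

.waltz_q_flip <- c(270, 360, 180, 270, 90, 180, 360, 180, 270)
.dipsi3_r_flip <- c(245, 395, 250, 275, 30, 230, 360, 245, 370, 340, 350,
                    260, 270, 30, 225, 365, 255, 395)

## phases alternating -x, +x, ... (or +x, -x ... if start_x = TRUE)
.alternating_phases <- function(k, start_x = FALSE) {
  ph <- rep(c(pi, 0), length.out = k)
  if (start_x) ph <- rep(c(0, pi), length.out = k)
  ph
}

## expand element flips into the 4-step supercycle  E Ebar Ebar E
.supercycle_eeb <- function(flip, phase, nu1, pattern = c(0, 1, 1, 0)) {
  do.call(rbind, lapply(pattern, function(bar)
    composite_segments(flip, phase + bar * pi, nu1)))
}

#' WALTZ-16 isotropic mixing, rotor-synchronized
#'
#' The WALTZ-16 supercycle Q Qbar Qbar Q with
#' Q = 270 360 180 270 90 180 360 180 270 (degrees, phases alternating
#' -x/+x), applied with the 90-degree pulse length equal to one rotor
#' period (`tau_90 = tau_R`, i.e. `nu_1 = nu_r / 4`). One cycle spans
#' exactly 96 rotor periods.
#'
#' @inheritParams tobsy_c9
#' @return A `sequence_program` (36 segments).
#' @export
waltz16 <- function(nu_r, phase0 = 0) {
  if (nu_r <= 0) stop("nu_r must be positive")
  nu1 <- nu_r / 4
  segs <- .supercycle_eeb(.waltz_q_flip,
                          .alternating_phases(length(.waltz_q_flip)), nu1)
  new_sequence_program("waltz16", segs, nu_r,
                       params = list(nu1_hz = nu1, tau90_tauR = 1),
                       phase0 = phase0)
}

#' DIPSI-3 isotropic mixing, rotor-synchronized
#'
#' The DIPSI-3 supercycle R Rbar Rbar R with the canonical 18-pulse element
#' (flip angles 245, 395, ..., 395 degrees summing to 4890, phases strictly
#' alternating +x/-x), applied at `tau_90 = tau_R` (`nu_1 = nu_r / 4`).
#' The supercycle spans 4 x 4890/90 = 217.33 rotor periods; because this is
#' not an integer, the program is flagged non-rotor-synchronous and the
#' engine uses the least common period of cycle and rotor period.
#'
#' @inheritParams tobsy_c9
#' @return A `sequence_program` (84 segments).
#' @export
dipsi3 <- function(nu_r, phase0 = 0) {
  if (nu_r <= 0) stop("nu_r must be positive")
  nu1 <- nu_r / 4
  segs <- .supercycle_eeb(.dipsi3_r_flip,
                          .alternating_phases(length(.dipsi3_r_flip),
                                              start_x = TRUE), nu1)
  new_sequence_program("dipsi3", segs, nu_r,
                       params = list(nu1_hz = nu1, tau90_tauR = 1),
                       phase0 = phase0)
}

#' FLOPSY-16 isotropic mixing, rotor-synchronized
#'
#' Eight composite elements of 23.556 tau_90 each (total 188.448 tau_90)
#' at `tau_90 = tau_R` (`nu_1 = nu_r / 4`), with an MLEV-type element
#' phase-inversion pattern. The flip-angle table of the base element is
#' loaded from a data file; the file shipped with the package
#' (`flopsy16_element_synthetic.tsv`) is a synthetic stand-in that
#' reproduces the documented aggregate structure of the original element
#' (total flip per element, strictly alternating +x/-x phases, palindromic
#' flip list) and can be replaced by the verbatim table from the original
#' publication via `element_file`.
#'
#' @inheritParams tobsy_c9
#' @param element_file Optional path to a two-column TSV (`flip_deg`,
#'   `phase_sign`) describing the base element.
#' @return A `sequence_program`.
#' @export
flopsy16 <- function(nu_r, phase0 = 0, element_file = NULL) {
  if (nu_r <= 0) stop("nu_r must be positive")
  if (is.null(element_file))
    element_file <- system.file("extdata", "flopsy16_element_synthetic.tsv",
                                package = "spinmix")
  if (!nzchar(element_file) || !file.exists(element_file))
    stop("FLOPSY element table not found; supply `element_file`")
  tab <- read.table(element_file, header = TRUE, sep = "\t")
  if (!all(c("flip_deg", "phase_sign") %in% names(tab)))
    stop("FLOPSY element table must have columns flip_deg and phase_sign")
  nu1 <- nu_r / 4
  phase <- ifelse(tab$phase_sign >= 0, 0, pi)
  ## MLEV-8 style inversion pattern: R Rb Rb R Rb R R Rb
  pattern <- c(0, 1, 1, 0, 1, 0, 0, 1)
  segs <- do.call(rbind, lapply(pattern, function(bar)
    composite_segments(tab$flip_deg, phase + bar * pi, nu1)))
  new_sequence_program("flopsy16", segs, nu_r,
                       params = list(nu1_hz = nu1, tau90_tauR = 1,
                                     element_file = element_file),
                       phase0 = phase0)
}

#' Finite-pulse RFDR with xy8 phase cycling
#'
#' One high-power pi pulse, centered in each rotor period, with phases
#' following the xy8 cycle x, y, x, y, y, x, y, x over eight rotor periods
#' (= one cycle). The pulse must fit well inside the rotor period, which
#' requires `nu_1 > nu_r / 2`; in practice `nu_1` on the order of `nu_r`
#' or larger is used (100-150 kHz in this package's reference setups).
#'
#' @inheritParams tobsy_c9
#' @param nu_1 RF amplitude of the pi pulses in Hz.
#' @return A `sequence_program` (24 segments, cycle `8 / nu_r`).
#' @export
#' @examples
#' p <- rfdr(55555, 100e3)   # tau_180 = 5 us
rfdr <- function(nu_r, nu_1, phase0 = 0) {
  if (nu_r <= 0) stop("nu_r must be positive")
  if (nu_1 <= nu_r / 2)
    stop("RFDR requires nu_1 > nu_r / 2 (got nu_1 = ", nu_1,
         " Hz at nu_r = ", nu_r, " Hz)")
  tau_r <- 1 / nu_r
  tau180 <- 1 / (2 * nu_1)
  pad <- (tau_r - tau180) / 2
  xy8 <- c(0, pi / 2, 0, pi / 2, pi / 2, 0, pi / 2, 0)
  segs <- do.call(rbind, lapply(xy8, function(ph)
    data.frame(duration_s = c(pad, tau180, pad),
               amp_hz = c(0, nu_1, 0),
               phase_rad = c(0, ph, 0))))
  new_sequence_program("rfdr", segs, nu_r,
                       params = list(nu1_hz = nu_1, tau180_s = tau180),
                       phase0 = phase0)
}

#' DREAM adiabatic amplitude sweep through the HORROR condition
#'
#' A tangent-shaped amplitude sweep
#' \deqn{\nu(t) = \bar\nu_1 + d_{eff} \tan\!\big(\tfrac{2}{\tau}
#'   \arctan(\Delta/d_{eff})\,(t - \tau/2)\big)}
#' discretized into `n_steps` equal-duration constant-amplitude segments
#' (sampled at segment midpoints, constant phase, strictly increasing
#' amplitude). Defaults follow the fast-MAS recommendation: modulation
#' depth `nu_r / 5`, effective dipolar coupling 1 kHz, and mean RF
#' `nu_r / 2` so the sweep passes through the HORROR recoupling condition
#' `nu_1 = nu_r / 2`. Unlike the cyclic schemes, a DREAM program realizes
#' one specific mixing time `tau`.
#'
#' @inheritParams tobsy_c9
#' @param tau Total sweep (mixing) duration in s.
#' @param d_eff Effective dipolar coupling in Hz (default 1000).
#' @param depth Modulation depth Delta in Hz (default `nu_r / 5`).
#' @param mean_rf Mean RF amplitude in Hz (default `nu_r / 2`).
#' @param n_steps Number of discretization steps (>= 100; default 1000).
#' @return A `sequence_program` flagged non-cyclic.
#' @export
dream <- function(nu_r, tau, d_eff = 1000, depth = nu_r / 5,
                  mean_rf = nu_r / 2, n_steps = 1000L, phase0 = 0) {
  if (nu_r <= 0) stop("nu_r must be positive")
  if (tau <= 0) stop("tau must be positive")
  if (depth <= 0) stop("modulation depth must be positive")
  n_steps <- as.integer(n_steps)
  if (n_steps < 100L) stop("n_steps must be >= 100")
  tm <- (seq_len(n_steps) - 0.5) / n_steps * tau
  amp <- dream_amplitude(tm, tau, d_eff, depth, mean_rf)
  segs <- data.frame(duration_s = rep(tau / n_steps, n_steps),
                     amp_hz = amp, phase_rad = 0)
  new_sequence_program("dream", segs, nu_r,
                       params = list(tau_s = tau, d_eff_hz = d_eff,
                                     depth_hz = depth, mean_rf_hz = mean_rf,
                                     n_steps = n_steps),
                       cyclic = FALSE, phase0 = phase0)
}

#' DREAM tangent amplitude profile
#' @inheritParams dream
#' @param t Time(s) in `[0, tau]` at which to evaluate the profile.
#' @return RF amplitude(s) in Hz.
#' @export
dream_amplitude <- function(t, tau, d_eff = 1000, depth = tau, mean_rf = 0) {
  mean_rf + d_eff * tan((2 / tau) * atan(depth / d_eff) * (t - tau / 2))
}

#' Scale the RF amplitude of a program
#'
#' Multiplies every segment amplitude by `factor`, emulating B1
#' inhomogeneity or miscalibration while keeping all timings fixed.
#'
#' @param prog A `sequence_program`.
#' @param factor Positive scale factor.
#' @return A `sequence_program`.
#' @export
scale_amplitude <- function(prog, factor) {
  if (factor < 0) stop("amplitude scale factor must be >= 0")
  prog$segments$amp_hz <- prog$segments$amp_hz * factor
  prog$params$b1_scale <- factor * (prog$params$b1_scale %||% 1)
  prog
}

#' Export an RF program as a plain-text table
#'
#' @param prog A `sequence_program`.
#' @param file Output path.
#' @param format `"tsv"` (columns duration_us, amplitude_hz, phase_deg) or
#'   `"simpson"` (a pulse list of `pulse <duration_us> <amp_Hz> <phase_deg>`
#'   lines for cross-validation in an external simulator).
#' @return The file path, invisibly.
#' @export
export_sequence <- function(prog, file, format = c("tsv", "simpson")) {
  format <- match.arg(format)
  seg <- prog$segments
  if (format == "tsv") {
    tab <- data.frame(duration_us = seg$duration_s * 1e6,
                      amplitude_hz = seg$amp_hz,
                      phase_deg = seg$phase_rad * 180 / pi)
    write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    lines <- c(sprintf("# %s, nu_r = %g Hz", prog$name, prog$nu_r),
               sprintf("pulse %.6f %.3f %.3f", seg$duration_s * 1e6,
                       seg$amp_hz, seg$phase_rad * 180 / pi))
    writeLines(lines, file)
  }
  invisible(file)
}
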