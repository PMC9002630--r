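## Propagation orchestration: powder loop, cycle caching, buildup curves.

## Smallest q <= max_q such that q program cycles span an integer number of
## rotor periods; NA if none (incommensurate at this tolerance).
.cycle_q <- function(program, config, max_q = 64L) {
  ratio <- program$cycle_s * config$nu_r
  for (q in seq_len(max_q)) {
    if (abs(ratio * q - round(ratio * q)) < 1e-6 * q) return(q)
  }
  NA_integer_
}

.cpp_args <- function(prep, cf, config) {
  list(L = prep$L, wz = prep$wz, csa_t = t(cf$csa),
       rf = as.integer(prep$rf_mask),
       pair_i = as.integer(prep$pairs$i - 1L),
       pair_j = as.integer(prep$pairs$j - 1L),
       homo = as.integer(prep$homo),
       zz_static = prep$zz_static, ff_static = prep$ff_static,
       dip_t = t(cf$dip),
       omega_r = 2 * pi * config$nu_r,
       dt_max = 1 / config$nu_r / config$steps_per_rotor_period)
}

.seg_matrix <- function(program)
  as.matrix(program$segments[c("duration_s", "amp_hz", "phase_rad")])

## Propagator over [t0, t0 + duration of `segments`] for one crystallite.
.window_U <- function(args, segments, t0) {
  do.call(cpp_propagate_window, c(args, list(segments = segments, t0 = t0)))
}

#' Cycle propagator of a rotor-compatible RF program
#'
#' Returns the unitary propagator over the least common period of the
#' program cycle and the rotor period for one crystallite orientation,
#' together with that period. Applying it k times equals stepwise
#' propagation over k periods (the engine uses identical sub-steps for
#' both paths).
#'
#' @param sys A [spin_system()].
#' @param program A cyclic `sequence_program`.
#' @param config A [sim_config()].
#' @param orientation Named list/row with `alpha`, `beta`, `gamma`.
#' @return List with `U` (complex matrix) and `period_s`.
#' @export
cycle_propagator <- function(sys, program, config, orientation) {
  if (!program$cyclic)
    stop("cycle_propagator() requires a cyclic program")
  q <- .cycle_q(program, config)
  if (is.na(q))
    stop("program cycle and rotor period are incommensurate; ",
         "use stepwise propagation (explicit tau_grid) instead")
  prep <- .prep_system(sys, config)
  cf <- .prep_orientation(prep, orientation)
  args <- .cpp_args(prep, cf, config)
  segments <- .seg_matrix(program)
  U <- diag(2^prep$L) + 0i
  for (j in seq_len(q) - 1L)
    U <- .window_U(args, segments, j * program$cycle_s) %*% U
  list(U = U, period_s = q * program$cycle_s)
}

#' Powder-averaged polarization-transfer buildup
#'
#' Propagates the density operator, starting from longitudinal polarization
#' on the source spin, through repeated cycles of an RF mixing program for
#' every crystallite of the configured powder set, and returns the
#' powder-averaged transfer efficiency
#' `<Iz(dest)>(tau) / <Iz(source)>(0)` for every destination spin on the
#' mixing-time grid. For cyclic programs the per-crystallite cycle
#' propagators are computed once and reused across the whole grid; mixing
#' times that are not multiples of the program cycle fall back to explicit
#' stepwise propagation (with a notice). For a DREAM program (non-cyclic,
#' fixed sweep length) the source and destination operators follow the
#' configured `dream_mode` and the efficiency is reported signed.
#'
#' @param sys A [spin_system()].
#' @param program A `sequence_program`.
#' @param config A [sim_config()].
#' @param source Source spin (label or index).
#' @param dest Destination spins (labels or indices; default all spins).
#' @return An object of class `buildup_curve`: list with `times` (s),
#'   `efficiency` (matrix, one column per destination spin), `source`,
#'   `program`, `config`.
#' @export
propagate <- function(sys, program, config, source, dest = NULL) {
  validate_spin_system(sys)
  src <- spin_index(sys, source)
  dst <- if (is.null(dest)) seq_len(n_spins(sys)) else spin_index(sys, dest)
  if (!program$cyclic)
    return(.propagate_dream(sys, program, config, src, dst))

  taus <- config$tau_grid %||%
    seq(0, config$max_mixing_time, by = program$cycle_s)
  kf <- taus / program$cycle_s
  ks <- round(kf)
  if (all(abs(kf - ks) <= 1e-9 * pmax(1, kf))) {
    eff <- .propagate_cyclic(sys, program, config, src, dst, max(ks))
    eff <- eff[ks + 1L, , drop = FALSE]
  } else {
    message("tau grid not commensurate with the program cycle; ",
            "falling back to stepwise propagation")
    eff <- .propagate_stepwise(sys, program, config, src, dst, taus)
  }
  .new_buildup(taus, eff, sys, src, dst, program, config)
}

.new_buildup <- function(times, eff, sys, src, dst, program, config) {
  colnames(eff) <- sys$label[dst]
  structure(list(times = times, efficiency = eff,
                 source = sys$label[src], system = sys$name,
                 program = program$name,
                 program_params = program$params,
                 nu_r = program$nu_r,
                 config = config),
            class = "buildup_curve")
}

#' @export
print.buildup_curve <- function(x, ...) {
  cat(sprintf("<buildup_curve> %s on %s, source %s, %d mixing times up to %.3g ms\n",
              x$program, x$system, x$source, length(x$times),
              max(x$times) * 1e3))
  invisible(x)
}

## Powder loop for cyclic programs: per-cycle snapshots up to n_cycles.
.propagate_cyclic <- function(sys, program, config, src, dst, n_cycles) {
  q <- .cycle_q(program, config)
  if (is.na(q)) {
    taus <- (0:n_cycles) * program$cycle_s
    return(.propagate_stepwise_raw(sys, program, config, src, dst, taus))
  }
  prep <- .prep_system(sys, config)
  L <- prep$L; D <- 2^L
  rho0 <- mz_vector(L, src)
  obs <- vapply(dst, function(i) mz_vector(L, i), numeric(D))
  segments <- .seg_matrix(program)
  pow <- config$powder
  acc <- matrix(0, n_cycles + 1L, length(dst))
  for (w in seq_len(nrow(pow))) {
    cf <- .prep_orientation(prep, pow[w, ])
    args <- .cpp_args(prep, cf, config)
    Us <- lapply(seq_len(q) - 1L, function(j)
      .window_U(args, segments, j * program$cycle_s))
    snap <- cpp_cycle_snapshots(Us, n_cycles, rho0, obs)
    acc <- acc + pow$weight[w] * snap
  }
  acc / (D / 4)
}

## Stepwise fallback: each tau propagated as a truncated repetition of the
## program's segment list (RF is constant within a segment, so cutting a
## segment at tau is exact).
.propagate_stepwise <- function(sys, program, config, src, dst, taus) {
  .propagate_stepwise_raw(sys, program, config, src, dst, taus)
}

.propagate_stepwise_raw <- function(sys, program, config, src, dst, taus) {
  prep <- .prep_system(sys, config)
  L <- prep$L; D <- 2^L
  rho0 <- mz_vector(L, src)
  obs <- vapply(dst, function(i) mz_vector(L, i), numeric(D))
  pow <- config$powder
  acc <- matrix(0, length(taus), length(dst))
  seg0 <- .seg_matrix(program)
  for (w in seq_len(nrow(pow))) {
    cf <- .prep_orientation(prep, pow[w, ])
    args <- .cpp_args(prep, cf, config)
    for (k in seq_along(taus)) {
      tau <- taus[k]
      if (tau == 0) {
        acc[k, ] <- acc[k, ] + pow$weight[w] * crossprod(rho0, obs)
        next
      }
      segs <- .truncate_program(seg0, program$cycle_s, tau)
      U <- .window_U(args, segs, 0)
      P <- abs(U)^2
      acc[k, ] <- acc[k, ] + pow$weight[w] * crossprod(P %*% rho0, obs)
    }
  }
  acc / (D / 4)
}

.truncate_program <- function(seg0, cycle_s, tau) {
  n_full <- floor(tau / cycle_s + 1e-12)
  rem <- tau - n_full * cycle_s
  segs <- seg0[rep(seq_len(nrow(seg0)), n_full), , drop = FALSE]
  if (rem > 1e-12 * cycle_s) {
    cum <- cumsum(seg0[, 1])
    last <- which(cum >= rem - 1e-15)[1]
    part <- seg0[seq_len(last), , drop = FALSE]
    part[last, 1] <- part[last, 1] - (cum[last] - rem)
    segs <- rbind(segs, part)
  }
  segs
}

## DREAM: one sweep of fixed length; source/detect along the instantaneous
## effective field (or Iz, per config$dream_mode), signed efficiency.
.propagate_dream <- function(sys, program, config, src, dst) {
  prep <- .prep_system(sys, config)
  L <- prep$L; D <- 2^L
  tau <- program$params$tau_s
  seg <- .seg_matrix(program)
  amp0 <- seg[1, 2]; amp1 <- seg[nrow(seg), 2]
  tilt <- function(i, amp) {
    if (config$dream_mode == "iz" || !prep$rf_mask[i]) return(c(0, 0, 1))
    v <- c(2 * pi * amp, 0, prep$wz[i])
    v / sqrt(sum(v^2))
  }
  op_dir <- function(i, n)
    n[1] * spin_op(L, i, "Ix") + n[2] * spin_op(L, i, "Iy") +
      n[3] * spin_op(L, i, "Iz")
  rho0 <- op_dir(src, tilt(src, amp0))
  obs <- lapply(dst, function(i) op_dir(i, tilt(i, amp1)))
  pow <- config$powder
  eff <- numeric(length(dst))
  for (w in seq_len(nrow(pow))) {
    cf <- .prep_orientation(prep, pow[w, ])
    args <- .cpp_args(prep, cf, config)
    U <- .window_U(args, seg, 0)
    M <- U %*% rho0 %*% Conj(t(U))
    eff <- eff + pow$weight[w] *
      vapply(obs, function(o) Re(sum(Conj(o) * M)), numeric(1))
  }
  eff <- eff / (D / 4)
  em <- rbind(as.numeric(seq_along(dst) == match(src, dst)), eff)
  em[1, is.na(em[1, ])] <- 0
  .new_buildup(c(0, tau), em, sys, src, dst, program, config)
}
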