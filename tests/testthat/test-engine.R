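ori1 <- list(alpha = 0.4, beta = 1.1, gamma = 0.3)

test_that("hamiltonian has the correct secular structure", {
  cfg <- sim_config(600, 55555, powder = single_orientation())
  ## two 13C, J only, no RF: eigenvalues of 2 pi J (I.S) are the
  ## singlet/triplet values 2 pi J * (-3/4, 1/4, 1/4, 1/4)
  sys <- ideal_j_pair(J = 33)
  H <- hamiltonian(sys, cfg, ori1, t = 0)
  ev <- sort(eigen(H, symmetric = TRUE)$values) / (2 * pi * 33)
  expect_equal(ev, c(-0.75, 0.25, 0.25, 0.25), tolerance = 1e-10)
  expect_equal(H, Conj(t(H)), tolerance = 1e-12)       # Hermitian
  expect_equal(sum(diag(H)), 0 + 0i, tolerance = 1e-10) # traceless

  ## heteronuclear H-C pair: secular dipolar term commutes with both Iz
  hc <- spin_system(c("1H", "13C"), c("H", "C"),
                    shift = data.frame(iso_ppm = c(1, 38)),
                    dipolar = dipolar_from_geometry("1H", "13C", 1.09,
                                                    axis = c(0.6, 0, 0.8)))
  Hhc <- hamiltonian(hc, cfg, ori1, t = 1e-6)
  for (i in 1:2) {
    Iz <- spin_op(2, i, "Iz")
    expect_equal(Hhc %*% Iz, Iz %*% Hhc, tolerance = 1e-10)
  }
})

test_that("split-operator propagation agrees with dense eigendecomposition", {
  ## reference: midpoint-Hamiltonian eigendecomposition per sub-step
  sys <- spin_system(
    c("13C", "13C", "1H"), c("CA", "CB", "HB"),
    shift = data.frame(iso_ppm = c(50, 20, 1.5), aniso_ppm = c(20, 20, 5),
                       eta = c(0.5, 0.3, 0)),
    j = data.frame(i = c(1L, 2L), j = c(2L, 3L), J_hz = c(33, 145)),
    dipolar = rbind(
      dipolar_from_geometry("13C", "13C", 1.53, axis = c(1, 0, 0)),
      dipolar_from_geometry("13C", "1H", 1.09, 1 / 3,
                            axis = c(0.3, 0.6, sqrt(1 - 0.45)), i = 2, j = 3)))
  prog <- tobsy_c9(24, 55555)
  fnorm <- function(M) sqrt(sum(Mod(M)^2))
  errs <- vapply(c(32, 64), function(spp) {
    cfg <- sim_config(600, 55555, powder = single_orientation(),
                      steps_per_rotor_period = spp)
    Uref <- spinmix:::.propagate_reference(sys, cfg, ori1,
                                           spinmix:::.seg_matrix(prog))
    Usplit <- cycle_propagator(sys, prog, cfg, ori1)$U
    fnorm(Usplit - Uref)
  }, numeric(1))
  expect_lt(errs[1], 2e-2)
  expect_lt(errs[2], errs[1])   # both paths converge to the same limit
})

test_that("propagators are unitary and cycle powering equals naive stepping", {
  leu <- build_leucine_system("branched_C6")
  cfg <- sim_config(800, 55555, powder = single_orientation())
  cp <- cycle_propagator(leu, tobsy_c9(48, 55555), cfg, ori1)
  D <- 2^6
  expect_lt(max(Mod(cp$U %*% Conj(t(cp$U)) - diag(D))), 1e-10)
  expect_equal(cp$period_s * 55555, 48, tolerance = 1e-9)

  ## applying the cycle propagator k times == one window over k cycles
  two <- two_carbon()
  cfg2 <- sim_config(600, 55555, powder = single_orientation())
  prog <- tobsy_c9(24, 55555)
  cp2 <- cycle_propagator(two, prog, cfg2, ori1)
  prep <- spinmix:::.prep_system(two, cfg2)
  cf <- spinmix:::.prep_orientation(prep, ori1)
  args <- spinmix:::.cpp_args(prep, cf, cfg2)
  seg3 <- spinmix:::.seg_matrix(prog)[rep(1:27, 3), ]
  U3 <- spinmix:::.window_U(args, seg3, 0)
  U3p <- cp2$U %*% cp2$U %*% cp2$U
  expect_lt(sqrt(sum(Mod(U3 - U3p)^2)), 1e-8)

  ## WALTZ-16 at tau_90 = tau_R: least common period 96 tau_R
  cpw <- cycle_propagator(two, waltz16(55555), cfg2, ori1)
  expect_equal(cpw$period_s * 55555, 96, tolerance = 1e-9)
  ## DIPSI-3: 3 cycles = 652 rotor periods
  cpd <- cycle_propagator(two, dipsi3(55555), cfg2, ori1)
  expect_equal(cpd$period_s * 55555, 652, tolerance = 1e-6)
  ## FLOPSY: incommensurate -> instructive error
  expect_error(cycle_propagator(two, flopsy16(55555), cfg2, ori1),
               "incommensurate")
  expect_error(cycle_propagator(two, dream(55555, 1e-3), cfg2, ori1),
               "cyclic")
})

test_that("tau = 0 gives unit source polarization and zero transfer", {
  two <- two_carbon()
  cfg <- sim_config(600, 55555, powder = tiny_powder(8, 2),
                    max_mixing_time = 2e-4)
  b <- propagate(two, tobsy_c9(24, 55555), cfg, source = "CB")
  expect_equal(unname(b$efficiency[1, "CB"]), 1, tolerance = 1e-9)
  expect_equal(unname(b$efficiency[1, "CA"]), 0, tolerance = 1e-9)
  expect_true(all(abs(b$efficiency) <= 1 + 1e-9))
})

test_that("ideal isotropic mixing follows sin^2(pi J tau) and conserves total Iz", {
  sys <- ideal_j_pair(J = 33)
  cfg <- sim_config(600, 55555, powder = single_orientation(),
                    max_mixing_time = 0.0201)
  b <- propagate(sys, free_program(55555), cfg, source = "CB")
  expect_equal(b$efficiency[, "CA"], sin(pi * 33 * b$times)^2,
               tolerance = 1e-9)
  ## total polarization conserved to 1e-10
  tot <- rowSums(b$efficiency)
  expect_lt(max(abs(tot - 1)), 1e-10)
  ## the same closed form holds under WALTZ irradiation (isotropic mixing)
  bw <- propagate(sys, waltz16(55555), cfg, source = "CB")
  expect_equal(bw$efficiency[, "CA"], sin(pi * 33 * bw$times)^2,
               tolerance = 1e-6)
})

test_that("stepwise fallback and truncation reproduce the cyclic path", {
  two <- two_carbon()
  prog <- tobsy_c9(24, 55555)
  cfg <- sim_config(600, 55555, powder = single_orientation(),
                    max_mixing_time = 6 * prog$cycle_s + 1e-9)
  b1 <- propagate(two, prog, cfg, source = "CB")
  cfg2 <- cfg; cfg2$tau_grid <- b1$times[c(1, 3, 5)]
  b2 <- propagate(two, prog, cfg2, source = "CB")
  expect_equal(b2$efficiency, b1$efficiency[c(1, 3, 5), ], tolerance = 1e-9)
  ## non-commensurate grid falls back with a notice and still propagates
  cfg3 <- cfg; cfg3$tau_grid <- c(0, 1.5 * prog$cycle_s)
  expect_message(b3 <- propagate(two, prog, cfg3, source = "CB"),
                 "stepwise")
  expect_true(all(abs(b3$efficiency) <= 1 + 1e-9))
})

test_that("doubling steps_per_rotor_period changes efficiencies by < 0.5%", {
  two <- two_carbon(aniso = c(20, 20), eta = c(0.5, 0.5))
  effs <- lapply(c(32, 64), function(spp) {
    cfg <- sim_config(600, 55555, powder = tiny_powder(8, 2),
                      steps_per_rotor_period = spp, max_mixing_time = 0.016)
    propagate(two, tobsy_c9(24, 55555), cfg, source = "CB")$efficiency
  })
  expect_lt(max(abs(effs[[1]] - effs[[2]])), 0.005)
  expect_error(sim_config(600, 55555, steps_per_rotor_period = 16), ">= 32")
})

test_that("powder averaging is independent of crystallite evaluation order", {
  two <- two_carbon()
  pow <- tiny_powder(13, 2)
  perm <- sample(nrow(pow))
  pow2 <- structure(pow[perm, ], class = class(pow))
  cfg1 <- sim_config(600, 55555, powder = pow, max_mixing_time = 2e-3)
  cfg2 <- sim_config(600, 55555, powder = pow2, max_mixing_time = 2e-3)
  b1 <- propagate(two, tobsy_c9(24, 55555), cfg1, source = "CB")
  b2 <- propagate(two, tobsy_c9(24, 55555), cfg2, source = "CB")
  expect_equal(b1$efficiency, b2$efficiency, tolerance = 1e-12)
})

test_that("DREAM reports signed (negative) cross transfer", {
  two <- two_carbon()
  cfg <- sim_config(600, 55555, powder = tiny_powder(8, 2))
  b <- propagate(two, dream(55555, tau = 6e-3), cfg, source = "CB")
  expect_lt(b$efficiency[2, "CA"], 0)     # negative cross peak
  expect_equal(b$efficiency[1, "CB"], 1)
  ## iz mode is available for comparison and differs
  cfg2 <- cfg; cfg2$dream_mode <- "iz"
  b2 <- propagate(two, dream(55555, tau = 6e-3), cfg2, source = "CB")
  expect_false(isTRUE(all.equal(b$efficiency[2, ], b2$efficiency[2, ])))
})
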