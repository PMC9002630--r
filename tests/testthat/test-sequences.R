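tauR <- function(nu_r) 1 / nu_r

test_that("TOBSY C9(1,n) obeys the symmetry timing and amplitude rules", {
  p <- tobsy_c9(24, 55555)
  expect_equal(p$params$nu1_hz, 41666.25)           # 2*9/24 * 55555
  expect_equal(p$cycle_s, 24 * tauR(55555), tolerance = 1e-12)
  p48 <- tobsy_c9(48, 94500)
  expect_equal(p48$cycle_s, 48 / 94500, tolerance = 1e-12)
  expect_equal(p48$cycle_s * 1e6, 507.94, tolerance = 1e-4)
  expect_equal(nrow(p48$segments), 27L)             # 9 POST elements x 3
  ## net flip per C element = 720 degrees
  for (n in c(21, 24, 30, 33, 39, 48)) {
    pn <- tobsy_c9(n, 60000)
    flips <- pn$segments$duration_s * pn$segments$amp_hz * 360
    expect_equal(sum(flips[1:3]), 720, tolerance = 1e-9)
    ## amplitude rule: nu1 * n / (2 * 9) = nu_r
    expect_equal(pn$params$nu1_hz * n / 18, 60000, tolerance = 1e-9)
    expect_true(pn$rotor_synchronous)
  }
  ## element phase increments of 2 pi / 9, middle pulse inverted
  ph <- matrix(p$segments$phase_rad, nrow = 3)
  expect_equal(ph[1, ], (2 * pi * (0:8) / 9) %% (2 * pi), tolerance = 1e-12)
  expect_equal((ph[2, ] - ph[1, ]) %% (2 * pi), rep(pi, 9), tolerance = 1e-12)
  expect_equal(ph[3, ], ph[1, ])
  expect_error(tobsy_c9(27, 55555), "9p")
  expect_error(tobsy_c9(20, 55555), "9p")
})

test_that("WALTZ-16 is rotor-synchronized with a 96 tau_R supercycle", {
  p <- waltz16(55555)
  expect_equal(p$params$nu1_hz, 13888.75)            # nu_r / 4
  expect_equal(1 / (4 * p$params$nu1_hz) * 1e6, 18.0, tolerance = 1e-3)
  expect_equal(p$cycle_s, 96 * tauR(55555), tolerance = 1e-12)
  expect_true(p$rotor_synchronous)
  ## Q element total flip = 2160 degrees
  flips <- p$segments$duration_s * p$segments$amp_hz * 360
  expect_equal(sum(flips[1:9]), 2160, tolerance = 1e-9)
  ## only +-x phases; the bar adds exactly pi to every phase
  expect_true(all(round(p$segments$phase_rad / pi, 9) %% 1 == 0))
  q1 <- p$segments$phase_rad[1:9]; q2 <- p$segments$phase_rad[10:18]
  expect_equal((q2 - q1) %% (2 * pi), rep(pi, 9), tolerance = 1e-12)
})

test_that("DIPSI-3 matches the printed supercycle duration", {
  p <- dipsi3(55555)
  expect_equal(p$cycle_s * 55555, 4 * 4890 / 90, tolerance = 1e-9)
  expect_equal(p$cycle_s * 55555, 217.33, tolerance = 1e-4)
  p2 <- dipsi3(94500)
  expect_equal(p2$cycle_s * 1e3, 2.2999, tolerance = 1e-4)  # ~2.2999 ms
  expect_equal(nrow(p$segments), 4L * 18L)
  ## strictly alternating +-x phases within each element
  ph <- p$segments$phase_rad[1:18]
  expect_equal(ph %% pi, rep(0, 18), tolerance = 1e-12)
  expect_equal(abs(diff(ph)) %% (2 * pi), rep(pi, 17), tolerance = 1e-12)
})

test_that("FLOPSY-16 has the documented aggregate timing", {
  p <- flopsy16(55555)
  expect_equal(p$cycle_s * 55555, 188.448, tolerance = 1e-9)
  expect_equal(p$params$nu1_hz, 55555 / 4)
  ## 8 elements of 188.448/8 = 23.556 tau_90 each
  nseg <- nrow(p$segments) / 8
  el <- sum(p$segments$duration_s[seq_len(nseg)])
  expect_equal(el * 55555, 23.556, tolerance = 1e-9)  # in tau_90 = tau_R units
  expect_error(flopsy16(55555, element_file = tempfile()), "not found")
})

test_that("RFDR places one centered pi pulse per rotor period with xy8 phases", {
  p <- rfdr(55555, 100e3)
  expect_equal(p$params$tau180_s * 1e6, 5.0)          # 1/(2 nu_1)
  expect_equal(p$cycle_s, 8 * tauR(55555), tolerance = 1e-12)
  expect_equal(nrow(p$segments), 24L)
  pulse <- p$segments$amp_hz > 0
  expect_equal(sum(pulse), 8L)
  expect_equal(p$segments$phase_rad[pulse],
               c(0, pi / 2, 0, pi / 2, pi / 2, 0, pi / 2, 0))
  ## pulse centered: equal flanking delays
  d <- matrix(p$segments$duration_s, nrow = 3)
  expect_equal(d[1, ], d[3, ])
  expect_error(rfdr(55555, 0.4 * 55555), "nu_1 > nu_r / 2")
})

test_that("DREAM tangent sweep hits its endpoints and midpoint exactly", {
  nur <- 55555; tau <- 5e-3
  expect_equal(dream_amplitude(tau / 2, tau, 1000, nur / 5, nur / 2),
               nur / 2)                                  # nu(tau/2) = mean
  expect_equal(dream_amplitude(0, tau, 1000, nur / 5, nur / 2),
               nur / 2 - nur / 5, tolerance = 1e-9)      # mean - depth
  expect_equal(dream_amplitude(tau, tau, 1000, nur / 5, nur / 2),
               nur / 2 + nur / 5, tolerance = 1e-9)      # mean + depth
  p <- dream(nur, tau = tau)
  expect_equal(nrow(p$segments), 1000L)
  expect_false(p$cyclic)
  amp <- p$segments$amp_hz
  expect_true(all(diff(amp) > 0))                        # strictly increasing
  ## defaults sweep through the HORROR condition nu_1 = nu_r / 2
  expect_lt(amp[1], nur / 2); expect_gt(amp[1000], nur / 2)
  ## midpoint-sampled first/last segments sit close to the nominal endpoints
  expect_equal(amp[1], nur / 2 - nur / 5, tolerance = 0.02)
  expect_equal(amp[1000], nur / 2 + nur / 5, tolerance = 0.02)
  expect_error(dream(nur, tau = 0), "tau")
  expect_error(dream(nur, tau = 1e-3, depth = -5), "depth")
  expect_error(dream(nur, tau = 1e-3, n_steps = 50), "n_steps")
})

test_that("cycle durations of rotor-synchronous schemes are integer rotor periods", {
  nur <- 71428.5714
  for (p in list(tobsy_c9(33, nur), waltz16(nur), rfdr(nur, 1.2 * nur))) {
    ratio <- p$cycle_s * nur
    expect_lt(abs(ratio - round(ratio)) / ratio, 1e-9)
    expect_true(p$rotor_synchronous)
  }
  expect_false(dipsi3(nur)$rotor_synchronous)   # 217.33 tau_R
})

test_that("amplitude scaling and export work", {
  p <- waltz16(50000)
  ps <- scale_amplitude(p, 0.9)
  expect_equal(ps$segments$amp_hz, p$segments$amp_hz * 0.9)
  expect_equal(ps$segments$duration_s, p$segments$duration_s)
  f <- tempfile(fileext = ".tsv")
  export_sequence(p, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(p$segments))
  expect_equal(tab$amplitude_hz, p$segments$amp_hz)
  expect_equal(sum(tab$duration_us) * 1e-6, p$cycle_s, tolerance = 1e-9)
  f2 <- tempfile(fileext = ".txt")
  export_sequence(p, f2, format = "simpson")
  expect_equal(sum(grepl("^pulse ", readLines(f2))), nrow(p$segments))
  unlink(c(f, f2))
})
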