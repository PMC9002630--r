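test_that("dipolar coupling constant follows the physical formula", {
  ## independent arithmetic oracle: b/2pi = -(mu0/4pi) gi gj hbar / r^3
  gH <- 267.52218744e6; gC <- 67.2828e6; hbar <- 1.054571817e-34
  oracle <- function(gi, gj, r_ang)
    -1e-7 * gi * gj * hbar / (r_ang * 1e-10)^3 / (2 * pi)
  cc <- dipolar_from_geometry("13C", "13C", 1.53)
  expect_equal(cc$b_hz, oracle(gC, gC, 1.53), tolerance = 1e-10)
  expect_gt(abs(cc$b_hz), 1.9e3)   # "about 2 kHz" for a bonded CC pair
  expect_lt(abs(cc$b_hz), 2.3e3)
  hc <- dipolar_from_geometry("1H", "13C", 1.09, motional_scale = 1 / 3)
  expect_equal(hc$b_hz, oracle(gH, gC, 1.09), tolerance = 1e-10)
  expect_equal(abs(hc$b_hz) / 1e3, 23.3, tolerance = 0.01)
  expect_equal(hc$scale, 1 / 3)    # stored, not pre-multiplied
  ## exact r^-3 scaling: doubling r divides |b| by 8
  expect_equal(dipolar_from_geometry("13C", "13C", 3.06)$b_hz,
               cc$b_hz / 8, tolerance = 1e-12)
})

test_that("degenerate or invalid geometry is rejected", {
  expect_error(dipolar_from_geometry("13C", "13C", 0), "positive")
  expect_error(dipolar_from_geometry("13C", "13C", -1.5), "positive")
  expect_error(dipolar_from_geometry("13C", "12C", 1.5), "unknown isotope")
  expect_error(dipolar_from_geometry("13C", "13C", 1.5, motional_scale = 0),
               "motional_scale")
})

test_that("alanine four-spin model matches its parameter set", {
  sys <- build_alanine_model()
  expect_equal(n_spins(sys), 4L)
  expect_setequal(sys$label, c("CA", "CB", "HA", "HB"))
  ## one-bond J values: 33 Hz CC, 145 Hz on both CH pairs
  expect_setequal(sys$j$J_hz, c(33, 145))
  expect_equal(sum(sys$j$J_hz == 145), 2L)
  cc <- sys$j[sys$j$J_hz == 33, ]
  expect_equal(sys$label[c(cc$i, cc$j)], c("CA", "CB"))
  ## all 6 pairwise dipolar couplings present
  expect_equal(nrow(sys$dipolar), 6L)
  ## methyl proton: HB-CB dipolar motionally scaled by 1/3
  ib <- match("CB", sys$label); ih <- match("HB", sys$label)
  k <- which(sys$dipolar$i == min(ib, ih) & sys$dipolar$j == max(ib, ih))
  expect_equal(sys$dipolar$scale[k], 1 / 3)
  expect_equal(sys$dipolar$scale[-k], rep(1, 5))
  ## effective coupling is one third of the geometric value
  expect_equal(abs(sys$dipolar$b_hz[k] * sys$dipolar$scale[k]),
               abs(sys$dipolar$b_hz[k]) / 3)
  ## removing both protons leaves a 2-spin system with one 33 Hz coupling
  cc2 <- subsystem(sys, c("CA", "CB"))
  expect_equal(n_spins(cc2), 2L)
  expect_equal(cc2$j$J_hz, 33)
  expect_equal(nrow(cc2$dipolar), 1L)
})

test_that("leucine topologies carry the correct J network", {
  c6 <- build_leucine_system("branched_C6")
  expect_equal(n_spins(c6), 6L)
  one_bond <- c6$j[c6$j$J_hz > 10, ]
  expect_equal(nrow(one_bond), 5L)
  expect_equal(sum(one_bond$J_hz == 50), 1L)   # CA-C'
  expect_equal(sum(one_bond$J_hz == 33), 4L)   # aliphatic
  k50 <- one_bond[one_bond$J_hz == 50, ]
  expect_setequal(c6$label[c(k50$i, k50$j)], c("C", "CA"))

  ## two-bond count == two-bond pairs of the bond graph (brute-force paths)
  bonds <- rbind(c("C", "CA"), c("CA", "CB"), c("CB", "CG"),
                 c("CG", "CD1"), c("CG", "CD2"))
  adj <- matrix(FALSE, 6, 6, dimnames = list(c6$label, c6$label))
  for (r in seq_len(nrow(bonds))) {
    adj[bonds[r, 1], bonds[r, 2]] <- TRUE
    adj[bonds[r, 2], bonds[r, 1]] <- TRUE
  }
  two_bond_oracle <- 0L
  for (i in 1:5) for (j in (i + 1):6) {
    if (adj[i, j]) next
    if (any(adj[i, ] & adj[, j])) two_bond_oracle <- two_bond_oracle + 1L
  }
  expect_equal(sum(c6$j$J_hz == 3), two_bond_oracle)

  ## all 15 carbon pairs have dipolar couplings; one-bond ones ~2.1 kHz
  expect_equal(nrow(c6$dipolar), 15L)
  for (r in seq_len(nrow(bonds))) {
    i <- match(bonds[r, 1], c6$label); j <- match(bonds[r, 2], c6$label)
    k <- which(c6$dipolar$i == min(i, j) & c6$dipolar$j == max(i, j))
    expect_gt(abs(c6$dipolar$b_hz[k]), 1.9e3)
  }
})

test_that("linear C5 is the exact induced subsystem of branched C6", {
  c6 <- build_leucine_system("branched_C6")
  c5 <- build_leucine_system("linear_C5")
  expect_equal(n_spins(c5), 5L)
  expect_false("CD2" %in% c5$label)
  ## field-wise comparison against subsystem extraction
  ref <- subsystem(c6, setdiff(c6$label, "CD2"))
  expect_equal(c5$isotope, ref$isotope)
  expect_equal(c5$shift, ref$shift)
  expect_equal(c5$j, ref$j)
  expect_equal(c5$dipolar, ref$dipolar)
  ## no coupling references a removed spin
  expect_true(all(c(c5$j$i, c5$j$j, c5$dipolar$i, c5$dipolar$j) <= 5L))
  ## unknown topology tag
  expect_error(build_leucine_system("linear_C4"), "arg")
})

test_that("make_system applies overrides and rejects unknown fields", {
  base <- make_system("leucine_c6")
  ov <- make_system("leucine_c6", list(iso_ppm = c(CD1 = 24.5),
                                       name = "custom"))
  expect_equal(ov$shift$iso_ppm[match("CD1", ov$label)], 24.5)
  expect_equal(ov$name, "custom")
  expect_equal(ov$shift$iso_ppm[-match("CD1", ov$label)],
               base$shift$iso_ppm[-match("CD1", base$label)])
  expect_error(make_system("leucine_c6", list(b0 = 14.1)), "unknown override")
  expect_error(make_system("nope"), "unknown fixture")
  ## fixture equality: leucine_c5 == leucine_c6 minus CD2, field by field
  c5 <- make_system("leucine_c5")
  ref <- subsystem(make_system("leucine_c6"), setdiff(base$label, "CD2"))
  expect_equal(c5$j, ref$j)
  expect_equal(c5$dipolar, ref$dipolar)
})

test_that("spin systems round-trip losslessly through YAML", {
  for (sys in list(build_alanine_model(), build_leucine_system("linear_C5"))) {
    f <- tempfile(fileext = ".yaml")
    write_spin_system(sys, f)
    back <- read_spin_system(f)
    expect_equal(back$isotope, sys$isotope)
    expect_equal(back$label, sys$label)
    expect_equal(back$shift, sys$shift, tolerance = 1e-12)
    expect_equal(back$j, sys$j, tolerance = 1e-12)
    expect_equal(back$dipolar, sys$dipolar, tolerance = 1e-12)
    unlink(f)
  }
})

test_that("spin system validation catches malformed input", {
  expect_error(spin_system(c("13C", "13C"), c("A", "A")), "unique")
  expect_error(spin_system("13C", "A",
                           shift = data.frame(iso_ppm = 1, eta = 2)), "eta")
  expect_error(spin_system(c("13C", "13C"), c("A", "B"),
                           j = data.frame(i = 2L, j = 1L, J_hz = 5)),
               "i < j")
  expect_error(spin_system(c("13C", "13C"), c("A", "B"),
                           j = data.frame(i = 1L, j = 3L, J_hz = 5)),
               "invalid spin index")
})
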