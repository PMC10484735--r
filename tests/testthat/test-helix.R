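test_that("radius:pitch ratio follows the ideal-helix relation", {
  # bare 0.56 nm/nt wound down to 0.41 nm/nt: ratio ~0.15
  expect_equal(radius_pitch_ratio(0.56, 0.41), 0.15, tolerance = 0.01 / 0.15)
  expect_equal(radius_pitch_ratio(0.56, 0.49), 0.08806, tolerance = 1e-3)
  expect_identical(radius_pitch_ratio(0.56, 0.56), 0)
  expect_error(radius_pitch_ratio(0.41, 0.56), class = "ssbfil_domain_error")
})

test_that("ratio increases as the filament winds more tightly", {
  lp <- seq(0.55, 0.30, by = -0.05)
  r <- radius_pitch_ratio(0.56, lp)
  expect_true(all(diff(r) > 0))
})

test_that("relaxed-filament worked example reproduces the printed geometry", {
  hp <- helix_parameters(R = 2.1, L = 0.56, L_prime = 0.41, bss_ref = 7)
  expect_equal(hp$nt_per_turn, 34, tolerance = 2 / 34)
  expect_equal(hp$proteins_per_turn, 4.9, tolerance = 0.3 / 4.9)
  expect_equal(hp$twist_per_protein, 73, tolerance = 4 / 73)
  expect_equal(hp$arc_per_protein, 3.9, tolerance = 0.1 / 3.9)
  expect_equal(hp$axial_per_protein, 2.8, tolerance = 0.1 / 2.8)
  expect_equal(hp$pitch, 13.9, tolerance = 0.6 / 13.9)
})

test_that("fully unwound filament: infinite pitch, bss shrinks to h/L", {
  hp <- helix_parameters(R = 2.1, L = 0.56, L_prime = 0.56, h = 2.8)
  expect_true(hp$infinite_pitch)
  expect_identical(hp$pitch, Inf)
  expect_identical(hp$ratio, 0)
  expect_identical(hp$twist_per_protein, 0)
  expect_equal(hp$bss, 5)
})

test_that("helix relation round-trips and conserves arc length per turn", {
  set.seed(42)
  for (i in 1:20) {
    L <- runif(1, 0.4, 0.7)
    Lp <- runif(1, 0.25, L * 0.999)
    R <- runif(1, 1, 4)
    hp <- helix_parameters(R = R, L = L, L_prime = Lp)
    # inverse: L/L' from (ratio); recovers the winding ratio exactly
    expect_equal(sqrt((2 * pi * hp$ratio)^2 + 1), L / Lp, tolerance = 1e-12)
    # ssDNA arc per helical turn equals the wound nucleotides times L
    expect_rel(sqrt(hp$pitch^2 + (2 * pi * R)^2), hp$nt_per_turn * L, 1e-9)
  }
})

test_that("helix sweep shows the expected monotone trends", {
  tab <- data.frame(concentration = c(5, 1000), L_prime = c(0.41, 0.49))
  sw <- helix_sweep(tab, R = 2.1, L = 0.56, h = 2.8)
  expect_equal(nrow(sw), 2)
  expect_gt(sw$pitch[2], sw$pitch[1])
  expect_gt(sw$proteins_per_turn[2], sw$proteins_per_turn[1])
  expect_lt(sw$twist_per_protein[2], sw$twist_per_protein[1])
  expect_lt(sw$bss[2], sw$bss[1])

  one <- helix_sweep(data.frame(concentration = 5, L_prime = 0.41),
                     R = 2.1, L = 0.56, h = 2.8)
  expect_equal(nrow(one), 1)

  const_tab <- data.frame(concentration = c(5, 100, 1000),
                          L_prime = rep(0.45, 3))
  cs <- helix_sweep(const_tab, R = 2.1, L = 0.56, h = 2.8)
  expect_equal(length(unique(cs$pitch)), 1)

  nonmono <- data.frame(concentration = c(5, 100, 1000),
                        L_prime = c(0.41, 0.50, 0.45))
  expect_warning(helix_sweep(nonmono, R = 2.1, L = 0.56, h = 2.8),
                 "not monotone")
})

test_that("volumetric radius estimate scales as expected", {
  expect_equal(filament_radius_from_volumes(100, 50, 100, 50, r_ds = 1), 1)
  expect_equal(filament_radius_from_volumes(400, 50, 100, 50, r_ds = 1), 2)
  # radical of 4.41 doubles-and-a-bit the dsDNA radius to 2.1 nm
  expect_equal(filament_radius_from_volumes(4.41 * 10, 100, 10, 100,
                                            r_ds = 1), 2.1,
               tolerance = 1e-9)
  # dsDNA reference length from bp count
  expect_equal(filament_radius_from_volumes(10, 10, 10, n_bp = 100),
               sqrt(100 * 0.34 / 10))
})

test_that("replication turnover arithmetic", {
  tv <- turnover_requirement(500, 7, 2000)
  expect_equal(tv$proteins_per_s, 500 / 7, tolerance = 1e-12)
  expect_equal(tv$per_protein_rate, 0.25)
  expect_equal(tv$proteins_per_fragment, 2000 / 7)
  # fragment of one site: per-protein rate equals the total rate
  tv1 <- turnover_requirement(500, 7, 7)
  expect_equal(tv1$per_protein_rate, tv1$proteins_per_s)
  # doubling the fragment halves the per-protein requirement
  expect_equal(turnover_requirement(500, 7, 4000)$per_protein_rate,
               tv$per_protein_rate / 2)
})
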