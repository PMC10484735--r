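test_that("contour length sums segment lengths", {
  expect_equal(trace_contour_length(backbone_trace(c(0, 1, 2), c(0, 0, 0))), 2)
  sq <- backbone_trace(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 1e-9))
  expect_equal(trace_contour_length(sq), 4, tolerance = 1e-6)
  th <- seq(0, pi, length.out = 1000)
  semi <- backbone_trace(100 * cos(th), 100 * sin(th))
  expect_rel(trace_contour_length(semi), pi * 100, 1e-3)
})

test_that("contour length is stable under resampling step choice", {
  th <- seq(0, pi, length.out = 2000)
  semi <- backbone_trace(150 * cos(th), 150 * sin(th))
  l0 <- trace_contour_length(semi)
  for (step in c(2, 5, 10)) {
    expect_rel(trace_contour_length(resample_trace(semi, step)), l0, 0.005)
  }
})

test_that("tangent correlation matches analytic profiles", {
  line <- backbone_trace(seq(0, 200, 5), rep(0, 41))
  pl <- tangent_correlation(line, resample_step = 5)
  expect_true(all(abs(pl$mean_cos - 1) < 1e-12))
  expect_equal(pl$mean_cos[pl$separation == 0], 1)

  thc <- seq(0, 2 * pi, length.out = 4000)[-4000]
  circ <- backbone_trace(100 * cos(thc), 100 * sin(thc))
  pc <- tangent_correlation(circ, resample_step = 5, max_separation = 150)
  sel <- pc$separation > 0
  expect_true(all(abs(pc$mean_cos[sel] - cos(pc$separation[sel] / 100)) < 0.01))
})

test_that("persistence fit inverts exact and simulated 2D WLC decay", {
  prof <- data.frame(separation = seq(0, 100, 5),
                     mean_cos = exp(-seq(0, 100, 5) / 40))
  expect_rel(fit_persistence_2d(prof)$p, 20, 1e-6)

  line <- backbone_trace(seq(0, 200, 5), rep(0, 41))
  pu <- fit_persistence_2d(tangent_correlation(line, 5))
  expect_true(pu$unbounded)
  expect_identical(pu$p, Inf)

  # anticorrelated profile has no positive decay window
  bad <- data.frame(separation = seq(5, 50, 5), mean_cos = rep(-0.2, 10))
  expect_error(fit_persistence_2d(bad), class = "ssbfil_fit_failure")

  # seeded chain ensemble: profile within 3 SEM of exp(-L/2p), p within 10%
  # (arc step aligned with the resample step so the chord estimator is
  # unbiased; see the methods vignette on chord smoothing)
  chains <- lapply(1:50, function(i) gen_chain_2d(20, 2500, seed = 500 + i,
                                                  arc_step = 5))
  prof2 <- tangent_correlation(chains, resample_step = 5,
                               max_separation = 100)
  sel <- prof2$separation > 0
  dev <- abs(prof2$mean_cos[sel] - exp(-prof2$separation[sel] / 40))
  expect_true(all(dev <= 3 * prof2$sem[sel]))
  expect_rel(fit_persistence_2d(prof2, L_max = 100)$p, 20, 0.10)
})

test_that("persistence recovery holds across stiffness scales", {
  for (p_true in c(5, 20, 50)) {
    step <- max(p_true / 4, 1.25)
    chains <- lapply(1:50, function(i)
      gen_chain_2d(p_true, 2500, seed = 7000 + 101 * p_true + i,
                   arc_step = step))
    prof <- tangent_correlation(chains, resample_step = step,
                                max_separation = 5 * p_true)
    fit <- fit_persistence_2d(prof, L_max = 5 * p_true)
    expect_rel(fit$p, p_true, 0.10)
  }
})

test_that("loop-free segmentation returns the known flank", {
  line <- backbone_trace(seq(0, 100, 2), rep(0, 51))
  expect_identical(longest_loopfree_segment(line, 4)$points, line$points)

  tr <- crossing_trace(flank1 = 100, flank2 = 60)
  lf <- longest_loopfree_segment(tr, 4)
  # the longer (first) flank survives, trimmed near the crossing at x = 100
  expect_true(all(lf$points[, 2] == 0))
  expect_lt(max(lf$points[, 1]), 100)
  expect_equal(min(lf$points[, 1]), 0)
  expect_gt(trace_contour_length(lf), 80)

  # two crossings bracketing a short middle: the longest flank survives
  a <- seq(0.3, 2 * pi - 0.3, length.out = 18)
  loop <- function(cx) cbind(cx + 8 * sin(a), 8 - 8 * cos(a))
  pts <- rbind(cbind(seq(0, 100, 2), 0), loop(100),
               cbind(seq(102, 120, 2), 0), loop(120),
               cbind(seq(122, 160, 2), 0))
  tr2 <- backbone_trace(pts[, 1], pts[, 2])
  lf2 <- longest_loopfree_segment(tr2, 4)
  expect_equal(min(lf2$points[, 1]), 0)
  expect_lt(max(lf2$points[, 1]), 100)
})

test_that("integrated volume behaves like a volume", {
  flat <- afm_image(matrix(0.5, 32, 32), pixel_size = 2, background = 0.5)
  expect_equal(integrated_volume(flat), 0)

  one <- matrix(0, 16, 16)
  one[8, 8] <- 1
  expect_equal(integrated_volume(afm_image(one, 2, background = 0)), 4)

  # additive over disjoint molecules and invariant to a background offset
  two <- one
  two[3, 3] <- 2
  img2 <- afm_image(two, 2, background = 0)
  expect_equal(integrated_volume(img2), 4 + 8)
  img_off <- afm_image(two + 5, 2)  # background re-estimated (median)
  expect_equal(integrated_volume(img_off), integrated_volume(img2))
})

test_that("synthetic image volume and skeleton round-trip", {
  chain <- gen_chain_2d(50, 150, seed = 3, arc_step = 2)
  img <- gen_afm_image(chain, seed = 4, molecule_height = 2, tip_sigma = 4,
                       pixel_size = 2, noise_sd = 0.02)
  v <- integrated_volume(img, noise_floor = 3 * img$meta$truth$noise_sd)
  expect_rel(v, img$meta$truth$injected_volume, 0.05)

  # straight molecule: skeleton recovers the backbone within one pixel
  st <- backbone_trace(seq(0, 100, 2), rep(0, 51))
  im2 <- gen_afm_image(st, seed = 5, tip_sigma = 2, noise_sd = 0)
  sk <- trace_afm_skeleton(im2)
  expect_true(all(abs(sk$points[, 2] - sk$points[1, 2]) <= im2$pixel_size))
  expect_rel(trace_contour_length(sk), 100, 0.05)
})
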