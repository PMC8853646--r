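test_that("interaction constants give the sheath area", {
  ic <- interaction_constants()
  expect_equal(ic$q, (1.02 + 0.63)^2 - 0.63^2, tolerance = 1e-12)
  expect_equal(ic$q, 2.3256, tolerance = 1e-10)
})

test_that("overlap length handles disjoint and containment geometries", {
  p <- example_profile()
  # disjoint fields
  expect_equal(overlap_length(520, 400, 100, p), 0)
  expect_equal(overlap_case(520, 400, 100), 0)
  # disk fully inside the cone circle: whole-disk length
  expect_equal(overlap_length(0, 400, 500, p), p$length_total,
               tolerance = 1e-6)
  expect_equal(overlap_case(0, 400, 500), 33)
  # cone circle inside the disk and covering the centre
  Lin <- overlap_length(10, 400, 60, p)
  expect_lt(Lin, p$length_total)
  expect_gt(Lin, 0)
  expect_error(overlap_length(-1, 400, 100, p), "negative")
})

test_that("quadrature agrees with the Monte-Carlo oracle across cases", {
  p <- example_profile()
  set.seed(7)
  # geometries covering all dispatch regimes, then random ones
  geoms <- rbind(
    c(250, 400, 100), c(380, 400, 100), c(420, 400, 150),
    c(150, 400, 100), c(50, 400, 100), c(120, 150, 100),
    c(60, 150, 100), c(20, 150, 100), c(100, 120, 200), c(50, 120, 200))
  for (i in seq_len(nrow(geoms))) {
    s <- geoms[i, 1]; rm <- geoms[i, 2]; rg <- geoms[i, 3]
    prof <- derive_mc_profile(0.25, 0.5, 0.003, rm)
    L <- overlap_length(s, rm, rg, prof)
    or <- mc_overlap_oracle(s, rm, rg, prof)
    expect_lt(abs(L - or$estimate), 3 * or$se + 1e-3)
  }
  for (i in 1:25) {
    rm <- stats::runif(1, 80, 600)
    rg <- stats::runif(1, 10, 160)
    s <- stats::runif(1, 0, rm + rg - 1)
    prof <- derive_mc_profile(stats::runif(1, 0.2, 0.3),
                              stats::runif(1, 1 / 3, 0.8),
                              stats::runif(1, 0.00255, 0.0051), rm)
    L <- overlap_length(s, rm, rg, prof)
    or <- mc_overlap_oracle(s, rm, rg, prof, n = 2e5)
    expect_lt(abs(L - or$estimate), 3 * or$se + 1e-3)
  }
})

test_that("overlap length is monotone in distance and continuous at case boundaries", {
  p <- example_profile()
  for (rg in c(60, 100, 450)) {
    L <- vapply(seq(0, 400 + rg, length.out = 60), function(s) {
      overlap_length(s, 400, rg, p)
    }, numeric(1))
    expect_true(all(diff(L) <= 1e-4))
  }
  # approach each case boundary from both sides
  for (rg in c(90, 150, 450)) {
    for (sb in c(400 - rg, rg, sqrt(400^2 + rg^2), abs(rg - 400))) {
      if (sb <= 0) next
      d <- 1e-4
      expect_equal(overlap_length(sb - d, 400, rg, p),
                   overlap_length(sb + d, 400, rg, p), tolerance = 0.05)
    }
  }
})

test_that("expected synapse count follows the occupancy-corrected volume", {
  gc <- list(r_max = 80, z0 = 40, z_max = 180, S_available = 240)
  lam <- expected_synapses(L = 50, z_m = 110, gc = gc, n_preexisting = 0,
                           mc_total_length = 1507.96)
  expect_equal(lam, 0.18688, tolerance = 1e-4)
  expect_equal(expected_synapses(0, 110, gc, 0, 1507.96), 0)
  # full occupancy nullifies the pair
  ic <- interaction_constants()
  n_full <- ic$q * pi * 1507.96 / ic$v_spine
  expect_equal(expected_synapses(50, 110, gc, n_full, 1507.96), 0)
  # occupancy correction is linear in between
  lam_half <- expected_synapses(50, 110, gc, n_full / 2, 1507.96)
  expect_equal(lam_half, lam / 2, tolerance = 1e-10)
  expect_error(expected_synapses(50, 110, gc, 0, 0), "degenerate")
})

test_that("connection probability is the Poisson at-least-one form", {
  expect_equal(connection_probability(0), 0)
  expect_equal(connection_probability(0.1), 0.09516, tolerance = 1e-4)
  expect_equal(connection_probability(0.18688), 0.17046, tolerance = 1e-4)
  lam <- seq(0, 5, by = 0.1)
  p <- connection_probability(lam)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 1))
  expect_error(connection_probability(-0.1), "non-negative")
})

test_that("pair-level overlap uses the oblique cone section", {
  pr <- example_pair()
  L <- pair_overlap_length(pr$mc, pr$gc)
  # independent recomputation: section radius and centre at z_m = 110
  frac <- (110 - 40) / (180 - 40)
  expect_equal(L, overlap_length(250, 400, 160 * frac, example_profile()),
               tolerance = 1e-9)
  # disk above the cone face: no overlap
  mc_hi <- pr$mc; mc_hi$z <- 185
  expect_equal(pair_overlap_length(mc_hi, pr$gc), 0)
})
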