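test_that("generated networks satisfy the structural invariants", {
  net <- tiny_net()
  # target GC count reached, no zero-degree GCs
  expect_equal(nrow(net$gc), 5 * nrow(net$mc))
  expect_true(all(net$gc$degree >= 1))
  # conservation: degree sums equal the synapse count
  expect_equal(sum(net$mc$degree), nrow(net$syn))
  expect_equal(sum(net$gc$degree), nrow(net$syn))
  # at most one synapse per pair
  expect_false(any(duplicated(net$syn[, c("mc_id", "gc_id")])))
  # spine budgets never exceeded
  expect_true(all(net$gc$degree <= floor(net$gc$S_available)))
  # dendritic distance within the disk radius
  expect_true(all(net$syn$dist <= net$mc$r_max[net$syn$mc_id] + 1e-9))
  # synapse heights at the MC disk height
  expect_equal(net$syn$z, net$mc$z[net$syn$mc_id])
  # adjacency consistent with the synapse table
  adj <- network_adjacency(net)
  expect_equal(Matrix::rowSums(adj), as.numeric(net$mc$degree))
  expect_equal(Matrix::colSums(adj), as.numeric(net$gc$degree))
  expect_error(generate_network(net$space, net$mc, gc_per_mc = -1))
})

test_that("type I mitral cells out-connect type II", {
  net <- tiny_net()
  expect_gt(mean(net$mc$degree[net$mc$type == 1]),
            mean(net$mc$degree[net$mc$type == 2]))
})

test_that("synapse locations lie in the lens with dendrite-weighted radii", {
  pr <- example_pair()
  set.seed(6)
  n <- 4000
  pts <- replicate(n, unlist(sample_synapse_location(pr$mc, pr$gc)))
  r <- pts["dendritic_distance", ]
  expect_true(all(r <= pr$mc$r_max + 1e-9))
  # every point inside both the disk and the cone section
  frac <- (110 - 40) / (180 - 40)
  rg <- 160 * frac
  dx <- pts["x", ] - 250
  expect_true(all(dx^2 + pts["y", ]^2 <= rg^2 + 1e-6))
  # radial density proportional to rho_m(r) * arc inside the lens:
  # compare binned counts against the analytic marginal (chi-squared)
  prof <- example_profile()
  marg <- function(r) {
    c0 <- (r^2 + 250^2 - rg^2) / (2 * r * 250)
    th <- acos(pmin(1, pmax(-1, c0)))
    mc_dendrite_density(r, prof) * r * 2 * th
  }
  br <- seq(250 - rg, min(400, 250 + rg), length.out = 9)
  pfun <- vapply(seq_len(length(br) - 1), function(i) {
    stats::integrate(marg, br[i], br[i + 1])$value
  }, numeric(1))
  pfun <- pfun / sum(pfun)
  obs <- table(cut(r, br))
  chi <- suppressWarnings(stats::chisq.test(obs, p = pfun))
  expect_gt(chi$p.value, 0.001)
  # disjoint pair errors
  far <- pr$gc; far$vx <- far$fx <- 2000
  expect_error(sample_synapse_location(pr$mc, far), "not overlap")
})

test_that("shared granule cells fall with distance in geometric mode only", {
  net <- tiny_net()
  set.seed(8)
  g <- shared_gc_by_distance(net, n_pairs = 4000, bin_width = 100,
                             n_bins = 3)
  expect_true(all(diff(g$shared) < 0))
  # distance-independent control: flat profile, near-normal degrees
  set.seed(9)
  mcs <- net$mc
  mcs$degree <- NULL
  ctrl <- generate_network(net$space, mcs, gc_per_mc = 5,
                           mode = "distance_independent", reference = net,
                           sample_params = FALSE)
  expect_equal(nrow(ctrl$syn), nrow(net$syn), tolerance = 0.1)
  c2 <- shared_gc_by_distance(ctrl, n_pairs = 4000, bin_width = 100,
                              n_bins = 3)
  spread <- (max(c2$shared) - min(c2$shared)) / mean(c2$shared)
  expect_lt(spread, 0.15)
  # control degrees concentrate (low dispersion) versus geometric
  expect_lt(stats::sd(ctrl$mc$degree) / mean(ctrl$mc$degree),
            0.5 * stats::sd(net$mc$degree) / mean(net$mc$degree))
  sh <- stats::shapiro.test(sample(ctrl$mc$degree, 100))
  expect_gt(sh$p.value, 1e-4)
})

test_that("sister pairs share more granule cells than non-sisters", {
  net <- tiny_net()
  set.seed(10)
  st <- network_statistics(net, fit_gc_skew = FALSE)
  expect_gt(st$sister_fraction_mean, st$nonsister_fraction_mean)
  expect_true(st$sister_fraction_mean > 0 && st$sister_fraction_mean < 1)
})

test_that("granule-cell degrees are right-skewed and skew-normal fittable", {
  net <- dense_net()
  deg <- net$gc$degree
  sk <- mean((deg - mean(deg))^3) / stats::sd(deg)^3
  expect_gt(sk, 0)
  set.seed(11)
  fit <- fit_skew_normal(deg)
  expect_equal(fit$convergence, 0)
  expect_gt(fit$shape, 0)
  # fitted density mass concentrates where the data are
  xs <- seq(min(deg), max(deg), length.out = 200)
  expect_gt(sum(dskewnorm(xs, fit$xi, fit$omega, fit$shape)) * diff(xs)[1],
            0.8)
})
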