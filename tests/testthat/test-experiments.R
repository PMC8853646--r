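test_that("lateral inhibition is inhibitory and strongest for close pairs", {
  net <- dense_net()
  set.seed(20)
  li <- exp_lateral_inhibition(net, n_pairs = 10, duration = 500, pad = 100,
                               degree_window = 200)
  # inhibition, not excitation, on average
  expect_gte(mean(li$pairs$delta_rate), 0)
  # pairs sharing no GCs are essentially unaffected
  none <- li$pairs$delta_rate[li$pairs$shared == 0]
  if (length(none) > 0) expect_true(all(abs(none) <= 2))
  # the most-affected pairs share more GCs than the unaffected ones
  if (any(li$pairs$delta_rate > 0)) {
    expect_gte(mean(li$pairs$shared[li$pairs$delta_rate > 0]),
               mean(li$pairs$shared[li$pairs$delta_rate <= 0]))
  }
})

test_that("identical odors stay perfectly correlated without granule cells", {
  net <- tiny_net()
  set.seed(21)
  panel <- odor_panel(net, n_odors = 2, gloms_per_odor = 3, stride = 0)
  # identical target sets share per-glomerulus draws, so inputs match
  expect_identical(panel$sets[[1]], panel$sets[[2]])
  c1 <- odor_currents(panel, 1)
  c2 <- odor_currents(panel, 2)
  act <- net$mc$glomerulus %in% panel$sets[[1]]
  expect_equal(c1$amp[act], c2$amp[act])
  expect_equal(c1$phase[act], c2$phase[act])
})

test_that("granule cells decorrelate odor pairs most at short windows", {
  net <- dense_net()
  set.seed(22)
  panel <- odor_panel(net, n_odors = 3, gloms_per_odor = 4, stride = 2)
  dec <- exp_decorrelation(net, panel, windows = c(10, 100),
                           duration = 500)
  m <- dec$by_window
  short <- m$decorrelation[m$window == 10]
  long <- m$decorrelation[m$window == 100]
  expect_gt(short, 0)
  expect_gt(short, long - 0.02)
  # without GCs, long-window correlation tracks glomerular overlap
  long_tab <- dec$pairs[dec$pairs$window == 100, ]
  if (length(unique(long_tab$overlap)) > 1) {
    expect_gte(stats::cor(long_tab$overlap, long_tab$corr_nogc,
                          method = "spearman"), 0)
  }
})

test_that("feedback to granule cells acts through the network architecture", {
  net <- tiny_net()
  set.seed(23)
  fb <- exp_gc_feedback(net, levels = c(0, 0.05, 0.2), n_gloms = 4,
                        duration = 1000 / 3)
  # zero-level feedback is undefined, reported as absent
  expect_true(is.na(fb$same_net[fb$level == 0]))
  ok <- fb[fb$level > 0, ]
  expect_true(all(ok$same_net > ok$cross_net))
  expect_true(all(ok$same_net > 0.3))
})

test_that("mitral cells with fewer granule cells respond most to feedback", {
  net <- tiny_net()
  set.seed(24)
  mf <- exp_mc_feedback(net, n_trials = 2, n_gloms = 4)
  # only targeted MCs are reported
  expect_true(all(mf$feedback_pA > 0))
  expect_lt(stats::cor(mf$delta_rate, mf$degree, method = "spearman"), 0)
  # the relation holds in both odor-receiving and non-receiving groups
  for (grp in unique(mf$odor_receiving)) {
    sub <- mf[mf$odor_receiving == grp, ]
    if (nrow(sub) > 10) {
      expect_lt(stats::cor(sub$delta_rate, sub$degree,
                           method = "spearman"), 0.2)
    }
  }
})

test_that("neurogenesis bookkeeping follows the growth arithmetic", {
  expect_equal(neurogenesis_add_count(864, 4320, 15, 10), 864)
  expect_equal(neurogenesis_add_count(916, 13470, 15, 10), 27)
})

test_that("granule-cell turnover and growth preserve network invariants", {
  net <- tiny_net()
  set.seed(25)
  n0 <- nrow(net$gc)
  shrunk <- remove_granule_cells(net, sample.int(n0, 50))
  expect_equal(nrow(shrunk$gc), n0 - 50)
  expect_equal(sum(shrunk$mc$degree), nrow(shrunk$syn))
  expect_equal(sum(shrunk$gc$degree), nrow(shrunk$syn))
  grown <- add_granule_cells(shrunk, 50)
  expect_equal(nrow(grown$gc), n0)
  expect_true(all(grown$gc$degree[(n0 - 50 + 1):n0] >= 1))
  expect_equal(sum(grown$mc$degree), nrow(grown$syn))
  # guided placement lands near the selected MCs and always overlaps
  w <- rep(0, nrow(net$mc)); w[7] <- 1
  g7 <- add_granule_cells(net, 10, placement = "guided", mc_weights = w)
  new <- g7$gc[(nrow(net$gc) + 1):nrow(g7$gc), ]
  d <- sqrt((new$vx - net$mc$x[7])^2 + (new$vy - net$mc$y[7])^2)
  expect_true(all(d <= net$mc$r_max[7] / 10 + 1e-9))
  expect_true(all(new$z_max >= net$mc$z[7]))
})

test_that("one neurogenesis round applies the configured turnover", {
  set.seed(26)
  sp <- build_space(80)
  mcs <- place_mitral_cells(sp)
  base <- generate_network(sp, mcs, gc_per_mc = 4)
  panel <- odor_panel(base, n_odors = 2, gloms_per_odor = 2,
                      arrangement = "random",
                      odor_mean_range = c(150, 600))
  ctl <- exp_neurogenesis(base, panel, mode = "control", rounds = 1,
                          duration = 1000 / 6)
  # replacement conserves the population
  expect_equal(nrow(ctl$final_network$gc), nrow(base$gc))
  add <- exp_neurogenesis(base, panel, mode = "addition", rounds = 1,
                          add_count = 40, duration = 1000 / 6)
  expect_equal(nrow(add$final_network$gc), nrow(base$gc) + 40)
  expect_equal(dim(ctl$correlations), c(2, 1))
})
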