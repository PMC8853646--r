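test_that("the resting state is a fixed point and the reset applies", {
  p <- izhikevich_defaults("MC")
  st <- izhikevich_step(list(v = p[["v_r"]], u = 0), p, I = 0)
  expect_equal(st$v, p[["v_r"]])
  expect_equal(st$u, 0)
  expect_false(st$spike)
  # just above cutoff: reset to c, recovery incremented by d
  st2 <- izhikevich_step(list(v = p[["v_c"]] + 60, u = 5), p, I = 0)
  expect_true(st2$spike)
  expect_equal(st2$v, -70)
  expect_gt(st2$u, 5 + 13 - 1)
  expect_error(izhikevich_step(list(v = Inf, u = 0), p, I = 0), "non-finite")
})

test_that("a mitral cell at 700 pA fires near 70 Hz", {
  r <- simulate_single_cell(izhikevich_defaults("MC"), 700)
  expect_equal(r$rate_hz, 70, tolerance = 0.1)
})

test_that("mitral cells are class II: discontinuous f-I onset", {
  fi <- fi_curve(izhikevich_defaults("MC"), seq(95, 130, by = 1))
  sustained <- fi$rate_hz[fi$rate_hz >= 2] # ignore single onset transients
  expect_gt(min(sustained), 4)            # nonzero frequency floor
  # granule cells (integrators) start arbitrarily low by contrast
  fg <- fi_curve(izhikevich_defaults("GC"), seq(10, 30, by = 1))
  expect_lte(min(fg$rate_hz[fg$rate_hz > 0]), 2)
})

test_that("excitability inversion matches and round-trips", {
  e <- gc_excitability_from_bk(-0.133, 0.067)
  expect_equal(e$rheobase, 15.09, tolerance = 1e-3)
  expect_equal(e$R, 0.4973, tolerance = 1e-3)
  # inside the acceptance windows
  expect_true(e$rheobase >= 10 && e$rheobase <= 70)
  expect_true(e$R >= 0.25 && e$R <= 1.5)
  # round trip to 1e-10 relative
  bk <- gc_bk_from_excitability(e$R, e$rheobase)
  expect_equal(bk$b, -0.133, tolerance = 1e-10)
  expect_equal(bk$k, 0.067, tolerance = 1e-10)
  expect_error(gc_excitability_from_bk(-10, 0.067), "no excitability")
})

test_that("simulated rheobase matches the analytic value within a grid step", {
  p <- izhikevich_defaults("GC")
  analytic <- gc_excitability_from_bk(p[["b"]], p[["k"]])$rheobase
  sim <- measure_rheobase(p, grid = seq(1, 100, by = 1))
  expect_lte(abs(sim - analytic), 1)
})

test_that("sampled parameters respect the constraints", {
  set.seed(12)
  pm <- sample_cell_params("MC", 400)
  mu <- izhikevich_defaults("MC")
  for (nm in colnames(pm)) {
    # the v_r < v_t < v_c redraws shift the voltage means slightly
    expect_equal(mean(pm[, nm]), mu[[nm]], tolerance = 0.05)
  }
  pg <- sample_cell_params("GC", 300)
  expect_true(all(pg[, "b"] < 0))
  for (i in seq_len(nrow(pg))) {
    e <- gc_excitability_from_bk(pg[i, "b"], pg[i, "k"],
                                 pg[i, "v_r"], pg[i, "v_t"])
    expect_true(e$rheobase >= 10 && e$rheobase <= 70)
    expect_true(e$R >= 0.25 && e$R <= 1.5)
  }
  expect_true(all(pg[, "v_r"] < pg[, "v_t"] & pg[, "v_t"] < pg[, "v_c"]))
})

test_that("receptor currents follow their closed forms", {
  sp <- synaptic_params()
  expect_equal(receptor_current("AMPA", 0, -60), 0)
  expect_equal(receptor_current("NMDA", 0, -60), 0)
  expect_equal(receptor_current("GABA", 0, -60), 0)
  # magnesium block at 0 and -58 mV
  blk <- function(v) 1 / (1 + exp(-0.062 * v) / 3.57)
  expect_equal(blk(0), 0.7812, tolerance = 1e-3)
  expect_equal(blk(-58), 0.0888, tolerance = 1e-2)
  expect_equal(receptor_current("NMDA", 0.5, -58),
               0.5 * sp$g_NMDA * (-58) * blk(-58), tolerance = 1e-10)
  # GABA dendritic attenuation: e^-1 at one length constant
  g0 <- receptor_current("GABA", 0.5, -50, dendritic_distance = 0)
  g675 <- receptor_current("GABA", 0.5, -50, dendritic_distance = 675)
  expect_equal(g675 / g0, exp(-1), tolerance = 1e-10)
})

test_that("gating variables decay correctly and stay bounded", {
  sp <- synaptic_params()
  s <- list(s_AMPA = 1, s_NMDA = 0.3, n = 0, s_GABA = 1)
  for (i in 1:180) s <- advance_gating(s, dt = 0.1, sp)
  # 18 ms at tau_GABA = 18: Euler approximation of e^-1
  expect_equal(s$s_GABA, exp(-1), tolerance = 0.01)
  # n = 0: NMDA decays monotonically
  expect_lt(s$s_NMDA, 0.3)
  # saturating bump fixed point at s = 1
  expect_equal(gating_bump(1), 1)
  expect_equal(gating_bump(0), 0.5)
  expect_equal(gating_bump(0, 0.5 * 0.006), 0.003) # second-order GABA
  # arbitrary event sequences stay in [0, 1]
  set.seed(13)
  s <- list(s_AMPA = 0, s_NMDA = 0, n = 0, s_GABA = 0)
  for (i in 1:2000) {
    s <- advance_gating(s, dt = 0.1, sp)
    if (stats::runif(1) < 0.05) {
      s$s_AMPA <- gating_bump(s$s_AMPA)
      s$n <- gating_bump(s$n)
      s$s_GABA <- gating_bump(s$s_GABA)
    }
    expect_true(all(unlist(s) >= 0 & unlist(s) <= 1))
  }
})

test_that("uncoupled network cells reproduce single-cell traces", {
  net <- tiny_net()
  nmc <- nrow(net$mc)
  dc <- numeric(nmc); dc[3] <- 400
  pr <- sim_protocol(duration = 300, mc_dc = dc, gaba_scale = 0,
                     record_v_mc = 3)
  sim <- run_simulation(net, pr)
  p <- unlist(net$mc[3, paste0("iz_", c("C", "k", "a", "b", "c", "d",
                                        "vr", "vt", "vc"))])
  names(p) <- c("C", "k", "a", "b", "c", "d", "v_r", "v_t", "v_c")
  single <- simulate_single_cell(p, 400, duration = 300, pad = 0,
                                 trace = TRUE)
  expect_equal(as.numeric(sim$v_mc[, 1]), single$v, tolerance = 1e-10)
})

test_that("disabling GABA removes granule-cell influence on mitral cells", {
  net <- dense_net()
  nmc <- nrow(net$mc)
  deg <- net$mc$degree
  a <- order(-deg)[5]
  dc <- numeric(nmc); dc[a] <- 700
  n_a <- function(gs) {
    pr <- sim_protocol(duration = 600, mc_dc = dc, gaba_scale = gs)
    sim <- run_simulation(net, pr)
    c(mc = sum(sim$spikes$kind == "MC" & sim$spikes$id == a),
      gc = sum(sim$spikes$kind == "GC"))
  }
  with_g <- n_a(1)
  no_g <- n_a(0)
  # GCs still spike, but the driven MC fires at its uncoupled rate
  expect_gt(no_g[["gc"]], 0)
  p <- unlist(net$mc[a, paste0("iz_", c("C", "k", "a", "b", "c", "d",
                                        "vr", "vt", "vc"))])
  names(p) <- c("C", "k", "a", "b", "c", "d", "v_r", "v_t", "v_c")
  iso <- simulate_single_cell(p, 700, duration = 600, pad = 0)
  expect_equal(no_g[["mc"]], iso$n_spikes)
  expect_lte(with_g[["mc"]], no_g[["mc"]])
})

test_that("sensory drive rates follow the sniff-locked profile", {
  # r(t) ranges over [rmax/2, rmax]; time-average is 3/4 rmax
  t <- seq(0, 1000, by = 0.1)
  rmax <- 2.5
  r <- rmax / 2 + rmax / 4 * (sin(2 * pi * 6 * t / 1000 - 1) + 1)
  expect_gte(min(r), rmax / 2 - 1e-9)
  expect_lte(max(r), rmax + 1e-9)
  expect_equal(mean(r), 3 * rmax / 4, tolerance = 0.01)
  net <- tiny_net()
  set.seed(14)
  drive <- osn_odor_drive(net)
  expect_equal(length(drive$odor_glomeruli),
               round(0.2 * nrow(net$space$glomeruli)))
  expect_true(all(drive$rate >= 0))
  odor_mc <- net$mc$glomerulus %in% drive$odor_glomeruli
  expect_gt(mean(drive$rate[odor_mc]), mean(drive$rate[!odor_mc]))
})

test_that("halving the time step leaves single-cell rates stable", {
  p <- izhikevich_defaults("MC")
  r1 <- simulate_single_cell(p, 700, dt = 0.1)$rate_hz
  r2 <- simulate_single_cell(p, 700, dt = 0.05)$rate_hz
  expect_equal(r1, r2, tolerance = 0.1)
  net <- tiny_net()
  dc <- numeric(nrow(net$mc)); dc[1] <- 700
  n1 <- run_simulation(net, sim_protocol(duration = 400, dt = 0.1,
                                         mc_dc = dc))
  n2 <- run_simulation(net, sim_protocol(duration = 400, dt = 0.05,
                                         mc_dc = dc))
  expect_equal(sum(n2$spikes$kind == "MC"), sum(n1$spikes$kind == "MC"),
               tolerance = 0.15)
})
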