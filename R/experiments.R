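#' Lateral-inhibition protocol
#'
#' Selects MC pairs with similar granule-cell degree (within
#' `degree_window` of the population mean) and similar disk height
#' (within `dz_max` um), and simulates each pair twice: (a) cell A alone
#' driven by direct current, (b) A and B driven together. The drop in A's
#' firing rate between the two conditions quantifies lateral inhibition.
#' Results are binned by inter-soma distance and fitted with a stretched
#' exponential, alongside the pair's shared-GC count.
#'
#' @param net a `bulb_network` with cell parameters.
#' @param n_pairs number of MC pairs to test.
#' @param current_a,current_b direct currents for cells A and B, pA.
#' @param duration recorded time, ms.
#' @param pad unrecorded settling time, ms.
#' @param degree_window admissible degree deviation from the mean.
#' @param dz_max admissible height difference, um.
#' @param bin_width,n_bins distance binning for summaries, um.
#' @param dt Euler step, ms.
#' @return list with the per-pair table, binned means and (when enough
#'   bins are occupied) stretched-exponential fits.
#' @export
exp_lateral_inhibition <- function(net, n_pairs = 50, current_a = 700,
                                   current_b = 750, duration = 1000,
                                   pad = 100, degree_window = 75,
                                   dz_max = 5, bin_width = 100, n_bins = 12,
                                   dt = 0.1) {
  mc <- net$mc
  ok <- which(abs(mc$degree - mean(mc$degree)) <= degree_window)
  if (length(ok) < 2) stop("too few MCs qualify for pairing")
  cand <- expand.grid(a = ok, b = ok)
  cand <- cand[cand$a < cand$b, ]
  cand <- cand[abs(mc$z[cand$a] - mc$z[cand$b]) <= dz_max, ]
  if (nrow(cand) < 1) stop("no qualifying MC pairs at this height tolerance")
  cand <- cand[sample.int(nrow(cand), min(n_pairs, nrow(cand))), ]
  sets <- mc_gc_sets(net)
  nmc <- nrow(mc)
  run_rate <- function(currents, id) {
    pr <- sim_protocol(duration = duration + pad, dt = dt,
                       mc_dc = currents)
    sim <- run_simulation(net, pr)
    sp <- sim$spikes
    sum(sp$kind == "MC" & sp$id == id & sp$t > pad) / (duration / 1000)
  }
  res <- lapply(seq_len(nrow(cand)), function(i) {
    a <- cand$a[i]; b <- cand$b[i]
    Ia <- numeric(nmc); Ia[a] <- current_a
    rate_a <- run_rate(Ia, a)
    Iab <- Ia; Iab[b] <- current_b
    rate_ab <- run_rate(Iab, a)
    sa <- sets[[a]]
    data.frame(mc_a = a, mc_b = b,
               distance = space_dist(net$space, mc$x[a], mc$y[a],
                                     mc$x[b], mc$y[b]),
               shared = length(intersect(sa, sets[[b]])),
               rate_alone = rate_a, rate_paired = rate_ab,
               delta_rate = rate_a - rate_ab)
  })
  pairs <- do.call(rbind, res)
  br <- seq(0, n_bins * bin_width, by = bin_width)
  bin <- cut(pairs$distance, br, labels = FALSE)
  okb <- !is.na(bin)
  binned <- data.frame(
    distance = br[sort(unique(bin[okb]))] + bin_width / 2,
    delta_rate = as.numeric(tapply(pairs$delta_rate[okb], bin[okb], mean)),
    shared = as.numeric(tapply(pairs$shared[okb], bin[okb], mean)),
    n = as.integer(tapply(bin[okb], bin[okb], length)))
  fit_d <- fit_s <- NULL
  if (nrow(binned) >= 4) {
    fit_d <- try(fit_stretched_exp(binned$distance,
                                   pmax(binned$delta_rate, 0)),
                 silent = TRUE)
    fit_s <- try(fit_stretched_exp(binned$distance, binned$shared),
                 silent = TRUE)
    if (inherits(fit_d, "try-error")) fit_d <- NULL
    if (inherits(fit_s, "try-error")) fit_s <- NULL
  }
  list(pairs = pairs, binned = binned, fit_delta_rate = fit_d,
       fit_shared = fit_s)
}

#' Odor-pattern decorrelation protocol
#'
#' Simulates each odor of a panel twice, with the granule-cell network
#' enabled and disabled (GABA conductance zero), computes per-window
#' Pearson correlations of the MC rate vectors for every odor pair at a
#' grid of window lengths, and reports the difference of the
#' post-first-sniff means (without minus with GCs) as the decorrelation
#' attributable to granule cells.
#'
#' @param net a `bulb_network`.
#' @param panel an [odor_panel()].
#' @param windows window-length grid, ms.
#' @param duration simulated time, ms (6 sniffs at 6 Hz by default).
#' @param dt Euler step, ms.
#' @return list with the per-pair/per-window table and its window means.
#' @export
exp_decorrelation <- function(net, panel, windows = c(2, 5, 10, 20, 50, 100),
                              duration = 1000, dt = 0.1) {
  nmc <- nrow(net$mc)
  ids <- seq_len(nmc)
  sniff_ms <- 1000 / panel$f_sniff
  sims <- lapply(seq_len(panel$n_odors), function(i) {
    cur <- odor_currents(panel, i)
    lapply(c(gc = 1, nogc = 0), function(gs) {
      pr <- sim_protocol(duration = duration, dt = dt,
                         mc_sin_amp = cur$amp, mc_sin_phase = cur$phase,
                         f_sniff = panel$f_sniff, gaba_scale = gs)
      sim <- run_simulation(net, pr)
      sim$spikes[sim$spikes$kind == "MC", c("id", "t")]
    })
  })
  pairs <- utils::combn(panel$n_odors, 2)
  rows <- list()
  for (w in windows) {
    rates <- lapply(sims, function(sc) {
      lapply(sc, windowed_rates, cell_ids = ids, window = w,
             overlap = 0.5, duration = duration)
    })
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      cg <- correlation_timecourse(rates[[i]]$gc, rates[[j]]$gc,
                                   first_sniff_ms = sniff_ms)
      cn <- correlation_timecourse(rates[[i]]$nogc, rates[[j]]$nogc,
                                   first_sniff_ms = sniff_ms)
      rows[[length(rows) + 1L]] <- data.frame(
        window = w, odor_a = i, odor_b = j,
        overlap = length(intersect(panel$sets[[i]], panel$sets[[j]])),
        corr_gc = cg$mean, corr_nogc = cn$mean,
        decorrelation = cn$mean - cg$mean)
    }
  }
  tab <- do.call(rbind, rows)
  by_window <- stats::aggregate(decorrelation ~ window, tab, mean)
  list(pairs = tab, by_window = by_window)
}

#' Sensory-drive oscillation protocol
#'
#' Drives the network with Poisson sensory input to a fraction of
#' glomeruli and records the LFP; with the full granule-cell complement
#' the spectrum peaks in the beta range, while masking GCs down to a
#' reduced active ratio moves the peak into the gamma range. Spectra are
#' averaged over trials (fresh odor draws and Poisson streams).
#'
#' @param net a `bulb_network`.
#' @param active_gc_per_mc active GCs per MC; `NULL` keeps every GC.
#' @param n_trials number of trials averaged.
#' @param duration simulated time per trial, ms.
#' @param dt Euler step, ms.
#' @param odor_fraction fraction of odor-receiving glomeruli.
#' @return list with the averaged spectrum and per-trial spectra.
#' @export
exp_lfp_oscillations <- function(net, active_gc_per_mc = NULL, n_trials = 10,
                                 duration = 1000, dt = 0.1,
                                 odor_fraction = 0.2) {
  ngc <- nrow(net$gc)
  nmc <- nrow(net$mc)
  specs <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    active <- rep(TRUE, ngc)
    if (!is.null(active_gc_per_mc)) {
      n_active <- min(ngc, round(active_gc_per_mc * nmc))
      active <- rep(FALSE, ngc)
      active[sample.int(ngc, n_active)] <- TRUE
    }
    drive <- osn_odor_drive(net, odor_fraction)
    pr <- sim_protocol(duration = duration, dt = dt,
                       osn = drive, gc_active = active, record_lfp = TRUE)
    sim <- run_simulation(net, pr)
    specs[[tr]] <- lfp_spectrum(sim$lfp, dt = dt)
  }
  avg <- specs[[1]]
  if (n_trials > 1) {
    avg$power <- Reduce(`+`, lapply(specs, `[[`, "power")) / n_trials
  }
  list(spectrum = avg, trials = specs)
}

#' Cortical feedback to granule cells
#'
#' Presents one odor and adds constant excitatory current to a subset of
#' GCs at each feedback level. The per-window change in odor-receiving MC
#' firing rates (relative to the no-feedback baseline) is correlated
#' between (i) two disjoint GC target sets in the same network and (ii)
#' the first set versus a regenerated GC arrangement around the same MCs.
#'
#' @param net a `bulb_network`.
#' @param levels fractions of all GCs receiving feedback.
#' @param n_gloms glomeruli targeted by the odor.
#' @param feedback_pA constant feedback current, pA.
#' @param duration simulated time (2 sniffs by default), ms.
#' @param window rate window, ms.
#' @param dt Euler step, ms.
#' @return data.frame per level with same-network and cross-network mean
#'   correlations.
#' @export
exp_gc_feedback <- function(net, levels = c(0.001, 0.01, 0.05, 0.1, 0.15, 0.2),
                            n_gloms = 35, feedback_pA = 50,
                            duration = 1000 / 3, window = 10, dt = 0.1) {
  ngc <- nrow(net$gc)
  nglom <- nrow(net$space$glomeruli)
  panel <- odor_panel(net, n_odors = 1,
                      gloms_per_odor = min(n_gloms, nglom))
  cur <- odor_currents(panel, 1)
  odor_mc <- which(net$mc$glomerulus %in% panel$sets[[1]])
  sniff_ms <- 1000 / panel$f_sniff
  net2 <- regenerate_granule_cells(net)
  rate_seq <- function(network, gc_dc) {
    pr <- sim_protocol(duration = duration, dt = dt, mc_sin_amp = cur$amp,
                       mc_sin_phase = cur$phase, gc_dc = gc_dc,
                       f_sniff = panel$f_sniff)
    sim <- run_simulation(network, pr)
    windowed_rates(sim$spikes[sim$spikes$kind == "MC", c("id", "t")],
                   odor_mc, window = window, overlap = 0.5,
                   duration = duration)
  }
  base1 <- rate_seq(net, 0)
  base2 <- rate_seq(net2, 0)
  out <- lapply(levels, function(lv) {
    n_fb <- round(lv * ngc)
    if (n_fb == 0) {
      return(data.frame(level = lv, n_targeted = 0L,
                        same_net = NA_real_, cross_net = NA_real_))
    }
    if (2 * n_fb > ngc)
      stop("requested level exceeds the available disjoint GC sets")
    pick <- sample.int(ngc, 2 * n_fb)
    set1 <- pick[seq_len(n_fb)]
    set2 <- pick[(n_fb + 1):(2 * n_fb)]
    dc1 <- numeric(ngc); dc1[set1] <- feedback_pA
    dc2 <- numeric(ngc); dc2[set2] <- feedback_pA
    dc3 <- numeric(nrow(net2$gc))
    dc3[sample.int(nrow(net2$gc), min(n_fb, nrow(net2$gc)))] <- feedback_pA
    d1 <- rate_seq(net, dc1) - base1
    d2 <- rate_seq(net, dc2) - base1
    d3 <- rate_seq(net2, dc3) - base2
    same <- correlation_timecourse(d1, d2, first_sniff_ms = sniff_ms)
    cross <- correlation_timecourse(d1, d3, first_sniff_ms = sniff_ms)
    data.frame(level = lv, n_targeted = n_fb, same_net = same$mean,
               cross_net = cross$mean)
  })
  do.call(rbind, out)
}

#' Cortical feedback to mitral cells
#'
#' Presents an odor with and without constant excitatory feedback to a
#' random fraction of MCs (per-cell strength Normal(200, 20) pA) and
#' relates each targeted MC's firing-rate change to its granule-cell
#' degree, split by odor-receiving status.
#'
#' @param net a `bulb_network`.
#' @param fraction fraction of MCs receiving feedback.
#' @param n_trials independent odor/feedback draws.
#' @param n_gloms glomeruli per odor.
#' @param fb_mean,fb_sd feedback current distribution, pA.
#' @param duration simulated time (2 sniffs), ms.
#' @param dt Euler step, ms.
#' @return data.frame per targeted MC and trial with `delta_rate` and
#'   `degree`.
#' @export
exp_mc_feedback <- function(net, fraction = 0.2, n_trials = 5, n_gloms = 35,
                            fb_mean = 200, fb_sd = 20,
                            duration = 1000 / 3, dt = 0.1) {
  nmc <- nrow(net$mc)
  nglom <- nrow(net$space$glomeruli)
  sniff_ms <- 1000 / 6
  rows <- list()
  for (tr in seq_len(n_trials)) {
    panel <- odor_panel(net, n_odors = 1,
                        gloms_per_odor = min(n_gloms, nglom))
    cur <- odor_currents(panel, 1)
    odor_mc <- net$mc$glomerulus %in% panel$sets[[1]]
    targets <- sample.int(nmc, round(fraction * nmc))
    fb <- numeric(nmc)
    fb[targets] <- stats::rnorm(length(targets), fb_mean, fb_sd)
    rate_of <- function(extra_dc) {
      pr <- sim_protocol(duration = duration, dt = dt,
                         mc_sin_amp = cur$amp, mc_sin_phase = cur$phase,
                         mc_dc = extra_dc, f_sniff = panel$f_sniff)
      sim <- run_simulation(net, pr)
      sp <- sim$spikes
      sp <- sp[sp$kind == "MC" & sp$t > sniff_ms, ]
      tabulate(sp$id, nmc) / ((duration - sniff_ms) / 1000)
    }
    delta <- rate_of(fb) - rate_of(numeric(nmc))
    rows[[tr]] <- data.frame(trial = tr, mc_id = targets,
                             delta_rate = delta[targets],
                             degree = net$mc$degree[targets],
                             odor_receiving = odor_mc[targets],
                             feedback_pA = fb[targets])
  }
  do.call(rbind, rows)
}

#' Granule cells added per neurogenesis round in addition modes
#'
#' One tenth of the GCs still needed to reach the target ratio.
#'
#' @param n_mc mitral cells in the base network.
#' @param n_gc granule cells in the base network.
#' @param target_ratio full GC:MC ratio.
#' @param rounds number of neurogenesis rounds.
#' @export
neurogenesis_add_count <- function(n_mc, n_gc, target_ratio = 15,
                                   rounds = 10) {
  round((target_ratio * n_mc - n_gc) / rounds)
}

#' Neurogenesis protocol
#'
#' Runs repeated rounds of granule-cell turnover or growth against a
#' fixed odor panel and tracks how odor-pair correlations evolve. Modes:
#' `control` replaces a random quarter of the GCs with randomly placed
#' newborn cells; `baseline` replaces the least-active quarter;
#' `addition` permanently adds randomly placed GCs each round; `guided`
#' adds GCs placed near active MCs (vertex within one tenth of the MC
#' arbor radius, face height drawn to guarantee overlap). New cells are
#' wired by the standard geometric rules against current occupancy.
#'
#' @param net base `bulb_network`.
#' @param panel an [odor_panel()] (for growth modes typically built with
#'   Uniform(150, 600) pA odor strengths).
#' @param mode neurogenesis mode.
#' @param rounds number of rounds.
#' @param replace_fraction fraction replaced per round (turnover modes).
#' @param add_count GCs added per round (growth modes); default from
#'   [neurogenesis_add_count()].
#' @param window correlation window, ms.
#' @param duration simulated time per odor (2 sniffs), ms.
#' @param dt Euler step, ms.
#' @param min_initial_corr odor pairs below this initial correlation are
#'   excluded from the relative-change summary.
#' @param target_ratio full GC:MC ratio used by the growth default.
#' @return list with the per-round correlation matrix, relative changes,
#'   the fraction of pairs decorrelated, and per-MC degree changes.
#' @export
exp_neurogenesis <- function(net, panel, mode = c("control", "baseline",
                                                  "addition", "guided"),
                             rounds = 10, replace_fraction = 0.25,
                             add_count = NULL, window = 5,
                             duration = 1000 / 3, dt = 0.1,
                             min_initial_corr = 0.1, target_ratio = 15) {
  mode <- match.arg(mode)
  if (is.null(add_count))
    add_count <- neurogenesis_add_count(nrow(net$mc), nrow(net$gc),
                                        target_ratio, rounds)
  sniff_ms <- 1000 / panel$f_sniff
  ids <- seq_len(nrow(net$mc))
  deg0 <- net$mc$degree
  pairs <- utils::combn(panel$n_odors, 2)
  measure <- function(network) {
    rates <- vector("list", panel$n_odors)
    gc_act <- numeric(nrow(network$gc))
    mc_act <- numeric(nrow(network$mc))
    for (i in seq_len(panel$n_odors)) {
      cur <- odor_currents(panel, i)
      pr <- sim_protocol(duration = duration, dt = dt,
                         mc_sin_amp = cur$amp, mc_sin_phase = cur$phase,
                         f_sniff = panel$f_sniff)
      sim <- run_simulation(network, pr)
      msp <- sim$spikes[sim$spikes$kind == "MC", c("id", "t")]
      rates[[i]] <- windowed_rates(msp, ids, window = window,
                                   overlap = 0.5, duration = duration)
      mc_act <- mc_act + tabulate(msp$id, nrow(network$mc))
      gsp <- sim$spikes[sim$spikes$kind == "GC", ]
      gc_act <- gc_act + tabulate(gsp$id, nrow(network$gc))
    }
    corr <- vapply(seq_len(ncol(pairs)), function(p) {
      correlation_timecourse(rates[[pairs[1, p]]], rates[[pairs[2, p]]],
                             first_sniff_ms = sniff_ms)$mean
    }, numeric(1))
    if (sum(mc_act) == 0) mc_act <- rep(1, length(mc_act))
    list(corr = corr, gc_activity = gc_act,
         mc_weights = mc_act / sum(mc_act))
  }
  corr_mat <- matrix(NA_real_, rounds + 1, ncol(pairs))
  m <- measure(net)
  corr_mat[1, ] <- m$corr
  for (rd in seq_len(rounds)) {
    if (mode %in% c("control", "baseline")) {
      n_rep <- round(replace_fraction * nrow(net$gc))
      drop_ids <- if (mode == "control") {
        sample.int(nrow(net$gc), n_rep)
      } else {
        order(m$gc_activity, stats::runif(length(m$gc_activity)))[
          seq_len(n_rep)]
      }
      net <- remove_granule_cells(net, drop_ids)
      net <- add_granule_cells(net, n_rep, placement = "random")
    } else if (mode == "addition") {
      net <- add_granule_cells(net, add_count, placement = "random")
    } else {
      net <- add_granule_cells(net, add_count, placement = "guided",
                               mc_weights = m$mc_weights)
    }
    m <- measure(net)
    corr_mat[rd + 1, ] <- m$corr
  }
  keep <- which(corr_mat[1, ] > min_initial_corr)
  rel_change <- (corr_mat[rounds + 1, keep] - corr_mat[1, keep]) /
    corr_mat[1, keep]
  list(correlations = corr_mat,
       pair_overlaps = vapply(seq_len(ncol(pairs)), function(p) {
         length(intersect(panel$sets[[pairs[1, p]]],
                          panel$sets[[pairs[2, p]]]))
       }, integer(1)),
       scored_pairs = keep,
       relative_change = rel_change,
       mean_relative_reduction = -mean(rel_change),
       fraction_decorrelated = mean(rel_change < 0),
       degree_initial = deg0, degree_change = net$mc$degree - deg0,
       final_network = net)
}
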