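#' Local field potential weights
#'
#' Point-source weights `1 / (4 pi sigma |r_e - r_s|)` converting a pA
#' synaptic current at position `r_s` into its microvolt contribution at
#' the electrode `r_e`. Distances below 1 um are clamped.
#'
#' @param positions n x 3 matrix of synapse positions, um.
#' @param electrode length-3 electrode position, um.
#' @param sigma extracellular conductivity, 1/(Ohm cm).
#' @return numeric vector of weights, uV per pA.
#' @export
lfp_weights <- function(positions, electrode, sigma = 1 / 300) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  d <- sqrt((positions[, 1] - electrode[1])^2 +
              (positions[, 2] - electrode[2])^2 +
              (positions[, 3] - electrode[3])^2)
  d <- pmax(d, 1)
  sigma_si <- sigma * 100 # 1/(Ohm cm) -> S/m
  1 / (4 * pi * sigma_si * d)
}

#' Synthesise an LFP trace from recorded synaptic currents
#'
#' @param currents steps x synapses matrix of currents, pA.
#' @param positions n x 3 synapse positions, um.
#' @param electrode electrode position, um.
#' @param sigma extracellular conductivity, 1/(Ohm cm).
#' @return LFP trace in uV, one sample per row of `currents`.
#' @export
compute_lfp <- function(currents, positions, electrode, sigma = 1 / 300) {
  w <- lfp_weights(positions, electrode, sigma)
  as.numeric(currents %*% w)
}

# default electrode: x-y centre of the space, halfway up the EPL
default_electrode <- function(space) {
  xy <- if (space$boundary == "periodic") c(space$box / 2, space$box / 2)
        else c(0, 0)
  c(xy, space$layers$epl_floor + space$layers$epl / 2)
}

#' Simulation protocol
#'
#' Bundles the external drive and switches for [run_simulation()]:
#' constant injected currents, sinusoidal sniff-locked odor currents
#' (`I(t) = I0/2 + I0/4 (sin(2 pi f t - phi) + 1)` per MC), Poisson
#' sensory-fiber drive, the active-GC mask, and the GABA scale used to
#' disable granule-cell inhibition.
#'
#' @param duration simulated time, ms.
#' @param dt Euler step, ms.
#' @param mc_dc,gc_dc constant currents (scalar or per-cell), pA.
#' @param mc_sin_amp,mc_sin_phase sinusoidal current amplitude (pA) and
#'   phase (rad) per MC; amplitude 0 disables.
#' @param osn list with per-MC `rate` (Hz) and `phase` (rad) for Poisson
#'   sensory drive, or `NULL`.
#' @param f_sniff sniff frequency, Hz.
#' @param gc_active logical mask of participating GCs.
#' @param gaba_scale multiplier on the GABA conductance (0 disables
#'   granule-cell inhibition).
#' @param record_lfp record the summed point-source LFP.
#' @param lfp_include_osn include sensory-synapse currents in the LFP sum.
#' @param record_v_mc,record_v_gc cell ids whose voltage traces to keep.
#' @param kappa_self second-order GABA update also applies to the spiking
#'   MC's own synapses.
#' @return a `bulb_protocol` list.
#' @export
sim_protocol <- function(duration = 1000, dt = 0.1, mc_dc = 0, gc_dc = 0,
                         mc_sin_amp = 0, mc_sin_phase = 0, osn = NULL,
                         f_sniff = 6, gc_active = TRUE, gaba_scale = 1,
                         record_lfp = FALSE, lfp_include_osn = TRUE,
                         record_v_mc = integer(), record_v_gc = integer(),
                         kappa_self = TRUE) {
  structure(as.list(environment()), class = "bulb_protocol")
}

#' Run a network simulation
#'
#' Forward-Euler integration of the full network under a protocol: per
#' step, receptor and injected currents are gathered, gating variables
#' advanced, all cells stepped, and spikes processed (AMPA/NMDA drive onto
#' connected granule cells, first- and second-order GABA onto mitral
#' cells).
#'
#' @param net a `bulb_network` with attached cell parameters.
#' @param protocol a [sim_protocol()].
#' @param syn_params a [synaptic_params()].
#' @param osn_pars an [osn_params()].
#' @param electrode LFP electrode position; default centre of the space,
#'   halfway up the EPL.
#' @param sigma extracellular conductivity, 1/(Ohm cm).
#' @return a `bulb_sim` list with `spikes` (cell kind, id, time),
#'   `lfp` (uV), voltage traces, and the timing metadata.
#' @export
run_simulation <- function(net, protocol = sim_protocol(),
                           syn_params = synaptic_params(),
                           osn_pars = osn_params(),
                           electrode = NULL, sigma = 1 / 300) {
  nmc <- nrow(net$mc)
  ngc <- nrow(net$gc)
  if (is.null(net$mc$iz_C)) stop("network has no cell parameters attached")
  pm <- as.matrix(net$mc[, paste0("iz_", c("C", "k", "a", "b", "c", "d",
                                           "vr", "vt", "vc"))])
  pg <- as.matrix(net$gc[, paste0("iz_", c("C", "k", "a", "b", "c", "d",
                                           "vr", "vt", "vc"))])
  if (is.null(electrode)) electrode <- default_electrode(net$space)
  syn <- net$syn
  lfpw <- if (protocol$record_lfp && nrow(syn) > 0)
    lfp_weights(cbind(syn$x, syn$y, syn$z), electrode, sigma)
  else rep(0, nrow(syn))
  use_osn <- !is.null(protocol$osn)
  osn_rate <- if (use_osn) rep_len(protocol$osn$rate, nmc) else rep(0, nmc)
  osn_phase <- if (use_osn) rep_len(protocol$osn$phase, nmc) else rep(0, nmc)
  osn_lfpw <- if (protocol$record_lfp && use_osn)
    lfp_weights(cbind(net$mc$x, net$mc$y, net$mc$z), electrode, sigma)
  else rep(0, nmc)
  ddr <- c(syn_params$g_AMPA, syn_params$g_NMDA, syn_params$g_GABA,
           syn_params$tau_AMPA, syn_params$tau_NMDA_rise,
           syn_params$tau_NMDA_decay, syn_params$tau_GABA,
           syn_params$alpha, syn_params$kappa, syn_params$W,
           syn_params$lambda_len, syn_params$E_e, syn_params$E_i,
           syn_params$Mg)
  osnv <- c(osn_pars$g_AMPA, osn_pars$g_NMDA, osn_pars$tau_AMPA,
            osn_pars$tau_NMDA_rise, osn_pars$tau_NMDA_decay,
            osn_pars$alpha, osn_pars$W)
  res <- cpp_simulate(pm, pg, net$syn$mc_id, net$syn$gc_id, net$syn$dist,
                      lfpw, ddr, osnv, use_osn,
                      as.integer(osn_pars$n_synapses), osn_rate, osn_phase,
                      protocol$f_sniff, osn_lfpw,
                      rep_len(protocol$mc_dc, nmc),
                      rep_len(protocol$gc_dc, ngc),
                      rep_len(protocol$mc_sin_amp, nmc),
                      rep_len(protocol$mc_sin_phase, nmc),
                      rep_len(protocol$gc_active, ngc),
                      protocol$gaba_scale, protocol$duration, protocol$dt,
                      protocol$record_lfp, protocol$lfp_include_osn,
                      as.integer(protocol$record_v_mc),
                      as.integer(protocol$record_v_gc),
                      protocol$kappa_self)
  kind <- ifelse(res$spike_cell <= nmc, "MC", "GC")
  id <- ifelse(res$spike_cell <= nmc, res$spike_cell, res$spike_cell - nmc)
  structure(list(
    spikes = data.frame(kind = kind, id = id, t = res$spike_t),
    lfp = if (protocol$record_lfp) res$lfp else NULL,
    v_mc = res$v_mc, v_gc = res$v_gc,
    duration = protocol$duration, dt = protocol$dt,
    n_mc = nmc, n_gc = ngc, electrode = electrode
  ), class = "bulb_sim")
}

#' @export
print.bulb_sim <- function(x, ...) {
  cat("Simulation:", x$duration, "ms at dt =", x$dt, "ms;",
      nrow(x$spikes), "spikes from", x$n_mc, "MCs and", x$n_gc, "GCs\n")
  invisible(x)
}

#' Odor panel for current-injection protocols
#'
#' Builds a set of odors as glomerulus subsets plus the per-glomerulus and
#' per-cell input draws. A glomerulus targeted by several odors keeps one
#' shared strength and phase (and per-MC jitter), so overlapping odors
#' drive shared glomeruli identically; background draws are per odor.
#'
#' @param net a `bulb_network`.
#' @param n_odors number of odors.
#' @param gloms_per_odor glomeruli targeted by each odor.
#' @param arrangement `"sliding"` (odor i targets glomeruli
#'   `(i-1)*stride + 1 ...`) or `"random"`.
#' @param stride sliding-window offset between consecutive odors.
#' @param pool for random arrangements, sample each odor's glomeruli from
#'   the first `pool` glomeruli only; a pool of roughly
#'   `gloms_per_odor^2 / target_overlap` sets the expected pairwise
#'   overlap. `NULL` uses all glomeruli.
#' @param odor_mean_range uniform range of the per-glomerulus mean odor
#'   current, pA.
#' @param background_range uniform range of the background mean current,
#'   pA.
#' @param f_sniff sniff frequency, Hz.
#' @return an `odor_panel` list; `currents(panel, odor)` gives per-MC
#'   sinusoid amplitude and phase.
#' @export
odor_panel <- function(net, n_odors = 6, gloms_per_odor = 30,
                       arrangement = c("sliding", "random"), stride = 5,
                       pool = NULL,
                       odor_mean_range = c(400, 600),
                       background_range = c(0, 150), f_sniff = 6) {
  arrangement <- match.arg(arrangement)
  nglom <- nrow(net$space$glomeruli)
  stopifnot(gloms_per_odor <= nglom)
  if (is.null(pool)) pool <- nglom
  pool <- max(gloms_per_odor, min(pool, nglom))
  sets <- lapply(seq_len(n_odors), function(i) {
    if (arrangement == "sliding") {
      ((seq_len(gloms_per_odor) + (i - 1) * stride - 1) %% nglom) + 1
    } else {
      sample.int(pool, gloms_per_odor)
    }
  })
  # shared per-glomerulus odor draws
  g_mean <- stats::runif(nglom, odor_mean_range[1], odor_mean_range[2])
  g_phase <- stats::runif(nglom, 0, 2 * pi)
  gid <- net$mc$glomerulus
  nmc <- nrow(net$mc)
  mc_amp_odor <- stats::rnorm(nmc, g_mean[gid], g_mean[gid] / 5)
  mc_phase_odor <- stats::rnorm(nmc, g_phase[gid], pi / 4)
  per_odor <- lapply(seq_len(n_odors), function(i) {
    bg_mean <- stats::runif(nglom, background_range[1], background_range[2])
    bg_phase <- stats::runif(nglom, 0, 2 * pi)
    amp <- stats::rnorm(nmc, bg_mean[gid], bg_mean[gid] / 5)
    ph <- stats::rnorm(nmc, bg_phase[gid], pi / 4)
    act <- gid %in% sets[[i]]
    amp[act] <- mc_amp_odor[act]
    ph[act] <- mc_phase_odor[act]
    list(amp = pmax(amp, 0), phase = ph)
  })
  structure(list(sets = sets, per_odor = per_odor, f_sniff = f_sniff,
                 n_odors = n_odors), class = "odor_panel")
}

#' Per-MC currents of one odor in a panel
#'
#' @param panel an [odor_panel()].
#' @param odor odor index.
#' @return list with `amp` (pA) and `phase` (rad) per MC.
#' @export
odor_currents <- function(panel, odor) panel$per_odor[[odor]]

#' Poisson sensory drive for an odor
#'
#' Selects a fraction of glomeruli as odor-receiving; per glomerulus a
#' mean rate (uniform 2-3 Hz odor, 0-0.25 Hz background) and phase are
#' drawn, then jittered per sister MC (rate sd one tenth of the mean,
#' phase sd pi/4).
#'
#' @param net a `bulb_network`.
#' @param odor_fraction fraction of glomeruli receiving odor.
#' @param odor_rate_range,background_rate_range uniform ranges, Hz.
#' @return list with per-MC `rate` and `phase` and the odor glomeruli.
#' @export
osn_odor_drive <- function(net, odor_fraction = 0.2,
                           odor_rate_range = c(2, 3),
                           background_rate_range = c(0, 0.25)) {
  nglom <- nrow(net$space$glomeruli)
  n_odor <- round(odor_fraction * nglom)
  odor_gloms <- sample.int(nglom, n_odor)
  xg <- stats::runif(nglom, background_rate_range[1], background_rate_range[2])
  xg[odor_gloms] <- stats::runif(n_odor, odor_rate_range[1],
                                 odor_rate_range[2])
  pg <- stats::runif(nglom, 0, 2 * pi)
  gid <- net$mc$glomerulus
  rate <- pmax(stats::rnorm(nrow(net$mc), xg[gid], xg[gid] / 10), 0)
  phase <- stats::rnorm(nrow(net$mc), pg[gid], pi / 4)
  list(rate = rate, phase = phase, odor_glomeruli = odor_gloms)
}
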