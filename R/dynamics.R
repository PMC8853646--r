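#' Default Izhikevich parameters
#'
#' Mean single-cell parameters for mitral and granule cells. Units:
#' `C` pF, `k` nS/mV, `a` 1/ms, `b` nS, `c` mV, `d` pA, `v_r`, `v_t`,
#' `v_c` mV. Mitral cells are class II (discontinuous f-I onset); granule
#' cells are integrators with `b < 0`.
#'
#' @param kind `"MC"` or `"GC"`.
#' @return named numeric vector in the order
#'   `C, k, a, b, c, d, v_r, v_t, v_c`.
#' @export
izhikevich_defaults <- function(kind = c("MC", "GC")) {
  kind <- match.arg(kind)
  if (kind == "MC")
    c(C = 191, k = 2.5, a = 0.02, b = 12, c = -70, d = 13,
      v_r = -58, v_t = -49, v_c = 30)
  else
    c(C = 48, k = 0.067, a = 0.01, b = -0.133, c = -75, d = 2,
      v_r = -71, v_t = -39, v_c = 25)
}

#' One forward-Euler step of the Izhikevich model
#'
#' Reference (scalar) implementation of the update used by the network
#' engine: `C dv/dt = k (v - v_r)(v - v_t) - u + I`,
#' `du/dt = a (b (v - v_r) - u)`, with post-update threshold test: if
#' `v >= v_c` the cell spikes, `v <- c` and `u <- u + d`.
#'
#' @param state list with `v` (mV) and `u` (pA).
#' @param p parameter vector as from [izhikevich_defaults()].
#' @param I injected current, pA.
#' @param dt time step, ms.
#' @return list with updated `v`, `u` and logical `spike`.
#' @export
izhikevich_step <- function(state, p, I, dt = 0.1) {
  stopifnot(dt > 0)
  v <- state$v + dt * (p[["k"]] * (state$v - p[["v_r"]]) *
                         (state$v - p[["v_t"]]) - state$u + I) / p[["C"]]
  u <- state$u + dt * p[["a"]] * (p[["b"]] * (state$v - p[["v_r"]]) - state$u)
  if (!is.finite(v) || !is.finite(u))
    stop("integration failure: non-finite state")
  spike <- v >= p[["v_c"]]
  if (spike) {
    v <- p[["c"]]
    u <- u + p[["d"]]
  }
  list(v = v, u = u, spike = spike)
}

#' Granule-cell excitability from (b, k)
#'
#' For an integrator with `b < 0` the Izhikevich pair `(b, k)` maps to the
#' input resistance `R` and rheobase via
#' `b = (v_r - v_t + 4 R rho) / (4 R^2 rho)` and `k = 1 / (4 R^2 rho)`.
#' Inverting with `D = b/k - (v_r - v_t)`: `rheobase = k D^2 / 4` and
#' `R = D / (4 rheobase)`.
#'
#' @param b recovery coupling, nS.
#' @param k voltage nonlinearity, nS/mV.
#' @param v_r,v_t resting and threshold potentials, mV.
#' @return list with `R` (GOhm) and `rheobase` (pA).
#' @export
gc_excitability_from_bk <- function(b, k, v_r = -71, v_t = -39) {
  stopifnot(k > 0)
  D <- b / k - (v_r - v_t)
  if (D <= 0) stop("no excitability solution: b/k - (v_r - v_t) <= 0")
  rheo <- k * D^2 / 4
  list(R = D / (4 * rheo), rheobase = rheo)
}

#' (b, k) from excitability
#'
#' Forward map used to verify the inversion in
#' [gc_excitability_from_bk()].
#'
#' @param R input resistance, GOhm.
#' @param rheobase rheobase current, pA.
#' @inheritParams gc_excitability_from_bk
#' @return list with `b` and `k`.
#' @export
gc_bk_from_excitability <- function(R, rheobase, v_r = -71, v_t = -39) {
  list(b = (v_r - v_t + 4 * R * rheobase) / (4 * R^2 * rheobase),
       k = 1 / (4 * R^2 * rheobase))
}

#' Sample heterogeneous Izhikevich parameters
#'
#' Every parameter is drawn from a normal distribution centred on its
#' mean with standard deviation one tenth of the absolute mean, except
#' the granule-cell pair `(b, k)`, which is drawn jointly with standard
#' deviation two thirds of the absolute mean and re-sampled until `b < 0`,
#' the implied rheobase lies in `[10, 70]` pA and the input resistance in
#' `[0.25, 1.5]` GOhm. Draws violating `v_r < v_t < v_c` or non-positive
#' `C`/`k` are also re-sampled.
#'
#' @param kind `"MC"` or `"GC"`.
#' @param n number of cells.
#' @param max_tries resampling cap per cell for the GC `(b, k)` pair.
#' @return matrix `n x 9`, columns `C, k, a, b, c, d, v_r, v_t, v_c`.
#' @export
sample_cell_params <- function(kind = c("MC", "GC"), n = 1,
                               max_tries = 10000) {
  kind <- match.arg(kind)
  mu <- izhikevich_defaults(kind)
  draw <- function(m, sdf) stats::rnorm(n, m, abs(m) * sdf)
  out <- matrix(NA_real_, n, 9, dimnames = list(NULL, names(mu)))
  for (nm in names(mu)) out[, nm] <- draw(mu[[nm]], 0.1)
  # enforce ordering and positivity by per-cell redraws
  bad <- which(!(out[, "v_r"] < out[, "v_t"] & out[, "v_t"] < out[, "v_c"]) |
                 out[, "C"] <= 0)
  for (i in bad) {
    for (tr in seq_len(max_tries)) {
      for (nm in c("C", "v_r", "v_t", "v_c"))
        out[i, nm] <- stats::rnorm(1, mu[[nm]], abs(mu[[nm]]) * 0.1)
      if (out[i, "v_r"] < out[i, "v_t"] && out[i, "v_t"] < out[i, "v_c"] &&
          out[i, "C"] > 0) break
      if (tr == max_tries) stop("parameter resampling cap exceeded")
    }
  }
  if (kind == "GC") {
    for (i in seq_len(n)) {
      ok <- FALSE
      for (tr in seq_len(max_tries)) {
        if (tr %% 200 == 0) {
          # a small |v_r - v_t| draw can make the window unreachable for
          # any (b, k); redraw the voltage pair as well
          repeat {
            vr <- stats::rnorm(1, mu[["v_r"]], abs(mu[["v_r"]]) * 0.1)
            vt <- stats::rnorm(1, mu[["v_t"]], abs(mu[["v_t"]]) * 0.1)
            if (vr < vt && vt < out[i, "v_c"]) break
          }
          out[i, "v_r"] <- vr
          out[i, "v_t"] <- vt
        }
        b <- stats::rnorm(1, mu[["b"]], abs(mu[["b"]]) * 2 / 3)
        k <- stats::rnorm(1, mu[["k"]], abs(mu[["k"]]) * 2 / 3)
        if (b >= 0 || k <= 0) next
        D <- b / k - (out[i, "v_r"] - out[i, "v_t"])
        if (D <= 0) next
        rheo <- k * D^2 / 4
        R <- D / (4 * rheo)
        if (rheo >= 10 && rheo <= 70 && R >= 0.25 && R <= 1.5) {
          out[i, "b"] <- b
          out[i, "k"] <- k
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("GC (b, k) resampling cap exceeded")
    }
  } else {
    out[, "k"] <- pmax(out[, "k"], 1e-3)
  }
  out
}

# attach sampled Izhikevich parameters to a network's cell tables
# (tables already carrying parameters, e.g. reused MCs, are left alone)
attach_cell_params <- function(net) {
  nm <- paste0("iz_", c("C", "k", "a", "b", "c", "d", "vr", "vt", "vc"))
  if (is.null(net$mc$iz_C)) {
    pm <- sample_cell_params("MC", nrow(net$mc))
    colnames(pm) <- nm
    net$mc <- cbind(net$mc, as.data.frame(pm))
  }
  if (is.null(net$gc$iz_C)) {
    pg <- sample_cell_params("GC", nrow(net$gc))
    colnames(pg) <- nm
    net$gc <- cbind(net$gc, as.data.frame(pg))
  }
  net
}

#' Dendrodendritic receptor parameters
#'
#' Conductances (nS), time constants (ms), the NMDA activation rate
#' `alpha` (1/ms), the gating increment `W`, the second-order GABA factor
#' `kappa`, the GABA dendritic attenuation length `lambda_len` (um), the
#' reversal potentials (mV) and the magnesium concentration (mM).
#'
#' @param ... overrides.
#' @export
synaptic_params <- function(...) {
  p <- list(g_AMPA = 0.73, g_NMDA = 0.84, g_GABA = 0.13, kappa = 0.006,
            tau_AMPA = 5.5, tau_NMDA_rise = 10, tau_NMDA_decay = 80,
            tau_GABA = 18, lambda_len = 675, alpha = 0.1, W = 0.5,
            E_e = 0, E_i = -70, Mg = 1)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

#' Sensory (OSN) input receptor parameters
#'
#' AMPA/NMDA parameters of the 100 olfactory-sensory-neuron synapses per
#' mitral cell.
#'
#' @param ... overrides.
#' @export
osn_params <- function(...) {
  p <- list(g_AMPA = 6.7, g_NMDA = 12, tau_AMPA = 14.3, tau_NMDA_rise = 13,
            tau_NMDA_decay = 70, alpha = 0.03, W = 0.5, n_synapses = 100L)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

#' Receptor current
#'
#' Driving-force receptor currents: AMPA `s g (V - E_e)`; GABA
#' `s g (V - E_i) exp(-L / lambda)` with `L` the dendritic distance of the
#' synapse from the MC centre; NMDA with the magnesium-block denominator
#' `1 + Mg exp(-0.062 V) / 3.57`.
#'
#' @param class one of `"AMPA"`, `"NMDA"`, `"GABA"`.
#' @param s gating variable in `[0, 1]`.
#' @param V membrane potential of the recipient cell, mV.
#' @param params a [synaptic_params()].
#' @param dendritic_distance synapse distance from the MC centre, um
#'   (GABA only).
#' @return current in pA (sign as written; depolarising currents are
#'   subtracted in the membrane equation).
#' @export
receptor_current <- function(class = c("AMPA", "NMDA", "GABA"), s, V,
                             params = synaptic_params(),
                             dendritic_distance = 0) {
  class <- match.arg(class)
  stopifnot(all(s >= 0), all(s <= 1))
  switch(class,
    AMPA = s * params$g_AMPA * (V - params$E_e),
    NMDA = s * params$g_NMDA * (V - params$E_e) /
      (1 + params$Mg * exp(-0.062 * V) / 3.57),
    GABA = s * params$g_GABA * (V - params$E_i) *
      exp(-dendritic_distance / params$lambda_len))
}

#' Advance synaptic gating variables by one Euler step
#'
#' AMPA and GABA decay exponentially; the NMDA open fraction relaxes with
#' its decay constant while being driven by the rise variable `n`:
#' `ds/dt = -s/tau_decay + alpha n (1 - s)`, `dn/dt = -n/tau_rise`.
#'
#' @param syn list with `s_AMPA`, `s_NMDA`, `n`, `s_GABA`.
#' @param dt time step, ms.
#' @param params a [synaptic_params()].
#' @return updated gating list; all variables remain in `[0, 1]`.
#' @export
advance_gating <- function(syn, dt = 0.1, params = synaptic_params()) {
  stopifnot(dt > 0)
  list(
    s_AMPA = syn$s_AMPA - dt * syn$s_AMPA / params$tau_AMPA,
    s_NMDA = syn$s_NMDA + dt * (-syn$s_NMDA / params$tau_NMDA_decay +
                                  params$alpha * syn$n * (1 - syn$s_NMDA)),
    n = syn$n - dt * syn$n / params$tau_NMDA_rise,
    s_GABA = syn$s_GABA - dt * syn$s_GABA / params$tau_GABA)
}

#' Spike-triggered gating update
#'
#' The saturating increment `s <- s + W (1 - s)` applied on presynaptic
#' spikes; the second-order GABA update uses `kappa * W`.
#'
#' @param s gating value(s) in `[0, 1]`.
#' @param W increment weight.
#' @return updated gating value(s).
#' @export
gating_bump <- function(s, W = 0.5) s + W * (1 - s)

#' Simulate one isolated cell under direct current
#'
#' @param params parameter vector as from [izhikevich_defaults()].
#' @param I direct current, pA.
#' @param duration recorded duration, ms.
#' @param dt Euler step, ms.
#' @param pad unrecorded settling time, ms.
#' @param trace return the voltage trace.
#' @return list with `n_spikes`, `rate_hz`, `spike_t` and optionally `v`.
#' @export
simulate_single_cell <- function(params, I, duration = 1000, dt = 0.1,
                                 pad = 100, trace = FALSE) {
  res <- cpp_single_cell(as.numeric(params[c("C", "k", "a", "b", "c", "d",
                                             "v_r", "v_t", "v_c")]),
                         I, duration, dt, pad, trace)
  res$rate_hz <- res$n_spikes / (duration / 1000)
  res
}

#' Frequency-current curve of a single cell
#'
#' One second of direct current per level, after a settling pad.
#'
#' @inheritParams simulate_single_cell
#' @param currents current levels, pA.
#' @return data.frame with `I` and `rate_hz`.
#' @export
fi_curve <- function(params, currents, duration = 1000, dt = 0.1,
                     pad = 100) {
  data.frame(I = currents, rate_hz = vapply(currents, function(I) {
    simulate_single_cell(params, I, duration, dt, pad)$rate_hz
  }, numeric(1)))
}

#' Rheobase by simulation
#'
#' Smallest current on a grid producing at least one spike in a
#' one-second simulation.
#'
#' @inheritParams simulate_single_cell
#' @param grid current grid, pA.
#' @return rheobase estimate, pA (`NA` if no grid point spikes).
#' @export
measure_rheobase <- function(params, grid = seq(1, 100, by = 1),
                             duration = 1000, dt = 0.1, pad = 100) {
  for (I in grid) {
    if (simulate_single_cell(params, I, duration, dt, pad)$n_spikes > 0)
      return(I)
  }
  NA_real_
}
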