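#' Remove granule cells from a network
#'
#' Deletes the given GCs and their synapses, renumbers the remaining GCs
#' and updates the mitral-cell occupancy/degree counts.
#'
#' @param net a `bulb_network`.
#' @param gc_ids ids of the GCs to remove.
#' @return the updated network.
#' @export
remove_granule_cells <- function(net, gc_ids) {
  keep <- setdiff(seq_len(nrow(net$gc)), gc_ids)
  map <- integer(nrow(net$gc))
  map[keep] <- seq_along(keep)
  net$gc <- net$gc[keep, , drop = FALSE]
  net$gc$id <- seq_len(nrow(net$gc))
  rownames(net$gc) <- NULL
  syn <- net$syn[!(net$syn$gc_id %in% gc_ids), , drop = FALSE]
  syn$gc_id <- map[syn$gc_id]
  rownames(syn) <- NULL
  net$syn <- syn
  net$mc$degree <- tabulate(syn$mc_id, nrow(net$mc))
  net$gc$degree <- tabulate(syn$gc_id, nrow(net$gc))
  net
}

# sample guided GC candidates: vertex within guide_radius_frac of a
# weight-sampled MC's arbor radius, face height resampled (bounded) to
# guarantee disk-cone overlap
sample_guided_gcs <- function(net, n, mc_weights, config,
                              guide_radius_frac = 0.1, max_tries = 20) {
  layers <- net$space$layers
  mc_idx <- sample.int(nrow(net$mc), n, replace = TRUE, prob = mc_weights)
  rr <- net$mc$r_max[mc_idx] * guide_radius_frac * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  vx <- net$mc$x[mc_idx] + rr * cos(th)
  vy <- net$mc$y[mc_idx] + rr * sin(th)
  if (net$space$boundary == "periodic") {
    vx <- vx %% net$space$box
    vy <- vy %% net$space$box
  }
  z0 <- stats::runif(n, 0, layers$epl_floor)
  zmc <- net$mc$z[mc_idx]
  z_max <- layers$epl_floor + stats::runif(n, layers$epl / 2, layers$epl)
  for (i in which(z_max < zmc)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      z_max[i] <- layers$epl_floor + stats::runif(1, layers$epl / 2,
                                                  layers$epl)
      if (z_max[i] >= zmc[i]) { ok <- TRUE; break }
    }
    if (!ok) # fallback: draw directly in the legal range
      z_max[i] <- stats::runif(1, zmc[i], layers$epl_floor + layers$epl)
  }
  r_max <- rtrunc_norm(n, config$gc_rmax_mean, config$gc_rmax_sd,
                       config$gc_rmax_bounds[1], config$gc_rmax_bounds[2])
  obl <- stats::runif(n, 0, config$gc_obliquity_max)
  oth <- stats::runif(n, 0, 2 * pi)
  vol <- pi * r_max^2 * (z_max - z0) / 3
  b <- spine_bounds(vol, config)
  S <- round(stats::runif(n, b[, "lo"], b[, "hi"]))
  s_av <- vapply(seq_len(n), function(i) {
    available_spines(list(z0 = z0[i], z_max = z_max[i], S = S[i]), layers)
  }, numeric(1))
  data.frame(vx = vx, vy = vy, fx = vx + obl * cos(oth),
             fy = vy + obl * sin(oth), r_max = r_max, z0 = z0,
             z_max = z_max, S = S, S_available = s_av)
}

#' Add newborn granule cells to a network
#'
#' Wires `n_new` connected GCs into an existing network using the same
#' sequential probabilistic rules as [generate_network()], against the
#' current synaptic occupancy. Placement is either random (as in the
#' initial build) or guided towards active MCs.
#'
#' @param net a `bulb_network`.
#' @param n_new connected GCs to add.
#' @param placement `"random"` or `"guided"`.
#' @param mc_weights MC sampling weights for guided placement.
#' @param config a [placement_config()].
#' @param guide_radius_frac vertex offset bound as a fraction of the
#'   chosen MC's arbor radius.
#' @return the grown network.
#' @export
add_granule_cells <- function(net, n_new,
                              placement = c("random", "guided"),
                              mc_weights = NULL,
                              config = placement_config(),
                              guide_radius_frac = 0.1) {
  placement <- match.arg(placement)
  if (n_new <= 0) return(net)
  if (placement == "guided" && is.null(mc_weights))
    stop("guided placement needs MC activity weights")
  mcs <- net$mc
  n_ps <- as.integer(mcs$degree)
  kept <- 0L
  offset <- nrow(net$gc)
  gc_rows <- list()
  syn_rows <- list()
  while (kept < n_new) {
    batch <- max(32L, ceiling((n_new - kept) * 1.15))
    gcs <- if (placement == "random") {
      place_granule_cells(net$space, batch, config)
    } else {
      sample_guided_gcs(net, batch, mc_weights, config, guide_radius_frac)
    }
    res <- cpp_wire_batch(mcs$x, mcs$y, mcs$z, mcs$r_max, mcs$alpha, mcs$k,
                          mcs$m, mcs$length_total, n_ps,
                          gcs$vx, gcs$vy, gcs$fx, gcs$fy, gcs$r_max,
                          gcs$z0, gcs$z_max, gcs$S_available,
                          as.integer(pmax(0, floor(gcs$S_available))),
                          net$consts$q, net$consts$v_spine, net$eps,
                          0L, 0, n_new - kept, box = net$space$box)
    n_ps <- res$n_ps
    proc <- res$processed
    keep <- res$keep[seq_len(proc)]
    if (res$kept > 0) {
      kb <- gcs[seq_len(proc), ][keep, , drop = FALSE]
      kb$batch_local <- which(keep)
      sr <- data.frame(mc_id = res$syn_mc, gc_local = res$syn_gc,
                       x = res$syn_x, y = res$syn_y, z = res$syn_z,
                       dist = res$syn_dist)
      idx <- match(sr$gc_local, kb$batch_local)
      sr$gc_id <- offset + kept + idx
      sr$gc_local <- NULL
      syn_rows[[length(syn_rows) + 1L]] <- sr
      gc_rows[[length(gc_rows) + 1L]] <- kb
      kept <- kept + res$kept
    }
  }
  gc_new <- do.call(rbind, gc_rows)
  gc_new$batch_local <- NULL
  pg <- sample_cell_params("GC", nrow(gc_new))
  colnames(pg) <- paste0("iz_", c("C", "k", "a", "b", "c", "d", "vr",
                                  "vt", "vc"))
  gc_new <- cbind(gc_new, as.data.frame(pg))
  gc_new$id <- offset + seq_len(nrow(gc_new))
  gc_new$degree <- 0L
  gc_new <- gc_new[, names(net$gc)]
  net$gc <- rbind(net$gc, gc_new)
  rownames(net$gc) <- NULL
  syn_new <- do.call(rbind, syn_rows)
  net$syn <- rbind(net$syn,
                   syn_new[, c("mc_id", "gc_id", "x", "y", "z", "dist")])
  rownames(net$syn) <- NULL
  net$mc$degree <- tabulate(net$syn$mc_id, nrow(net$mc))
  net$gc$degree <- tabulate(net$syn$gc_id, nrow(net$gc))
  net
}

#' Regenerate the granule-cell arrangement around fixed mitral cells
#'
#' Builds a fresh GC population and wiring for the same space and MC
#' table (keeping the MCs' dynamics parameters), as used by the
#' cross-network feedback comparison.
#'
#' @param net a `bulb_network`.
#' @param ... passed to [generate_network()].
#' @return a new `bulb_network`.
#' @export
regenerate_granule_cells <- function(net, ...) {
  mcs <- net$mc
  mcs$degree <- NULL
  generate_network(net$space, mcs, gc_per_mc = net$gc_per_mc,
                   mode = net$mode, p_connect = net$p_connect,
                   consts = net$consts, eps = net$eps, ...)
}
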