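#' Generate a mitral/granule-cell network
#'
#' Granule cells are drawn one at a time and wired to the placed mitral
#' cells: for every overlapping MC (visited in a freshly shuffled order)
#' the expected synapse count is computed from the dendritic overlap,
#' discounted by the MC's current synaptic occupancy, and sampled as a
#' Bernoulli connection with probability `1 - exp(-lambda)`. Connections
#' beyond the GC's EPL spine budget are dropped uniformly at random (with
#' occupancy rollback), GCs left unconnected are discarded, and generation
#' continues until `gc_per_mc` connected GCs per MC exist. Each retained
#' connection is assigned a synapse location drawn from the overlap lens
#' with radial density proportional to the dendrite density.
#'
#' In `distance_independent` mode (a control) every pair connects with a
#' constant probability calibrated so that the expected total synapse
#' count matches a geometric reference; spine budgets and discards still
#' apply.
#'
#' @param space an `ob_space` from [build_space()].
#' @param mcs mitral-cell table from [place_mitral_cells()].
#' @param gc_per_mc target number of connected GCs per MC.
#' @param mode `"geometric"` or `"distance_independent"`.
#' @param p_connect constant pair probability for the control mode; if
#'   `NULL`, calibrated from `reference`.
#' @param reference a geometric `bulb_network` used to calibrate
#'   `p_connect` (control mode only).
#' @param config a [placement_config()].
#' @param consts an [interaction_constants()].
#' @param eps vertex clamp for the spine density, um.
#' @param tol overlap quadrature tolerance, um.
#' @param uniform_loc sample synapse locations uniformly over the lens
#'   instead of following the dendrite density.
#' @param sample_params draw per-cell Izhikevich parameters and attach
#'   them to the cell tables.
#' @param progress print wiring progress every 1000 GCs.
#' @return a `bulb_network` object.
#' @export
generate_network <- function(space, mcs, gc_per_mc = 15,
                             mode = c("geometric", "distance_independent"),
                             p_connect = NULL, reference = NULL,
                             config = placement_config(),
                             consts = interaction_constants(),
                             eps = 1, tol = 1e-3, uniform_loc = FALSE,
                             sample_params = TRUE, progress = FALSE) {
  mode <- match.arg(mode)
  stopifnot(gc_per_mc > 0)
  nmc <- nrow(mcs)
  target <- round(gc_per_mc * nmc)
  imode <- if (mode == "geometric") 0L else 1L
  if (imode == 1L && is.null(p_connect)) {
    if (is.null(reference))
      stop("control mode needs p_connect or a geometric reference network")
    p_connect <- nrow(reference$syn) / (nrow(reference$gc) * nmc)
  }
  if (is.null(p_connect)) p_connect <- 0
  n_ps <- integer(nmc)
  gc_rows <- list()
  syn_rows <- list()
  kept <- 0L
  drawn <- 0L
  discarded <- 0L
  while (kept < target) {
    batch <- max(64L, ceiling((target - kept) * 1.15))
    gcs <- place_granule_cells(space, batch, config)
    res <- cpp_wire_batch(mcs$x, mcs$y, mcs$z, mcs$r_max, mcs$alpha, mcs$k,
                          mcs$m, mcs$length_total, n_ps,
                          gcs$vx, gcs$vy, gcs$fx, gcs$fy, gcs$r_max,
                          gcs$z0, gcs$z_max, gcs$S_available,
                          as.integer(pmax(0, floor(gcs$S_available))),
                          consts$q, consts$v_spine, eps,
                          imode, p_connect, target - kept,
                          box = space$box, tol = tol,
                          uniform_loc = uniform_loc)
    n_ps <- res$n_ps
    proc <- res$processed
    keep <- res$keep[seq_len(proc)]
    drawn <- drawn + proc
    discarded <- discarded + sum(!keep)
    if (res$kept > 0) {
      kb <- gcs[seq_len(proc), ][keep, , drop = FALSE]
      kb$batch_local <- which(keep)
      gc_rows[[length(gc_rows) + 1L]] <- kb
      sr <- data.frame(mc_id = res$syn_mc, gc_local = res$syn_gc,
                       x = res$syn_x, y = res$syn_y, z = res$syn_z,
                       dist = res$syn_dist)
      # re-index batch-local GC ids to global kept order
      idx <- match(sr$gc_local, kb$batch_local)
      sr$gc_id <- kept + idx
      sr$gc_local <- NULL
      syn_rows[[length(syn_rows) + 1L]] <- sr
      kept <- kept + res$kept
    }
    if (progress)
      message(sprintf("wired %d / %d GCs (%d drawn, %d discarded)",
                      kept, target, drawn, discarded))
  }
  gc <- do.call(rbind, gc_rows)
  gc$batch_local <- NULL
  gc$id <- seq_len(nrow(gc))
  rownames(gc) <- NULL
  syn <- do.call(rbind, syn_rows)
  syn <- syn[, c("mc_id", "gc_id", "x", "y", "z", "dist")]
  rownames(syn) <- NULL
  mcs$degree <- tabulate(syn$mc_id, nmc)
  gc$degree <- tabulate(syn$gc_id, nrow(gc))
  stopifnot(all(n_ps == mcs$degree))
  net <- structure(list(space = space, mc = mcs, gc = gc, syn = syn,
                        mode = mode, p_connect = p_connect,
                        gc_per_mc = gc_per_mc, consts = consts, eps = eps,
                        n_discarded = discarded, n_drawn = drawn),
                   class = "bulb_network")
  if (sample_params) net <- attach_cell_params(net)
  net
}

#' @export
print.bulb_network <- function(x, ...) {
  cat("Olfactory bulb network (", x$mode, " wiring)\n", sep = "")
  cat("  space radius:", x$space$radius, "um (", x$space$boundary, ")\n")
  cat("  mitral cells:", nrow(x$mc), " granule cells:", nrow(x$gc), "\n")
  cat("  synapses:", nrow(x$syn),
      sprintf(" (mean %.1f GCs/MC, %.1f MCs/GC)\n",
              mean(x$mc$degree), mean(x$gc$degree)))
  invisible(x)
}

#' Sparse adjacency matrix of a network
#'
#' @param net a `bulb_network`.
#' @return a binary sparse `Matrix` of dimension MC x GC.
#' @export
network_adjacency <- function(net) {
  Matrix::sparseMatrix(i = net$syn$mc_id, j = net$syn$gc_id, x = 1,
                       dims = c(nrow(net$mc), nrow(net$gc)))
}

# list of connected GC-id sets per MC
mc_gc_sets <- function(net) {
  out <- vector("list", nrow(net$mc))
  sp <- split(net$syn$gc_id, net$syn$mc_id)
  out[as.integer(names(sp))] <- sp
  out
}

#' Shared-granule-cell structure of MC pairs
#'
#' For each sampled (ordered) MC pair, counts the GCs connected to both
#' cells and expresses the overlap as a fraction of the reference MC's
#' connected GCs. `jaccard = TRUE` uses the symmetric union denominator
#' instead.
#'
#' @param net a `bulb_network`.
#' @param pairs 2-column matrix of MC ids; default samples `n_pairs`
#'   unordered pairs uniformly.
#' @param n_pairs number of sampled pairs when `pairs` is `NULL`.
#' @param jaccard use the symmetric |shared| / |union| fraction.
#' @return data.frame with ids, inter-soma distance, shared count and
#'   shared fraction (two rows per unordered pair unless `jaccard`).
#' @export
shared_gc_pairs <- function(net, pairs = NULL, n_pairs = 2000,
                            jaccard = FALSE) {
  sets <- mc_gc_sets(net)
  nmc <- nrow(net$mc)
  if (is.null(pairs)) {
    a <- sample.int(nmc, n_pairs, replace = TRUE)
    b <- sample.int(nmc, n_pairs, replace = TRUE)
    ok <- a != b
    pairs <- cbind(a[ok], b[ok])
  }
  d <- space_dist(net$space, net$mc$x[pairs[, 1]], net$mc$y[pairs[, 1]],
                  net$mc$x[pairs[, 2]], net$mc$y[pairs[, 2]])
  shared <- mapply(function(i, j) {
    length(intersect(sets[[i]], sets[[j]]))
  }, pairs[, 1], pairs[, 2])
  if (jaccard) {
    un <- mapply(function(i, j) length(union(sets[[i]], sets[[j]])),
                 pairs[, 1], pairs[, 2])
    frac <- ifelse(un > 0, shared / un, 0)
    data.frame(mc_a = pairs[, 1], mc_b = pairs[, 2], distance = d,
               shared = shared, fraction = frac)
  } else {
    da <- net$mc$degree[pairs[, 1]]
    db <- net$mc$degree[pairs[, 2]]
    # both orders contribute one sample
    data.frame(mc_a = c(pairs[, 1], pairs[, 2]),
               mc_b = c(pairs[, 2], pairs[, 1]),
               distance = c(d, d), shared = c(shared, shared),
               fraction = c(ifelse(da > 0, shared / da, 0),
                            ifelse(db > 0, shared / db, 0)))
  }
}

#' Degree and overlap statistics of a network
#'
#' Summarises per-MC and per-GC degree distributions (exponential means
#' overall and by MC type; a skew-normal fit for GC degrees), and the
#' shared-GC fraction for sister (same glomerulus) versus non-sister MC
#' pairs.
#'
#' @param net a `bulb_network`.
#' @param n_nonsister number of sampled non-sister pairs.
#' @param fit_gc_skew fit the skew-normal to GC degrees (needs enough GCs).
#' @return a list of class `bulb_network_stats`.
#' @export
network_statistics <- function(net, n_nonsister = 2000, fit_gc_skew = TRUE) {
  mc <- net$mc
  deg_mc <- mc$degree
  deg_gc <- net$gc$degree
  glom <- split(mc$id, mc$glomerulus)
  sister <- do.call(rbind, lapply(glom, function(ids) {
    if (length(ids) < 2) return(NULL)
    t(utils::combn(ids, 2))
  }))
  sister_df <- shared_gc_pairs(net, pairs = sister)
  nons <- shared_gc_pairs(net, n_pairs = n_nonsister)
  nons <- nons[mc$glomerulus[nons$mc_a] != mc$glomerulus[nons$mc_b], ]
  skew <- if (fit_gc_skew) try(fit_skew_normal(deg_gc), silent = TRUE)
          else NULL
  if (inherits(skew, "try-error")) skew <- NULL
  structure(list(
    n_mc = nrow(mc), n_gc = nrow(net$gc), n_syn = nrow(net$syn),
    mc_degree_mean = mean(deg_mc),
    mc_degree_mean_typeI = mean(deg_mc[mc$type == 1]),
    mc_degree_mean_typeII = mean(deg_mc[mc$type == 2]),
    gc_degree_mean = mean(deg_gc),
    gc_skew_fit = skew,
    sister_fraction_mean = mean(sister_df$fraction),
    nonsister_fraction_mean = mean(nons$fraction),
    sister_pairs = sister_df, nonsister_pairs = nons
  ), class = "bulb_network_stats")
}

#' @export
print.bulb_network_stats <- function(x, ...) {
  cat("Network statistics\n")
  cat(sprintf("  MCs %d, GCs %d, synapses %d\n", x$n_mc, x$n_gc, x$n_syn))
  cat(sprintf("  mean GCs per MC: %.1f (type I %.1f, type II %.1f)\n",
              x$mc_degree_mean, x$mc_degree_mean_typeI,
              x$mc_degree_mean_typeII))
  cat(sprintf("  mean MCs per GC: %.2f\n", x$gc_degree_mean))
  cat(sprintf("  shared-GC fraction: sister %.3f, non-sister %.3f\n",
              x$sister_fraction_mean, x$nonsister_fraction_mean))
  invisible(x)
}

#' Binned shared-GC counts versus inter-soma distance
#'
#' @param net a `bulb_network`.
#' @param n_pairs sampled MC pairs.
#' @param bin_width bin width, um.
#' @param n_bins number of distance bins.
#' @return data.frame with bin centres, mean shared counts, standard
#'   errors and pair counts.
#' @export
shared_gc_by_distance <- function(net, n_pairs = 4000, bin_width = 100,
                                  n_bins = 12) {
  df <- shared_gc_pairs(net, n_pairs = n_pairs)
  br <- seq(0, n_bins * bin_width, by = bin_width)
  bin <- cut(df$distance, br, labels = FALSE)
  ok <- !is.na(bin)
  agg <- tapply(df$shared[ok], bin[ok], mean)
  se <- tapply(df$shared[ok], bin[ok], function(v) {
    stats::sd(v) / sqrt(length(v))
  })
  n <- tapply(df$shared[ok], bin[ok], length)
  idx <- as.integer(names(agg))
  data.frame(distance = br[idx] + bin_width / 2, shared = as.numeric(agg),
             se = as.numeric(se), n = as.integer(n))
}

#' Sample a synapse location for one connected pair
#'
#' Draws a point inside the disk-cone overlap lens with planar density
#' proportional to the MC dendrite density, and returns the point plus its
#' radial (dendritic) distance to the MC centre.
#'
#' @param mc list with `x`, `y`, `z`, `r_max`, `alpha`, `k`, `m`,
#'   `length_total`.
#' @param gc list with `vx`, `vy`, `fx`, `fy`, `r_max`, `z0`, `z_max`,
#'   `S_available` (budget fields unused here).
#' @return list with `x`, `y`, `z`, `dendritic_distance`.
#' @export
sample_synapse_location <- function(mc, gc) {
  if (mc$z <= gc$z0 || mc$z > gc$z_max)
    stop("pair does not overlap: MC disk outside the cone height range")
  frac <- (mc$z - gc$z0) / (gc$z_max - gc$z0)
  rg <- gc$r_max * frac
  cx <- gc$vx + (gc$fx - gc$vx) * frac
  cy <- gc$vy + (gc$fy - gc$vy) * frac
  s <- sqrt((mc$x - cx)^2 + (mc$y - cy)^2)
  if (s >= rg + mc$r_max)
    stop("pair does not overlap: fields are disjoint at the disk height")
  smp <- cpp_sample_lens(s, mc$r_max, rg, mc$alpha, mc$k, mc$m, 1L)
  ang <- atan2(cy - mc$y, cx - mc$x) + smp$theta
  list(x = mc$x + smp$r * cos(ang), y = mc$y + smp$r * sin(ang), z = mc$z,
       dendritic_distance = smp$r)
}
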