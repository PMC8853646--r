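#' Area density of glomerular projections
#'
#' Derived from the total glomerulus count per bulb and the EPL volume:
#' the EPL is flattened into a sheet of area `volume / thickness`, and the
#' density is `n_glomeruli / area`.
#'
#' @param n_glomeruli glomeruli per bulb.
#' @param epl_volume EPL volume, mm^3.
#' @param epl_thickness EPL thickness, um.
#' @return density in glomeruli per mm^2.
#' @export
glomerular_density <- function(n_glomeruli = 1800, epl_volume = 1.5,
                               epl_thickness = 131) {
  area_mm2 <- epl_volume * 1e9 / epl_thickness / 1e6
  n_glomeruli / area_mm2
}

#' Placement configuration
#'
#' Sampling distributions for cell placement. Defaults:
#' 15-25 MCs per glomerulus (uniform integers); MC soma offset from the
#' glomerular projection follows a logistic distribution (location 78.4 um,
#' scale 23.1 um) truncated to `[0, 300]` um; MC disk radius uniform on
#' `[75, 800]` um; two thirds of MCs are type I (disks in the lower half of
#' the EPL), the rest type II (disks between 2/5 and 4/5 of the EPL
#' height); profile shape variables `gamma_peak ~ U(0.2, 0.3)`,
#' `xi_center ~ U(1/3, 4/5)`, `w ~ U(0.00255, 0.0051)` um^-1. Granule-cell
#' cones have face radius Normal(83, 28) truncated to `[30, 160]` um,
#' vertex height uniform over the IPL+MCL, face height uniform over the
#' top half of the EPL, vertex-to-face obliquity uniform on `[0, 50]` um,
#' and spine counts uniform between `a*atan(b*V)` bounds in the cone
#' volume `V`.
#'
#' @param ... overrides for any of the listed fields.
#' @return a list of class `placement_config`.
#' @export
placement_config <- function(...) {
  cfg <- list(
    glomerulus_density = 157,           # per mm^2
    mcs_per_glomerulus = c(15L, 25L),
    mc_offset_mu = 78.4, mc_offset_s = 23.1, mc_offset_max = 300,
    mc_radius_range = c(75, 800),
    mc_type_I_prob = 2 / 3,
    mc_gamma_range = c(0.2, 0.3),
    mc_xi_range = c(1 / 3, 4 / 5),
    mc_w_range = c(0.00255, 0.0051),
    gc_rmax_mean = 83, gc_rmax_sd = 28, gc_rmax_bounds = c(30, 160),
    gc_obliquity_max = 50,
    spine_lo = c(a = 39.31, b = 1.043e-5),
    spine_hi = c(a = 357.7, b = 2.653e-6)
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "placement_config"
  cfg
}

# inverse-CDF draw from a logistic distribution truncated to [0, upper]
rtrunc_logistic <- function(n, mu, s, upper) {
  plo <- stats::plogis(0, mu, s)
  phi <- stats::plogis(upper, mu, s)
  stats::qlogis(plo + (phi - plo) * stats::runif(n), mu, s)
}

# inverse-CDF draw from a normal distribution truncated to [lo, hi]
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + (phi - plo) * stats::runif(n), mean, sd)
}

#' Spine-count bounds from cone volume
#'
#' Both bounds have the form `a * atan(b * V)` with `V` the cone volume in
#' um^3.
#'
#' @param volume cone volume(s), um^3.
#' @param config a [placement_config()].
#' @return matrix with columns `lo`, `hi`.
#' @export
spine_bounds <- function(volume, config = placement_config()) {
  cbind(lo = config$spine_lo["a"] * atan(config$spine_lo["b"] * volume),
        hi = config$spine_hi["a"] * atan(config$spine_hi["b"] * volume))
}

#' Build the bulb space and scatter glomerular projections
#'
#' In `bounded` mode the space is a disk of the given radius; glomeruli
#' are placed uniformly in the disk and dendritic fields may extend past
#' the boundary. In `periodic` mode the space is a square of equal area
#' (side `sqrt(pi) * radius`) with wrapped x-y distances.
#'
#' @param radius bulb radius, um.
#' @param config a [placement_config()].
#' @param layers a [layer_stack()].
#' @param boundary `"bounded"` or `"periodic"`.
#' @return an `ob_space` object.
#' @export
build_space <- function(radius, config = placement_config(),
                        layers = layer_stack(),
                        boundary = c("bounded", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(radius >= 0)
  area_mm2 <- pi * radius^2 / 1e6
  n_glom <- round(config$glomerulus_density * area_mm2)
  if (boundary == "bounded") {
    r <- radius * sqrt(stats::runif(n_glom))
    th <- stats::runif(n_glom, 0, 2 * pi)
    gx <- r * cos(th); gy <- r * sin(th)
    box <- 0
  } else {
    box <- sqrt(pi) * radius
    gx <- stats::runif(n_glom, 0, box)
    gy <- stats::runif(n_glom, 0, box)
  }
  structure(list(radius = radius, area_mm2 = area_mm2, layers = layers,
                 boundary = boundary, box = box,
                 glomeruli = data.frame(id = seq_len(n_glom), x = gx, y = gy)),
            class = "ob_space")
}

#' @export
print.ob_space <- function(x, ...) {
  cat("Olfactory bulb space: radius", x$radius, "um,",
      format(x$area_mm2, digits = 3), "mm^2,",
      nrow(x$glomeruli), "glomeruli,", x$boundary, "boundary\n")
  invisible(x)
}

# uniform x-y position inside the space
runif_space <- function(space, n) {
  if (space$boundary == "periodic") {
    data.frame(x = stats::runif(n, 0, space$box),
               y = stats::runif(n, 0, space$box))
  } else {
    r <- space$radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    data.frame(x = r * cos(th), y = r * sin(th))
  }
}

# pairwise-safe distance respecting the boundary mode
space_dist <- function(space, x1, y1, x2, y2) {
  dx <- x1 - x2; dy <- y1 - y2
  if (space$boundary == "periodic") {
    dx <- dx - space$box * round(dx / space$box)
    dy <- dy - space$box * round(dy / space$box)
  }
  sqrt(dx^2 + dy^2)
}

#' Place mitral cells around the glomeruli
#'
#' Each glomerulus receives a uniform integer number of MCs; each MC soma
#' is offset from the glomerular projection by a truncated-logistic radial
#' distance at a uniform angle. Type I cells sit in the lower half of the
#' EPL, type II cells between 2/5 and 4/5 of its height. Disk radii and
#' profile shape variables are drawn per cell and converted to the density
#' constants via [derive_mc_profile()].
#'
#' @param space an `ob_space`.
#' @param config a [placement_config()].
#' @return data.frame, one row per MC, with position, type, morphology
#'   constants and total dendritic length.
#' @export
place_mitral_cells <- function(space, config = placement_config()) {
  glom <- space$glomeruli
  layers <- space$layers
  n_per <- sample(config$mcs_per_glomerulus[1]:config$mcs_per_glomerulus[2],
                  nrow(glom), replace = TRUE)
  n <- sum(n_per)
  gid <- rep(glom$id, n_per)
  off <- rtrunc_logistic(n, config$mc_offset_mu, config$mc_offset_s,
                         config$mc_offset_max)
  th <- stats::runif(n, 0, 2 * pi)
  x <- glom$x[gid] + off * cos(th)
  y <- glom$y[gid] + off * sin(th)
  if (space$boundary == "periodic") {
    x <- x %% space$box
    y <- y %% space$box
  }
  type <- ifelse(stats::runif(n) < config$mc_type_I_prob, 1L, 2L)
  z <- ifelse(type == 1L,
              layers$epl_floor + stats::runif(n, 0, layers$epl / 2),
              layers$epl_floor +
                stats::runif(n, 2 / 5 * layers$epl, 4 / 5 * layers$epl))
  r_max <- stats::runif(n, config$mc_radius_range[1], config$mc_radius_range[2])
  gam <- stats::runif(n, config$mc_gamma_range[1], config$mc_gamma_range[2])
  xi <- stats::runif(n, config$mc_xi_range[1], config$mc_xi_range[2])
  w <- stats::runif(n, config$mc_w_range[1], config$mc_w_range[2])
  m <- atan(sqrt(1 / xi - 1))
  k <- tan(m) / (gam * r_max)
  len <- w * pi * r_max^2
  alpha <- len / (atan(k * r_max - tan(m)) + m)
  data.frame(id = seq_len(n), glomerulus = gid, type = type,
             x = x, y = y, z = z, r_max = r_max,
             gamma_peak = gam, xi_center = xi, w = w,
             alpha = alpha, k = k, m = m, length_total = len)
}

#' Sample granule-cell cone geometries
#'
#' Draws `n` candidate granule cells: vertex x-y uniform in the space,
#' vertex height uniform over IPL+MCL, face height uniform over the top
#' half of the EPL, truncated-normal face radius, uniform obliquity, and a
#' spine count uniform between the volume-dependent bounds. The
#' EPL-available spine budget is computed in closed form.
#'
#' @param space an `ob_space`.
#' @param n number of cells to draw.
#' @param config a [placement_config()].
#' @return data.frame, one row per GC.
#' @export
place_granule_cells <- function(space, n, config = placement_config()) {
  layers <- space$layers
  pos <- runif_space(space, n)
  z0 <- stats::runif(n, 0, layers$epl_floor)
  z_max <- layers$epl_floor + stats::runif(n, layers$epl / 2, layers$epl)
  r_max <- rtrunc_norm(n, config$gc_rmax_mean, config$gc_rmax_sd,
                       config$gc_rmax_bounds[1], config$gc_rmax_bounds[2])
  obl <- stats::runif(n, 0, config$gc_obliquity_max)
  oth <- stats::runif(n, 0, 2 * pi)
  fx <- pos$x + obl * cos(oth)
  fy <- pos$y + obl * sin(oth)
  if (space$boundary == "periodic") {
    fx <- fx %% space$box
    fy <- fy %% space$box
  }
  vol <- pi * r_max^2 * (z_max - z0) / 3
  b <- spine_bounds(vol, config)
  S <- round(stats::runif(n, b[, "lo"], b[, "hi"]))
  s_av <- vapply(seq_len(n), function(i) {
    available_spines(list(z0 = z0[i], z_max = z_max[i], S = S[i]), layers)
  }, numeric(1))
  data.frame(vx = pos$x, vy = pos$y, fx = fx, fy = fy,
             r_max = r_max, z0 = z0, z_max = z_max,
             S = S, S_available = s_av)
}
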