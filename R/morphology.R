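#' Layer thicknesses of the model bulb
#'
#' The model space is a thin cylinder stacked, from the bottom up, as
#' internal plexiform layer (IPL), mitral cell layer (MCL) and external
#' plexiform layer (EPL). Heights are measured in micrometres from the
#' bottom of the IPL; the floor of the EPL therefore sits at
#' `ipl + mcl`.
#'
#' @param epl,mcl,ipl layer thicknesses in micrometres.
#' @return an object of class `layer_stack` with fields `epl`, `mcl`,
#'   `ipl`, `total` and `epl_floor`.
#' @export
layer_stack <- function(epl = 131, mcl = 36, ipl = 27) {
  stopifnot(epl > 0, mcl >= 0, ipl >= 0)
  structure(list(epl = epl, mcl = mcl, ipl = ipl,
                 total = epl + mcl + ipl, epl_floor = ipl + mcl),
            class = "layer_stack")
}

#' Derive the mitral-cell radial profile constants
#'
#' The cumulative lateral-dendrite length inside radius `r` is modelled as
#' `f(r) = alpha * (atan(k*r - tan(m)) + m)`, so that the areal density is
#' `rho_m(r) = (alpha*k / (2*pi*r)) / (1 + (k*r - tan(m))^2)`. The three
#' constants are fixed by three interpretable shape variables:
#' `gamma_peak`, the fraction of `r_max` at which `df/dr` peaks;
#' `xi_center`, the value of `df/dr` at the origin relative to that peak;
#' and `w`, the total dendritic length per unit disk area, so that
#' `f(r_max) = w * pi * r_max^2`.
#'
#' @param gamma_peak fraction in (0, 1).
#' @param xi_center fraction in (0, 1].
#' @param w total-length scale, um^-1.
#' @param r_max disk radius, um.
#' @return list with `alpha` (um), `k` (um^-1), `m` (rad), `r_max`, `w`,
#'   and the total length `length_total = w*pi*r_max^2`.
#' @export
derive_mc_profile <- function(gamma_peak, xi_center, w, r_max) {
  if (!(gamma_peak > 0 && gamma_peak < 1))
    stop("gamma_peak must lie strictly between 0 and 1")
  if (!(xi_center > 0 && xi_center <= 1))
    stop("xi_center must lie in (0, 1]")
  if (!(r_max > 0 && w > 0)) stop("r_max and w must be positive")
  m <- atan(sqrt(1 / xi_center - 1))
  k <- tan(m) / (gamma_peak * r_max)
  len <- w * pi * r_max^2
  alpha <- len / (atan(k * r_max - tan(m)) + m)
  list(alpha = alpha, k = k, m = m, r_max = r_max, w = w,
       length_total = len)
}

#' Mitral-cell lateral-dendrite areal density
#'
#' @param r radial distance from the soma, um; must satisfy
#'   `0 < r <= r_max`. The density is singular at the origin.
#' @param profile a profile from [derive_mc_profile()].
#' @return density in um of dendrite per um^2, strictly positive.
#' @export
mc_dendrite_density <- function(r, profile) {
  if (any(r <= 0)) stop("rho_m is singular at r = 0; evaluate at r > 0")
  if (any(r > profile$r_max + 1e-9)) stop("r exceeds the disk radius r_max")
  with(profile, (alpha * k / (2 * pi * r)) / (1 + (k * r - tan(m))^2))
}

#' Cumulative dendritic length within radius r
#'
#' `f(r) = alpha*(atan(k*r - tan(m)) + m)`; monotone, `f(0) = 0` and
#' `f(r_max)` equals the total length `w*pi*r_max^2`.
#'
#' @inheritParams mc_dendrite_density
#' @export
mc_cumulative_length <- function(r, profile) {
  if (any(r < 0) || any(r > profile$r_max + 1e-9))
    stop("r must lie in [0, r_max]")
  with(profile, alpha * (atan(k * r - tan(m)) + m))
}

#' Granule-cell volumetric spine density
#'
#' The linear spine density along the cone height is a parabola
#' `N_s(z) = -a (z - z0) (z - z_max)` normalised so that its integral over
#' the cone equals the spine count; dividing by the cone cross-section
#' gives the volumetric density
#' `rho_g(z) = 6 S (z_max - z) / (pi r_max^2 (z_max - z0) (z - z0))`.
#' The density diverges at the vertex, so evaluation is clamped to
#' `z >= z0 + eps`.
#'
#' @param z height, um; must satisfy `z0 < z <= z_max`.
#' @param gc list with `r_max`, `z0`, `z_max` (um).
#' @param effective_S spine count entering the density (typically the
#'   EPL-available count).
#' @param eps clamp distance above the vertex, um.
#' @return spines per um^3; zero at `z = z_max`.
#' @export
gc_spine_density <- function(z, gc, effective_S, eps = 1) {
  if (any(z <= gc$z0)) stop("z must exceed the cone vertex z0")
  if (any(z > gc$z_max + 1e-9)) stop("z exceeds the cone face z_max")
  zz <- pmax(z, gc$z0 + eps)
  6 * effective_S * (gc$z_max - zz) /
    (pi * gc$r_max^2 * (gc$z_max - gc$z0) * (zz - gc$z0))
}

#' Linear spine density along the cone
#'
#' @inheritParams gc_spine_density
#' @param S total spine count of the cone.
#' @return spines per um of height.
#' @export
gc_linear_spine_density <- function(z, gc, S) {
  h <- gc$z_max - gc$z0
  -6 * S / h^3 * (z - gc$z0) * (z - gc$z_max)
}

#' Spines available for synapse formation
#'
#' Only spines inside the EPL can contact mitral-cell lateral dendrites,
#' so the usable spine budget is the integral of the linear spine density
#' from the EPL floor to the top of the cone (closed form of the cubic
#' antiderivative). Cones entirely below the EPL have no available spines.
#'
#' @param gc list with `z0`, `z_max`, `S`.
#' @param layers a [layer_stack()].
#' @return available spine count, in `[0, S]`.
#' @export
available_spines <- function(gc, layers = layer_stack()) {
  zf <- layers$epl_floor
  if (gc$z_max <= zf) return(0)
  lo <- max(gc$z0, zf)
  h <- gc$z_max - gc$z0
  a <- 6 * gc$S / h^3
  prim <- function(z) {
    u <- z - gc$z0
    a * (h * u^2 / 2 - u^3 / 3)
  }
  min(gc$S, max(0, prim(gc$z_max) - prim(lo)))
}
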