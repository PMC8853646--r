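#' Interaction-volume constants
#'
#' A spine can reach a lateral dendrite anywhere inside a cylindrical
#' sheath of thickness `d_shell` (the effective spine diameter) around the
#' dendrite, itself a cylinder of radius `r_dendrite`. The sheath
#' cross-section area is `q = (d_shell + r_dendrite)^2 - r_dendrite^2`, so
#' an overlap dendritic length `L` corresponds to an interaction volume
#' `q * pi * L`.
#'
#' @param d_shell sheath thickness, um.
#' @param r_dendrite dendrite cylinder radius, um.
#' @param v_spine average spine volume, um^3.
#' @return list with `d_shell`, `r_dendrite`, `q` (um^2) and `v_spine`.
#' @export
interaction_constants <- function(d_shell = 1.02, r_dendrite = 0.63,
                                  v_spine = 0.58) {
  q <- (d_shell + r_dendrite)^2 - r_dendrite^2
  stopifnot(q > 0)
  list(d_shell = d_shell, r_dendrite = r_dendrite, q = q, v_spine = v_spine)
}

#' Overlap dendritic length between a disk and a cone section
#'
#' Integrates the mitral-cell dendrite density over the lens where the MC
#' disk intersects the granule-cell cone cross-section at the disk height.
#' The radial part of the integral is closed-form; the angular part uses
#' adaptive quadrature with absolute tolerance `tol` (um). The case
#' dispatch follows the mutual sizes (`r_m` vs `r_g`) and the centre
#' distance `s`.
#'
#' @param s distance between disk centre and cone-section centre, um.
#' @param r_m MC disk radius, um.
#' @param r_g cone cross-section radius at the disk height, um.
#' @param profile MC radial profile from [derive_mc_profile()]
#'   (with `r_max = r_m`).
#' @param tol absolute quadrature tolerance on the returned length, um.
#' @return overlap dendritic length, um (zero when the fields miss).
#' @export
overlap_length <- function(s, r_m, r_g, profile, tol = 1e-3) {
  if (any(c(s, r_m, r_g) < 0)) stop("invalid geometry: negative input")
  cpp_overlap_length(s, r_m, r_g, profile$alpha, profile$k, profile$m, tol)
}

#' Overlap-case identifier
#'
#' Enumerates the quadrature regime for a given geometry: 0 = disjoint,
#' 1 = far lens, then per size class (`1x` disk much larger, `2x`
#' comparable, `3x` cone larger) sub-cases by decreasing centre distance.
#'
#' @inheritParams overlap_length
#' @export
overlap_case <- function(s, r_m, r_g) cpp_overlap_case(s, r_m, r_g)

#' Overlap length for a placed mitral/granule cell pair
#'
#' Computes the cone cross-section radius and centre at the MC disk height
#' (linear interpolation along the oblique cone axis) and evaluates
#' [overlap_length()].
#'
#' @param mc list with `x`, `y`, `z`, `r_max`, `alpha`, `k`, `m`.
#' @param gc list with `vx`, `vy`, `fx`, `fy`, `r_max`, `z0`, `z_max`.
#' @param tol quadrature tolerance, um.
#' @return overlap length, um.
#' @export
pair_overlap_length <- function(mc, gc, tol = 1e-3) {
  if (mc$z <= gc$z0 || mc$z > gc$z_max) return(0)
  frac <- (mc$z - gc$z0) / (gc$z_max - gc$z0)
  rg <- gc$r_max * frac
  cx <- gc$vx + (gc$fx - gc$vx) * frac
  cy <- gc$vy + (gc$fy - gc$vy) * frac
  s <- sqrt((mc$x - cx)^2 + (mc$y - cy)^2)
  prof <- list(alpha = mc$alpha, k = mc$k, m = mc$m, r_max = mc$r_max)
  overlap_length(s, mc$r_max, rg, prof, tol)
}

#' Expected synapse count for a pair
#'
#' Converts an overlap length into an interaction volume `q*pi*L`,
#' discounts it by the fraction of the MC's total interaction volume
#' already occupied by pre-existing synapses, and multiplies by the
#' granule-cell spine density at the disk height.
#'
#' @param L overlap dendritic length, um.
#' @param z_m MC disk height, um.
#' @param gc list with `r_max`, `z0`, `z_max`, `S_available`.
#' @param n_preexisting synapses already on the MC.
#' @param mc_total_length the MC's total dendritic length `f(r_max)`, um.
#' @param consts from [interaction_constants()].
#' @param eps vertex clamp passed to [gc_spine_density()].
#' @return expected synapse count (Poisson mean), non-negative.
#' @export
expected_synapses <- function(L, z_m, gc, n_preexisting = 0,
                              mc_total_length,
                              consts = interaction_constants(), eps = 1) {
  stopifnot(L >= 0, n_preexisting >= 0)
  if (mc_total_length <= 0) stop("degenerate MC: zero total dendritic length")
  if (L == 0) return(0)
  v <- consts$q * pi * L
  v_tot <- consts$q * pi * mc_total_length
  v_eff <- max(0, v * (1 - n_preexisting * consts$v_spine / v_tot))
  rho <- gc_spine_density(z_m, list(r_max = gc$r_max, z0 = gc$z0,
                                    z_max = gc$z_max),
                          effective_S = gc$S_available, eps = eps)
  rho * v_eff
}

#' Connection probability from an expected synapse count
#'
#' Pairs are restricted to at most one synapse; the probability of a
#' connection is the Poisson probability of at least one synapse,
#' `1 - exp(-lambda)`.
#'
#' @param lambda_syn expected synapse count, non-negative.
#' @return probability in `[0, 1)`.
#' @export
connection_probability <- function(lambda_syn) {
  if (any(lambda_syn < 0)) stop("expected synapse count must be non-negative")
  1 - exp(-lambda_syn)
}
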