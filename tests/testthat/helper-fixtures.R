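# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# tiny bounded network (radius 150 um, 5 GCs per MC)
tiny_net <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- make_fixture("tiny", seed = 101)
  }
  .fixture_cache$tiny
}

# tiny network at the full 15:1 GC:MC ratio (denser inhibition)
dense_net <- function() {
  if (is.null(.fixture_cache$dense)) {
    set.seed(202)
    sp <- build_space(150)
    mcs <- place_mitral_cells(sp)
    .fixture_cache$dense <- generate_network(sp, mcs, gc_per_mc = 15)
  }
  .fixture_cache$dense
}

# example mitral-cell radial profile used across modules
example_profile <- function() derive_mc_profile(0.25, 0.5, 0.003, 400)

# a placed MC/GC pair with guaranteed overlap
example_pair <- function() {
  prof <- example_profile()
  list(
    mc = list(x = 0, y = 0, z = 110, r_max = prof$r_max,
              alpha = prof$alpha, k = prof$k, m = prof$m,
              length_total = prof$length_total),
    gc = list(vx = 250, vy = 0, fx = 250, fy = 0, r_max = 160,
              z0 = 40, z_max = 180, S = 10000,
              S_available = available_spines(
                list(z0 = 40, z_max = 180, S = 10000))))
}

# Monte-Carlo estimate of the overlap dendritic length by rejection
# sampling over the MC disk (independent oracle for the quadrature)
mc_overlap_oracle <- function(s, r_m, r_g, profile, n = 4e5) {
  r <- sqrt(stats::runif(n)) * r_m
  th <- stats::runif(n, 0, 2 * pi)
  inside <- (r * cos(th) - s)^2 + (r * sin(th))^2 <= r_g^2
  dens <- mc_dendrite_density(pmax(r, 1e-9), profile)
  est <- mean(dens * inside) * pi * r_m^2
  se <- stats::sd(dens * inside) / sqrt(n) * pi * r_m^2
  list(estimate = est, se = se)
}
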