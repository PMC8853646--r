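# bulbnet

Anatomically grounded network models of the mammalian olfactory bulb.

The olfactory bulb reshapes odor representations through reciprocal
dendrodendritic synapses between excitatory mitral cells (MCs) and a
much larger population of inhibitory granule cells (GCs). How that
circuit behaves collectively — lateral inhibition, odor-pattern
decorrelation, theta/beta/gamma field-potential oscillations, the
expression of cortical feedback, the benefit of adult neurogenesis —
depends on *who connects to whom*, and the anatomy constrains that
tightly. bulbnet is for computational neuroscientists who want
large-scale bulb networks whose connectivity follows from dendritic
geometry rather than from ad-hoc random wiring, with spiking dynamics
fast enough to run thousands of cells on one core.

## The model in brief

An MC's lateral dendrites are a radially symmetric density on a disk:
the dendritic length within radius *r* is
*f*(*r*) = α[tan⁻¹(*kr* − tan *m*) + *m*], giving the areal density
ρ<sub>m</sub>(*r*) = (α*k*/2π*r*) / (1 + (*kr* − tan *m*)²). A GC is an
inverted oblique cone carrying a parabolic spine distribution, with
volumetric density
ρ<sub>g</sub>(*z*) = 6*S*(*z*<sub>max</sub> − *z*) /
[π*r*²<sub>max</sub>(*z*<sub>max</sub> − *z*₀)(*z* − *z*₀)].
For each cell pair, integrating ρ<sub>m</sub> over the disk–cone
intersection yields an overlap length *L* (the radial integral is
closed-form; the angular part is adaptive quadrature), which becomes an
interaction volume *q*π*L* (*q* = 2.32 μm², a spine-diameter sheath
around the dendrite), is discounted by the MC's synaptic occupancy, and
multiplied by ρ<sub>g</sub> at the disk height to give the expected
synapse count λ. The pair connects with the Poisson tail probability
*P* = 1 − e^(−λ), at most one synapse per pair, under per-GC spine
budgets restricted to the EPL.

Cells are Izhikevich units (*C v̇* = *k*(*v* − *v*<sub>r</sub>)(*v* −
*v*<sub>t</sub>) − *u* + *I*; class II mitral cells, integrator granule
cells) coupled through AMPA/NMDA receptors on GCs and
distance-attenuated GABA receptors on MCs, driven by sniff-locked
Poisson sensory input, integrated by forward Euler at 0.1 ms in
compiled code. Local field potentials are inverse-distance sums of
synaptic currents with Welch spectral analysis, and the package ships
the five standard protocols: lateral inhibition, decorrelation,
feedback to GCs, feedback to MCs, and four modes of GC neurogenesis.

## Worked example

```r
library(bulbnet)

# one MC radial profile and one pair's connection probability
prof <- derive_mc_profile(gamma_peak = 0.25, xi_center = 0.5,
                          w = 0.003, r_max = 400)
prof$length_total                      # 1507.964 um of dendrite
L <- overlap_length(s = 250, r_m = 400, r_g = 100, prof)   # 55.4954 um
lam <- expected_synapses(L, z_m = 110,
                         gc = list(r_max = 80, z0 = 40, z_max = 180,
                                   S_available = 240),
                         n_preexisting = 0,
                         mc_total_length = prof$length_total)
connection_probability(lam)            # 0.187: P(at least one synapse)

# a small bulb network and its structure
net <- make_fixture("tiny", seed = 1)  # radius 150 um, 5 GCs per MC
net
#> Olfactory bulb network (geometric wiring)
#>   space radius: 150 um ( bounded )
#>   mitral cells: 218  granule cells: 1090
#>   synapses: 23642  (mean 108.4 GCs/MC, 21.7 MCs/GC)
set.seed(2)
network_statistics(net, fit_gc_skew = FALSE)
#> Network statistics
#>   MCs 218, GCs 1090, synapses 23642
#>   mean GCs per MC: 108.4 (type I 125.9, type II 75.1)
#>   mean MCs per GC: 21.69
#>   shared-GC fraction: sister 0.150, non-sister 0.125
```

Type I mitral cells (deep disks) out-connect type II, and sister MCs —
cells of the same glomerulus — share only a small fraction of their
granule cells, two structural signatures of the geometric wiring. A
single mitral cell with mean parameters under 700 pA direct current
fires at 75 Hz (`simulate_single_cell(izhikevich_defaults("MC"),
700)`), and network simulations run through `sim_protocol()` /
`run_simulation()`, e.g. sensory-driven runs with
`osn = osn_odor_drive(net)` and `record_lfp = TRUE` for spectra via
`lfp_spectrum()`.

A command-line front end over the same functions lives at
`inst/cli/bulbnet.R`:

```sh
Rscript inst/cli/bulbnet.R generate --radius 300 --ratio 15 --seed 1 --out net300
Rscript inst/cli/bulbnet.R stats --net net300 --out net300_stats
Rscript inst/cli/bulbnet.R experiment lateral-inhibition --net net300 --seed 1 --out li_out
```

The full printed configuration (radius 600 μm, about 3,550 MCs and
53,250 GCs at 15:1) is `make_fixture("paper")`; building and simulating
it takes hours, so the vignette documents which results are checked at
reduced scale. See `vignettes/bulbnet-methods.Rmd` for the model's
assumptions, parameter tables, numerical choices and limitations.

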