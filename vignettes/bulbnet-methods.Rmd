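---
title: "Geometry-constrained olfactory bulb networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-constrained olfactory bulb networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulbnet)
```

## The modelling problem

The olfactory bulb reshapes odor input through dendrodendritic synapses
between excitatory mitral cells (MCs) and inhibitory granule cells (GCs).
MC lateral dendrites spread radially through the external plexiform layer
(EPL); GC dendrites rise roughly orthogonally, carrying spines that form
reciprocal synapses wherever the two arbors interdigitate. Because the
inhibitory population outnumbers the excitatory one roughly fifteen to
one, biophysically detailed simulation of the full circuit is
impractical; at the same time, purely random connectivity discards the
anatomy that turns out to control lateral inhibition, decorrelation and
oscillations. bulbnet takes the middle road: it summarises each cell's
arbor as a closed-form density, derives per-pair connection probabilities
from the geometric overlap of those densities, and simulates the
resulting network with two-variable Izhikevich units coupled through
receptor-gated currents.

## Dendritic density models

**Mitral cells.** A cell's lateral-dendrite field is a flat disk of
radius $r_{\max}$ at its EPL height $z_m$. The cumulative dendritic
length inside radius $r$ is

$$f(r) = \alpha\,[\tan^{-1}(k r - \tan m) + m],$$

so the areal density is
$\rho_m(r) = \frac{\alpha k / 2\pi r}{1 + (k r - \tan m)^2}$.
Rather than exposing $(\alpha, k, m)$ directly, `derive_mc_profile()`
fixes them from three interpretable shape variables: the fraction of
$r_{\max}$ where $df/dr$ peaks (`gamma_peak`, drawn U(0.2, 0.3)), the
relative slope at the origin (`xi_center`, U(1/3, 4/5)), and a
length-per-area scale `w` (U(0.00255, 0.0051) um^-1) that pins the total
length to $f(r_{\max}) = w \pi r_{\max}^2$. The disk is treated as a
plane: the spine density it meets is taken as constant across the disk's
physical thickness, so disk thickness never enters the calculation.

**Granule cells.** A GC is an inverted oblique cone: vertex at
$(v_x, v_y, z_0)$ in the mitral-cell layer or below, face of radius
$r_{\max}$ at $z_{\max}$ in the top half of the EPL, with the face centre
laterally offset up to 50 um. The linear spine density along the height
is a parabola vanishing at both ends and integrating to the spine count
$S$; dividing by the cone cross-section gives the volumetric density

$$\rho_g(z) = \frac{6S\,(z_{\max}-z)}
{\pi r_{\max}^2 (z_{\max}-z_0)(z-z_0)},$$

which diverges at the vertex. Evaluation is clamped to $z \ge z_0 + 1$
um (`eps`); the clamp touches only the vanishing fraction of pairs whose
disk grazes a cone vertex and keeps synapse expectations finite. Spine
counts are drawn uniformly between bounds $a\tan^{-1}(bV)$ of the cone
volume $V$, and only the spines above the EPL floor — the closed-form
integral `available_spines()` — can form synapses.

## From overlap to connection probability

For a pair, the disk meets the cone in a lens at the disk height; the
dendritic length in the lens is $L = \int_A \rho_m\,dA$. Since
$\int \rho_m(r)\, r\,dr$ has the closed form $\frac{\alpha}{2\pi}
\tan^{-1}(kr - \tan m)$, every case reduces to a one-dimensional angular
integral over chords of the cone circle, evaluated by adaptive Simpson
quadrature with an absolute tolerance of $10^{-3}$ um on $L$ (the
tolerance and scheme are engineering choices; the tests compare the
quadrature against a Monte-Carlo rejection oracle to three standard
errors). The case dispatch — far lens, near lens, contained circle,
covered centre, contained disk — is enumerated by `overlap_case()`.

$L$ becomes an interaction volume $V = q\pi L$, where
$q = (d_{\text{shell}} + r_{\text{dend}})^2 - r_{\text{dend}}^2 = 2.32$
um^2 wraps each dendrite (radius 0.63 um) in a sheath one spine diameter
(1.02 um) thick. Synapses already on the MC occupy part of its total
interaction space, so the volume is discounted by
$1 - N_{ps} V_{\text{spine}} / V_{\text{tot}}$ with
$V_{\text{spine}} = 0.58$ um^3. The expected synapse count is
$\lambda = \rho_g(z_m)\,V_{\text{eff}}$ (with the EPL-available spine
count standing in for $S$), and since pairs are limited to one synapse,
the connection probability is the Poisson tail
$P = 1 - e^{-\lambda}$.

## Placement and wiring

A bulb of radius $r_c$ holds $\rho_{\text{glom}} \pi r_c^2$ glomerular
projections (157 per mm^2, from 1800 glomeruli over an EPL of 1.5 mm^3
flattened at 131 um thickness), placed uniformly. Each glomerulus anchors
U{15..25} MCs whose somata scatter around it with truncated-logistic
radial offsets (location 78.4 um, scale 23.1 um, truncated to 300 um,
realised by inverse-CDF restriction rather than rejection so that draws
are reproducible and cheap). Two thirds of MCs are type I (disks in the
lower half of the EPL); the rest ramify between 2/5 and 4/5 of the EPL
height. Disk radii are U(75, 800) um.

GCs are generated one at a time until the target of 15 connected deep
GCs per MC is reached. Each candidate visits every overlapping MC in a
freshly shuffled order; the pair's $\lambda$ uses the MC's *current*
occupancy, and the connection is a Bernoulli draw. If a GC accepts more
connections than its spine budget, a uniformly random subset of budget
size is kept and the occupancy of the affected MCs is rolled back —
occupancy must reflect retained synapses only (the alternative, leaving
stale counts, would make wiring order-dependent in a way nothing in the
model motivates). GCs that connect to nothing are discarded and not
counted. Each retained connection receives a synapse location drawn from
the lens with planar density proportional to $\rho_m$ (synapses sit on
dendrite); a uniform-over-lens alternative is a configuration switch.
The radial draw doubles as the synapse's dendritic distance, which the
GABA current attenuates as $e^{-L/675\,\mu m}$.

Two control variants exist: `distance_independent` wiring replaces the
geometric probability with a constant calibrated to match a geometric
reference network's realized synapse count, and `periodic` boundaries
place cells on an equal-area square (side $\sqrt{\pi} r_c$) with wrapped
x-y distances, eliminating edge effects; the square realisation is our
choice, since a disk cannot tile the plane.

## Cell and synapse dynamics

Both cell types follow the two-variable Izhikevich equations
($C\dot v = k(v-v_r)(v-v_t) - u + I$,
$\dot u = a(b(v-v_r) - u)$, reset $v \to c$, $u \to u + d$ at the cutoff
$v_c$), integrated by forward Euler at `dt = 0.1` ms. Spike detection is
a post-update threshold test; the reset applies immediately and the
spike time is recorded at the step's end. MC parameters produce class II
behaviour — on a 1 pA current grid, sustained firing starts at about 5
Hz rather than growing continuously from zero — and a rate near 70 Hz at
700 pA. GC parameters make integrators; the pair $(b, k)$ maps
algebraically to input resistance and rheobase
(`gc_excitability_from_bk()`), and per-cell draws (sd 2/3 of the mean
for $b$ and $k$, 1/10 for everything else) are re-sampled until $b<0$,
the rheobase lies in [10, 70] pA and the resistance in [0.25, 1.5]
GOhm. When a cell's voltage draws make that window unreachable (a small
$|v_r - v_t|$ caps the attainable rheobase), the voltage pair is redrawn
as well — the printed constraints say only that draws are repeated until
the window holds, and this is the minimal completion that terminates.

Synapses carry AMPA, NMDA (with the magnesium-block denominator
$1 + \mathrm{Mg}\,e^{-0.062V}/3.57$) and GABA conductances with
first-order gating: exponential decay for AMPA/GABA, a rise-variable
pair for NMDA. A presynaptic spike applies the saturating bump
$s \leftarrow s + W(1-s)$, $W = 0.5$. When an MC spikes, its GCs'
AMPA/NMDA gates are bumped, and — standing in for network-driven GC
activity — the GABA gates of every synapse on MCs sharing a GC with the
spiker receive the second-order bump with weight $\kappa W$
($\kappa = 0.006$). Whether the spiking MC's own synapses are included
is not forced by the rule's motivation; we include them by default
(`kappa_self`), reasoning that the shared GC's activity does not
distinguish the cell that triggered it, and expose the switch.

Sensory drive arrives on 100 olfactory-sensory-neuron synapses per MC,
each an independent Bernoulli stream at the sniff-locked rate
$r(t) = r_{\max}/2 + (r_{\max}/4)(\sin(2\pi f t - \phi) + 1)$, $f = 6$
Hz, with per-glomerulus rates (U(2, 3) Hz odorized, U(0, 0.25) Hz
background) jittered across sister cells. The thinning by $r\,dt$ is
valid at these rates. Current-injection protocols use the same sinusoid
shape with per-glomerulus amplitudes.

## LFP and analysis

The LFP is the point-source sum
$\phi = \sum_s I_s / (4\pi\sigma |r_e - r_s|)$ over synaptic currents,
with $\sigma = 1/300$ (Ohm cm)^-1, the electrode at the x-y centre
halfway up the EPL, and a 1 um minimum-distance clamp. Sensory-synapse
currents are included in the sum by default — the summation is over
synapses and nothing in its derivation excludes a class — with a switch
to restrict to dendrodendritic synapses. Spectra are estimated by a
6th-order low-pass Butterworth (200 Hz, zero-phase), linear detrend,
200 ms transient discard, and Welch averaging of Hann-windowed 400 ms
segments at 50% overlap (the Welch average is implemented directly on
the FFT since the filtering tools at hand provide no spectral
estimator).

Windowed firing-rate matrices use sliding windows at 50% overlap;
per-window Pearson correlations over cells skip zero-variance windows
(the coefficient is undefined there; scoring them zero would
manufacture decorrelation) and are summarised as the mean over windows
after the first sniff. Distance relations are fitted with the stretched
exponential $a e^{-b x^n}$ by Levenberg-Marquardt, and GC degree
distributions with a maximum-likelihood skew-normal
($\frac{2}{\omega}\phi(z)\Phi(\zeta z)$, $z = (x - \xi)/\omega$).

## Experiments

The five protocols mirror their laboratory counterparts. Lateral
inhibition drives one cell of a height- and degree-matched MC pair with
700 pA, then both (750 pA to the partner), and records the drop in the
first cell's rate over one second. Decorrelation presents panels of
odors with shared glomeruli receiving identical strength and phase, and
attributes to GCs the correlation difference between GABA-enabled and
GABA-disabled runs across window lengths {2, 5, 10, 20, 50, 100} ms (the
grid below 20 ms is our choice; nothing finer is printed). GC feedback
injects 50 pA into 0.1-20% of GCs and compares rate-change correlations
between disjoint target sets in the same network versus a regenerated GC
arrangement; MC feedback injects Normal(200, 20) pA into 20% of MCs and
relates each cell's rate change to its GC degree. Neurogenesis runs ten
rounds of turnover or growth against a fixed 10-odor panel (8 glomeruli
each, sampled from a 15-glomerulus pool so the expected pairwise overlap
is near 4.3): `control` replaces a random quarter of GCs, `baseline` the
least-active quarter (ties broken at random), `addition` adds one tenth
of the GCs still needed for the 15:1 ratio per round, and `guided`
places those additions with vertices within a tenth of a
weight-sampled active MC's arbor radius, redrawing the face height
(bounded retries, then a direct draw from the legal range) so the new
cone always overlaps its MC. The printed small-network bases (916 MCs
with 13,470 GCs for turnover modes — about 14.7 GCs per MC, kept as
printed — and 864 MCs with 4,320 GCs for growth modes) are presets, not
requirements; any network can be passed.

## Problem sizes, reproducibility and limitations

The package's own test suite and worked examples run the full printed
configuration only where it is cheap (placement of the radius-600 um
bulb, single-cell physiology); wired-network and simulation checks use
radius 100-150 um networks at 5:1 or 15:1 ratios, sizes chosen so the
whole suite completes in minutes on one core. At those sizes the
*structure* of the results — exponential-like MC degrees, type I > type
II connectivity, low sister-MC overlap, distance-dependent shared-GC
counts and lateral inhibition (and their flatness in the
distance-independent control), theta plus a GC-dependent fast LFP band,
window-dependent decorrelation, growth-mode neurogenesis benefits — is
stable, but the printed magnitudes that depend on absolute degree (mean
GCs per MC near 1226, the 15 Hz beta and 40-55 Hz gamma peak positions,
the neurogenesis percentages) emerge only at the full radius-600
configuration, which takes hours of simulation. The full presets are
exposed (`make_fixture("paper")`, the experiment defaults) so those runs
can be reproduced offline.

All randomness flows through R's RNG: a single seed reproduces a
network, its parameters and every protocol bit-for-bit. Networks persist
as delimited text with a JSON manifest; a save/load/save cycle is
byte-identical.

What the generator does not emulate: curved bulb geometry (the space is
flat; periodic boundaries only remove edges, they do not add curvature),
tufted cells and superficial GCs, synaptic plasticity, graded
(spike-independent) GABA release beyond the kappa rule, and spatial bulb
growth during neurogenesis. Passing tests therefore speak to the model's
internal consistency and to the anatomical mechanism they exercise, not
to features of real bulbs outside this scope.
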