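---
title: "Models and methods: compartment-resolved SPT, spatial statistics, and photokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: compartment-resolved SPT, spatial statistics, and photokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcspt)
```

## The scientific question

Herpes simplex virus 1 (HSV1) builds membraneless replication
compartments (RCs) in the host nucleus, and RNA polymerase II (Pol II)
becomes strongly enriched there. Two mechanisms could explain the
enrichment: liquid–liquid phase separation, which predicts a distinct
Pol II mobility inside the compartment, slowed exchange across its
boundary, and homogenisation within it; or transient nonspecific
binding to the naked, nucleosome-free viral DNA, which predicts mostly
unchanged free diffusion but a higher bound fraction, anisotropic
revisiting of DNA-rich sites, and multi-scale clustering. `rcspt`
implements the quantitative analyses that distinguish the two on
single-particle tracking (SPT), localization-microscopy, and
photobleaching data, together with particle-based simulators that
generate data with the statistical structure each analysis assumes, so
every stage is testable without any imaging data.

## Coordinate and containment conventions

All coordinates are micrometres, 2-D, origin at the image top-left
with y increasing downward; frames are 0-based and time intervals are
half-open. Compartment and nucleus outlines are closed simple
polygons. Containment uses the even-odd rule, and a point lying
exactly on an edge counts as *inside*. That tie-break is applied by
every containment test in the package (trajectory sorting, angle
vertices, point patterns, mock placement), so boundary points are
never counted twice or dropped.

## The two-state jump-length model

The kinetic model treats a population of molecules as a mixture of an
immobile (chromatin-bound) state and a freely diffusing state. For a
lag of $n$ frames ($t = n\,\Delta t$), the squared displacement of
state $X$ is exponential with scale $4(D_X t + \sigma^2)$, where
$\sigma$ is the static localization error; the jump-length CDF is

$$P_X(r) = 1 - \exp\!\left(-\frac{r^2}{4(D_X t + \sigma^2)}\right).$$

Defaults follow the acquisition this package targets: $\Delta t =
7.447$ ms (7 ms integration + 0.447 ms dead time), $\sigma = 45$ nm,
and fitting bounds $D_\mathrm{free} \in [0.5, 25]$,
$D_\mathrm{bound} \in [10^{-4}, 0.08]$ µm²/s,
$F_\mathrm{bound} \in [0, 1]$.

### Defocalization

Fast molecules leave the axial detection slab (depth $\Delta z = 0.7$
µm) between frames, so free jumps are under-represented at long lags.
`defocalization_fraction()` computes the survival of a molecule
starting uniformly in an absorbing slab by the standard eigenseries

$$Z(t) = \sum_{k\ \mathrm{odd}} \frac{8}{(k\pi)^2}
  \exp\!\left(-\frac{(k\pi)^2 D t}{\Delta z^2}\right),$$

truncated when terms drop below $10^{-10}$. The choice of an exact
absorbing-slab solution (rather than an empirically corrected slab
depth) keeps the quantity oracle-verifiable: the test suite checks it
against a Brownian-bridge Monte-Carlo walker simulation to 0.005.

### Weighting the free component: the jump cap matters

Jump statistics are compiled with at most `cap = 4` jumps per
trajectory per lag (`compile_jump_statistics()`), which stops
long-lived bound trajectories from swamping the displacement
histograms. This cap has a consequence for the mixture weight of the
free component that is easy to miss. The $j$-th retained lag-$n$ jump
of a trajectory spans frames $(j, j+n)$, so it is observed only if the
molecule survives $j + n$ frames; with the cap, the expected number of
observed lag-$n$ free jumps per trajectory is
$\sum_{j=0}^{3} Z((n+j)\Delta t)$, against $4$ for a bound molecule.
The correct mixture weight is therefore the *cap-averaged* survival

$$\bar Z_n = \tfrac14 \sum_{j=0}^{3} Z\big((n+j)\,\Delta t\big),$$

not the single-time survival $Z(n\Delta t)$. The difference is not a
refinement: at the reference conditions (50% bound, $D_\mathrm{free} =
3.5$ µm²/s) the single-$Z$ weight misestimates the bound fraction by
roughly +15 percentage points, while the cap-averaged weight recovers
it to within 1–2 points (both variants are exposed via
`z_weighting = c("cap", "single")` in `two_state_cdf()` and
`fit_two_state()`; the package defaults to `"cap"`).

### Fitting

`fit_two_state()` minimises the count-weighted sum of squared
differences between the model CDF and the empirical CDFs jointly over
lags 1–7, with bounded L-BFGS-B from a fixed stratified grid of nine
starts; the best solution is returned, making the procedure
deterministic. The empirical support is thinned to at most 500 points
per lag for speed. Fits refuse fewer than 100 trajectories and warn
below 1000, the minimum for a reliable two-state fit. A finite-data
caveat: with only ~1000 trajectories, correlated noise in the
empirical CDF can be absorbed by a small spurious free component
(all-bound data may fit at $F_\mathrm{bound} \approx 0.93$); at the
5000-trajectory scale used throughout the package the boundary case
recovers cleanly.

Because single cells rarely carry 1000 trajectories — least of all
inside compartments — per-condition uncertainty comes from
`subsample_fit()`: draw 15 cells without replacement, pool, fit, and
repeat 100 times (both numbers configurable), reporting the median and
SD per parameter.

## The spaSPT simulator

`simulate_spaspt()` emits two-state Brownian trajectories inside a
polygonal nucleus. Design choices that matter:

* **No state switching by default.** The fitting model assumes fixed
  states; the generator matches it. Equilibrium-consistent switching
  is available behind `allow_switching` for robustness studies.
* **Bound residual motion.** Bound molecules move with
  $D_\mathrm{bound} = 0.005$ µm²/s, mimicking chromatin jiggle, well
  inside the fitting bounds.
* **Defocalization by Brownian bridge.** The hidden z coordinate is
  propagated in sub-steps with Brownian-bridge barrier-crossing tests,
  so the simulated survival follows the *continuous* absorbing-slab
  law that the fit corrects for. A naive per-frame $|z| > \Delta z/2$
  check would inflate survival nearly two-fold at $D = 3.5$ µm²/s and
  silently bias every recovery test.
* **Track length.** Trajectories are observed for at most 12 frames
  (enough for lag 7 with the 4-jump cap); optional geometric
  photobleaching shortens them. Photoactivation sparsity is not
  simulated — trajectories are emitted directly.
* **Boundary handling.** Steps leaving the nucleus are mirrored
  through the nearest boundary point (and clamped onto the boundary if
  the mirror image still falls outside); with nuclei tens of step
  lengths wide this affects a few percent of steps.

### Binding traps

For anisotropy studies the simulator can scatter point traps
(Poisson, `density` per µm²) in the compartments. A free molecule
stepping within the capture radius is trapped; each frame it escapes
with probability `escape_prob`. While trapped it does **not** freeze:
by default (`trap_mode = "confine"`) it keeps free-state mobility but
is reflected inside the capture disc — transient confinement on
clustered DNA, the microscopic picture behind repetitive revisiting
(hopping/sliding between adjacent nonspecific sites). A frozen
variant (`trap_mode = "freeze"`) exists, but frozen molecules move
only by localization error (~90 nm apparent jumps), which the
mandatory 150 nm analysis filter removes, so freezing produces no
measurable angular signature — confinement is the variant that
actually transports the binding signal into the observable. The
default capture radius is 0.25 µm because the displacement scale of
confined motion ($\approx 0.9 R$) must exceed the 150 nm filter for
any confined triple to be retained.

## Angular anisotropy

`filter_mobile_segments()` takes every gap-free three-point segment
whose two displacements both exceed 150 nm — the hard threshold is
essential because the apparent motion of bound molecules is pure
localization error, which is strongly anti-correlated between
consecutive frames (the shared-error term) and would make everything
look anisotropic. An optional two-state displacement HMM (Rayleigh
emissions, EM plus Viterbi smoothing) additionally removes segments
classified as bound. `compute_angles()` folds the angle between
consecutive displacement vectors to $[0°, 180°]$ and assigns each
angle to a region by containment of its vertex (the middle point) in
the drift-interpolated compartment at that frame.
`fold_anisotropy()` reports
$f_{180/0} = \#\{\theta \ge 150°\} / \#\{\theta \le 30°\}$ with a
bootstrap SD. Ideal Brownian motion gives $f = 1$; trapping gives
$f > 1$, increasing with trap density. Note that even *with* the
filter, realistic localization noise leaves a residual backward bias
($f \approx 1.2$ at $\sigma = 45$ nm for pure free diffusion), so
isotropy nulls in the test suite are run at $\sigma = 0$, isolating
the motion statistics from the measurement artefact.

## Edge-corrected Ripley statistics

For a point pattern in a polygonal region the package computes the
neighbourhood density with isotropic edge correction,

$$N(r) = \frac{1}{N_p} \sum_i \sum_{j \neq i}
  f(i,j,r), \qquad
  f = \begin{cases} 0 & d(i,j) > r \\
  \dfrac{2\pi\, d(i,j)}{C_\mathrm{in}} & \text{otherwise},
  \end{cases}$$

where $C_\mathrm{in}$ is the arclength of the circle of radius
$d(i,j)$ centred on $i$ that lies inside the region; then
$K(r) = N(r)/\lambda$ and $L(r) - r = \sqrt{K(r)/\pi} - r$, which is 0
under complete spatial randomness, positive for clustering, negative
for regularity. $C_\mathrm{in}$ is computed analytically
(circle–edge intersection with midpoint classification of each arc, in
C++), and verified against numeric arc integration at $10^{-4}$ rad
resolution in the tests. Pairs whose circle lies entirely outside the
region are excluded with a warning. Uncertainty follows the
localization-microscopy convention: subsample 25,000 detections 100
times and report the pointwise mean and SD; CSR reference bands come
from seeded Poisson simulations with the observed point count. At
radii below ~20 nm fluorophore blinking inflates $L(r)-r$ in real
data; choose the radius grid accordingly.

## Trajectory linking and annotations

Linking is greedy nearest-neighbour with gap closing: the search
radius for a $k$-frame link is $r_\mathrm{max}(k) =
\sqrt{4 D_\mathrm{max} k \Delta t}$ ($D_\mathrm{max} = 10$ µm²/s, one
gap frame), links are granted shortest-first within each frame, and an
end seeing more than 3 candidates is terminated rather than linked —
the ambiguity rule that replaces probabilistic multi-hypothesis
scoring with an auditable deterministic procedure. Nucleus and
compartment outlines are drawn on "before" and "after" reference
images and linearly interpolated per frame (vertex-paired polygons),
which is what makes the per-frame containment tests drift-corrected.
A trajectory is labelled *inside* if **any** of its localizations
falls inside a compartment at its own frame — deliberately permissive,
so the label cannot be biased against fast molecules that merely
clip a compartment. The companion null is
`place_mock_compartments()`: real compartment outlines dropped at
random positions (translation only by default; rotation behind a
flag) subject to non-overlap constraints, on which inside/outside fits
must agree.

## Photokinetics

FRAP traces are double-normalised: spot over whole-nucleus reference
(cancelling acquisition photobleaching), then over the mean of the 15
pre-bleach frames, so the pre-bleach level is exactly 1. FLIP traces,
whose measurement spot is far from the repeatedly bleached one, are
corrected by the empirically determined global decay
$e^{-0.09\,\mathrm{frame}}$ (the rate is a per-frame argument; the
default corresponds to 250 ms frames). `aggregate_curves()` returns
the pointwise mean flanked by SEM. Kinetic model fitting of recovery
curves is deliberately out of scope — the analyses report empirical
curves.

## Disorder segmentation

Per-residue disorder likelihoods (IUPred-style two-column files) are
smoothed by a centred 8-residue rolling mean (left-heavy for even
windows, shrinking at the termini — the convention is stated because
the source material does not fix one), then maximal runs strictly
above 0.55 become disordered regions, and runs of **more than** 10
residues (i.e. ≥ 11; the strict reading, flagged because
boundary-length proteins shift by one residue) count toward the
fraction-IDR. Score computation itself is out of scope; the module
consumes score files.

## Genome bookkeeping

`estimate_copy_number()` calibrates FISH intensities on the median of
a replication-inhibited (PAA) condition, where each punctum holds one
genome. `genome_budget()` turns a copy number into total viral base
pairs, the viral share of nuclear DNA, and host/viral concentrations
— fixed at diploid host content ($2 \times 3.2 \times 10^9$ bp) by
convention, making viral shares an upper bound in hyperploid lines —
and `atac_enrichment()` divides the viral ATAC-seq read share by the
viral DNA share. Values are kept at full precision; presentation
rounds to 2 significant figures. The Poisson MOI estimator
$\mathrm{MOI} = -\ln f_\mathrm{uninfected}$ and the Feret-diameter
aspect ratio (rotating calipers on the convex hull) complete the
descriptive toolkit.

## What the simulations do and do not establish

The generators reproduce the statistical structure the estimators
assume: two-state diffusion with localization error and slab
truncation, homogeneous or clustered point patterns, reaction-free
recovery with multiplicative bleaching, lognormal FISH intensities.
They do not include photophysics (blinking), detection/linking errors,
camera noise, 3-D PSF shape, state switching within trajectories (off
by default), or anything cell-biological (chromatin structure, real
RC geometry). Green tests therefore certify the *estimators* under
their stated assumptions — parameter recovery within ±5 points of
bound fraction and ±15% of $D_\mathrm{free}$ at 5000 trajectories,
unbiased CSR nulls, exact photobleaching algebra — not the biological
conclusions on real movies. The FRAP/FLIP simulator also idealises
geometry to a single 2-D nucleus, whereas the real assays are
confocal; the normalization contracts are unaffected.

## Problem sizes and numerical settings

Default test-scale runs use 5000 trajectories for single fits, 8–24
synthetic cells for resampling checks, 200 replicate patterns of 1000
points for CSR nulls, and $2\times10^5$–$10^6$ Monte-Carlo draws for
oracles; the SSE tolerance of the optimiser is $10^{-8}$ (`factr`
scaled), eigenseries truncation $10^{-10}$, and bootstrap folds use
1000 draws. A full pipeline demo (`run_pipeline()` on a 4-cell
simulation) completes in well under a minute on one CPU.

```{r demo, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, "rcspt-demo")
res$kinetics
```
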