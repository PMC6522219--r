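# rcspt

Compartment-resolved single-particle tracking (SPT) and spatial
statistics for membraneless nuclear bodies — built around the question
of **how a protein becomes enriched in a compartment**: by
phase-separation-like partitioning, or by transient nonspecific binding
to the DNA the compartment contains.

The motivating system is the herpes simplex virus 1 (HSV1) replication
compartment (RC), where RNA polymerase II is strongly enriched during
lytic infection. The two mechanisms leave different quantitative
fingerprints, and the package implements the analyses that read them
out:

* **Two-state jump-length kinetics.** Trajectories sorted inside/outside
  drift-corrected compartment outlines are compiled into jump-length
  CDFs over lags 1–7 and fitted with a bound/free mixture. For state
  *X* at lag time *t* the jump-length CDF is
  `1 − exp(−r² / (4 (D_X t + σ²)))` with localization error σ = 45 nm;
  the free component is down-weighted by the absorbing-slab survival
  *Z(t)* (detection depth Δz = 0.7 µm, exact eigenseries) averaged over
  the four retained jumps per trajectory. Per-condition uncertainty
  comes from 100 random 15-cell resamples.
* **Angular anisotropy.** The folded angle between consecutive
  displacements (both ≥ 150 nm) gives the backward/forward ratio
  `f(180°±30° / 0°±30°)` — 1 for ideal Brownian motion, > 1 for
  DNA-trapping/revisiting behaviour.
* **Edge-corrected Ripley statistics.** `L(r) − r = sqrt(K(r)/π) − r`
  with the isotropic arclength correction
  `f(i,j,r) = 2π d(i,j)/C_in` for localization patterns in polygonal
  regions, with complete-spatial-randomness (CSR) envelopes and
  25,000-detection × 100 subsampling.
* **FRAP / FLIP photokinetics.** Double normalization for recovery
  curves (reference, then 15 pre-bleach frames) and the `e^(−0.09·frame)`
  acquisition-bleaching correction for loss curves.
* **Disorder segmentation.** 8-residue rolling mean, runs strictly above
  0.55 and longer than 10 residues → fraction IDR per protein.
* **Genome bookkeeping.** FISH copy numbers calibrated on a
  replication-inhibited (PAA) condition, viral share of nuclear DNA,
  host/viral concentrations, ATAC accessibility enrichment, and the
  Poisson MOI estimator `MOI = −ln(f_uninfected)`.
* **Synthetic data for everything.** Particle-based generators
  (two-state diffusion in a slab with Brownian-bridge defocalization,
  binding traps, Poisson/Thomas point patterns, recovery traces,
  FISH intensities, disorder profiles) make every stage testable
  offline.

## Worked example

Simulate a 5000-trajectory spaSPT experiment at the reference
conditions (50% bound, D_free = 3.5 µm²/s, Δt = 7.447 ms) and fit it:

```r
library(rcspt)
sim   <- simulate_spaspt(spaspt_config(n_trajectories = 5000), seed = 42)
jumps <- compile_jump_statistics(sim$trajectories)
fit_two_state(jumps)
#> Two-state jump-length fit (all)
#>   F_bound = 0.500
#>   D_free  = 3.447 um^2/s
#>   D_bound = 0.0053 um^2/s
#>   SSE     = 6.59e-06 (5000 traj)
```

The fitted bound fraction recovers the generating 0.5 exactly and the
free diffusion coefficient to within 2% — the defocalization-corrected
mixture is doing its job (drop to `z_weighting = "single"` to see the
~15-point bias the jump cap would otherwise induce).

Genome bookkeeping from published-scale inputs (82 viral genome copies
of 1.5×10⁵ bp against a diploid 6.4×10⁹ bp host genome; nucleus 681 µm³,
RCs 315 µm³; 24.2% of ATAC-seq reads mapping to the virus):

```r
genome_budget(copy_number = 82, nucleus_volume = 681, rc_volume = 315,
              atac_viral_read_pct = 24.2)
#> Genome budget (2 significant figures for presentation)
#>   host total      6.4e+09 bp; viral total 1.2e+07 bp (82 copies)
#>   viral % of DNA  0.19%
#>   conc host/viral 9.4e+06 / 3.9e+04 bp/um^3 (ratio 2.4e+02)
#>   ATAC % viral    24.2 -> fold enrichment 1.3e+02
```

Viral DNA is ~0.2% of nuclear DNA and ~240× more dilute than host
chromatin, yet captures a quarter of the accessibility reads — a
~130-fold enrichment.

`run_pipeline(pipeline_config(seed = 1), "out")` runs simulate → link →
sort → kinetics/anisotropy/Ripley end to end and writes JSON/CSV
results plus a parameter log; re-running the same config reproduces the
outputs bit for bit.

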