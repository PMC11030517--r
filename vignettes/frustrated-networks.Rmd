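---
title: "Modeling dynamic frustration in coupled excitable neuron networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dynamic frustration in coupled excitable neuron networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frustranet)
```

## The scientific problem

Monolayers and micropatterned grids of neuronal cells respond to a
periodic chemical stimulus (alternating ATP / growth medium at 50% duty
cycle) with calcium transients. Two empirical regularities motivate this
package: node-to-node deviations shrink as the stimulus period grows, and
— at long periods — *better-connected* networks synchronize *worse* than
sparsely connected ones. `frustranet` implements a minimal dynamical model
that exhibits both effects, together with the trace statistics needed to
quantify them identically in simulations and recordings.

## Model and assumptions

Each cell is a quadratic integrate-and-fire (QIF) unit,
$\dot v = b + v^2$, spiking at $v_\mathrm{peak} = 1$ and resetting to
$v_\mathrm{reset} = 0$. For $b > 0$ the spiking period is
$\tau(b) = b^{-1/2}\arctan(b^{-1/2})$ (`qif_period()`); the inverse map
(`b_from_period()`) is computed by bracketed root finding on this strictly
monotone formula, accurate to better than $10^{-10}$ relative error. The
origin of the $(b, v_\mathrm{reset})$ plane is the saddle-node homoclinic
orbit (SNHO) point (`classify_regime()` reports the regime, with an
explicit `on_bifurcation` flag on either boundary rather than a silent
assignment). Operating near the SNHO point is the key assumption: there,
diffusive (gap-junction) coupling $g(v_j - v_i)$ repels the phases of a
weakly coupled pair toward anti-phase, while strong coupling
($g\tau \gtrsim 1$) locks the pair in-phase.

The external stimulus is a third QIF unit $u$ on thresholds $(0, 1)$,
resetting $1 \to 0$, so that its period is exactly
$T = b_0^{-1/2}\arctan(b_0^{-1/2})$; it drives every cell diffusively with
strength $g_0$ but is not influenced by them (bath stimulation). The reset
interpretation of $u$ was chosen over an idealized smooth waveform because
the printed period formula is precisely the $0\to1$ transit time of the
reset unit. Cell-to-cell heterogeneity is specified on periods, not rates:
$\tau_i \sim N(T, T/10)$, mapped through `b_from_period()`
(`sample_heterogeneity()`; draws below $T/100$ — vanishingly rare at this
sd — are resampled).

### Coupling strengths are per drive cycle

Throughout the experiment layer, couplings are parameterized by the
dimensionless products $g\tau$ and $g_0 T$. What separates the weak
(anti-phase) from the strong (in-phase) regime is the coupling
accumulated per oscillation cycle, so holding $g_0 T$ fixed across a
period sweep keeps every sweep point in the same entrainment regime. This
is also what produces the clean $T^{-1/2}$ decay of the deviation score in
`exp_period_sweep()` (default $g_0 T = 0.1$): with a fixed *absolute*
$g_0$ the forcing deepens as $T$ grows and the deviation collapses much
faster than $T^{-1/2}$. The coupling sweep (`exp_coupling_sweep()`)
likewise uses $gT$ on its axis with $g_0 T = 1$.

### Integration and reset numerics

The integrator (Rcpp core) is fixed-step RK4 (Euler available for
convergence checks), default step $\tau_{\min}/1000$ and a hard validity
bound of $\tau_{\min}/200$. The dynamics are bounded above by the reset,
so no blow-up handling is needed. When a step carries a unit across
$v_\mathrm{peak}$, the crossing time is located by linear interpolation
within the step and recorded as the spike time; the unit restarts from
$v_\mathrm{reset}$ and is advanced over the step remainder with a
coupling-free Euler update (an $O(g\,dt)$ approximation incurred once per
period, far below the 0.5% period tolerance the tests enforce). A
resetting cell's voltage is discontinuous; partners see the post-reset
value from that step onward — coupling is purely diffusive, no spike pulse
is transmitted.

Initial conditions are uniform on $[v_\mathrm{reset}, v_\mathrm{peak})$
per cell from the trial seed (random phases are needed both for the
desynchronization transient of the weakly coupled pair and for honest
trial averaging); $u(0) = 0$. All trial randomness flows through a
deterministic seed hierarchy: a base seed spawns one child seed per
(trial, role) with roles lattice / heterogeneity / initial conditions, so
sweeping the connectivity alone does not reshuffle the heterogeneity
draws.

## Lattices

`build_square_lattice()` includes each nearest-neighbour edge of a
non-periodic grid independently with probability $p$ (the micropatterned
bridge probability). `build_triangular_lattice()` builds the six-neighbour
row-offset lattice — node $(r, c)$ neighbours $(r, c\pm1)$, $(r\pm1, c)$,
$(r\pm1, c+(-1)^r)$ — and disrupts each node with probability $q$,
removing all its edges while keeping the node and its drive term
(disruption models connexin-43 knockout, not removal of the cell; ATP
reaches every cell). Boundaries are non-periodic: edge and corner cells
simply have fewer neighbours, matching a finite field of view.

## Synchrony statistics

The deviation score (`deviation_score()`) follows the recording analysis
exactly: within each moving window of width $T$ every node's segment is
linearly rescaled to $[0,1]$; the population-average normalized curve is
formed; node $i$ scores $\frac{1}{T}\int |R_{i,N} - \langle R_N\rangle|\,dt$
by trapezoidal quadrature; the per-node score is the mean over windows.
Windows are free-running (stride defaults to $T/4$; conclusions are
insensitive to using non-overlapping windows instead) rather than aligned
to stimulus onsets, since onset times are uncertain in recordings.
Constant ("degenerate") segments cannot be rescaled; they are flagged,
contribute zeros to the population curve, and are excluded from that
node's own average — never an error. The window span is taken between its
first and last sample, which makes the anti-phase square-wave fixture
score exactly 0.5 independent of the sampling rate. Both per-node means
and the full window-by-node score matrix are returned.

Pair synchrony is the zero-lag Pearson correlation of the full records
(`cross_correlation()`; no lag search — the 0.8 threshold presupposes a
bounded normalized statistic), and `sync_fraction()` counts pairs
*strictly* above the threshold. `spike_phase_offset()` quantifies
in-phase/anti-phase locking: spikes in the last third of the record
(first two thirds discarded as transient) are matched to the nearest
partner spike and folded circularly into $[0, T/2]$.
`fit_scaling_exponent()` is an ordinary least-squares slope on log-log
axes.

## Synthetic recordings

`generate_dataset()` emulates the statistics the analysis consumes: a
square-wave stimulus (period 40–200 s, duty 0.5, 1 s sampling), per-node
per-cycle onset delays $\delta t \sim \mathrm{Poisson}(\alpha T)$ seconds
(so the delay variance grows linearly with $T$ — the noise-integration
mechanism behind the $T^{-1/2}$ scaling; default $\alpha = 0.05\,
\mathrm{s}^{-1}$, giving $\sigma \approx 3.2$ s at $T = 200$ s, small
against the 100 s ON half-cycle), a calcium-transient kernel
(exponential rise 2 s, decay 10 s, peak-normalized), 10% per-node
amplitude heterogeneity, additive Gaussian noise (sd 0.01 on a baseline
of 1, typical of node-averaged fluorescence fold-change), and a grid
layout with the 70 µm micropattern pitch. Delays are redrawn every cycle
because the scaling argument concerns activation-timing noise per
stimulus, not a fixed per-node latency. Bridged neighbour pairs are drawn
at probability $p$; at $p = 0$ each node is instead paired with one
randomly sampled spatially nearest neighbour, tagged `spatial_nearest`.
Every random quantity is reproducible from the JSON manifest alone
(`dataset_from_manifest()` regenerates files byte-identically).

What the generator does *not* emulate: spatially resolved images,
mechanistic IP3/calcium kinetics, and gap-junction coupling between
traces (coupled dynamics come from the network simulator). Passing tests
on synthetic data therefore validate the metric pipeline and the
delay-variance scaling mechanism, not the full biology of recorded
monolayers.

## Shape of the coupling response

The driven heterogeneous pair's deviation-vs-coupling curve is
single-peaked, and the package treats that as a real feature of the
model rather than smoothing it away: deviation rises with $gT$
throughout the weak regime ($gT \lesssim 1$) — gap-junction-mediated
dynamic frustration — and falls again by $gT = 3$, where strong coupling
locks the pair in-phase, consistent with the two-neuron weak/strong
dichotomy. The network experiments accordingly default to weak-regime
coupling $g = 1/(3T)$ (the $g\tau = 1/3$ anchor), with $g_0 = 1/T$; both
are exposed in every experiment's configuration.

## Problem sizes and determinism

Default experiment sizes follow the study design: 1000 trials for the
pair sweeps, an 18×18 square lattice with 30 trials per $p \in
\{0, 0.75\}$, a 10×10 triangular lattice with 15 trials per $q \in
\{0, 0.5\}$, 8 drive periods per simulation. The test-suite and
acceptance-script runs use reduced counts (100 trials per sweep point, 10
and 8 lattice trials, 20-seed dichotomy checks, 20 synthetic datasets per
period) — sizes at which every direction-of-effect is stable across
seeds. Traces are recorded at roughly 200 samples per drive period
(spike times are always exact), which over-resolves the window metric by
two orders of magnitude. Fixed seeds make every simulation bit-for-bit
reproducible.

## Known limitations

* Two lattice topologies only, non-periodic boundaries, spatially uniform
  drive.
* No synaptic (pulse) coupling and no conductance-based membrane models;
  the QIF reset is the only spike mechanism.
* The deviation score needs at least two nodes and at least two samples
  per window; records shorter than one stimulus period cannot be scored.
* The scaling-exponent fit assumes a single power law across the supplied
  periods; it will average over regime changes (e.g. the steepening of
  entrainment when $g_0$ is held fixed in absolute terms).
* `analyze_recordings()` expects the package's tabular trace format; an
  adapter is needed for other recording layouts.
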