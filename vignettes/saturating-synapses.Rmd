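---
title: "Saturating synapses and linearly non-separable computation in a one-compartment neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturating synapses and linearly non-separable computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satif)
```

## The model and its assumptions

`satif` simulates a single-compartment leaky integrate-and-fire neuron whose
synaptic inputs are pooled into conductance *groups*:

$$\tau \frac{dv}{dt} = -(v - v_{rest}) + R \sum_j g_j(t)\,(E_s - v),$$

with a spike recorded and $v$ reset whenever $v$ reaches the threshold.
Each group's conductance decays exponentially with time constant $\tau_s$
and, on every afferent spike, either jumps **to** its ceiling
$g_{max}$ (`set_to_max`, the saturating semantics) or jumps **by** $g_{max}$
without bound (`additive_unbounded`, the linear LIF semantics). The
saturating form models the fact that nearby synapses compete for a bounded
conductance per unit of membrane surface (or mutually deplete transmitter),
so co-activating inputs that share a site adds nothing once the site is
saturated — whereas inputs targeting *different* sites sum their ceilings.

Assumptions worth keeping in mind:

* one membrane voltage (electrically compact cell) — no cable structure, no
  dendritic spikes, no voltage-gated conductances;
* excitatory inputs only ($E_s$ well above threshold);
* saturation is instantaneous and complete (a single spike pins the group at
  its ceiling); partial or graded saturation is not modelled;
* conductances persist through the somatic reset (only $v$ is reset), the
  standard integrate-and-fire convention.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau_ms` | 20 | ms | membrane time constant |
| `v_rest_mV` | −65 | mV | rest and leak reversal |
| `R_MOhm` | 20 | MΩ | input resistance |
| `v_threshold_mV` | −62 | mV | spike threshold (replaced by calibration, below) |
| `v_reset_mV` | −65 | mV | post-spike reset |
| `E_s_mV` | 0 | mV | synaptic reversal |
| `tau_s_ms` | 1 | ms | synaptic decay |
| `g_max_pS` | 100 | pS | per-group ceiling / per-spike increment |
| `drive_scale` | 1 | — | global multiplier on all ceilings |

The default cell (`sif_neuron()`) has four input sources mapped pairwise
onto two saturating groups; `make_lif()` collapses any spec into the matched
single-group unbounded control with identical membrane parameters and
per-spike increment.

## The task battery

`make_cfbp(m)` builds the compact feature binding problem over $2m$ inputs:
clusters $A = \{1..m\}$ and $B = \{m+1..2m\}$; the indicator rows of $B$ and
$A$ must output 0, and two complementary $m$-sets that each straddle both
clusters must output 1. For $m = 2$ these are the canonical rows
0011, 1100 → 0 and 0101, 1010 → 1. The generalisation was chosen so that
the two 0-rows and the two 1-rows partition the same input set for every
$m$: the pairing contradiction (below) then certifies non-separability of
the whole family, not just the 4-input case. Other generalisations (e.g.
more than four rows) would be possible but are not implemented.

## Certifying (non-)separability

`is_linearly_separable()` decides whether weights $w$ and a threshold
$\Theta$ exist with $w \cdot X \ge \Theta$ exactly on the output-1 rows.

* **LP route** (any $n$): feasibility of
  $\{w \cdot X \ge \Theta$ on 1-rows; $w \cdot X \le \Theta - 1$ on
  0-rows$\}$. The unit margin costs nothing because the strict system is
  invariant under positive scaling of $(w, \Theta)$, and it turns an open
  feasibility region into a closed one. Free variables are split into
  non-negative parts and the system is handed to `boot::simplex()` with a
  minimise-total-mass objective under a generous mass bound, which keeps
  returned witnesses small and the solver well-posed.
* **Exhaustive route** ($n \le 4$): brute force over integer
  $w \in \{-8..8\}^n$, $\Theta \in \{-32..32\}$ — deliberately generous for
  threshold functions of at most 4 variables, and fully independent of the
  LP, so each route cross-checks the other (the test suite enumerates all
  16 two-input and 256 three-input complete functions and recovers the
  classical separable counts, 14 and 104).

Every witness is replayed through the defining inequality on all rows
before a certificate is returned. `check_pairing_contradiction()` implements
the proof device for the task family: two disjoint 0-rows and two disjoint
1-rows with equal active-input unions force $S \le 2\Theta$ and
$S > 2\Theta$ simultaneously. Rows must have at least one active input —
the device is about tuples of active inputs, so the all-zero pattern does
not participate (XOR is left to the generic checker).

## The stimulation protocol and calibration

A truth-table row becomes a stimulation episode in one of two readings:

* **spike mode** — one simultaneous spike on each active input
  (`generate_single_spike_trains()`); deterministic;
* **rate mode** — each active input fires a Poisson train at 50 Hz
  (`generate_poisson_trains()`), episodes of 500 ms.

Episodes are independent (state reset between episodes), so their order is
irrelevant. The episode Boolean readout is "at least one somatic spike".

### Why calibration exists

With the default parameter magnitudes ($R \cdot g_{max}$ =
20 MΩ · 100 pS = 2·10⁻³), a single scattered volley depolarises the cell by
only ~12 µV — far below the 3 mV threshold gap. The qualitative claim is
insensitive to the magnitudes, so `calibrate()` resolves the gap
mechanically: with spiking disabled it measures each episode's peak
depolarisation, scales `drive_scale` up by powers of 10 until the midpoint
between the largest output-0 peak and the smallest output-1 peak clears
rest by at least 0.5 mV, and adopts that midpoint as the spike threshold.
Saturation pins the clustered:scattered conductance ratio at 1:2 at every
scale, so scaling never distorts the contrast — all conductance-ratio
results are reported at `drive_scale` 1. A model whose episode classes do
not separate in peak voltage (the LIF: its episode traces are *identical*)
is reported `not-calibratable`, a scientific outcome rather than an error.

### Rate coding, synchrony and what the package asserts

The Poisson generator takes a synchrony parameter (`sync`, default 1) built
as a multiple-interaction process: one mother train, thinned per source, so
each active source keeps its 50 Hz marginal rate while `sync` sets how often
active inputs fire together within an episode. The default is full
within-episode synchrony, which reads a truth-table row as *repeated joint
activation* of its active ensemble. The choice matters: saturation only
engages when spikes of one group fall within ~$\tau_s$ = 1 ms of each
other, and at 50 Hz fully independent streams almost never do — the
saturating and linear models then converge and no readout can tell the
classes apart. Episode firing rates also depend on the input correlation in
exactly this way, which is why no absolute rates are asserted anywhere.

Even at full synchrony, the *episode-level categorical* readout is fragile
in rate mode: the membrane integrates over $\tau$ = 20 ms, so an episode's
peak voltage and spike count scale with the local event density of that
seed's Poisson draw — a common-mode fluctuation larger than the 2:1
saturation contrast. `implements_table()` therefore demands unanimity over
20 seeds in rate mode and reports the agreement fraction honestly; the test
suite asserts the robust *ordinal* form of the claim (within every episode
set, each scattered episode out-fires every clustered one, and the LIF shows
no contrast at all), while the categorical truth-table reproduction is
asserted in spike mode, where it is exact and deterministic.

## Numerical choices

* **Integration**: conductance decay is integrated exactly
  ($e^{-dt/\tau_s}$); the membrane equation is affine once $g$ is frozen
  over a step, and is advanced by its exact solution (exponential Euler).
  Default $dt$ = 0.1 ms; a guard rejects $dt > \tau_s/5$.
* **Accuracy**: at $dt$ = 0.1 ms the peak depolarisation of single-volley
  fixtures at `drive_scale` 1 agrees with an independent forward-Euler
  reference at $dt$ = 10⁻³ ms to better than 1 µV (asserted in the tests).
* **Event binning**: a spike at time $t$ acts in the step ending at
  $(\lfloor t/dt \rfloor + 1)\,dt$; within a step, arrivals apply after the
  decay, in ascending source order — irrelevant for saturating groups,
  deterministic for additive ones.
* **Threshold handling**: crossings are detected at step boundaries; the
  stored sample after a spike is the reset value, so stored voltages always
  lie in $[v_{reset}, v_{threshold}]$ during spiking runs.
* **Degenerate inputs**: empty patterns produce silent episodes (output 0);
  single-output-class tables are not calibratable (midpoint undefined);
  conflicting duplicate truth-table rows are rejected at construction.
* **Problem sizes**: the test suite enumerates complete Boolean functions
  up to $n = 3$ (256 tables, both certification routes), checks the
  saturation bound over 1000 random 500 ms Poisson episodes, and verifies
  the Poisson marginal rate over 200 repetitions — sizes chosen to exercise
  every claim while keeping the default suite quick.

## Determinism and file formats

Spike-mode results are bit-identical across runs; rate-mode results are
bit-identical for a fixed seed, and every source draws its train whether or
not it is active, so a source's drive never depends on which other inputs
are on. Spike trains and truth tables travel as two-column CSV, simulation
results and certificates as JSON at 17 significant digits (lossless for
doubles), configurations as YAML with unit-suffixed keys. `write_fixtures()`
regenerates the bundled fixture set byte-identically.

## Limitations

* The model is a caricature of synaptic saturation: binary, instantaneous,
  history-free. It shows that *interaction between synapses* suffices for
  linearly non-separable computation in a compact cell; it does not predict
  quantitative granule-cell responses.
* Absolute firing rates are meaningless here (they trade off against
  `drive_scale`, the input rate and the synchrony); only orderings are
  interpreted.
* The pairing certificate is sufficient, not necessary: tables can be
  non-separable without it (XOR is the bundled example).
* The exhaustive certification route is capped at 4 inputs by design; the
  LP route has no such cap but returns real-valued witnesses.
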