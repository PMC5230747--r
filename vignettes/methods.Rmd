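---
title: "A silicon model organism: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A silicon model organism: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silicophys)
```

## Why analyze a chip like a brain

A clocked digital circuit is a system whose function, wiring, and module
boundaries are known exactly, yet whose activity — binary switching across
thousands of three-terminal devices — superficially resembles large-scale
neural recordings. That makes it an unusually honest benchmark for the
analysis methods systems neuroscience applies to data it does *not*
understand: every analysis run on the circuit can be scored against ground
truth. `silicophys` packages that idea as a reusable validation platform:

1. a deterministic **switch-level simulator** for NMOS transistor netlists,
   with per-transistor lesioning;
2. the **analysis battery**: spike extraction, binning and z-scoring,
   stimulus tuning curves, spike-word statistics with shuffle controls,
   spatially weighted "local field potentials" and Welch spectra,
   trial-based conditional Granger causality with BIC order selection,
   non-negative matrix factorization (NMF) of population activity, and a
   stochastic block model (SBM) on the transistor connectome;
3. **synthetic ground truth**: circuit fixtures with annotated modules and
   named control signals, and surrogate generators with planted parameters,
   so every stage of (2) is testable without any external data.

## The circuit model

A netlist holds wires and enhancement-mode transistors; a transistor
conducts between its channel terminals `c1` and `c2` exactly when its gate
wire is high. Depletion-mode pullups are modeled as a wire attribute
(`pullup = TRUE`): a static load that pulls an undriven wire high. Power
and ground are single distinguished wires.

### Settling semantics

Simulation is synchronous relaxation to a fixed point. One timestep applies
the stimulus assignment to the input wires and then iterates passes until
no wire changes:

* conduction is recomputed from gate values (lesions override it:
  `stuck_on` forces conduction — the input-forced-high intervention —
  `stuck_off` forbids it);
* wires connected through conducting channels form a *group*; the group
  value follows a fixed precedence: contains **ground** → low; else
  **power** → high; else a **pinned input wire** → its driven value, low
  dominating on conflict; else any **pullup** → high; else any member high
  at the start of the pass → high (**charge retention**); else low;
* rails and pinned inputs always keep their driven values.

The pinned-input rule is our addition to the usual ground/power/pullup/
charge precedence: input pins are externally driven, so they must be able
to pull a charged storage node low through a pass transistor. Without it a
transmission-gate latch fed directly from a pin cannot store a zero.

Degenerate inputs are handled deterministically rather than rejected: a
power-to-ground short resolves low (ground dominates), conflicting pinned
inputs resolve low. A circuit that does not settle within `100 × n_wires`
passes raises an "unstable" error naming the oscillating wires; because
every fixture is two-phase clocked and free-running oscillators are
excluded by construction, instability only arises from lesions or
adversarial netlists, and the lesion screen counts it as behavioral
failure. The initial state is all wires low except power; fixtures embed
whatever reset prefix they need in their stimulus programs.

These conventions are *declared*, not derived: real switch-level
simulators differ in their short-circuit and charge-sharing rules. The
test suite therefore pins the semantics twice — once in compiled code, once
in an independent plain-R relaxation oracle — and checks equality on
hundreds of random netlists.

### Gates and fixtures

The builder provides canonical NMOS structures (`not`, `nand2/3`, `nor2`,
derived `and`/`xor`, `pass_latch`, two-phase `dff_2phase`). A clock cycle
spans two timesteps: `clk0` high then `clk1` high, non-overlapping. Four
fixtures ship with the package:

* **adder4** — combinational 4-bit ripple-carry adder; ground truth is
  4-bit arithmetic over all 256 input pairs. This is the lesioning
  workhorse: per-transistor necessity can be brute-forced exhaustively.
* **shiftreg8** — eight master–slave stages; a pattern presented at the
  input reappears on the output seven clocks later (the first stage
  registers its input within the presenting clock).
* **counter3_decoder** — 3-bit synchronous counter plus 3-to-8 decoder.
  The three bit cells are laid out 4000 µm apart so that a 500 µm Gaussian
  field-potential channel sees one cell at a time; bits 0–2 oscillate with
  periods 4, 8, and 16 timesteps (2, 4, 8 clocks).
* **microfsm** — a ~230-transistor two-phase machine with annotated
  modules: control (a read/write line toggling fetch and write clocks),
  clock tree and RW distribution buffers, 3-bit program counter, 3-to-8
  decoder, 4-bit adder, accumulator, and output register. Three operand
  "behaviors" emit distinct scalar output streams (the luminance
  analogue). Its registry names 28 known signals (clock phases, RW, counter
  bits, bus bits) for component interpretation.

Every fixture verifies its expected output streams by simulation when it is
built (`make_fixture()` aborts on mismatch), so the ground-truth registry
can never drift from the netlist.

### Why the microfsm looks the way it does

Two architectural choices matter for the population analyses and were made
deliberately:

* **Clock tree and RW fanout buffers.** Real processors dedicate large
  transistor populations to clock and control distribution; those
  transistors follow the distributed line wholesale. They are what makes
  the leading latent dimensions of population activity track the clock and
  the read/write line.
* **No complement-gated register muxes.** The accumulator recirculates via
  a single pass transistor gated by RW (charge retention covers the write
  phase) instead of an rw/rwb transmission-gate pair. With both `rw`- and
  `rwb`-gated unit families present, the "conjunction" patterns
  (`clk0 ∧ rw`, `clk0 ∧ ¬rw`, ...) reconstruct every pure clock or RW row
  additively, so a parts-based factorization is free to choose conjunctions
  — an exactly degenerate alternative whose components correlate with each
  underlying line at only `r ≈ 0.58`. Removing the `rwb`-gated family makes
  the pure basis strictly cheaper, and NMF then recovers clock and RW
  components with `|r| > 0.95`.

## The analysis battery

**Spikes.** A spike is the off→on transition of a transistor's conduction
state (the analogue of an action potential; analyzing wire voltages would
be the analogue of transmembrane recording). Counts are binned (default
100 timesteps) and optionally z-scored with the population (1/N) variance
convention; constant units map to zero rather than NaN. Tuning-curve rates
use a trailing 100-timestep window.

**Tuning curves** average the rate over timesteps sharing a stimulus value
(occupancy normalization). Classification replaces by-eye judgment with an
explicit rule: least-squares fit of a Gaussian plus baseline
`a·exp(−(s−µ)²/2w²) + b`; *simple* if `R² ≥ 0.8` with an interior peak,
*complex* if the Gaussian fails but stimulus explains `η² ≥ 0.1` of rate
variance, else *untuned*. Both thresholds are arguments; they are
conventions, not estimates.

**Spike words.** The population vector per time bin, summarized by its
weight histogram and pairwise correlations over 64 units chosen nearest
the mean rate (ties to the lower id). The shuffle control circularly
shifts each unit's train by an independent uniform offset — preserving
marginal counts and autocorrelations exactly while destroying synchrony.
The null histogram is the *average* over 20 independent shuffle draws: a
single draw adds its own sampling noise on top of the raw histogram's,
which at 10⁴ bins is the same order as the raw-vs-null distance being
tested. An alternative per-bin label permutation is available but
preserves word weights by construction, so it can only serve as a control
for unit-resolved statistics.

**LFP.** Switching events (both edges by default, distinct from the
rising-edge spike definition) are integrated with Gaussian spatial weights
`exp(−d²/2σ²)` (σ = 500 µm) around a recording point and low-pass filtered
with a centered width-4 moving average (even widths lean one sample
forward; edges truncate). Spectra use Welch's method: 256-sample
non-overlapping segments, constant detrend per segment, Hann window.
Detrending matters: the mean switching load otherwise leaks through the
Hann main lobe and dominates the lowest bins. Frequencies are in
cycles/timestep (Nyquist 0.5); `spectrum_peak()` reports the non-DC argmax.
A width-4 boxcar has transfer-function nulls at 0.25 and 0.5
cycles/timestep, so period-4 event trains — including the period-4 edge
train of a symmetric period-8 square wave — are suppressed, and the
period-8 counter bit's channel peaks cleanly at 0.125.

**Granger causality.** Trials are non-overlapping segments of one long
recording; VAR fits stack lagged regressors across trials (no lag crosses
a boundary) with an intercept, residual covariance pooled with the 1/N
convention. `BIC(p) = log det Σ̂ + log(N)·p·m²/N`; selection defaults to
the argmin, with a plateau rule (smallest order within a configured
fraction of the range above the minimum) behind a flag, because "where the
curve flattens" is otherwise a judgment call. Conditional GC from source to
target given the rest is `log(σ²_reduced/σ²_full)`, clipped at zero; the
analytic check `y_t = 0.9·x_{t−1} + ε` gives `log 1.81 ≈ 0.5933`.
Significance for the graph uses a trial-permutation null — source trials
permuted relative to the target, 500 permutations by default — with
Bonferroni correction across the `m(m−1)` ordered pairs. The permutation
count bounds the smallest attainable p-value at `1/(n_perm+1)`, so
`n_perm` must exceed `n_tests/α` for any edge to survive correction.

**NMF** factorizes the per-timestep binary transistor-state matrix (the
whole-circuit recording) into nonnegative `W` (unit loadings) and `H`
(component time courses), minimizing `‖X − WH‖²_F` by multiplicative
updates from a deterministic NNDSVD initialization with mean filling; the
objective trace is recorded and is non-increasing. `k = 6` by default — a
hand-chosen interpretability setting, exposed as configuration. Components
are interpreted by signed Pearson correlation of `H` rows against the
registry's known signals on the same time grid, and units by their
dominant component. Planted-factor recovery is scored after resolving
permutation ambiguity by exhaustive best matching on absolute
correlations.

**Connectomics.** Six binary relations over transistors — G→C1, G→C2,
C1→C2, C2→C1, C1→G, C2→G — connect devices whose respective terminals
share a wire, with power and ground excluded (they would connect nearly
everything). A Bernoulli SBM with Beta(1,1) priors and one assignment
shared across all six relations is fit by collapsed Gibbs sampling; the
best-posterior assignment across 5 restarted chains is returned (single-
site Gibbs reliably finds the dominant mode only from some
initializations; restarts are the standard remedy). This is a deliberate
simplification of the nonparametric distance-dependent model family: K is
fixed, and spatial decay enters only through an optional logistic
reweighting flag.

## Surrogate generators and what they do and do not emulate

The generators plant known structure: stationary VAR trial sets (stability
enforced via the companion spectral radius), Bernoulli spike trains with
Gaussian tuning `λ(s) = a·exp(−(s−µ)²/2w²) + b` per 100-step window under
a block stimulus (values 0–10 held for 250 steps — persistence is what a
trailing-window rate estimator needs to see tuning), noisy low-rank
nonnegative matrices, and multi-relation SBM graphs. Defaults follow the
validation conditions used throughout: tuning `(a, b, µ, w) =
(8, 1, 5, 1.5)` over 5·10⁴ steps; VAR(3) order selection at `n = 5000`;
the bivariate analytic GC system at 100 trials × 1000 steps; planted
`k = 4` factors on a 60 × 400 grid with noise SD 0.02; three 30-node
blocks with `p_in = 0.6`, `p_out = 0.05`.

Passing on these surrogates demonstrates correctness of the estimators
under their own assumptions — linear Gaussian dynamics, Poisson-like
spiking, exact low rank, exchangeable blocks. Real recordings (and the
circuit itself) violate all of these: circuit activity is deterministic
given the stimulus, binary, and strongly non-Gaussian. That contrast is
the platform's point — the battery can be *correct* and still, as the
report shows, recover only the shallow skeleton (clock, control lines,
block structure) of a system whose function is fully known.

## Problem sizes and determinism

The shipped defaults complete the whole battery in about a minute on one
core: 1024 clock cycles of microfsm simulation (2048 timesteps, ~230
units), 200 random netlists for the oracle cross-check, 20 seeded
repetitions for the stochastic recovery rates, 500-permutation nulls where
a graph is tested and 200 where the report only needs magnitudes. Every
stochastic step takes an explicit seed; `run_report()` derives per-stage
substreams from one global seed so stages can be rerun independently, and
reruns with the same seed produce identical manifest digests. Known
limitations: the simulator is unit-delay (no analog timing), the SBM is
fixed-K, spectral estimates are reported in cycles/timestep without a
physical clock rate, and the lesion screen's "behavior" is whatever
success predicate the registry defines — all inherited simplifications of
the platform, not of the systems it emulates.
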