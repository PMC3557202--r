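---
title: "Three-state asynchronous modeling of the palmitate ER-stress network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state asynchronous modeling of the palmitate ER-stress network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trinet)
```

## The model and its assumptions

`trinet` implements qualitative dynamic modeling for signed interaction
networks under the assumption that the network architecture — not kinetic
parameters — determines the major dynamic features of the system. Every
component holds one of three states relative to the unstimulated control:
0 (below), 1 (control), 2 (above). One time step is one full pass over the
non-clamped nodes in a fresh uniformly random order, with each update
realized immediately within the pass. Randomizing the order encodes that
reaction speeds differ between cells; averaging many randomized runs
emulates a bulk measurement over a heterogeneous population.

### Influence aggregation

The classical single-regulator rules are: an activator above control shifts
its target up; an inhibitor above control shifts it down; when regulators
are inactive the target decays back to control. These rules do not fix what
several simultaneous regulators do, so a combination rule is a genuine
design choice. `trinet` uses the *signed sum of deviations*

$$I_v = \sum_{e:\,u \to v} \mathrm{sign}(e)\,\bigl(S_u(t - d_e) - 1\bigr),$$

thresholded at zero: $I_v>0$ shifts up one level, $I_v<0$ shifts down one
level, $I_v=0$ decays one level toward control. For a lone regulator this
reduces exactly to the classical rules, and it is symmetric around the
control state: an activator *below* control contributes $-1$ (loss of a
positive input is repressive) and an inhibitor below control contributes
$+1$ (de-repression). The symmetric completion matters for knockouts:
clamping a kinase at 0 actively drags its targets below control, which is
what distinguishes silencing one of two redundant kinases from merely
deleting its edge.

Single-level shifts (never jumping 0→2, decay 2→1 rather than 2→0) mirror
the granularity of the shift rules themselves.

### Delays as lagged history reads

Slow processes — transcription, translation, late kinase activation — are
modeled by integer edge delays. While computing step $i$, a delay-$d$ edge
reads the snapshot of its source at step $i-1-d$; lags that reach before
the start of the simulation return the baseline state 1, because cells are
at control before stimulation. Delay-0 edges read the in-pass working
state, so a fast cascade can traverse several nodes within one step when
the update order happens to run downstream.

An alternative encoding — chains of virtual intermediate nodes — was
rejected: virtual nodes would participate in the random update order, so a
favorable order could traverse the whole chain in one step and destroy the
minimum-latency guarantee that a delay is meant to impose. Lagged reads
implement the history-dependent formulation $S_i = f(S_{i-1}, \dots, S_1)$
exactly and deterministically.

### Clamps

Inputs (stimuli), posterior constraints and knockouts are all *clamps*:
nodes held at a fixed level at every step of every run, exempt from the
update rule. A clamped node's incoming edges remain in the graph but have
no effect (clamp supremacy). Knockout = clamp at 0 models siRNA silencing
as sub-control activity while keeping the graph — and thus all influence
sums and delays — well defined. Pathway *deletion* is a different
operation (`delete_edge`) that removes a single interaction; the two give
deliberately different predictions (see the PKA case below).

### The ensemble

A simulation is 5000 independent runs (the default population size used in
all bundled analyses). Each run draws its initial state — ordinary nodes
start at 0 or 2 with probability $p = 0.1$ each, at control otherwise, so
the expected initial state is exactly 1 — and a fresh order permutation
per step. The spread $p$ is a calibration knob, not a measured quantity; it
is chosen small so the population is centered at control yet heterogeneous,
and it is exposed in every scenario file. Per-run random streams derive
from `(master_seed, run_index)` through a counter-based generator
(splitmix64), so ensembles are bit-reproducible and independent of R's
global RNG state. Means and standard deviations accumulate exactly over
the integer states.

## The palmitate model family

The bundled models describe how palmitate (PA, the stimulus, clamped at 2)
drives eIF2α phosphorylation, ATF4 accumulation and CREB1 phosphorylation
in liver cells. The interaction inventory was reconstructed from the
textual description of the network, and the refinement ladder is encoded
so that each version differs from the previous one by auditable edits
(delay edits, one clamp, edge additions or deletions) — the test suite
verifies this structure.

The arms: PA→PACT→PKR→eIF2α and PA→PERK→eIF2α (the two eIF2α kinases);
eIF2α→ATF4 (translational induction, delay 1); ATF4→GADD34→PP1⊣eIF2α (the
phosphatase feedback, transcriptional step at delay 2); PA→PKA→CREB1
directly and PKA⊣PP2A⊣CREB1 indirectly; PA→Ca²⁺→CaM→CREB1; PA→p38→CREB1
and PA→Ras→CREB1; and in the later versions the feedback edges CREB1→ATF4
and ATF4→ATF4 (transcription, delay 2).

**Attenuation pairs.** Each palmitate-responsive kinase arm carries an
activating edge and a delayed inhibitory edge from PA (e.g. PA→PACT at
delay 0, PA⊣PACT at delay 33). The pair is an adaptation motif: the arm is
active only in the window between the two delays, reflecting that
stimulus-induced phosphorylation episodes are self-limiting. This motif is
load-bearing for the whole version story:

* **v1_literature** — every delay is 0 ("all activation steps at similar
  time scales"). Activation and attenuation then cancel exactly, so eIF2α
  and ATF4 show *no* net response while CREB1 (whose Ca²⁺/p38/Ras drives
  carry no attenuation, matching its persistently elevated phosphorylation)
  is sustained. This reproduces the fully flat eIF2α/ATF4 curves of the
  initial literature-model simulation — which a model with sustained
  kinase arms cannot produce, since two active kinases always outvote the
  single PP1 inhibitor under the signed-sum rule. A variant without the
  PACT–PKR arm (`v1_literature_nopkr`) is bundled because the graphical
  source is ambiguous about that arm; both variants behave identically
  here.
* **v2_delays** — measured response-time separations are added: PKR
  responds promptly, PERK 5 steps later, PKA at 35 steps; transcription
  and translation get delays 2 and 1; attenuation at 33 steps. eIF2α now
  rises early and relaxes by step ~35; after the kinase window closes the
  still-active GADD34→PP1 feedback drives eIF2α and then ATF4 *below*
  control at the end of the run.
* **v3_pp1_const** — the posterior observation that PP1 activity does not
  change is encoded by clamping PP1 at 1. ATF4 is no longer pushed below
  control (terminal mean ≈ 1), but nothing sustains it either: it remains
  transient.
* **v4_feedback_creb1 / v4_feedback_atf4** — either CREB1 binding the ATF4
  promoter or ATF4 binding its own promoter (delay-2 transcriptional
  edges) converts ATF4 into a sustained response; both wirings work.
* **v5_essential** — the distilled network: PACT–PKR/PERK, PKA and Ca²⁺
  arms plus the ATF4/CREB1 feedback structure; the direct p38–CREB1 and
  Ras–CREB1 interactions, the PP2A branch and the GADD34–PP1 feedback are
  removed. Dropping PP2A avoids a signed-sum artifact whereby a PKA
  knockout would de-repress PP2A and spuriously cancel the calcium drive,
  contradicting the finding that calcium signaling alone suffices for
  CREB1 activation.

**Delay calibration.** The reporting (never the dynamics) uses
10 steps ≈ 6 h. Onset delays follow the measured order of responses
(PKR prompt, PERK ~3 h later → 5 steps, PKA ~24 h → 35 steps;
transcription/translation 2/1 steps). The attenuation delay of 33 steps is
calibrated so that eIF2α has fully relaxed by step 40 (~24 h), as observed,
while remaining elevated at the 6-h checkpoint. These magnitudes are free
parameters exposed in the model files.

**Knockout predictions.** On the essential model, silencing PKR (clamp 0)
removes the early eIF2α drive *and* actively represses it until PERK
arrives, so early ATF4 collapses; silencing PERK leaves the prompt PKR
drive intact and early ATF4 only dips. At step 5 the ATF4 means order
PKR-KO < PERK-KO < unperturbed with wide margins, and the difference
closes by step ~15 as PERK's contribution matures. The pathway screens
(calcium, PKA, p38, Ras) use `delete_edge`: deleting Ca→CaM leaves CREB1
flat until the late PKA window (not elevated), while deleting the
PKA–CREB1, p38 or Ras arms leaves CREB1 activation intact.

## Trajectory classification

Mean trajectories are classified with a deviation threshold of 0.2 state
units at two checkpoints, step 5 (early, ~3 h) and the final step:
*sustained* (elevated at both), *transient* (elevated early only),
*suppressed* (below 0.8 at the end without early elevation), *unchanged*
otherwise; *elevated* means sustained or transient. The thresholds and
checkpoints are arguments, because the underlying curves are qualitative;
0.2 sits well away from both the Monte-Carlo noise floor at 5000 runs
(≈0.01) and the single-level state resolution (1.0).

## Numerical choices and degenerate inputs

* Exact integer accumulation for means/variances; sample variances are
  clipped at 0 before the square root; an ensemble of one run reports
  standard deviation 0.
* A network whose nodes are all clamped is a fixed point; a horizon below
  1 and an initial state inconsistent with the clamps are errors.
* Uniform permutations come from Fisher–Yates driven by the per-run
  stream; ties never arise because influence is integer-valued and the
  threshold at 0 is part of the rule.
* The canonical file writer sorts nodes and edges, so structural equality
  equals byte equality — used by the round-trip property tests.

## What the simulations do and do not show

The randomness in the model (initial spread, update order) represents
cell-to-cell variability, not molecular noise: there is no stochastic
firing of individual reactions, no graded expression levels beyond three
states, and no resource coupling (e.g. global translational load). Passing
the bundled checks shows that the encoded wiring reproduces the
*qualitative* response classes and orderings; it does not validate rate
constants, absolute fold changes, or any behavior outside the 40-step
(~24 h) window. Wet-lab quantities (blot densitometry, binding ratios,
statistical tests on experimental replicates) are outside the package's
scope. The verification strategy is two-route: the compiled engine is
checked against an independent plain-R enumeration oracle (every initial
state × every order sequence) on networks of up to 3 ordinary nodes and
horizon 3, where exact trajectory distributions are computable; larger
networks are then trusted to the same code paths.

Test problem sizes: the enumeration comparisons use 50,000 runs; the
figure-suite and robustness checks run the bundled scenarios at the full
5000-run, 40-step study size; the dispersion-scaling measurement uses a
one-node network at 50/500/5000 runs with 12 repeats per size, which makes
the log–log slope estimate stable to about ±0.04.
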