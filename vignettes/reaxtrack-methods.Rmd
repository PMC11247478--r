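---
title: "Methods: species, events, pathways and onset from bond-order trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species, events, pathways and onset from bond-order trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reaxtrack)
```

## The problem

A reactive force field such as ReaxFF does not declare bonds; it emits a
continuous bond order per atom pair at every dump step. All chemistry read
from such a trajectory therefore rests on a chain of conventions: when is a
pair bonded, what is a species, when has a bond event *really* happened,
and how are events assembled into a mechanism. This vignette records the
conventions `reaxtrack` uses, why each default was chosen, and what the
package's synthetic validation does and does not demonstrate.

The motivating systems are two modified lignin model compounds under
thermo-oxidation: a monomer (molecule A, C19H30O3, an esterified and
di-tert-butylated phenol) and a dimer (molecule B, C26H34O4, a biphenyl
diol with hydroxypropenyl side chains), each simulated as 50 copies with
300 O2 in a periodic box (3200 and 3800 atoms respectively), dumped every
250 fs (0.25 fs MD step, every 1000 steps) for 1 ns — 4000 frames per run,
with three replicate runs per system.

## Species from bond orders

A pair is bonded when its order is **greater than or equal to** the cutoff;
the closed lower bound makes results reproducible bit for bit at boundary
values. Species are connected components of that graph, computed per frame,
and named by canonical Hill formula (carbon, then hydrogen, then other
elements alphabetically; purely alphabetical with no carbon, so water is
`H2O`). Species identity for counting and ranking is the formula —
structural isomers are not distinguished, which matches how products are
reported in this field — while the exact atom-id set is retained for
lineage tracking.

The operating cutoff (default **0.5**) is selected from a sweep: the count
of distinct formulas over sampled frames (every 10th by default), pooled
per replicate, then averaged. Both tails of the sweep inflate the count —
weak intermolecular contacts below ~0.45 merge molecules at low cutoffs,
and bond-order noise fragments real single bonds at high cutoffs — so the
selector takes the grid argmin, ties broken toward the smaller cutoff.
Chemical plausibility of the surviving species is deliberately left to the
analyst; the selector is purely count-based and can be overridden
everywhere a cutoff is accepted.

## Lifetimes and flicker

An instance (exact atom set) accumulates lifetime as *total occupancy* over
the whole trajectory, not the longest contiguous run: a species that blinks
out for one frame through bond-order vibration and returns is the same atom
set and keeps accumulating. A formula is retained when at least one of its
instances reaches the threshold, default **12.5 ps = 50 frames** at the
250 fs dump interval. The same 50-frame constant reappears as the event
persistence below, so the species view and the bond view agree on what is
"real". The filter is idempotent and monotone in the threshold.

## Bond events

Template bonds carry labels (`1A` = phenolic O–H, `2A` = C–C(=O) ester
alpha bond, `3A` = ester C–O, `4A` = ester O–ethyl; `1B`–`4B` and primed
equivalents on the dimer's two rings). Each label is bound to concrete atom
pairs by element-colored graph isomorphism between the template and each
same-formula component of the reference frame, using BLISS canonical
labeling — deterministic, so the automorphic primed/unprimed assignment in
the symmetric dimer is arbitrary but stable, and reports may aggregate the
label pairs.

Bond states classify at the midpoints of the nominal orders: `absent`
below 0.5, `single` in [0.5, 1.5), `double` at or above 1.5. A state
change is **committed** only when the new state persists 50 consecutive
frames (12.5 ps); shorter excursions are vibration, not reaction. The event
time is the first frame of the new state. New (non-template) bonds are
scanned the same way over watched element pairs, defaulting to C–O and H–O
— the pairs relevant to peroxide and water formation.

## Pathways

For a product instance at the final frame, the tracer records the species
containing each product atom at every frame, and the product's event
sequence is every committed event whose atom pair touches a product atom,
time-ordered. This includes donor events (the phenolic H lost early and
captured later by the peroxide radical). Sequences pooled by product
formula across instances and replicates are summarised as: steps ordered by
median first-occurrence time, each with the fraction of instances
containing it (support), plus all pairwise precedence fractions. When the
precedence majority contradicts the median order — near-simultaneous steps
— the conflict is reported rather than forced into a total order. This
aggregation formalises what is otherwise done by visual inspection, and is
a methodological extension of this package.

## Degradation onset

Along a linear ramp (300 → 3500 K over 800 ps, 4 K/ps — temperatures come
from the schedule, since bond dumps carry no thermostat state), a molecule
is *intact* when some component is graph-isomorphic to the template;
formula-preserving rearrangements do not count. Intact counts vs
temperature are fitted by least squares to a plateau with shifted
exponential decay,

$$N(T) = \begin{cases} N_0 & T \le T_0 \\ N_0\,e^{-(T-T_0)/s} & T > T_0,\end{cases}$$

a purely empirical form whose only purpose is a well-defined read-off: the
reported onset is where the fitted curve equals $N_0 - 1$, i.e.
$T_0 + s\,\ln\!\frac{N_0}{N_0-1}$ — the temperature at which the first
molecule is lost. The objective has a non-smooth knot at $T_0$, so the
minimiser is a deterministic coarse grid over $(T_0, \log s)$ polished by
Nelder–Mead; on noise-free model data this recovers $T_0$ to well under
1 K. Replicate onsets are aggregated as mean ± sample sd; for parameter
recovery the decay curve is fitted jointly to the replicates
(`pool_ramp_series()`), mirroring the practice of fitting one curve to all
ramp runs while quoting the spread of the individual data sets.

## The synthetic generator

`generate_trajectory()` evolves bond orders as step functions at scripted
event frames and logs ground truth (species intervals, committed events,
flicker-merged atom sets) from its own union-find bookkeeping — a code path
deliberately separate from the igraph-based analysis it validates. On top
of the scripted signal it adds:

- **Gaussian bond-order noise**, default sd 0.05 — small enough that the
  0.5/1.5 state thresholds are essentially never crossed spontaneously, the
  regime in which the published bond-order distributions are well separated;
- **flicker bonds** (orders 0.5–0.7, lifetime 1–5 frames) — above the
  cutoff, so they transiently merge species and must be caught by the
  lifetime filter, not by thresholding;
- **weak contacts** (orders 0.15–0.45, same lifetimes) — below the default
  cutoff, felt only by too-low cutoffs in the sweep, emulating the
  van-der-Waals-scale orders a reactive force field reports for close
  non-bonded pairs.

The ramp generator draws per-molecule dissociations with the per-frame
hazard implied by the plateau+exponential survival model, so the fit is
validated against data from its own model family (a self-consistency
check), and a scripted random template bond drops to zero on dissociation.

Mechanism presets script the headline routes onto the packaged templates:
for the monomer, phenolic H loss (`1A`), the CO2 route (`4A` ethyl loss →
`3A` single-to-double → `2A` release of the O=C–O fragment) and the ethyl
hydroperoxide route (`1A` + `4A` → C–O formation with O2 → H–O capture);
for the dimer, phenolic H loss and side-chain OH release recombining to
water (`1B`/`1B'` + `4B`/`4B'` → H–O). The packaged template connectivity
is reconstructed from the compounds' systematic names with valence checks;
labeled-bond placement follows the described chemistry of each route.

**What passing synthetic tests shows — and does not.** The generator
produces step-function kinetics with stationary Gaussian noise and
isolated, scripted reactions. Real reactive-MD output has correlated
noise, gradual bond-order drifts during reactions, recrossings, and
concurrent many-body events. Recovery of the scripted truth therefore
validates the bookkeeping chain (parsing → graphing → filtering → event
commitment → tracing), not the physics; absolute onset temperatures and
product yields of the real systems require running the MD itself and are
out of scope here.

## Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| bond-order cutoff | 0.5 | – | sweep valley; standard choice for hydrocarbon oxidation analyses |
| state thresholds | 0.5, 1.5 | – | midpoints of nominal orders 0/1/2 |
| lifetime threshold | 12.5 | ps | 50 frames at 250 fs; removes cutoff flicker |
| event persistence | 50 | frames | same timescale as the lifetime filter |
| prevalence window | 100 | ps | trailing window for product ranking |
| top-k report | 10 | – | dominant-species overview |
| dump interval | 250 | fs | 0.25 fs step × 1000 steps |
| ramp | 300→3500 at 4 | K, K/ps | 800 ps ramp protocol |
| generator noise sd | 0.05 | – | keeps states separated at the 0.5 cutoff |

## Problem sizes used by the test suite

The suite and the acceptance script validate on reduced systems chosen to
exercise every code path: scenario boxes of ~5–10 molecules over 120–300
frames, full-size (50-copy) boxes for single-frame assembly and mapping
checks, 200 random frames of ≤ 60 atoms against the brute-force
reachability oracle, and onset recovery from the truth count series of
full-length (3200-frame) ramps — with the 3-replicate recovery study
repeated 30 times to estimate the estimator's bias rather than a single
noisy draw.

## Known limitations

- Isomers sharing a formula are one species for counting; only atom-set
  lineage separates them.
- Labeled-bond mapping anchors on the *initial* frame; copies already
  reacted at frame 0 are reported but not labeled.
- The intermediate search pools by formula after lifetime filtering;
  per-instance intermediate lists can be reconstructed from the instance
  table if needed.
- Temperatures along ramps are taken from the nominal schedule, not from
  thermostat output.
- The event persistence rule cannot see reactions that complete and revert
  within 50 frames; that is by construction the same blind spot as the
  lifetime filter, and both move together if the threshold is changed.
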