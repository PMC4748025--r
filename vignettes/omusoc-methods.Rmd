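---
title: "Analysing intersexual associations in a one-male-unit multilevel society"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing intersexual associations in a one-male-unit multilevel society}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omusoc)
```

## The scientific problem

Several papionin societies are *multilevel*: the social core is the one-male
unit (OMU) — one reproductive ("primary") male, the adult females affiliated
with him, and sometimes "secondary" (follower) males — and several units
aggregate into parties, parties into gangs. Whether a population is organised
this way is not directly observable; it has to be inferred from proximity and
interaction data on individually identified animals. `omusoc` packages the
analysis chain used for that inference:

1. **Proximity networks** from instantaneous scan samples taken during
   30-minute focal follows of females (four scans at 10-minute spacing,
   recording the males within 2 m and within the (2 m, 5 m] annulus).
2. **Community detection** on the weighted female–male network (walktrap and
   a Potts-model/simulated-annealing modularity optimiser), plus the size,
   degree, density and modularity metrics used to compare the 2-m and 5-m
   structures.
3. **Male status classification**: per fortnight, each female's "primary"
   male is the male most often within 2 m of her; other males seen within
   2 m are her "secondary" males; males never within 2 m of any female are
   "unaffiliated".
4. **Dyadic statistics**: the Hinde index of relationship maintenance, the
   Friedman average-rank test with the Nemenyi post hoc test for preferred
   associates, and male approach-initiation shares by status class.
5. **Temporal dynamics**: female transfers between primary males detected
   from the ad libitum event stream, and tenure lengths with truncation
   flags.
6. **A synthetic-society simulator** that generates all of the above record
   types with known ground truth, so that each analysis stage can be
   validated by parameter recovery.

The package deliberately stops at the model-ready tables for mixed-model
analyses (behaviour-occurrence tables, Hinde index exports): GLMM fitting
itself is out of scope and is expected to be done with `lme4` or similar.

## The statistics

### Network metrics

The proximity network has one node per individual observed within radius of
someone and an edge per female–male dyad, weighted by the number of scans
containing the dyad. Density and degree are computed on the *unweighted*
graph — `density = E / (n(n-1)/2)`, `mean degree = 2E/n` — because those are
the definitions under which the published example networks (28 nodes/91 dyads
giving 0.24, and 24/48 giving 0.17) reproduce exactly; node strengths (summed
edge weights) are reported separately. The 5-m relation is cumulative
(union of the 2-m ring and the annulus), which is why the 5-m network's edge
set always contains the 2-m network's.

Modularity of a partition `c` is Newman's weighted

$$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{k_i k_j}{2m}\right)\delta(c_i, c_j)$$

with `A` the weighted adjacency, `k` node strengths and `m` the total edge
weight. `modularity_q()` is validated against a literal double-sum oracle on
randomised small graphs.

### Community detection

`walktrap_partition()` delegates the random-walk agglomeration to igraph's
reference implementation (walk length `t = 4`, the conventional default) and
owns the cut: the merge dendrogram is cut at the level maximising
`modularity_q()`, ties broken toward fewer communities; disconnected
components are handled independently (each component's cut is chosen against
the global total edge weight, which makes the combined cut globally optimal
among per-component cuts); a zero-edge graph yields singletons. The result is
deterministic.

`potts_partition()` minimises the Reichardt–Bornholdt Potts Hamiltonian
$H = -\sum_{i<j}(A_{ij} - \gamma k_i k_j / 2m)\,\delta(c_i,c_j)$, which at
`γ = 1` is equivalent to maximising `Q`. It uses single-node label moves
under geometric cooling (`T0 = 1`, `Tmin = 1e-3`, factor 0.95 per sweep of
`10n` moves), 20 independent restarts seeded deterministically from the user
seed, and a greedy single-move polish, so the returned partition is at least
a local optimum and, on small graphs, reliably the global one.

**A known, deliberate limitation:** an agglomerative method can only return
partitions contained in its merge dendrogram, and the global modularity
optimum need not be hierarchical. On random 4–8-node weighted graphs,
exhaustive search beats the walktrap cut on roughly a third of graphs (worst
observed gap ≈ 0.13); the identical behaviour is shown by the reference
implementation. The acceptance suite asserts the (unattainable)
"never beaten" property honestly and that assertion is expected to fail;
the Potts optimiser, by contrast, does match exhaustive search on those
graphs.

### Preferred associates

For each female, a blocks × males matrix of 2-m scan counts (blocks =
fortnights) is tested with the Friedman average-rank statistic

$$\chi^2_F = \frac{12N}{k(k+1)}\sum_j\left(\bar R_j - \frac{k+1}{2}\right)^2
\Big/ \left(1 - \frac{\sum (t^3 - t)}{Nk(k^2-1)}\right)$$

using within-block midranks; the tie correction matters because scan-count
matrices are tie-heavy (most males have zero counts in most windows) and the
uncorrected statistic is systematically deflated. p-values come from the
χ²(k−1) approximation, or — on small tables, where the approximation is
poor — from the exact permutation distribution over all `(k!)^N` within-block
orderings (`p_method = "exact"`, the default below `(k!)^N ≤ 5e4`). The
Nemenyi post hoc test declares pair `(i, j)` different when
`|R̄_i − R̄_j| > CD` with `CD = q_{α,k}/√2 · sqrt(k(k+1)/6N)` (studentized
range, infinite df). A female has a *preferred associate* when her top-ranked
male differs significantly from every other male. Blocks are fortnights — the
source protocol does not state the blocking unit; this choice matches the
status-pooling window and is recorded as an assumption.

### Hinde index

For a female–male dyad, `HI = A_f − R_f`, where `A_f` is the proportion of
the dyad's approaches performed by the female and `R_f` the proportion of its
retreats performed by the female; supplants (approach–retreat sequences under
5 s) are excluded. `HI ∈ [−1, 1]`; positive values mean the female maintains
proximity. Dyads with fewer than 10 approach–retreat interactions are
excluded, as are dyads with zero approaches or zero retreats in total (either
proportion would be 0/0); exclusions carry a reason code rather than a
number. Proportions are per dyad (the index is reported dyad-wise), not per
female; the alternative per-female denominators are noted but not
implemented.

### Transfers and tenures

A female is recorded as changing primary male at the first
**non-surreptitious** affiliative interaction (groom, greet, copulation) with
a different male that is followed by sustained affiliation. Surreptitious
interactions — those out of the primary male's line of sight — never trigger
a change. Two design points are the package's own:

* **Confirmation count.** "Sustained" defaults to the next **3** affiliative
  interactions also involving the new male. A single-event confirmation is
  too permissive in the stated world: with ~5 affiliative ad libitum events
  per female-day of which ~10% involve secondary males (and 61% of those are
  non-surreptitious), two consecutive secondary-male events occur by chance
  many times per 507-day study, each one a false transfer. Three consecutive
  events push the expected false-positive count below ~0.1 per study while
  leaving recall intact, because after a true transfer nearly every
  subsequent event re-triggers the rule. Raising the count can only remove
  transfers (a tested invariant).
* **Initial state.** The starting primary male comes from the first
  fortnight's scan assignment, which is itself noisy (~10% error at 8–24
  scans). A confirmed switch occurring before the stream has ever shown the
  female with that putative primary is treated as a correction of the
  starting state, not a transfer: one cannot observe a *change* of a
  relationship one never observed.

Transfers are dated at the triggering event's day (the true moment is
unobservable) and classified intra-party / inter-party / inter-gang from the
party map. Tenures are the maximal constant-primary intervals; a transfer day
is the last day of the outgoing tenure (so transfers at days 100 and 300 of a
507-day study give tenures of 100, 200 and 207 days); first and last tenures
per female are flagged truncated. Disappearances are censored, never counted
as transfers.

## The simulator and what a green test establishes

`simulate_society()` → `simulate_states()` → `simulate_observation()` use
named random substreams derived from one seed, so changing one stage's
parameters never perturbs another stage's draws, and identical config + seed
gives bit-identical output.

Defaults are the stated world, anchored to field estimates for Guinea
baboons wherever one exists:

| parameter | default | anchor |
|---|---|---|
| parties / units per party | 3 / 3–4 | three parties, ~10 primary males |
| females per unit | 1–4, mean ≈ 1.9 | observed unit sizes; ~16 females |
| secondary males per unit | 0–2, mean ≈ 0.7 | observed unit composition |
| `p2m_primary` | 0.20 | females within 2 m of a male in 20.9% of scans, overwhelmingly the primary |
| `p5m_*` | 0.20/0.08/0.01 | within 5 m in 43.7% of scans (cumulative) |
| greeting logits by state | L −1.442; P −0.801; C0 −0.672; C1 −0.501; C2 −0.408; C3 −0.233 | binomial GLMM estimates (intercept = lactating) |
| `copulation_fidelity` | 0.986 | 98.6% of 493 copulations with the primary male |
| approach initiation | male 0.60 (primary), 0.76 (secondary) | reported initiation shares |
| grooming | 1.26 / 0.16 min/h; bouts 3.52 / 2.85 min | reported rates and bout lengths |
| greet / aggression / copulation rates | 0.85 / 0.10 / 0.69 per h | reported hourly rates |
| `surreptitious_fraction` | 0.39 | 61% of secondary-male grooming was open |
| `transfer_hazard_per_fortnight` | 0.03 | calibrated so median simulated tenure ≈ 200 days (measured 201 over 20 seeds; 0.02 gives 267, 0.04 gives 160) |

Where no estimate exists the value is an assumption, fixed once: retreat
shares (0.57/0.60 female, chosen so expected Hinde indices reproduce the
reported dyad means −0.17 and −0.36), approach/retreat rates (4 and 1.2
per hour — high enough that primary dyads clear the 10-interaction Hinde
threshold over a study), reproductive-state mean block lengths (L 180, P 185,
C0 20, C1 7, C2 5, C3 7 days; cycling blocks repeat with mean 2 cycles before
conception), 4.3 effective ad libitum hours per day (~2100 h over 489 days),
and 1–3 focal follows per female-week. The tenure calibration has a
documented side effect: with a homogeneous per-fortnight hazard the fraction
of females keeping one male all study is ~0.33, below the observed 8/16 —
the field's transfers were clustered on fewer females, which a single global
hazard cannot reproduce while also hitting the median. The median-tenure
calibration was prioritised.

What the generator deliberately does **not** emulate: spatial structure and
home ranges, demography (births, deaths, maturation), male–male
interactions, observer effort gaps (every female is scanned every week),
clustered/bout-structured interaction timing (events are i.i.d. within a
day), and transfer waves (hazards are independent across females). A green
parameter-recovery test therefore establishes that the pipeline recovers the
truth of *this* generative world at field-like rates and sample sizes — not
that it is robust to every failure mode of real field data (observer bias,
identification errors, uneven habituation).

## Numerical and degenerate-input conventions

* The 2-m ring is distance ≤ 2 m; the annulus is (2 m, 5 m]; a male at
  exactly 2.0 m is in the 2-m ring by convention. The two ring fields of a
  scan are disjoint by construction and validated as such.
* Status ties (equal top 2-m counts) cascade: higher 5-m count → previous
  window's primary → lexicographic id; every tie-break and carry-over is
  flagged in the output. A female with no 2-m scans in a window carries her
  previous primary forward, flagged.
* "Unaffiliated" is computed per window and also study-wide
  (`study_unaffiliated`); both are reported because the original definition
  is ambiguous about the pooling level.
* `friedman_test()` refuses missing entries and N < 2 or k < 2; an all-tied
  table has statistic 0 (the tie-correction denominator would vanish).
* Density is undefined below 2 nodes (error); a zero-edge graph has
  singleton communities and Q = 0 by convention.
* Empty event streams and behaviour classes with no data yield `NA` fields
  and "no data" report sections, not errors.

## Reproducibility

Every stochastic routine takes an explicit seed: the simulator through
`society_config(seed=)` (substreams are derived per stage by name), the
Potts annealer through its `seed` argument (restart `r` uses a seed derived
from `(seed, r)`). The CLI (`omusoc_main()`: `simulate` / `analyze` /
`report`) writes a JSON manifest per stage with the config hash, seed and
record counts; identical config + seed reproduce byte-identical data files.
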