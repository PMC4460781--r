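---
title: "Chaining non-branching RNA structures: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaining non-branching RNA structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsmotif)
```

## The problem and the model

Two RNAs that act through their structure may share a *motif
architecture*: the same succession of stem-loops at similar spacings, even
when their sequences have diverged beyond alignability. `nbsmotif`
formalizes this search in three layers.

**Non-branching structures.** A predicted local secondary structure is cut
into non-branching structures (NBSs): maximal substructures containing
exactly one hairpin loop. From each hairpin, the stem is extended outward
through stacked pairs, bulges and internal loops; extension stops at a
multiloop (a loop with two or more child helices) or at the unpaired
exterior. Helices that merely close multiloops belong to no NBS: without a
hairpin of their own they have no stem-loop shape of the kind the search
targets. An NBS always starts and ends on a paired position.

**The descriptor.** Each NBS, paired with its reference subsequence,
forms an RNA sequence-structure pattern (RSSP); the ordered list of RSSPs
is the secondary structure descriptor (SSD). RNA, and long non-coding RNA
in particular, is not expected to hold one unique fold, so the SSD comes
in two flavors: `S1` keeps a single non-overlapping set of NBSs (a unique
prediction of the reference structure), while `Sk` keeps every distinct
NBS, overlapping alternatives included.

**Matching and chaining.** A pattern *matches* a target window when every
paired position maps to an allowed pair — AU, UA, CG, GC, GU, UG; unpaired
positions are unconstrained, because loops tolerate substitutions and the
object of the search is the structure, not the sequence. Matches are then
chained under two conditions: strictly increasing NBS indices, and
non-overlapping, increasing target intervals. A chain scores

$$\mathrm{sc}(C) = \sum_{i=1}^{n} P(m_i) + \sum_{i=1}^{n-1} Q(m_i, m_{i+1})$$

with $P(m) = w_p\,\mathrm{len}(m)$ (a match's individual relevance is its
number of bases) and, for consecutive matches of NBS indices $g < f$,

$$Q = \frac{w_q}{d(f,g)}\; e^{-\delta/\lambda},\qquad
\delta = \frac{|\,\mathrm{gap}_T - \mathrm{gap}_R\,|}{\max(\mathrm{gap}_R, \mathrm{gap}_T, 1)}$$

so that $Q$ is maximal when the target reproduces the reference spacing
between two structurally adjacent NBSs, and is damped both by spacing
discrepancy and by the structural distance $d(f,g)$: one plus the maximum
number of mutually non-overlapping NBSs lying strictly between $s_g$ and
$s_f$. In an `S1` descriptor $d(f,g) = f-g$ exactly. The published form of
this score function states only the qualitative dependencies of $P$ and
$Q$ (match size; positional consistency damped by $d$); the algebraic
forms above, including the exponential decay and the normalization of
$\delta$, are this package's own concrete instantiation, chosen to be
deterministic, dimensionless, bounded in $(0, w_q]$, and monotone in
spacing consistency. Scores produced by other implementations of the same
scheme are therefore not directly comparable number-for-number.

The best chain ending at each match is computed by dynamic programming
with an optimal-substructure recurrence; the `max(0, ...)` floor lets a
chain start fresh at any match, which is never suboptimal under
non-negative $P$ and $Q$ but keeps the recurrence safe should a user
supply negative weights. Traceback ties resolve to the smallest
predecessor index, and ranked chains tie-break by earlier first target
position then shorter span, so results are deterministic.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `w_p` | 1 | per nt | weight of each matched base in $P$ |
| `w_q` | 1 | unitless | ceiling of each pairwise term $Q$ |
| `lambda` | 0.5 | unitless | decay of $Q$ in the normalized gap discrepancy $\delta \in [0,1]$; at the default, a fully inconsistent spacing retains $e^{-2} \approx 14\%$ of $w_q$ |
| `tau` | 0.5 | unitless | fold-propensity filter threshold; an all-GU stem scores 1/3, an all-GC stem 1 |
| `min_identity` | 0 | fraction | optional sequence-identity requirement; 0 means pure structure matching, the method's default philosophy |
| `top_k` | 10 | count | chains reported |
| `min_pairs`, `min_len` | 2, 6 nt | | minimum NBS size; single-pair stems match almost everywhere and drown the chainer |
| `d_method` | `"greedy"` | | distance algorithm, see below |

The fold-propensity filter `PS = (3·n_GC + 2·n_AU + n_GU)/(3·n_pairs)` is
a declared surrogate for a thermodynamic refolding probability: it is
deterministic, dependency-free and monotone in pair strength. A
thermodynamic engine can replace it through the `engine` hook of
`filter_matches()` under the same `≥ tau` contract.

## The distance algorithm

`distance_d()` implements the iterative scheme: starting from the anchor
$l = f$, repeatedly select the *largest* index $k$ with $g < k < f$ whose
interval fits to the left of $s_l$ and to the right of $s_g$, then anchor
on it. The count of selected indices plus one is $d(f,g)$. The greedy
max-index pick is not guaranteed to realize the true maximum number of
mutually non-overlapping intermediates when intervals have heterogeneous
lengths, so an `"exact"` variant (classic earliest-end interval
scheduling) is provided; the greedy value never exceeds the exact one, and
the test suite measures how often the two diverge on random overlapping
descriptors (rarely; they coincide on all non-overlapping ones). The
greedy form is the default because it is the published algorithm. A
related reading question: the printed selection condition compares
$\mathrm{pos}(s_k)$ against $\mathrm{pos}(s_l)$ without a length term,
which would let $s_k$ overlap the current anchor; this package uses
$\mathrm{pos}(s_k) + \mathrm{len}(s_k) \le \mathrm{pos}(s_l)$, the
non-overlap reading consistent with the distance's own definition.

Cost accounting follows the method's complexity analysis: the DP calls
$Q$ once per order-compatible pair — exactly $n(n-1)/2$ calls when all $n$
matches are mutually compatible — and in `Sk` mode each call pays a
distance scan of $f-g$ steps, summing to $n(n^2-1)/6$, i.e. $O(n^3)$;
in `S1` mode the closed form makes each call constant-time, $O(n^2)$
overall. Both counters (`q_call_count()`, `d_step_count()`) are exposed
on every `chain_result` and asserted against these identities in the
tests.

## Coordinates and numeric conventions

Positions are 1-based inclusive throughout, matching both R's indexing
and the 1-based starts of local-folding output; an interval is disjoint
from a later one iff `start + length <= start'`, so every formula above is
unchanged. Chain scores are re-evaluated independently after traceback and
must agree with the DP value within 1e-9 (they agree exactly in practice;
the DP and the re-evaluation share $P$/$Q$ but group additions
differently). Dot-bracket parsing rejects pseudoknots (crossing pairs are
unrepresentable in the single-bracket alphabet) and `N` never pairs. DNA
input is silently normalized (`T` to `U`).

Degenerate cases: an empty SSD or an empty match set yields an empty chain
list with best score 0; in `significance()`, a null distribution with zero
standard deviation yields a z-score of `Inf` when the observed score
exceeds the null mean and 0 otherwise; the empirical p-value uses the
$(1 + \#\{null \ge obs\})/(N+1)$ correction so 0 is never reported — at
1000 shuffles the smallest attainable p is $\approx 0.001$, the package's
rendering of "p ≈ 0".

## What the synthetic generator emulates

`plant_reference_and_target()` builds a reference carrying `k` hairpins at
regular spacings in random background, one folding window per hairpin, and
a target carrying pairing-compatible copies in the same order — unpaired
positions mutated at `mutation_rate`, gaps jittered by up to `jitter` nt.
This emulates the situation the method is designed for: a conserved
*architecture* of stem-loops whose sequences drift. Defaults are fixed
study conditions, not tuning knobs: stems of 8 pairs with 4-nt loops
(well-determined helices of realistic depth, specific enough that a random
300-nt background matches a pattern with probability of order
$(6/16)^8 \cdot L \approx 0.1$), GC-enriched pair composition
(GC : AU : GU = 2 : 1 : 0.25, typical of stable helices and comfortably
above the `tau` filter), uniform ACGU background with a GC-content knob,
motif spacing 20 nt, and per-motif window energies proportional to stem
size.

What the generator deliberately does **not** emulate: thermodynamically
realistic decoy structure in the background, folding-prediction errors
(planted windows are exact), pseudoknots, and compositional biases of real
transcripts. Passing the recovery and ranking simulations therefore
demonstrates the correctness and discriminative behavior of the decompose
→ match → filter → chain machinery under its stated model, not the
field accuracy of any particular folding engine on real lncRNAs.

Two simulation-design notes. First, recovery under noise is insensitive to
`mutation_rate` by construction — only unpaired positions are mutated, and
matching constrains only paired positions — so the noisy-recovery
simulations primarily stress spacing jitter and background confusion.
Second, the significance *calibration* runs (pure background as target)
use shallower 4-pair stems: with highly specific 8-pair patterns, a random
background and all of its shuffles usually score exactly 0, the null is a
point mass, and the empirical p-value is pinned at 1 rather than uniform;
calibration needs score variability under the null, which weaker patterns
provide. This is a property of permutation tests on discrete score
distributions, not of this method in particular.

## Problem sizes used in the packaged simulations

The packaged tests run the DP-vs-enumeration comparison on 200 random
instances of up to 12 matches (exhaustive enumeration beyond that is
pointless), self-recovery on 50 synthetic references, noisy recovery on
100 planted pairs (k = 10, jitter 5, mutation 0.1), significance at 200
shuffles for the planted case and 50 × 49 shuffles for calibration, and
ranking with 30 family members against 300 decoys of ~220 nt. These sizes
give stable pass/fail behavior at desk scale; the implementation itself
has no hard-coded limits and the chaining cost is governed by the match
count as analyzed above.

## Known limitations

- The matcher is a plain scan, $O(|SSD| \cdot |T| \cdot \text{pairs})$;
  it is entirely adequate for transcripts and small databases but makes no
  attempt at index structures for genome-scale search.
- Structure-only matching is permissive for shallow stems; specificity is
  governed by stem depth, `tau`, and the chain requirement itself (single
  spurious matches score low without consistent neighbors).
- Pseudoknots are rejected, not modeled.
- Alternative (`Sk`) descriptors can place overlapping reference NBSs in
  one chain when their target intervals are disjoint; only condition (ii)
  constrains target geometry, which is intended — alternatives represent
  mutually exclusive reference folds whose motifs may still co-occur in a
  target.
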