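---
title: "Methods: junction calling, repair classification and resection quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction calling, repair classification and resection quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchjoin)
```

This vignette records the methodological choices behind `switchjoin`: the
split-alignment objective, how microhomology is defined and annotated, the
tie-break convention, what the synthetic-data generator guarantees, and the
statistical conventions. It is the place to look when a number produced by
the package needs to be traced back to a definition.

## 1. The junction-calling objective

A class switch recombination junction read is, up to noise, a donor-region
prefix followed by an optional untemplated insertion followed by an
acceptor-region suffix. The caller searches over

* a donor alignment diagonal and an acceptor alignment diagonal (offsets of
  the read against each reference), and
* a breakpoint pair $b_1 \le b_2$ in read coordinates,

and scores

$$ S = \mathrm{score}(\text{read}[1..b_1] \mid \text{donor}) +
       \mathrm{score}(\text{read}[b_2{+}1..L] \mid \text{acceptor}), $$

with +1 per matching base and −3 per mismatching base. The gap
$\text{read}[b_1{+}1..b_2]$ is the insertion and is **unscored**. Every
read base is therefore scored at most once. This single-count design is
deliberate: if overlapping bases were scored against both references, a
microhomology bonus could exactly cancel a mismatch penalty, creating
score ties between the true junction and spurious nearby 4-mers that
happen to match both references. Under the single-count objective, on a
noise-free read only all-match splits can tie all-match splits.

The −3 mismatch penalty makes one mismatch more expensive than three
unscored (insertion) bases, so the caller prefers declaring a short
insertion over forcing noisy bases onto a reference, while still absorbing
isolated point mutations into long anchors (an anchor base is worth +1,
and a read with a 1% mutation rate keeps per-anchor identity far above the
0.9 acceptance threshold).

### Microhomology annotation

Microhomology (MH) is a property of an optimal split, annotated after
optimisation. At a junction with $b_1 = b_2 = b$, extend forward along the
donor while read bases continue to match it ($h$ bases) and backward along
the acceptor while read bases continue to match it ($g$ bases). The MH is
the $g + h$ bases that match *both* references; the reported donor end is
$b + h$ and the acceptor start $b - g + 1$ (read coordinates; reference
coordinates add the respective diagonal offset). Every breakpoint inside
an MH tract yields the same score and the same annotation, which is what
makes the MH length well defined. A consequence of this classical
definition is that the reported MH segment always matches both references
exactly — a property the test suite asserts on whole cohorts.

### Tie-breaks and ambiguity

Distinct optimal splits are first deduplicated by their annotation
(donor end, acceptor start, MH length, insertion). Survivors are ordered
by larger MH, then shorter insertion, then smallest donor reference end.
If the survivors of that ordering still disagree on the insertion
*content*, the read is reported `ambiguous` rather than called — the
caller never guesses between biologically different events. Reads whose
best split fails the anchor-length (default 20 nt each side) or
anchor-identity (default 0.9) requirements are retried as reverse
complements and otherwise reported `unalignable`.

### Search strategy

The default mode seeds candidate diagonals with exact k-mers (the
`max_diagonals` most supported diagonals per side, k-mer sampling stride
`seed_stride`) and then optimises exactly over the seeded diagonal pairs
using prefix-maximum arrays, so for every diagonal pair the optimal
$b_1 \le b_2$ is found in $O(L)$. `junction_opts(exhaustive = TRUE)`
scores *all* diagonal pairs, which is what the test-suite oracle
comparisons use on small instances. On repetitive switch-like references
the true diagonal is k-mer supported along the whole anchor, so seeding is
not a heuristic compromise at the read lengths used here; the oracle
agreement and round-trip tests back that up empirically.

## 2. What the generator guarantees

Acceptance in this package is parameter recovery, which requires exact
planted truth. The cohort generator therefore engineers, rather than
samples, the properties the caller is tested on:

* **Blunt and short-MH junctions** are produced by rejection: a candidate
  (donor cut, acceptor cut) pair is accepted only when the exact MH flank
  equals the requested length — including the bases *just outside* the
  flank differing, so a planted `mh = k` cannot silently be `k + 1`.
* **Long-MH junctions** are engineered by editing the donor so that a copy
  of the acceptor-side flank sits at the junction, with stop bases placed
  so the MH cannot extend. Edits are confined to disjoint donor windows,
  and the edited donor is returned as part of the simulation output —
  downstream calling must use it. A donor of length $\ell$ hosts roughly
  $(\ell - d_{\min})/12$ such windows, so large cohorts need longer
  references (the workflow uses 8–16 kb; the generator raises a "donor too
  crowded" error rather than degrading truth).
* **Insertions** are required to be non-absorbable: no prefix or suffix of
  the insertion may extend either anchor, so the planted insertion is the
  annotated insertion.
* **ECS insertions** are verbatim (or reverse-complement) decoy-genome
  segments of >30 nt with recorded contig, coordinates and strand.
* **Mutations** are placed in a halo around the junction but outside a
  protected exact zone, so noise never rewrites the planted signature;
  duplicated reads are verbatim copies under new identifiers with their
  source recorded.

## 3. Classification and statistics conventions

* Pathway rule: MH ≤ 3 nt and no insertion → C-NHEJ; MH ≥ 4 nt or any
  insertion → A-EJ. Insertions > 30 nt form the `ins_long` class in which
  ECS is sought by seed-and-extend against a genome k-mer index (coverage
  and identity thresholds of 0.9 each, both strands).
* Unique junctions: reads collapse when they share
  (donor end, acceptor start, MH length, insertion) — PCR clones differing
  only by distal point mutations share this signature.
* The two-tailed Fisher test uses the point-probability convention (sum of
  all tables with the observed margins whose probability is at most the
  observed one, within a 1e-12 relative tolerance), matching standard
  exact-test implementations; per-category comparisons report raw and
  Bonferroni-adjusted p-values.
* MH spectra are binned per length 0–9 with ≥10 grouped; the three-way
  partition (MH 0–3 / MH ≥4 / insertion) is the pathway-facing coarsening.

## 4. Resection and expression calculi

The restriction-protection assay digests double-stranded DNA; resected
(single-stranded) template survives and amplifies earlier. With
$\Delta C_t = C_t^{\text{digested}} - C_t^{\text{mock}}$,

$$ \text{ssDNA\%} = \frac{1}{2^{\Delta C_t - 1} + 0.5} \times 100, $$

which is 100 at $\Delta C_t = 0$ and strictly decreasing. The generator
uses the exact inverse $\Delta C_t(f) = \log_2(1/f - 0.5) + 1$ (capped at
15 cycles, flagged), so noiseless panels round-trip to 1e-9 and noisy
recovery bounds are meaningful. Negative $\Delta C_t$ is clamped to zero
with a QC flag: near full protection it is measurement noise, not an
error. Replicates are averaged arithmetically before $\Delta C_t$;
amplification efficiency is fixed at 2 as in the printed formulas.
Relative expression uses $2^{-\Delta\Delta C_q}$ and ChIP enrichment uses
$100 \cdot 2^{(C_q^{\text{input}} - \log_2(1/\text{input fraction}) -
C_q^{\text{IP}})}$; both are invariant to adding a constant to every
$C_q$.

## 5. Problem sizes

Test and workflow problem sizes were chosen for single-CPU runtimes, not
tuned to outcomes: cohorts of 100–2,000 junctions, reads of 200–450 nt,
references of 2–16 kb (longer when many engineered long-MH junctions must
fit), and the seeded search (`max_diagonals = 6`, `seed_stride = 4`) for
the 200-replicate discrimination experiments. Accuracy at these settings
is pinned by the acceptance tests (oracle equivalence, 100% noise-free
round trips), so the size choices affect wall-clock time only.
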