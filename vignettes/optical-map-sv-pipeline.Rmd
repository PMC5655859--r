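---
title: "Optical genome map simulation, assembly and SV calling with omsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical genome map simulation, assembly and SV calling with omsv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omsv)
```

## The method

Optical genome mapping images megabase-size double-stranded DNA molecules
whose nick sites — occurrences of a nicking-endonuclease motif such as
Nt.BspQI `GCTCTTC` or Nb.BssSI `CACGAG` — carry fluorescent labels. Each
molecule is therefore an ordered list of label positions along a measured
backbone. Because the molecules are hundreds of kilobases long, large
structural variants (deletions, insertions, inversions, translocations)
that defeat short-read sequencing are directly visible as label-pattern
differences against a reference map.

`omsv` implements this measurement chain end to end at desk scale:

1. **Reference maps** — in-silico digestion of sequence
   (`digest_reference()`, via Biostrings IUPAC matching) or direct
   stochastic placement of labels by a homogeneous Poisson process
   (`poisson_reference()`). Structural variants are planted with exact
   ground truth by `apply_sv_to_map()`.
2. **Molecule simulation** — `simulate_run()` draws log-normal molecule
   lengths, places them uniformly over haplotype copies, and observes each
   through a parametric error model (below).
3. **De novo assembly** — `run_assembly()` is an Overlap-Layout-Consensus
   pipeline with the platform's staged P-value cutoffs: pairwise overlap
   graph, spanning-tree layout with progressive consensus, Refine-B
   (P < 1e-11) with chimeric-join removal, five extend-and-merge rounds
   (Extension P < 1e-11, Merge P < 1e-15), extend-and-split re-assembly of
   molecules with > 30 kb end alignment gaps, and a final refinement
   (P < 1e-11) that converts maps with < 50 kb internal alignment gaps into
   two haplotype maps.
4. **SV calling** — `call_svs()` aligns each consensus to the reference
   (alignment cutoff P < 1e-12), splits non-contiguous alignments into
   segments, tests span discrepancies between adjacent matched labels
   two-sided against the sizing model (outlier P < 3e-3), and classifies
   junction geometry: opposite orientations on one chromosome = inversion,
   different chromosomes = inter-chromosomal translocation, same-strand
   reference gaps over 5 Mbp = intra-chromosomal translocation, smaller
   gaps = indels sized by label-interval arithmetic. Signs follow the
   gain/loss convention (deletions negative).
5. **Cohort validation** — `build_cohort()` recreates an eleven-sample
   X-linked dystrophinopathy case series (six hemizygous deletions of
   45,839–250,092 bp, a heterozygous 249,994-bp carrier mother, a
   non-carrier mother, a 12,968/12,857-bp duplication-insertion duo, and a
   hemizygous 5.1-Mbp inversion run with two enzyme channels) on synthetic
   references, and `score_concordance()` checks type, size (±5 %) and
   zygosity against planted truth with no extra calls allowed.

## The alignment kernel and its P-values

Two label maps are aligned by dynamic programming over matched label pairs
(`align_maps()`, C++ kernel). The score of a matching is

    sum over matched pairs [ match_bonus - r^2 / (2 sigma^2(L)) ]
      - miss_penalty  * (skipped reference labels)
      - false_penalty * (skipped query labels)

with `r` the difference between the query and reference interval lengths
between consecutive matches and `sigma^2(L) = sd0^2 + sd_scale * L` the
sizing variance of a reference interval of length `L`. Defaults:
match 3.0, miss 1.0, false 1.0, lookback `max_skip` 5, `sd0` 100 bp,
`sd_scale` 12 bp²/bp (matching the simulator). The alignment is local on
both ends, so molecule overhangs are free; tie-breaks prefer more matched
pairs and are otherwise resolved by the fixed scan order, making results
deterministic.

P-values are empirical: `fit_null()` aligns interval-shuffled windows of
the reference back to it, fits a Gumbel location/scale per query-label-count
bucket, and smooths both linearly in label count so the far tail
extrapolates stably. The staged cutoffs quoted above are bound verbatim to
this empirical scale; that correspondence to the vendor's internal scale is
approximate by construction, and `assembly_params(p_scale = ...)` rescales
every stage cutoff at once if recalibration is wanted. Two consequences are
documented rather than hidden: (i) a pairwise molecule overlap needs about
120 kb of clean shared labels to pass the (paper-unstated) pairwise default
of 1e-8, and molecules below roughly 180 kb do not reach the Refine-B
1e-11 cutoff, which emulates realistic molecule-to-reference map rates of
55–85 %; (ii) short split-off alignment segments (10–20 labels, the flanks
of nascent allele maps) cannot reach 1e-12, so the strict cutoff is applied
to the primary anchoring of each map and a secondary cutoff
(`sv_params(secondary_p = 1e-6)`) to the realigned remainder — junctions
classified as inversions or translocations still require both segments to
pass 1e-12.

## The molecule error model

`error_model()` parameterizes the observation chain, applied in this
order: fragile-site truncation, label miss, interval sizing jitter, false
labels, optical resolution merging, chimera formation.

| parameter | default | meaning |
|---|---|---|
| `sizing_sd0` | 100 bp | baseline interval noise SD |
| `sizing_sd_scale` | 12 bp²/bp | linear variance growth with interval length |
| `label_miss_rate` | 0.10 | probability a true nick is unlabeled |
| `false_label_rate` | 0.8 / 100 kb | spurious labels along the backbone |
| `fragile_break_prob` | 0.5 | break probability at opposite-strand nick pairs closer than `fragile_window` (1 kb) |
| `chimera_rate` | 0.01 | artifactual junction of two unrelated fragments |
| `resolution_limit` | 1500 bp | labels closer than this merge into one |

None of these rates are quantified in the platform literature; the values
are chosen once as a realistic operating point (sizing error ~2–5 % of an
interval, miss and false rates in the range reported for nanochannel
instruments) and are the fixed study conditions for all shipped tests.
Molecule lengths default to log-normal with 250 kb mean and a 150 kb
minimum-length filter; per-molecule seed substreams make molecule *k*
identical regardless of batch size. Fragile sites exist only on
sequence-derived references (opposite-strand motif hits closer than the
window); the Poisson cohort references carry none, so fragile breakage is
exercised in unit tests rather than in the cohort.

What the generator deliberately does not emulate: image-level artifacts,
per-label intensity/SNR, inhomogeneous label density of real genomes,
segmental duplications and other repeat structure, and reference errors.
Passing the cohort therefore demonstrates the pipeline's logic under a
clean parametric error model, not performance on real chips.

## Numerical and design choices

* **Progressive consensus.** The overlap-graph layout propagates
  orientation and offset along a maximum-weight spanning tree, but offsets
  drift with accumulated sizing noise, so the consensus is built
  progressively: molecules (in layout order, with retry passes for
  stranded ones) are aligned to the growing consensus; matched labels
  reinforce sites, unmatched labels seed new ones through piecewise
  projection between matched anchors. Growth beyond the anchored span is
  only trusted for strongly anchored alignments (≥ 12 pairs over ≥ 60 kb),
  and alignment targets exclude stale support-1 sites, both of which stop
  junk accumulation at the growth frontier. If a run stalls, the stranded
  molecules seed further maps that the merge rounds reunite.
* **Refinement.** Site positions are re-estimated from the mean measured
  spans between matched sites, distributed proportionally across skipped
  sites; site support below `max(3, 0.35 × local molecule coverage)` is
  dropped (false-label clusters sit far below this, real sites at ~0.9 of
  coverage well above); sites closer than ~1 kb merge. Refine-B runs the
  refit twice, and the final refinement reassigns every molecule to its
  best-fitting map so allele maps de-mix their parents.
* **Chimera removal.** A mis-joined map has almost no molecules whose
  matched span crosses the junction, so maps are split where
  spanning-molecule coverage falls below 30 % of the map median — a
  signature that resolution-limit artifacts (which dip site support but
  not spanning coverage) cannot trigger.
* **Extend-and-split.** End-gap molecules (> 30 kb unaligned) and
  molecules that align nowhere are pooled and re-assembled with
  overlap-graph edges required to explain the molecules' full overlap
  (agreement ≥ 0.7), which keeps cross-allele molecule pairs disconnected.
  Two pool/re-assemble rounds are used: the first can still mix an allele
  cluster with unrelated end-gap molecules, and the second isolates it
  once the first round's maps have absorbed the rest. Allele maps never
  merge back into the primary maps they diverged from.
* **Haplotype conversion.** Per consensus interval, molecule span
  residuals are split by exact 1-D two-means; a split is accepted when the
  separation exceeds 3 within-cluster SDs, an absolute floor
  (max of 3 kb and 5 sizing SDs), is below the 50-kb internal-gap rule,
  and both clusters have ≥ 3 molecules with a genuine mode gap. With the
  default scoring, wild-type molecules do not align across a ≥ 10 kb
  insertion (the bridge penalty exceeds the gain), so such events route
  through extend-and-split and appear as two allele maps covering the
  locus; the interval-residual detector handles smaller allelic
  differences and is exercised on constructed fixtures.
* **Segment tension.** A local alignment can absorb a large indel as a
  chain of small skips. When the cumulative query-vs-reference drift
  within one segment exceeds `drift_tol_bp` (9 kb — far above the ~2–3 kb
  random-walk drift of a 40x consensus, far below the smallest cohort
  event of 12.9 kb), the query is split at the largest drift step and both
  halves realigned; junction arithmetic then sizes the event exactly at
  zero noise.
* **Breakpoint-uncertainty intervals.** The breakpoint lies beyond the
  last matched reference label toward the event, no further than the
  unexplained query span across the junction, and no further than the
  next reference label that is resolvable (beyond the 1.5-kb optical
  resolution of the anchor — a closer unmatched label may be merged, not
  absent). Dual-enzyme calls intersect the two channels' intervals; when
  the channels disagree (disjoint intervals) one junction is corrupted, and
  mixing sides across channels would pair a good anchor with a bad one, so
  both breakpoints are kept from the channel with the smaller total
  uncertainty, flagged. Junction sizes use the nearest-anchor span
  difference when it agrees with a 5x5 anchor-combination median (exact at
  zero noise), and the robust median otherwise; segment edges are trimmed
  of offset-step outliers before anchoring. Calls smaller than
  `min_size_bp` (8 kb, about 1.3 label intervals at the default spacing)
  are suppressed as below the label-density resolution floor, and every
  indel or junction call must be crossed by at least
  `min_junction_support` (4) of the supporting map's own molecules.
* **Zygosity.** On haploid contigs every call is hemizygous. On diploid
  contigs a call is heterozygous when a non-supporting map covers the
  event concordantly — for large deletions, when such maps cover ≥ 50 % of
  the deleted interior, since the wild-type allele is often assembled as
  two maps cut near the junction — homozygous when only variant maps
  cover the locus, and unknown without covering maps.

## Problem sizes and expected behavior

The shipped tests and the acceptance script run the cohort at 3-Mb regions
(8 Mb for the inversion family) with mean label spacing 6 kb per channel
and default noise; haploid probands are simulated at 40x raw coverage and
diploid mothers at 60x — the published runs put substantially deeper
coverage (80-158x effective) on the mothers, whose allelic evidence is
split between two haplotypes. A full cohort pass takes some minutes on
one CPU. On these conditions the pipeline recovers every planted event
with the correct type and zygosity, sizes within a fraction of a percent
at default noise and exactly at zero noise, single-enzyme
breakpoint-uncertainty medians under 10 kb, and the 5.1-Mb inversion
breakpoints within 7 kb using two channels.

One geometric limitation is worth stating precisely. With labels placed by
a Poisson process of mean spacing `s` per channel, the interval containing
an independently placed breakpoint is length-biased: its width is the sum
of a backward and a forward exponential. Bounding it additionally by the
unexplained query span gives a single-channel width of
`U + min(V, W)` (mean `1.5 s`, median ≈ `1.23 s` ≈ 7.4 kb at `s` = 6 kb),
and intersecting two independent channels gives
`min(U1, U2) + min(V1, W1, V2, W2)` (mean `0.75 s`, median ≈ 3.6 kb).
A 3-kb dual-channel median is therefore right at — slightly beyond — what
6-kb-per-channel label density can deliver, and the dual-enzyme
resolution check should be read with that geometry in mind; real enzyme
pairs reach 1.5–3 kb because their combined site density is higher than
two 6-kb channels.

## Limitations

Desk-scale only: all-vs-all overlap search and genome-wide realignment are
quadratic and tuned for ≤ 10 Mb regions, not whole human genomes. The
empirical P scale is not the vendor's. Duplicated-source identification
for insertions is not attempted (gain-of-material events are called
insertions, as on the platform). Known-SV filtering is a mechanical
reciprocal-overlap check against a user catalog, with no population
frequencies.
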