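---
title: "Methods: strength-stratified connectomics of clock neuron networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strength-stratified connectomics of clock neuron networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clocknet)
```

# The analysis model

`clocknet` analyses dense-connectome edge lists in which a directed
connection between two neurons carries an integer weight: the number of
postsynaptic densities (PSDs) on the postsynaptic cell contacted by the
presynaptic cell's T-bars. Because single T-bars are polyadic in the fly
brain, the PSD count is the natural unit for both the input and the
output side of a connection, and all totals in this package are raw PSD
counts.

Three modelling commitments underlie everything downstream:

1. **Strength stratification.** A connection is *weak* when its total
   weight is below `medium_min` (default 3), *medium* up to
   `strong_min - 1`, and *strong* from `strong_min` (default 10) upward.
   One- and two-synapse contacts are treated as potentially spurious at
   EM reconstruction scale, which is why most analyses default to the
   medium+strong (weight ≥ 3) or strong (weight ≥ 10) restriction.
   Classification is always applied to the total weight of a pair, never
   to its per-ROI components — a connection split 7/5 across two
   neuropils is one strong connection, not two medium ones.
2. **Partner sets, not weights, define similarity.** Connectomic typing
   uses the Jaccard index of two cells' partner sets,
   J(A, B) = |A ∩ B| / |A ∪ B|, computed over medium+strong partners by
   default. Weights enter the selection of partners, not the index
   itself; the index asks *who* a cell talks to, not *how loudly*.
3. **Shared strong connectivity defines group structure.** A partner
   "shared" by a cell group is one with strong connections to at least
   two distinct members (`min_members = 2`). Whether a shared target of,
   say, a four-cell group is in fact contacted by all four members is an
   empirical outcome, not part of the definition.

## Recurrence and inter-clock neurons

For a cell group G and a designated clock set C (default: the 28
catalogued clock neurons), the recurrence analysis takes the strong
shared output targets of G and flags each target that forms at least one
medium-or-stronger synapse onto any member of C. The percent-recurrent
statistic is 100 × (recurrent targets) / (targets); it is undefined
(reported `NA` with a flag) when the group has no shared strong targets.
Weak back-contacts are listed for completeness but never set the flag,
mirroring the medium+strong criterion used for the forward analysis.
Only length-2 paths (group → target → clock) are considered; longer
polysynaptic motifs are out of scope. Targets that are themselves clock
cells are marked `target_is_clock` and remain eligible — a clock neuron
receiving convergent strong output and contacting other clock cells is
exactly the kind of hub the analysis is meant to surface. Direct
group → clock connections are not recurrence.

## Neuropil profiles

Per-connection ROI breakdowns allow a cell's medium+strong connections to
be apportioned across neuropils. The phrase "percentage of connections"
is ambiguous between synapse-weighted and partner-counted readings, so
both bases are implemented and recorded in the result's metadata:

- `synapse_weight` (default): percentage of summed per-ROI synapse
  counts over summed total weights. Synapses without an ROI assignment
  go to an explicit `unassigned` bucket, preserving the sum-to-100
  invariant rather than silently dropping mass.
- `partner_count`: each qualifying connection contributes once, to its
  majority ROI; ties break to the alphabetically first ROI for
  determinism.

The ROI vocabulary is treated as a flat, mutually exclusive label set
chosen at ingest (`roi_level` records which); nested ROI hierarchies must
be flattened by the exporter, otherwise per-ROI counts would be double
counted.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `medium_min`, `strong_min` | 3, 10 | class boundaries on total PSD count |
| `min_members` | 2 | members a shared partner must reach |
| `min_class` (similarity) | `"medium"` | partner-set criterion for Jaccard |
| `back_min_class` | `"medium"` | back-contact class that makes a target recurrent |
| `linkage`, `cut` | `"average"`, 0.85 | clustering method and dendrogram cut on 1 − J |
| `basis` | `"synapse_weight"` | neuropil percentage basis |

The clustering step is this package's own device: the connectomic groups
in the source domain were read off Jaccard heatmaps by eye, and no
algorithm is prescribed for them. Average-linkage agglomerative
clustering on the distance 1 − J is the least committal standard choice;
the default cut of 0.85 — i.e. cells merge while their average partner
overlap exceeds roughly 0.15 — was fixed once against the synthetic
suite's default geometry, where within-group distances concentrate near
0.45 and between-group distances near 1.0, leaving a wide insensitive
band (roughly 0.6–0.95) for the cut. Both the linkage and the cut are
recorded in outputs and exposed as arguments.

# Numerical and edge-case choices

- **Both-empty Jaccard is 0**, not 1 or NaN, and the convention is
  flagged in report metadata (`empty_sets_zero`). Sparsely connected
  cells would otherwise cluster together on the strength of having no
  partners at all. Consequently a Jaccard matrix diagonal is 1 only for
  cells with non-empty partner sets.
- **Duplicate edge keys sum with a warning.** The weight between a pair
  is the total PSD count, so duplicated export rows are merged rather
  than rejected; the warning preserves an audit trail.
- **Autapses are rejected at ingest** by default (`allow_autapses`
  admits them); self-contacts in EM exports are usually segmentation
  artefacts.
- **Uncatalogued endpoints become fragment records** instead of errors:
  truncated, unnamed bodies carry real synapses and belong in totals and
  partner counts.
- **Deterministic ordering everywhere**: shared-partner rows sort by
  descending summed weight then body id; matrix rows follow the caller's
  cell order; cluster codes are numbered by first appearance. Repeated
  runs of `run_full_analysis()` on identical inputs produce
  byte-identical bundles.
- **Per-ROI weights may undershoot a stated total** (the remainder is
  `unassigned`) but may never exceed it — that is a consistency error at
  ingest.

# The synthetic connectome generator

`synthetic_spec()` / `generate_connectome()` make the statistical
assumptions of the analysis explicit and testable. The generator plants:

- `n_groups` groups of `members_per_group` cells (default 4 × 3);
- a pool of `shared_pool_size` strong shared targets per group (default
  30), each hit independently by every member with probability
  `p_member_hits_target` (default 0.7), redrawn until at least two
  members hit so every planted target satisfies the shared criterion;
- strong weights `10 + Geometric(mean = 8)`, a floor-plus-heavy-tail law
  mimicking the long upper tail of empirical strong-connection weights
  (the empirical weight distribution is not published, so this law is a
  stand-in, exposed as a parameter);
- per-target medium back-edges onto a random planted cell with
  probability `recurrence_prob` (scalar or per-group), uniform weights
  3–9;
- weak background noise edges with probability `background_edge_prob`
  (default 0.01) between any unconnected ordered pair, weights uniform
  on {1, 2} — the weak stratum only, emulating spurious one- and
  two-synapse contacts without contaminating medium+strong partner sets
  (medium noise is available by raising `background_weight_max`);
- `n_bystanders` cells (default 100) receiving only background edges,
  standing in for the fragment population;
- one ROI per connection, drawn from a per-group preference (by default
  each group places 70% of its connections in its own preferred
  neuropil).

Group pools are disjoint by default (`cross_group_overlap = 0`); overlap
is opt-in for robustness experiments. One integer seed drives a single
RNG stream, generation is byte-reproducible, and the caller's RNG state
is untouched.

**What passing recovery tests does and does not show.** The generator
emulates convergent strong output, stratified weights, noise and
recurrence — the features the pipeline's statistics rely on. It does not
emulate morphology, ROI geometry, distance-dependent connectivity,
correlated noise from segmentation errors, hemispheric truncation, or
daily synaptic remodelling. Perfect recovery on synthetic data therefore
validates the implementation and the internal consistency of the
criteria, not the biological typing of any real dataset.

# Validation problem sizes

The test suite and the acceptance script exercise, per run: 100
synthetic connectomes at the default geometry (12 planted cells, ~120
targets, 100 bystanders, ≈ 900 connections each) for partition recovery;
the same 100 for recurrence recovery with planted probabilities (1.0,
0.4, 0.5, 0.3), pooled over 3,000 targets per group and compared within
binomial 95% intervals; 1,000 random set pairs on a universe of 100 for
the Jaccard oracle; and brute-force cross-checks of every partner
operation on random tables of up to 50 neurons. These sizes give the
recovery estimates sub-percent standard errors while keeping a full run
in the minutes range on one CPU.

# Known limitations

- Single-hemisphere exports truncate contralateral connectivity; totals
  computed from them undercount true synapse numbers. The package
  reports what the table contains and makes no completeness correction.
- Electrical synapses and non-synaptic (peptidergic) signalling are
  invisible to PSD-count connectomics and hence to this package.
- The catalog's "select orphan bodies" provenance in the source data
  cannot be reconstructed from published information; ingest treats any
  uncatalogued endpoint uniformly as a fragment.
- Subdividing groups below the shared-partner criterion (e.g. splitting
  a three-cell group into sub-pairs) is supported by passing arbitrary
  subgroups, but the package hard-codes no such split.
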