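# clocknet

Connectomic analysis of circadian clock neuron networks in R.

Dense electron-microscopy connectomes such as the *Drosophila* hemibrain
report, for every ordered pair of neurons, a synaptic weight: the number of
postsynaptic densities (PSDs) the presynaptic cell contacts on the
postsynaptic one. `clocknet` turns such edge lists into the quantities used
to characterise the fly's circadian clock network — in particular the
lateral-neuron (LN) pacemaker classes (s-LNvs, LNds, 5th LNv) and their
functional subgroups M, E1, E2 and E3 — and ships a synthetic connectome
generator with ground truth so every stage of the pipeline can be
validated.

## What it computes

Connections are stratified by total weight *w* into **weak** (*w* < 3),
**medium** (3 ≤ *w* ≤ 9) and **strong** (*w* ≥ 10) classes; thresholds are
configurable, classification always applies to the pair's total weight,
never per-ROI counts. On top of this stratification the package provides:

- **Connectivity matrices** — pairwise weight matrices over any cell set
  (weak included, for all-connection heatmaps), class-aggregated
  medium+strong matrices between groups, and raw input/output synapse
  totals per cell (`pairwise_matrix()`, `class_aggregate()`,
  `synapse_totals()`).
- **Shared strong partners** — for a cell group, the neurons that make or
  receive strong connections with ≥ 2 distinct members, with per-member
  weights, distinct-partner counts and Sankey-ready flow exports
  (`shared_strong_partners()`, `distinct_strong_partner_count()`,
  `pairwise_shared_count()`, `sankey_export()`).
- **Jaccard connectomic typing** — similarity of medium+strong partner
  sets, J(A, B) = |A ∩ B| / |A ∪ B|, and average-linkage clustering on
  1 − J to partition cells into connectomic groups (`jaccard()`,
  `jaccard_matrix()`, `cluster_by_similarity()`).
- **Recurrence ("inter-clock" neurons)** — strong shared output targets of
  a group that form medium+strong synapses back onto clock neurons,
  length-2 paths group → target → clock, and the percent-recurrent
  statistic per group (`recurrent_targets()`, `interclock_summary()`).
- **Neuropil profiles** — the percentage of a cell's medium+strong
  connections located in each ROI, by synapse weight or by partner count
  (`roi_percentages()`, `neuropil_profiles()`).
- **Synthetic connectomes** — planted-partition generators with
  strength-stratified weights, ROI preferences, recurrence hubs and full
  ground truth, plus Adjusted-Rand-Index scoring of recovered partitions
  (`synthetic_spec()`, `generate_connectome()`, `evaluate_recovery()`).

The 28 identified hemibrain clock neurons, with their body ids, sequential
labels and M/E1/E2/E3 subphase assignments, ship as `default_catalog()`.
Edge lists are read from neuPrint-style CSV exports (`read_connections()`,
long or wide dialect), and `run_full_analysis()` drives every stage on one
input to produce a self-describing report bundle.

## Worked example

The package ships a six-neuron worked fixture — a two-cell group (`m1`,
`m2`), three targets and one further clock cell — whose every statistic is
checkable by hand:

```r
library(clocknet)
x <- toy_connectome()
x
#> <connectome> 6 connections among 6 neurons (6 catalogued, 0 fragments)
#>   strength: 0 weak / 3 medium / 3 strong (thresholds 3/10)

shared_strong_partners(x, cell_group("M", c(1, 2)), "outputs")
#> <shared_partner_report> group M, outputs, >= 2 members at strong: 1 partner(s)
#>   partner label n_members total    m1    m2
#> 1      11 t1            2    22    12    10
```

Target `t1` receives strong output from both group members (12 and 10
synapses). The members' medium+strong output partner sets overlap in one
of four neurons:

```r
jaccard_matrix(x, c(1, 2), "outputs")
#>      m1   m2
#> m1 1.00 0.25
#> m2 0.25 1.00
```

`t1` contacts the clock cell `c1` with 5 synapses (medium), so the group's
single shared strong target recurs to the clock set — 100% recurrence:

```r
glance(recurrent_targets(x, cell_group("M", c(1, 2)), clock_set = c(21, 1, 2)))
#>   group n_targets n_recurrent percent_recurrent
#> 1 M             1           1               100

roi_percentages(x, 1, "outputs")
#>   roi   amount percentage
#> 1 SLP       12       46.2
#> 2 SMP       11       42.3
#> 3 AME        3       11.5
```

The last table reads: of `m1`'s 26 medium+strong output synapses, 12 lie
in the superior lateral protocerebrum, 11 in the superior medial
protocerebrum and 3 in the accessory medulla.

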