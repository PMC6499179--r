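---
title: "Inferring whole-genome duplication status from Ks, trees, synteny, and karyotypes"
author: "wgdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring whole-genome duplication status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`wgdetect` decides, for each species in a comparison set, whether its
genome carries a whole-genome duplication (WGD) within the evolutionary
window the data cover, and — when a WGD is present in a sister lineage
but absent in a slow "relic" diploid — whether the evidence favors
allopolyploidy with the relic's ancestor as one subgenome donor. The
package combines five semi-independent evidence channels (Ks peaks,
gene-family copy numbers, gene-tree topology patterns, synteny depth,
karyotypes/genome sizes) and ships a generative simulator so every stage
can be validated against ground truth.

# The estimator: NG86 with Jukes–Cantor correction

`ng86()` implements the unweighted Nei–Gojobori (1986) counting method
on aligned in-frame CDS pairs:

* Synonymous sites per codon are `sum over positions of (synonymous
  one-step neighbors) / 3`; changes producing a stop codon are counted as
  nonsynonymous. Site counts are averaged between the two sequences.
* Codon pairs differing at 2–3 positions are scored by averaging the
  synonymous/nonsynonymous step counts over all minimal mutational
  pathways with equal weights; pathways passing through a stop codon are
  excluded (if every pathway is blocked, all are used with stop steps
  counted nonsynonymous).
* `Ks = -(3/4) ln(1 - 4 ps / 3)` with `ps = Sd / S`; saturated pairs
  (argument ≤ 0) are flagged invalid and excluded from histograms.
* Codons containing non-ACGT characters in either sequence are skipped
  entirely, so `S + N = 3 ×` (codons counted) always holds.

**Known limitation.** The Jukes–Cantor inversion assumes every
synonymous site is a symmetric 4-state site. Two-fold degenerate
positions are 2-state toggles and three-fold (isoleucine) positions are
3-state, so under a uniform-sense-codon composition the estimator drifts
upward at moderate-to-high divergence (about +3% at true d = 0.3, +7% at
d = 0.6, measured on the package's own generator). This is a property of
the published estimator, not of the implementation; the test suite
therefore verifies exact consistency on four-fold-degenerate codon sets
(where third positions are true JC sites and "true synonymous
divergence" is unambiguous) and verifies the full sequence model at
moderate divergence (d = 0.2) within sampling error. All Ks-calibrated
quantities in the package (peak positions, cutoffs) live on the NG86
scale, where this drift is immaterial because every stage uses the same
scale.

# Histograms, modal peaks, and cutoffs

Histograms (`ks_histogram()`) cover \[0, 2\] in uniform bins (default
width 0.05 — 40 bins, narrow enough to separate a 0.15 speciation peak
from a 0.25 homoeolog peak), left-closed right-open with the last bin
closed; only valid estimates in range are counted.

`modal_peak()` reports the highest bin at or above an exclusion floor
(default 0.05). The floor plus an *amplitude-dominance* rule handle the
near-zero shoulder that tandem duplications put into every
self-comparison: the candidate mode must strictly exceed every bin count
below the floor, otherwise a "no peak" result is returned. A decaying
tandem shoulder therefore never masquerades as a WGD peak, while a
genuine duplication burst — which outnumbers the shoulder at its mode —
is always reported. Ties break toward the smaller Ks for determinism.

Per-species-pair clustering cutoffs are `1.5 ×` the modal Ks
(`ks_cutoff()`), with a configurable fallback (default 2.0, the
histogram ceiling) when no peak exists — e.g. the relic's own
self-comparison.

`solve_branches()` turns modal Ks values into consensus branch lengths:
each branch of a fixed rooted topology is a variable, each observed
modal Ks is a linear path-sum constraint. Short internal branches that
path data cannot determine are fixed at 0.01; symmetric homoeolog
terminals can be tied to one variable. Exactly determined systems are
reproduced to machine precision, overdetermined ones solved by least
squares, underdetermined ones refused with the offending branch list
(never silently guessed). Negative solutions are clamped at zero with a
residual report.

# Families: Ks-filtered graphs, MCL, profile refinement

`build_graph()` keeps a pair iff its Ks is within the species-pair
cutoff; the weight transform is the linear decay `1 - Ks/cutoff` floored
at 1e-3 — monotone, bounded, and consistent with the cutoff (the exact
transform used by the original large-scale pipelines is not published;
any monotone decay gives the same clusters on well-separated data).
`mcl_cluster()` is a faithful Markov clustering implementation
(column-stochastic matrix with max-incident-weight self-loops, expansion
/ inflation alternation, entry pruning at 1e-5, convergence at max
change < 1e-6 or 200 iterations), defaulting to inflation 1.2 as used
for legume-scale families; clusters are the connected components of the
converged support and always form a partition.

`refine_families()` reproduces the two-round profile refinement: score
members against their family profile, drop those under 40% of the family
median, rebuild, rescan the *entire* proteome (including genes the Ks
filter never clustered), assign each protein to its best family if it
clears that family's 40% bar, and drop sub-threshold members once more.
Profiles are per-column amino-acid log-odds against a uniform background
with a Laplace pseudocount and an affine length penalty (−2 open, −0.5
extend): the package's positional stand-in for profile HMMs, preserving
the 40%-of-median logic without reimplementing Plan7 (real-data mode can
ingest externally computed bitscores instead). Scores are raw, not
length-normalized; with a shared family alignment length the two differ
by a constant factor and the 40% rule is unaffected.

# Trees: NJ, rooting, collapsing, species overlap, mining

For simulated data, gene trees are neighbor-joined (`ape::nj`) from
pairwise NG86 distances (saturated pairs imputed at Ks 3, beyond the
informative range) and rooted by the closest outgroup, falling back to
midpoint rooting with a flag. Two collapse criteria exist and are never
mixed: both terminal branches < 0.01 (used before clade mining, to
remove private recent duplicates) and pair Ks < 0.2 (used for the
reduced copy-number tables). Collapsing iterates to a fixpoint and
keeps the lexicographically smaller gene id.

`label_overlap()` labels a node duplication (`D`) iff any pair of child
subtrees share a species — the species-overlap rule; multifurcations use
any-pair intersection (an extension; simulated trees are binary).
`mine_clades()` extracts *maximal* clades whose leaves are all
relic/sister (maximality avoids double-counting nested clades), types
them by relic/sister leaf counts, and for the (1 relic, ≥ 2 sister) type
reads the nested pattern off the MRCA label: `D` ⇒ `[(C,B),B]`
(duplication predating speciation — the allopolyploidy signature), `S`
⇒ `[(B,B),C]` (speciation then duplication). `count_table()` tabulates
per-species family sizes 0/1/2/3/≥4 and the duplication-ratio statistic
`100 × (≥2) / (=1)`, rounded to integer percent and flagged undefined
when no single-copy families exist.

# Synteny: chaining and quota screening

Coordinates are ordinal gene ranks per chromosome (the simulator emits
gene orders; depth logic is coordinate-scale-free). `chain_anchors()`
finds maximal monotone chains (inversions allowed) by O(n²) dynamic
programming with an adjacency cap of 10 ranks on both axes and a
4-anchor block floor. `quota_select()` admits blocks greedily by score
under a per-position depth audit — a transparent surrogate for the exact
LP quota solver, validated against simulation truth rather than
bit-compatibility; the audit guarantees the depth constraint exactly,
and an exhaustive-search oracle confirms chain optimality on small
inputs. `quota_screen()` marks the smallest-depth quota reaching ≥ 90%
coverage on both axes as `BEST`.

Self-comparisons suppress the trivial diagonal *and* a near-diagonal
band (default 10 ranks): tandem pairs sit just off the diagonal and
would otherwise chain into spurious self-synteny. With the band in
place, a genome with one WGD is fully covered at quota 1:1 by its
homoeologous blocks (the expected signature), and a WGD-free genome has
no self-blocks at all. Restricting Ks histograms to block anchors
(`synteny_ks()`) removes the tandem shoulder entirely, which is why the
pipeline's per-species self-peak verdict uses the synteny provenance.

# Karyotypes and genome sizes

`genus_mode()` pools species-level gametic counts per genus; all
co-modes are reported with the smallest designated primary (deterministic
and conservative; ties are flagged). Polyploid series within a genus are
pooled as-is. `clade_summary()` tallies genus modes per clade into the
6…16/>16 columns, keeping unassigned genera visible in an `unplaced`
row. `pg_to_mbp()` converts 2C picograms at 1 pg = 978 Mbp, halves to
1C, and rounds to the nearest Mbp. `annotate_tree()` paints genus modes
onto a species tree with clade-modal labels; leaves without data are
flagged, never pruned.

# The simulator: what it emulates, and what it does not

`sim_config()` + `build_history()` define timed event lists (ages before
present, strictly decreasing) with per-lineage rate multipliers; branch
lengths accumulate as elapsed time × rate, i.e. in expected-Ks units.
The default **allopolyploid scenario** is: outgroup split at age 0.2,
relic-ancestor/donor split at 0.128, outgroup autopolyploidy at 0.12,
hybridization of relic ancestor × donor into the tetraploid at 0.1195,
donor extinction at 0.05; rates relic 0.25, donor/tetraploid 1, outgroup
2.5. These ages were chosen once so the expected pairwise Ks match the
calibration targets: relic–tetraploid ≈ 0.15, homoeolog pair ≈ 0.25,
relic–outgroup ≈ 0.55, outgroup self ≈ 0.6 — and so the donor's
divergence predates the hybridization, as allopolyploidy requires. The
**autopolyploid contrast** moves the sister's WGD to age 0.07, *after*
the speciation at 0.128, flipping the expected clade pattern from
`[(C,B),B]` to `[(B,B),C]` and making the self peak (0.14) younger than
the speciation peak (0.16). Karyotypes start at n = 7 and double at each
polyploidy (allopolyploid n = 7 + 7 = 14).

Families replay the history: speciations copy genes to both daughters;
polyploidy duplicates survive fractionation i.i.d. with the retention
probability (default 0.8 — a single-parameter stand-in for ongoing loss,
sufficient to reproduce the copy-number table structure); allopolyploidy
joins one copy from each parent; tandem duplications arise at rate 2 per
gene per unit time with survival `exp(-10 × age)`. Those two tandem
parameters were set so that roughly 15–20% of relic genes carry a
surviving tandem — matching the observed no-WGD duplication-ratio band
(~20–24%) and producing the characteristic decaying near-zero Ks
shoulder. Sequences start from uniform random sense codons; synonymous
substitutions are a Poisson process with expectation branch length ×
synonymous sites, applied in ≤ 0.05-length segments (so site counts
track the evolving sequence), choosing uniformly among synonymous
single-nucleotide neighbors; nonsynonymous changes run at 0.05 × the
synonymous per-site rate. Per-family random streams are derived from the
master seed, so any family is reproducible independently of generation
order.

Deliberately not modeled: codon-usage bias, amino-acid selection,
indels (within-family alignment is positional by construction),
gene conversion, transcriptome incompleteness, and base-pair-resolution
coordinates. Passing tests therefore demonstrate the *logic* of the
inference chain under known ground truth — not robustness to alignment
error or assembly artifacts in real data. Real-data mode consumes
externally produced match tables, alignments, trees, and position
tables through the same interfaces.

# The verdict rule table

Narrative synthesis of the evidence channels is made explicit and
testable in `run_pipeline()`:

* `no-WGD`: no synteny-restricted self Ks peak in \[0.05, 1\], AND
  duplication ratio < 30% (between the observed no-WGD ~24% and WGD
  ≥ 42% bands), AND self-synteny 1:1 coverage < 30% (no duplicated
  depth).
* `allopolyploid-parent-pattern`: a self peak older than the
  between-species speciation peak with the relic, with `[(C,B),B]`
  dominant among (1 relic, ≥ 2 sister) clades.
* `WGD`: a self peak coinciding with a high duplication ratio or
  duplicated self-synteny (1:1 coverage ≥ 70%).
* `inconclusive`: anything conflicting.

Every evidence field in the JSON report carries its provenance (stage
and inputs). Identical config + seed reproduce every artifact
byte-for-byte.

# Problem sizes and numerical choices

Scenario-level analyses use 200 base families of 300 codons (≈ 950
genes across three species) — large enough that modal bins hold
~100+ pairs and clade-pattern dominance is decisive, small enough for
interactive use. Distances for NJ impute saturated pairs at Ks 3;
MCL prunes entries below 1e-5 and renormalizes; the branch solver uses a
QR decomposition with an explicit rank check; clade records are reported
in deterministic post-order; all tables are written with fixed formats
so reruns are byte-identical. The spec-level interfaces are all exported
R functions; a shell entry point would add nothing here since every
stage artifact is a plain-text file produced by `run_pipeline()`.
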