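---
title: "Methods: compartment variability and tunnel correspondence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment variability and tunnel correspondence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunvar)
```

This vignette documents the models, rules and numerical choices behind
`tunvar`, in the order the pipeline applies them, and states what the
synthetic-data validation does and does not demonstrate.

## Sequence curation

Candidate family sequences are deduplicated by exact sequence identity
(first occurrence kept) and filtered on two catalytic motifs
characteristic of epoxide hydrolases: the oxyanion-hole motif H-G-X-P and
the nucleophile-elbow motif G-X-Sm-X-S/T. A motif is an ordered list of
residue classes matched against every contiguous window. Two of the
classes are not fully determined by the literature and are explicit,
configurable choices here:

* **X** matches any canonical residue by default. X is *often* aromatic
  in this family, but "often" is not a constraint; an aromatic-restricted
  X (F/H/W/Y) is available via `motif_hgxp(aromatic_x = TRUE)`.
* **Sm** defaults to Taylor's "small" class {A, C, D, G, N, P, S, T, V}
  (`SMALL_RESIDUES`), overridable per call.

Records containing ambiguity codes (B, Z, X, U, ...) have undefined motif
semantics; they are flagged and excluded from motif filtering by default,
and are an error in strict mode. Motif search runs on unaligned
sequences. Sequences longer than 420 residues typically carry a fused
second domain; because excising it is an alignment-guided manual act, the
package only reports the candidates (`flag_long_sequences`) and never
trims. Alignment construction itself is out of scope: the pipeline
consumes any pre-built FASTA alignment.

## Column entropy

Conservation is scored per alignment column by the Schneider entropy,
the Shannon entropy of the column's residue frequencies normalized to
[0, 1] by ln 20. The logarithm base cancels in the normalization; the
implementation uses natural logarithms. Sequences are unweighted.

Gap handling is the one genuinely open choice. The default policy
(`"exclude"`) drops gaps and renormalizes over the residues actually
present, which keeps the ln 20 normalization coherent; the alternative
(`"gap21"`) counts the gap as a 21st symbol and normalizes by ln 21. The
policy in force is recorded on the profile object. Columns that are all
gaps carry `NA` — never a fabricated 0 — and are excluded from every
downstream median and test. Entropy values computed under the two
policies are not comparable; published per-residue values can shift if
the other policy is chosen.

## Trimming and the background

All variability comparisons run inside the *trimmed* alignment: the
columns at which at least one structure-linked reference row has a
residue (`trim_columns`). For a compartment with mapped columns C and
trimmed mask M, the background is exactly M \\ C — the partition
`C ∪ (M \ C) = M`, `C ∩ (M \ C) = ∅` is asserted in the pipeline tests.
Structure residues map to columns by walking the reference row: the k-th
structure residue takes the column of the k-th non-gap symbol. The
ungapped reference row must equal the structure-derived sequence exactly;
a mismatch is reported at its first position and never silently
realigned, because the reference rows are the alignment's own structures
and a mismatch signals a data error. Author residue numbering from the
PDB file is authoritative. For multi-domain structures a residue-range
restriction in `read_structure` selects the catalytic domain; domain
bounds are configuration, not code.

## Classification

A compartment is classified by the median distance
`median(S_comp) − median(S_bg)`: strictly positive means *variable*,
zero or negative *conserved* (ties go to conserved — the rule is a strict
inequality). Each compartment is reported three ways: all residues,
surface residues excluded, and surface-only; the two subgroups are
disjoint and union to the compartment, which is tested, while no ordering
of their median distances is assumed (none holds in general).
Surface/buried and active-site annotations are consumed from a table,
never predicted.

Distributional significance uses the Epps–Singleton two-sample test: the
empirical characteristic functions of the two samples are compared at
t = (0.4, 0.8) scaled by the semi-interquartile range of the pooled
sample; the quadratic-form statistic is asymptotically chi-squared with
degrees of freedom equal to the rank of the estimated covariance (4 in
the regular case), and the small-sample correction of the original
publication is applied when both samples have fewer than 25 observations.
These are the published defaults of the test and of the common
implementations, and the unit suite pins the implementation to an
external reference implementation at 1e-8 on shared inputs. Samples with
fewer than `min_n = 5` values, or a pooled sample with zero
interquartile range, produce an NA marker rather than an error, because
variability tables legitimately contain such cells (e.g. tunnels with
almost no surface residues). No multiple-testing correction is applied
across compartments: each p-value is reported raw, matching how such
tables are usually read; a correction can be layered on by the caller.

For profile plots, each tunnel entropy value is paired with a background
value by empirical-CDF matching. "Closest CDF" underdetermines the
procedure, so the package fixes it as: sort both lists; take tunnel
values in ascending order; pair each with the unused background value
whose ECDF position is nearest, breaking ties toward the smaller
background value. Pairing is without replacement, so a background at
least as large as the tunnel sample is required.

## Tunnel correspondence

Crystal and MD tunnels are compared purely through lining-residue sets.
Occurrence is atom counts for crystal tunnels (all atoms equal weight)
and snapshot counts for MD tunnels. Thresholding is strict —
o > max(o)·τ — so the maximal-occurrence residue always survives any
τ < 1, and thresholded sets of non-empty tables are never empty. Both
sides are thresholded independently over the 19 × 19 grid
τ ∈ {0.05, …, 0.95}² (361 combinations); the cell minimizing the Jaccard
distance is optimal, with ties broken toward the lexicographically
smallest (τ_crystal, τ_md) for deterministic output. Cells where a
thresholded set would be empty are skipped as undefined rather than
assigned distance 1; by the argument above they cannot occur on valid
inputs.

The assignment of crystal to MD tunnels from the optimized distance
matrix is not fully determined by "lower distance means corresponding
pair", so the package uses greedy global-minimum selection: repeatedly
take the smallest remaining cell and delete its row and column. This is
the minimal mechanism consistent with that reading; because the full
matrix and per-cell optimal thresholds are part of the result, a reader
preferring optimal (Hungarian) assignment or many-to-one readings can
derive them from the same output. Row-major index order breaks exact
ties, making results independent of input table order up to tie-breaks.

## Spatial profiles

Tunnel residues are plotted as entropy versus distance from the geometric
centre of the enzyme's Cα atoms. A residue's position is its own Cα —
not a side-chain centroid — which keeps the measure rotamer-independent;
residues lacking a Cα get an NA distance. Active-site membership
overrides surface/buried in the three-way class used for colouring. The
marginal entropy histogram uses 0.05-wide bins by default (configurable);
bin counts are conserved against the point count.

## Synthetic data: what it emulates

`gen_msa` draws each column's residue distribution from a symmetric
Dirichlet and samples sequences independently per column; the
concentration is the entropy dial. The calibration (empirical, at
n_seqs = 500) is frozen in `SYNTH_ALPHA`:

| class      | concentration | realized Schneider entropy           |
|------------|---------------|--------------------------------------|
| conserved  | 5e-4          | mean ≈ 0.005; 98% of columns ≤ 0.15  |
| background | 0.1           | mean ≈ 0.44; spread ≈ 0.10–0.68      |
| variable   | 1.5           | mean ≈ 0.90; essentially all ≥ 0.6   |

The very small conserved concentration is deliberate: symmetric-Dirichlet
entropy is heavy-tailed, and larger values leave too many "conserved"
columns with a visible second residue. Reference rows are gap-free except
on planted `ref_gap` columns (gapped in *every* reference row, populated
in the others), which exercise the trimming rule; a fraction of columns
receives random gaps in non-reference rows at rates up to 0.6.

`gen_structure` realizes one reference row as a Cα-only chain on a
spherical spiral with class-dependent radii (active site 3–5 Å, buried
7–12 Å, surface 16–21 Å), so buried residues are strictly nearer the
centroid than surface residues — a geometric invariant the tests check
per seed. Compartments AS/BAA/SAA follow the planted classes; TUN1 mixes
active-site, buried and surface residues (a conserved-leaning lining),
TUN2 is surface-dominated (variable-leaning).

`gen_occurrence_tables` plants tunnels with disjoint high-occurrence
cores and noisy low-occurrence fringes; the MD partner shares the full
core and flips each fringe residue with probability 0.1 (default). MD
snapshot totals default to 1,000 — large production runs use tens of
thousands of frames, but the count scales no downstream rule, only the
occurrence magnitudes.

What passing on these data shows: the rules are implemented exactly
(thresholding, trimming, partition, medians, matching) and the pipeline
recovers planted truth under independent-column noise. What it does not
show: behaviour under phylogenetic correlation between sequences (columns
here are independent, and sequences are unweighted), realistic protein
geometry, or the numeric values of any published table — those depend on
the original family alignment and tunnel-detection outputs, which are
inputs, not deliverables, of this package.

## Problem sizes and determinism

Default validation sizes are 500 sequences × 300 columns for alignments
(100 replicates for label recovery), 4 planted tunnels × 100 seeds for
matching, 2000 null replicates (n = 100 per arm) for the Epps–Singleton
type-I check, and the full 4096-pair subset universe for the Jaccard
metric axioms. A complete synthetic study runs in well under a minute on
one core. Every generator takes an explicit integer seed and is fully
determined by it; the workflow manifests record seeds, settings and input
checksums, and contain no timestamps, so re-running a stage on unchanged
inputs reproduces its outputs byte-identically.
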