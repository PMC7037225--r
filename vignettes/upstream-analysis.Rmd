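---
title: "Methods: upstream analysis from expression to master regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: upstream analysis from expression to master regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and
procedures it implements, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish about real data.

## The inference problem

An expression experiment yields differentially expressed genes (DEGs);
the biological question is what *caused* them. The package walks the
causal chain backwards in three stages: DEGs → the transcription
factors whose binding sites are over-represented in DEG promoters →
the signaling-network nodes positioned upstream of those TFs. A node
that can reach many of the active TFs through short directed paths is
a candidate *master regulator* of the expression program.

Each stage is a self-contained module with files as boundaries, so any
stage can be re-run in isolation and the whole pipeline is a
deterministic function of (inputs, configuration, seed).

## Stage 1: differential expression

Counts are modeled as negative binomial. Normalization uses
median-of-ratios size factors (reference: per-gene geometric mean over
genes with all-positive counts; factors rescaled to geometric mean 1;
total-count fallback with a warning when no gene qualifies). A single
common dispersion is estimated by the method of moments on normalized
counts — per gene, `alpha_g = (v - m)/m^2` with `v` the pooled
within-group variance — taking the median of the finite per-gene
values, floored at zero. The median is deliberately robust: per-gene
moment estimates are noisy at 3 replicates, and a handful of outlier
genes should not move the common value.

The test is an exact conditional test on group sums: under the null
the two sums are NB with means proportional to the summed size
factors and size parameters matched to the variance of a sum of
per-sample NB variables; the two-sided p-value adds up the
conditional probabilities, given the total, of all splits at most as
likely as the observed one (`dpois` limit at dispersion 0). A
pseudo-count of 0.5 in both group means keeps `logFC` finite; genes
with zero counts everywhere are retained with `logFC = 0, p = 1` so
the gene universe is preserved.

Cut-offs are strict inequalities — `logFC > 0.7`, `logFC < -0.7`,
`p < 0.05` — matching how the thresholds are printed wherever such a
pipeline is described. The DEG stage filters on *unadjusted*
p-values while the enrichment stage uses BH-adjusted ones; this
asymmetry is intentional and mirrors the analysis the pipeline
reproduces, so it is implemented as printed rather than harmonized.
The stage is pluggable: a pre-computed DEG table (e.g. from edgeR or
DESeq2) can be supplied and bypasses the internal test, since the
contribution of the pipeline lies downstream of DE calling.

Calibration: on null NB simulations (2000 genes, 10+10 replicates,
dispersion 0.1) the observed type-I error at p < 0.05 stays within
[0.03, 0.07] across seeds (the acceptance suite checks five).

## Stage 2: promoters, motifs, enrichment, composite modules

**Scanning.** Promoters are fixed 1100-bp windows, −1000..+100 around
the TSS, stored 5'→3' with 0-based half-open coordinates (TSS at
index 1000); a single internal convention avoids off-by-one drift.
Matrix rows are normalized to frequencies with pseudocount 0.01 added
before any logarithm (so zero counts never produce −∞ weights). The
scoring is MATCH-style: information weights
`I(i) = Σ_b f(i,b) ln(4 f(i,b))` (natural log), window raw score
`Σ_i I(i) f(i, b_i)`, min–max rescaled into `mss ∈ [0,1]`; `css` is
the same quantity restricted to the most informative 5 consecutive
positions (leftmost on ties; length configurable). A degenerate
matrix with Max = Min scores 1 by convention. Windows containing `N`
are conservatively scored as no-hit. Both strands are scanned; a
reverse-strand hit is reported by its forward-strand start
`len − L − s'`.

Since per-matrix score-cutoff profiles are library-specific and not
portable, the package uses global defaults `mss ≥ 0.85`,
`css ≥ 0.90`, overridable per call. Overlapping hits are all
reported; deduplication is the enrichment stage's concern.

**Enrichment.** "Site frequency" defaults to promoter
presence/absence — a promoter counts once per PWM however many sites
it carries — because the one-sided Fisher exact test on the resulting
2×2 table is then exactly valid. A per-bp site-density variant is
available behind `stat = "density"` for users who prefer counting
sites, with the caveat that its 2×2 approximation treats base pairs
as independent trials. The "No" background is all expressed, non-DE
genes; an optional seeded downsampling to a fixed multiple of the Yes
set caps the table sizes. Selection is BH-adjusted p < 0.01, strict.

**Composite modules.** The module score of a promoter is
`max_s Σ_m w_m · min(#hits_m in [s, s+W), c_m)` — a weighted,
saturating co-occurrence count in the best W-bp window. Fitness of a
candidate module is the one-sided Wilcoxon rank-sum separation of Yes
over No promoter scores, as `-log10 p`, minus a complexity penalty of
0.05 per member. The penalty is the package's own parsimony device:
published composite-module fitnesses combine several penalty terms
whose exact form is not public, and the Wilcoxon separation alone is
the quantity stated to be optimized, so the package optimizes exactly
that plus the smallest term that discourages free-riding members.
The window width W is part of the searched genome (range 200–300 bp)
since the procedure specifies a range, not a value.

The optimizer is a seeded genetic algorithm: population 50,
100 generations, tournament selection (k = 3), uniform crossover
(p = 0.5 per field), mutation (p = 0.1 per field), elitism of one
(which makes the best fitness non-decreasing across generations —
a tested invariant). The member cap is 10. The Wilcoxon p uses exact
enumeration when both groups have fewer than 8 scores (valid under
ties) and a normal approximation with tie and continuity correction
otherwise; all pooled scores identical gives p = 1. The inner loop —
scoring every promoter for every candidate — is compiled C++; only
window starts coinciding with a hit start (clipped to `len − W`) need
evaluation, because the windowed count is a step function of s.

## Stage 3: master regulators in the signaling network

From each active TF a breadth-first search along reversed edges finds
every node with a directed path of length ≤ R (default 12) down to
that TF; a TF reaches itself at distance 0 (configurable convention:
a TF can be its own regulator candidate). The key-node score is

    S(u) = [ Σ_{t reached} β^{d(u,t)} ] / log2(2 + outdeg(u)),

with decay β = 0.5. The numerator implements the stated contract —
nodes regulating the maximal number of TFs through the shortest paths
rank highest — and the logarithmic hub penalty prevents
high-out-degree nodes from scoring by indiscriminate connectivity.
This closed form is artifact-defined: the published key-node formula
is in prior literature not reproduced in the description this
pipeline follows, so the package documents its own choice prominently
and tests its contract properties (monotone in reach set, invariant
under relabeling, non-decreasing in R).

The null draws `n_permutations` (default 1000) TF sets of the
observed size uniformly without replacement from all TF nodes and
re-scores every node; distances to all TFs are computed once, so each
permutation is a column subset. Z-scores use each node's own null
mean and sd (sd = 0 yields an `Inf` sentinel and is excluded from FDR
reporting). The empirical FDR at rank r is the null-average count of
top-r permutation scores meeting or exceeding the observed rank-r
score, divided by r, clipped to [0,1] and made monotone by cumulative
maximum; selection is FDR < 0.05 and requires at least 100
permutations. The null preserves set size only, not the degree
structure of the observed TF set — a documented limitation shared
with simple permutation designs.

The two DEG directions run independently end-to-end, producing
separate up- and down-regulated master-regulator tables. How a
direction label attaches to a regulator is not specified anywhere
authoritative; running the directions separately is the cleanest
interpretation and is flagged in the output. The TF set handed to
this stage defaults to the union of the enriched PWMs and the
composite-module members (`--tf-source {enriched,module,union}`),
since the stage description does not say which feeds forward; union
is the least lossy choice and either pure source is one flag away.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of their parameters and seed.

* `simulate_counts`: NB counts, `mu_gs = lib_g * q_g * 2^{±lfc}`,
  log-normal abundances, common dispersion; defaults 3 replicates per
  group (the donor-replicate design of the motivating experiments),
  2000 genes as a working size tractable for exact tests, library
  sizes 2–4×10^5, dispersion 0.1 and planted |logFC| = 1 — values in
  the range typical for bulk RNA-seq of primary human cells.
* `simulate_promoters`: i.i.d. background at GC 0.5 (promoter-like),
  planted sites drawn from PWM column distributions (not fixed
  consensus) so scores have realistic spread, Poisson site counts at
  per-set rates. No Markov structure, no CpG islands, no repeats —
  the enrichment null is exactly exchangeable by construction, which
  is the property the tests need.
* `simulate_network`: Erdős–Rényi background on a fixed topological
  order (acyclic, so shortest-path truth is unambiguous; density
  0.005), TF nodes at the downstream end. Planted regulators get
  short paths to ≥ 90% of a designated active-TF set, partly direct
  and partly through shared relays — the connectivity profile of a
  genuine master regulator. Planted paths may create cycles, which is
  fine: the search never assumes acyclicity.
* `simulate_study` chains all three with motif names doubling as TF
  node ids, which is how the promoter stage hands its TF set to the
  network stage. Its planted regulator uses direct edges
  (radius 1), the strongest planting, so end-to-end recovery is
  judged against an unambiguous truth even when the promoter stage
  recovers only part of the TF set.

Passing planted-recovery tests therefore shows the machinery is
correct and calibrated under the stated statistical structure. It
does not show robustness to promoter composition bias, motif
redundancy, network curation artifacts, or correlated TF activity —
none of which the generators emulate, and all of which real data
have.

## Numerical choices and degenerate inputs

* Exact-test two-sidedness is by probability mass (all splits no more
  likely than observed), with a `1 + 1e-7` tie tolerance.
* Wilcoxon exact/approximate switch at group size 8; deep-tail
  p-values from the normal branch are floored at the smallest
  positive double rather than 0 so `-log10 p` stays finite.
* `mss` of windows containing `N` is −∞ internally (never a hit);
  a consensus matrix scores k/L for k matching positions, so score
  distributions can be lattice-valued — oracle-equivalence tests
  avoid cutoffs exactly on that lattice.
* Fold sentinel: enrichment fold is `Inf` when the No rate is 0 and
  `NA` when both rates are 0.
* Empty directions (fewer than 2 Yes promoters) skip with a warning
  rather than erroring, so one-sided experiments still run.
* Problem sizes in tests and the acceptance script (2000-gene null
  matrices, 200-promoter scans, 300-node networks, 200 permutations)
  are the package's chosen working sizes: large enough for the
  asymptotics the checks rely on, small enough to keep the full suite
  interactive.

## Known limitations

* The NB test uses one common dispersion; genes with atypical
  dispersion are mis-calibrated at the margin (no tagwise shrinkage).
* No TMM normalization and no multi-factor designs.
* Enrichment has no GC-matched background and no motif-redundancy
  reduction; closely related PWMs will co-enrich.
* The key-node score and the CMA complexity penalty are
  package-defined quantities; rankings are comparable within this
  package, not across implementations of similarly named scores.
* The permutation null conditions on TF-set size only.
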