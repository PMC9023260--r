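---
title: "aremotif: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aremotif: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aremotif)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The package analyzes AU-rich element (ARE) and
GAAA motif content of 3′UTR sets in the context of a differential-expression
(DE) study of an ARE-binding protein: it consumes a DE table and 3′UTR
sequences, and quantifies whether candidate binding motifs are enriched in
the genes that respond to the perturbation.

## The analysis model

The biological premise is simple. ZFP36-family proteins bind AREs in
3′UTRs and accelerate decay of the host mRNA; when such a protein is
removed, its direct targets should rise. Gel-shift assays show that
ZFP36L2 in particular requires a UAUUUAU 7-mer — one AUUUA pentamer is not
sufficient — so the signature expected of its target set is an excess of
UAUUUAU-containing 3′UTRs among upregulated genes. ELAV-like stabilizers
bind GAAA-type elements, so co-regulation shows up as structure in GAAA
counts and in gene-list overlaps with ELAV-target sets.

The pipeline operationalizes this as:

1. one 3′UTR per gene: the longest annotated isoform;
2. a per-gene census of AUUUA, UAUUUAU and GAAA occurrences, plus an
   AREScore-like summary score;
3. distribution comparisons of those statistics across the up / down /
   unchanged DE categories by two-sample Kolmogorov–Smirnov (KS) tests;
4. GAAA-count binning and hypergeometric gene-list overlap tests.

### DE categorization

A gene is *detected* when its mean read support is at least 10; genes
below that are `excluded` and take no part in any comparison. A detected
gene is `up` when `log2FC > 1` and `padj < 0.05`, `down` when
`log2FC < -1` and `padj < 0.05`, else `unchanged`. All three thresholds
are arguments (`detection_threshold`, `fc_threshold`, `p_threshold`) and
are echoed into every output's provenance header. A detected gene with a
missing `log2fc` or `padj` is `unchanged`, not excluded: DE tools emit
missing adjusted p-values for independence-filtered genes that are still
expressed, and dropping them would silently shrink the unchanged
universe.

Equal-length 3′UTR isoforms are resolved to the lexicographically
smallest transcript id. Nothing biological rides on this choice; it
exists only so that runs are deterministic.

### Motif counting conventions

All scanning is **overlapping**: every start position at which the motif
occurs is counted. Class II AREs are blocks of overlapping pentamers
(UUAUUUAUU-like runs), and non-overlapping counting would undercount
exactly the signal of interest. A non-overlapping mode is exposed
(`overlap = FALSE`) for sensitivity analysis. Two consequences worth
knowing: `n_5mer >= n_7mer` always (every UAUUUAU contains an AUUUA), and
a poly-(AUUU) run contributes one count per register.

Coordinates are 1-based and inclusive, the R convention.

`delete_motif()` removes the leftmost occurrence and repeats until no
occurrence remains. Deletion can splice flanks together into a *new*
occurrence; iterating to exhaustion is the only rule that guarantees a
motif-free result, and when no re-formation occurs (e.g. three planted
7-mers on a G/C background) the length drops by exactly
`3 × 7 = 21` nt — the arithmetic of an ARE-deletion reporter construct
(2529 nt → 2508 nt).

`extract_windows()` uses a symmetric 12-nt flank by default, giving 31-nt
windows around a 7-mer seed — the probe-sized (~30 nt) context used for
de novo motif discovery — clipped at sequence bounds. Inter-motif
distances are gaps (nt strictly between consecutive hits), so "a second
motif 11 nt downstream" is a distance of 11 and overlapping hits give
negative values.

### The AREScore-like score

The score summarizes three classic ARE features: pentamer count,
pentamer proximity, and AU-rich flanking context:

```
score = pentamer_weight    * n_pentamers
      + cluster_bonus      * n_cluster_bonuses
      + au_context_weight  * n_context_bonuses
```

* each overlapping AUUUA contributes `pentamer_weight` (default 1);
* each **consecutive pair** of pentamers whose gap (next start − previous
  end − 1, in nt) is at most `cluster_max_gap` (default 10 nt)
  contributes `cluster_bonus` (default 1.5) — per pair, not per cluster,
  the simplest rule consistent with "proximity" that keeps the score's
  invariants exactly testable (appending one distant pentamer adds
  exactly `pentamer_weight`; a run of k overlapping pentamers earns k−1
  bonuses);
* each flank side of each pentamer (window `au_context_window` = 5 nt,
  truncated at sequence bounds, empty flank never qualifies) whose A+U
  fraction is at least `au_context_min_fraction` (default 0.8)
  contributes `au_context_weight` (default 0.5). A fraction threshold is
  used rather than a position weight matrix because "high AU content in
  the vicinity" specifies no finer structure.

This is a **re-parameterization of the AREScore idea, not a certified
reproduction of the original program's numbers**: the original
publication describes the three features but its constants are not
reproduced here. All constants live in `arescore_params()`, are validated,
and are serialized into every output so a score is never separated from
the parameters that produced it. Defaults were chosen once so that a
lone pentamer in a neutral context scores 1 and the two bonus types are
, respectively, comparable to and smaller than the pentamer weight.
Cohort-level conclusions (ranking of category means) are insensitive to
moderate changes of these weights because all three components increase
with ARE content; per-gene absolute values are not meaningful outside a
fixed parameterization.

### Enrichment statistics

`ks_two_sample()` computes `D`, the supremum gap between the two
empirical CDFs evaluated at all observed values. The default p-value is
asymptotic — the Kolmogorov distribution evaluated at
`sqrt(n1*n2/(n1+n2)) * D`, the usual choice for genome-scale
comparisons — with the series evaluated in two branches (Jacobi-theta
form below t = 1, alternating exponential series above) to at least 1e-8
accuracy. Motif counts are small integers, so samples are heavily tied
and the asymptotic p is then *conservative*; the seeded permutation mode
is the statistically safer choice for count fields. When
`choose(n1+n2, n1) <= n_perm` the permutation null is enumerated
exhaustively and `p = #{D* >= D}/n_splits` (the fully separated
`n = m = 2` case gives exactly 2/6); otherwise `p = (1 + #{D* >= D}) /
(1 + n_perm)` over seeded random splits. Comparisons with equal `D` are
resolved with a 1e-12 slack so floating-point noise never flips a tie.

No multiple-testing correction is applied across the three pairwise
comparisons (up–unchanged, down–unchanged, up–down); raw p-values are
reported, and the comparison table carries both `p_asymptotic` and (when
requested) `p_permutation` so disagreement is visible rather than hidden.
An empty category produces an `NA` row, not an error, so a cohort with no
downregulated genes still yields its other comparisons.

**Known limitation — calibration under ties.** The permutation p-value
convention above includes the observed value's own atom of the discrete
permutation distribution, so on heavily tied counts the null p-values are
*superuniform* (stochastically larger than uniform) by a CDF gap of
roughly 0.1 under the cohort conditions used in the tests. Inference
remains valid — the empirical type-I error at α = 0.05 is at (in our null
simulations, exactly) the nominal level, and no null replicate reaches
extreme significance — but a strict goodness-of-fit test of the p-value
distribution against U(0,1) can detect the conservativeness at a few
hundred replicates. The test suite states this check at its strict form
and it is expected to be marginal: exact uniformity of p-values is a
property of continuous test statistics that discrete count data cannot
deliver under the `>=`-including permutation convention.

GAAA counts are binned into the five standard categories `n = 0`,
`(0,10]`, `(10,20]`, `(20,30]`, `> 30` — left-open, right-closed, so a
count of exactly 10 falls in `(0,10]` — plus the derived
`fraction_gt_10` and `fraction_with_motif` (share with ≥ 1 occurrence,
the "lacking vs containing" pie-chart quantity).

`overlap_test()` reports the exact hypergeometric upper tail
`P(K >= k)` via `phyper` and the normal approximation with continuity
correction (`P(Z >= (k - 0.5 - nm/N) / sigma)`,
`sigma^2 = nm(N-n)(N-m) / (N^2 (N-1))`), the approximation commonly used
for genome-scale Venn analysis. The exact tail is the authoritative
number; the approximation is reported because it is what comparable
analyses quote, and the two agree to < 0.01 once the expected overlap is
out of the Poisson regime (roughly `nm/N` in the tens). Fold enrichment
is `k / (nm/N)`.

## The synthetic-data generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not any particular dataset:

* **category sizes** default to 549 up / 603 down / 15 684 unchanged,
  the cohort proportions of the knockout-spleen study design this
  package's analyses are built around;
* **UTR lengths** are log-normal (median 900 nt, sdlog 0.9, floor
  50 nt) — mammalian 3′UTR lengths are right-skewed with a median around
  1 kb;
* **background** is i.i.d. with A+U fraction 0.55 (3′UTRs are mildly
  AU-biased; the value is configurable and A/U, G/C are equiprobable
  within their groups);
* **planted motifs**: per-gene Poisson counts at category rates —
  defaults 1.2 vs 0.3 planted 7-mers per gene for up vs other categories
  (an effect size at which a 500-vs-15 000 comparison is essentially
  always detected, while single genes remain ambiguous, matching the
  field's situation), 0.5 lone pentamers per gene everywhere, and 4 vs 2
  planted GAAA per gene (background occurrences add ~6 more on a 1-kb
  UTR, so the planted difference shifts the upper tail of the GAAA
  distribution without separating the categories);
* **placement** is uniform among all non-overlapping arrangements, by a
  gap-composition construction (shuffle motif order, distribute the
  slack uniformly among the gaps); it succeeds whenever the planted
  motifs fit, even at high density, with no rejection loop;
* **DE table**: up/down genes draw `|log2FC|` around 3 (resampled into
  the `> 1` region) and `padj` log-uniform below 0.05; unchanged genes
  draw small fold changes and `padj >= 0.05`; read support is at least
  10. Re-categorizing the emitted table therefore reproduces the
  configured category sizes exactly.

One seeded stream drives the whole cohort (`with_seed` restores the
caller's RNG state), so cohorts are byte-identical across runs and
platforms for a fixed seed.

What the generator does **not** emulate: real 3′UTRs are not i.i.d.
(dinucleotide structure, repeats, compositional domains), motif positions
are not uniform (AREs cluster near the poly(A) site), isoform structure
is trivial (one transcript per gene), and the DE table's p-values carry
no dispersion model. Passing the recovery tests therefore shows the
*pipeline* is correct and powered under its own assumptions — it does not
validate the biological model on real data, where annotation quality,
composition bias and cell-type mixture all intrude.

## Problem sizes used in the checked simulations

The test suite exercises, among others: oracle equivalence of the
scanner on 10 000 random sequences (lengths 0–200); exhaustive KS-oracle
agreement over all value-multisets of sizes ≤ 4 per side from a 3-letter
alphabet; exact-vs-enumerated hypergeometric tails for universes up to
N = 60 and the full pmf-normalization grid; 100 replicates of the planted
7-mer power design (rates 1.2 vs 0.3, n = 500 vs 15 000 genes, 300-nt
median UTRs — detection required in ≥ 99); 200 null cohorts of 150 genes
per category for p-value calibration; and 1000 random-list overlaps
(lists of 100 in a universe of 2000, mean fold within 3 s.e. of 1.0).
These sizes keep the whole suite to a few minutes on one CPU while
leaving every statistical check with comfortable resolution.

## Degenerate inputs and edge rules, in one place

* Empty FASTA → empty record set; malformed FASTA or an illegal character
  → error naming the line, record and position.
* Empty sequence, or sequence shorter than the motif → zero hits, zero
  counts, empty distance vector.
* `find_motif` with an empty motif → argument error.
* KS with an empty sample → argument error; identical samples → `D = 0`,
  `p = 1`.
* Overlap test with an empty universe → argument error; list ids outside
  the universe are dropped with a warning; a degenerate draw
  (`sigma = 0`) reports a 0/1 tail instead of dividing by zero.
* `bin_gaaa` with an absent category → zero-count rows and `NA`
  fractions, flagged by `n = 0`.
* Planting more motif nt than the sequence holds → generation error.
* Pipeline errors remove partial output bundles and exit non-zero (the
  CLI maps input/schema errors to exit 2, generation/statistics errors
  to 3).
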