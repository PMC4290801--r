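---
title: "Methods: differentially private SNP release by top-down specialization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentially private SNP release by top-down specialization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpdp)
```

## The release mechanism and its guarantee

`snpdp` releases a genotype table $D$ ($n$ individuals $\times$ $m$ diploid
SNP genotypes) as noisy counts of generalized *partitions*.  A randomized
algorithm $\mathcal{A}$ is $\varepsilon$-differentially private if for all
datasets $D, D'$ differing in at most one record and all outputs $\hat D$,

$$\Pr[\mathcal{A}(D) = \hat D] \le e^{\varepsilon} \,
  \Pr[\mathcal{A}(D') = \hat D].$$

The mechanism has four stages, with an explicit per-stage budget ledger
(returned in every release's metadata):

| stage | what it does | budget |
|---|---|---|
| blocking | split the $m$ SNPs into contiguous blocks of `block_size` | 0 (data-independent) |
| taxonomy | one generalization tree per block | 0 (public knowledge), or flagged |
| specialization | $h$ uniformly random cut refinements | 0 (never reads records) |
| noisy counts | each leaf partition count $+ \mathrm{Lap}(1/\varepsilon)$ | $\varepsilon$ |

The leaf partitions are disjoint and cover all records (an invariant the
test suite checks exhaustively on small instances), so the noising stage
costs a single $\varepsilon$ by parallel composition; everything before it
is independent of the records.  Conditioned on the specialization trace, the
release is a Laplace mechanism on the leaf-count vector, whose log density
ratio between removal neighbors is

$$\log\frac{f_D(y)}{f_{D'}(y)}
  = \sum_i \varepsilon\left(|y_i - c'_i| - |y_i - c_i|\right)
  \;\le\; \varepsilon \sum_i |c_i - c'_i| = \varepsilon.$$

`dp_audit()` verifies this bound analytically for every removable record
under many random traces, and `empirical_ratio_mc()` re-derives it from
actual runs by histogram comparison.  Conditioning on the trace is sound
because candidate selection is a data-independent coin: the same trace can
be replayed on a neighbor dataset.  To make that replay possible, one run
seed is split into two independent streams (selection, noise), so a release
is bit-reproducible from `(table, forest, parameters, seed)`.

Two deliberate conventions: **empty child partitions are retained and
noised** — suppressing them would leak the data's support set — and released
counts are **raw reals by default**; `rounded_nonnegative` adds a
presentation column $\max(0, \mathrm{round}(\cdot))$ (round-half-to-even),
which is pure post-processing.

## Taxonomies and the partition-count geometry

Because every specialization applies to *all* leaf partitions generalized to
the chosen node, the leaf set is always the cross product of the per-block
cut frontiers.  This has a consequence that is easy to miss: with a
two-level (**flat**) tree, one specialization jumps straight from the root
to *all* observed block values.  On a realistic panel (say 150 distinct
6-SNP values per block) five flat specializations would demand
$150^5 \approx 10^{11}$ noised rows — unrepresentable, and the noise mass of
the empty cells would drown all utility.  `specialize()` therefore guards
the partition count (`max_rows`, default 65,536) and the package provides
`build_prefix_taxonomy()`: a multilevel hierarchy that refines one SNP
position at a time (internal labels like `"AG * *"`), with branching at most
the number of genotypes per SNP (3 for a biallelic SNP).  Five prefix
specializations create at most $3^5 = 243$ rows.  Flat trees remain the
default for small worked examples; the evaluation pipeline uses prefix
trees.

Both constructions scan the data, so releases under them are stamped
`taxonomy: non-private`: strictly, a data-derived leaf set itself reveals
which values occur.  Only a user-supplied (public) taxonomy gives the clean
guarantee; `load_taxonomy()` accepts arbitrary multilevel JSON configs.  One
validation rule is deliberately lenient: an internal node may share its
label with a leaf in its subtree (leaf labels and internal labels are each
unique per tree).  Category nodes named after a prototype value — e.g. an
internal `"CT AG"` covering leaves `{CT AG, CT GG, TT AG}` — are the natural
way to express coarse groupings, and some released structures are only
expressible this way.

## Reconstruction rule for utility scoring

The release contains generalized labels, not genotypes, so per-SNP tests
need a reconstruction rule; the choice is genuinely open and is recorded in
the output metadata.  `reconstruct_snp_counts()` uses the maximum-entropy
default: each row's count, clamped to be nonnegative (fractional mass
allowed), is spread uniformly over the leaf block values under each of its
generalized labels, independently per block.  Fully specialized rows
contribute exactly their count to their literal genotypes, so the rule is
lossless in the $\varepsilon \to \infty$, full-specialization limit (a
tested invariant, along with exact mass conservation per SNP).

The nonnegativity clamp matters for interpretation: every empty cell
contributes $\mathbb{E}[\max(0, \mathrm{Lap}(1/\varepsilon))] =
1/(2\varepsilon)$ of spurious mass on average, biasing reconstructed
frequencies towards the leaf-composition prior.  Pool-frequency estimates
are therefore unbiased only where clamping rarely binds (large counts or
large $\varepsilon$); the test suite demonstrates both the unbiased regime
and the lossless limit.

## The membership attack

For individual $i$ with binarized genotype vector $x$,

$$\bar L = \sum_j x_j \log\frac{\hat p_j}{p_j}
 + (1 - x_j) \log\frac{1 - \hat p_j}{1 - p_j},$$

with $p$ the population minor-allele frequencies and $\hat p$ the pool's.
Design choices:

* **Binarization** (`per_allele`, default): each of the two allele copies is
  one Bernoulli trial against the *allele* frequency $p_j$, doubling the
  panel length; a `dominant` mode (carrier of $\ge 1$ minor allele) is
  provided for sensitivity analysis.
* **Frequency clamping** to $[1/(2n+1), 1 - 1/(2n+1)]$ keeps every log term
  finite, including monomorphic SNPs.
* **Power** at false-positive rate $f$ uses the nearest-rank $(1-f)$
  percentile of the non-member (test group) statistics as threshold and
  counts case statistics *strictly* above it — no interpolation ambiguity.
* For real data, $p$ is estimated from a reference group unrelated to case
  and control.  For *calibration experiments* the package's tests use the
  generator's true $p$ instead: a baseline estimated from the test group
  deflates the test individuals' own statistics (their alleles are inside
  $\hat p$'s competitor), which inflates apparent power even under the null.
* The **null scenario** is "$\hat p$ carries no membership signal".  Setting
  $\hat p = p$ literally makes every statistic exactly zero (all log terms
  vanish), so the null is implemented as $\hat p$ estimated from an
  independent cohort of the same population, which yields power
  $\approx f$ as it should.

At fixed pool size the attack's power grows with panel size; with $n = 200$
per group it is strong but not saturated at 311 SNPs and essentially
saturated at 610 — the acceptance suite measures both.

## The synthetic cohort generator

`generate_population()` / `sample_cohort()` emulate the shape of the
case/control/test SNP panels used to benchmark genomic privacy methods:

* minor-allele frequencies uniform on $(0.05, 0.5)$;
* Hardy–Weinberg sampling — two independent Bernoulli allele copies per SNP;
* a subset of *effect SNPs* whose case-group frequency is shifted additively
  by `delta`.

The two stock scenarios are `chr2_like` (311 SNPs, 20 effect SNPs) and
`chr10_like` (610 SNPs, 40 effect SNPs), both with 200 individuals per
group and `delta = 0.15`.  The shift was fixed, before any pipeline tuning,
so that a typical effect SNP ($p \approx 0.3$, 400 alleles per group) has an
allelic $\chi^2$ around 19: nearly always significant at $5 \times 10^{-2}$
and near the $10^{-5}$ boundary — giving truth-set sizes that shrink across
the cutoff ladder the way real panels do.  Model seeds are fixed per
scenario (the panel is an input, not a random variable); cohort draws are
seeded by the caller.

Deliberately **not** modelled: linkage disequilibrium, population structure,
genotyping error.  Both the attack and the utility statistic treat SNPs
independently, so none of the tested contracts would change; but absolute
power and error rates on real, LD-structured panels will differ, and
passing tests here say nothing about those absolute values.

## What degrades, and what saturates, as the budget shrinks

Shrinking $\varepsilon$ adds noise to every released count.  Precision, F1
and accuracy of significant-SNP recovery degrade monotonically, and attack
power does not increase — both are tested properties (averaged over 50
seeds, tolerance 0.05 for Monte-Carlo error).  *Sensitivity alone is not
monotone*: under heavy noise the association scan on reconstructed counts
calls nearly every SNP significant, which saturates sensitivity near 1
while precision collapses towards the truth base rate.  An
everything-significant predictor is maximally "sensitive" — which is why
sensitivity on its own is a poor utility scale for noisy releases, and why
the evaluation reports all four metrics.

The same effect shapes the high-sensitivity/low-precision signature that
very noisy pipelines show.  Under this package's study conditions
($\varepsilon = 1$, $h = 5$, prefix taxonomies, 200-record groups) the
released counts are comparatively accurate: false positives dominate at
loose cutoffs (sensitivity well above precision at $5\times10^{-2}$ and
$10^{-2}$), but at $10^{-5}$ the surviving predictions are mostly true
effects and precision can exceed sensitivity.  The acceptance suite states
the strict all-cutoffs form of the signature and reports its outcome
honestly.

A further empirical point the pipeline makes visible: with *data-derived*
taxonomies the released leaf sets themselves carry cohort information, and
the membership attack on reconstructed pool frequencies retains substantial
power even at $\varepsilon = 1$.  That is precisely the leak the
`taxonomy: non-private` stamp warns about; a strictly private deployment
needs owner-supplied trees.

## Numerical and procedural conventions

* Genotypes are normalized to alphabetical allele order (`"GA"` →
  `"AG"`); all label matching is exact on canonical spellings, sorted in the
  C locale so results are collation-independent.
* Release rows are ordered lexicographically by generalized labels; counts
  are serialized at full precision (`%.17g`), with rounding confined to the
  presentation column.
* Specialization stops early (with a logged message, not an error) when
  every cut node is a leaf before $h$ steps.
* Minor-allele ties (frequency exactly 0.5) break towards the
  lexicographically smaller letter.
* Degenerate $\chi^2$ inputs: all-zero rows/columns are dropped (reducing
  the degrees of freedom); if fewer than two rows or columns remain the
  statistic is 0 with $p = 1$; an all-zero table is an error.
* Empty truth sets in utility reports are flagged
  (`no_significant_snps = TRUE`) rather than raised.

## Problem sizes used by the test suite

The suite runs everything at desk scale, chosen to keep the full run in a
few minutes on one core: exhaustive privacy audits on a 10-record, 8-SNP
worked example (every removal neighbor × 20 traces; Monte-Carlo at $10^4$
runs per budget); statistic oracles at $10^4$ random inputs; attack
calibration and monotonicity properties at 50 seeds; the full pipeline at
100 trials of the chr2-like scenario; and runtime-linearity of `anonymize()`
across 1,000–8,000 records at 300 SNPs ($R^2 \ge 0.9$ for a linear fit,
matching the mechanism's $O(|D| \times m)$ design).
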