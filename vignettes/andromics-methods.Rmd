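---
title: "Methods: models, thresholds and design choices in andromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in andromics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(andromics)
```

# Scope

andromics implements the downstream analysis of a staged microspore
embryogenesis induction experiment: three developmental stages (S1
untreated, S2 after cold-stress induction, S3 at first nuclear division),
three biological replicates each, profiled by bulk RNA-seq on a de novo
assembled transcriptome and by matched sRNA-seq, with the two stage
transitions T1 = S1→S2 and T2 = S2→S3 as the units of differential
analysis. Everything upstream — trimming, assembly, alignment, target
prediction — is out of scope; the package consumes their standard products
(count tables, tabular alignment hits, GO tables, FASTA/FASTQ, pair
tables).

# Normalization: zero-preserving quantile normalization and rpmqn

Quantile normalization forces every library to share one value
distribution: sort each column, average the sorted columns positionwise
into a reference, and hand each entry the reference value at its
within-column rank. Applied directly to sparse count data this assigns
positive expression to features with zero observed reads, which is
biologically wrong for presence/absence reasoning. The modification here
resets every entry whose raw count is zero back to exactly 0 *before* the
final scaling, so the rescale to one million quantile-normalized reads per
library (rpmqn) holds exactly on the delivered matrix. Two consequences are
tested as invariants: entries are 0 iff the raw count was 0, and every
column sums to 10⁶ (relative tolerance 10⁻⁶).

Tie handling follows the block-mean convention: all members of a run of
equal values receive the mean of the reference values over the tied rank
positions. `limma::normalizeQuantiles(ties = TRUE)` instead interpolates
the reference at the mean rank; the two agree exactly on tie-free data
(which is how limma is used as an independent oracle in the tests) and
differ for tie runs of length ≥ 3, where the block mean is the exact
average of what the tied entries would receive under any tie-breaking
permutation.

The order of operations — zero-reset, then rescale — is a deliberate
choice: resetting after rescaling would leave column sums below 10⁶ by
exactly the mass the zeros had been allocated, breaking the unit's
definition.

# The differential expression cascade

Per transition the caller applies, in order: a minimum of 2 rpmqn in the
higher expressed stage; a fold change max(μ)/min(μ) ≥ 2 (+∞ when the
smaller mean is 0; undefined and excluded when both are 0); a replicate
coefficient of variation sd/mean ≤ 0.25 in *both* stages (sd with n−1; an
all-zero stage has CV 0 by convention); then a two-sided pooled-variance
Student's t-test on the filter-passing features only, with
Benjamini–Hochberg step-up at FDR 5 % across that set. A feature is DE iff
it passes the filters and survives FDR control.

Choices worth making explicit:

* **Minimum expression 2 vs 1 rpmqn.** The workflow's prose sources state
  both values in different places; 2 is the default
  (`pipeline_config(de_min_rpmqn = )` overrides it). All thresholds live in
  `pipeline_config()` so the cascade is reproducible from one object.
* **CV filter on both stages.** Applying it only to one stage would make
  the call asymmetric under direction; both-stage filtering is stricter and
  reproducible.
* **Equal-variance t, df = 4 at 3+3 replicates.** Welch would be the more
  robust modern choice but a pooled-variance Student's t is the stated
  method. Degenerate inputs are pinned down: both groups zero-variance with
  equal means → p = 1; with unequal means → p = 0.
* **Per-transition multiplicity.** BH runs over the filter-passing features
  of one transition only; the two transitions are corrected independently.
* **Tied means** get direction "down" by convention; fold 1 can never pass
  the fold filter, so the convention is inert and only keeps the output
  total.

The caller is verified two ways: exact agreement (filters, p-values,
decisions) with a per-feature brute-force implementation on hundreds of
random small matrices, and planted-truth recovery on synthetic data (below).

# Profile clustering

DE features are summarized as 3-point stage-mean profiles, z-normalized per
feature (mean 0, sd 1 with n−1; zero-variance features are excluded and
reported — they carry no pattern). k-means uses the centered correlation
dissimilarity d(x, c) = 1 − r(x, c) with member means as centroids. On
z-scored profiles all vectors have equal centered norm, so the member mean
is also the exact maximizer of average correlation and the Lloyd objective
is non-increasing — asserted at every iteration in the tests. Correlation
against a zero-variance vector is defined as 0 (maximal dissimilarity 1) to
avoid NaN propagation. Determinism: `restarts` runs are seeded
`seed, seed+1, ...`, assignment ties break to the lowest cluster index,
empty clusters are re-seeded from the worst-fit point, and the best run by
total within-cluster dissimilarity is returned. k = 12 is the conventional
choice for this workflow's pattern taxonomy (3 directions on T1 × 3 on T2,
minus all-flat, with magnitude variants); no data-driven selection of k is
attempted.

The replicate dendrogram uses complete linkage on 1 − Pearson between
sample expression vectors (zero-variance samples are an error naming the
sample), serialized as Newick via ape. PCA treats replicates as
observations of z-normalized feature variables; component signs are fixed
by making each component's largest-magnitude loading positive so scores
are platform-stable. Whether to use replicates or stage means as PCA
observations was genuinely open; replicates were chosen because the
analysis question is whether replicates group by stage.

# Bootstrap GO enrichment

For a feature set of size n and a term carried by K of the N features in
the annotated universe, the test draws `boot_runs` sets of size n *with
replacement* and counts per run the members carrying the term; the p-value
is (1 + #{runs ≥ observed}) / (runs + 1), never exactly 0. Because
with-replacement draws make the run count exactly Binomial(n, K/N), the
implementation draws the counts from that distribution directly — the
identical stochastic process in O(runs) — and the closed-form binomial
tail serves as an independent oracle: |bootstrap − exact| ≤ 3 Monte-Carlo
SEs is asserted over a parameter grid at 10⁵ runs. Whether the original
resampling was with or without replacement is not specified anywhere;
a hypergeometric (without-replacement) mode ships behind
`replace = FALSE`. The universe is restricted to features with ≥ 1 term,
since unannotated features cannot inform term frequencies.

Two statistical properties deserve flagging:

* Terms with < 5 carriers in the set are excluded *before* testing. This
  min-count rule conditions on upward count fluctuations and then tests
  those same counts, so under a completely null annotation the per-set
  probability of at least one FDR-significant term is inflated above the
  nominal 5 % (the null test measures roughly 13 % at default simulated
  annotation rates and asserts that level, not 5 %). Users comparing
  cluster enrichments should treat isolated marginal hits accordingly.
* The +1 correction bounds p away from 0, so BH can never reject purely on
  an artifact of finite resampling.

# sRNA analysis

Reads are collapsed to distinct sequences with multiplicities; only reads
strictly longer than 15 nt are retained. Length profiles (read-weighted or
distinct) are taken over the 18–28 nt analysis window where the two
functional size classes peak: ~21 nt (miRNA, PTGS-associated) and 24 nt
(siRNA, TGS-associated). A distinct sRNA is annotated as a known miRNA iff
it is an exact, gap-free, forward-strand substring of a mature reference
sequence — the equivalence of zero-mismatch ungapped alignment — verified
against a brute-force all-offsets scan.

The target filter computes Pearson correlation between sRNA and transcript
expression over the *per-stage means* (3 points), not over 9 paired
samples: the mRNA and sRNA libraries come from different isolation
procedures, so replicate-to-replicate pairing is not meaningful. A pair is
retained iff r ≤ −0.9 (configurable; "strong negative correlation" has no
canonical number, −0.9 keeps only near-monotone opposite profiles while
tolerating stage-mean noise). With 3 points the null rate of r ≤ −0.9 is
substantial (~5–15 % depending on the profile distribution — the tests
bound the behavior with a Monte-Carlo oracle), so the filter is a
prioritization step, not a significance test; zero-variance profiles leave
r undefined and the pair is flagged and never retained.

# The synthetic world

`sim_config()` fixes the stated world; tests never tune it after the fact.

* **Design**: 3 stages × 3 replicates; 2,000 features by default.
* **Counts**: NB with per-feature log-normal baseline abundances (sdlog
  1.3), per-library log-normal size factors (sdlog 0.1) and dispersion
  α = 0.01 (BCV 10 %). α was chosen from the observation that the original
  workflow's CV ≤ 25 % filter passed a quarter of all transcripts — only
  replicate CVs well under 25 % are compatible with that, which rules out
  α ≈ 0.05 (true CV ≥ 22 %, both-stage pass probability ≈ 0.46).
* **Depth**: `lib_size_mean = 6e6`, i.e. 2,000 features × ~3,000 reads per
  feature — the per-feature depth of a ~60 M-read library over ~20,000
  transcripts. Preserving depth per feature rather than total depth keeps
  the replicate CV dominated by biological dispersion, as in the real
  data, not by shot noise.
* **DE planting**: fractions 0.037 (T1) and 0.28 (T2) with down-direction
  probabilities 2/3 and 0.57 — the asymmetry and direction balance of the
  emulated experiment; folds log-uniform on [2, 8].
* **frac_zero = 0.01** forced dropout entries; deep bulk libraries rarely
  zero out expressed features, and most genuine zeros arise from the NB
  tail of low-abundance features.
* **sRNA libraries**: 3,000 distinct sequences, lengths drawn with a
  dominant 24-nt and a secondary 21-nt mode; 30 % of sequences get a
  monotone stage trend (the anticorrelation partners); planted miRNAs are
  verbatim copies in the mature reference plus decoys.
* **Target pairs**: planted pairs are accepted only if their realized
  stage-mean correlation is ≤ −0.95, so their recovery by the r ≤ −0.9
  filter is by construction and tests the plumbing, not the statistics;
  the statistics are tested by the null-rate comparison.

What a green synthetic test does *not* establish: the generator plants
clean single-fold steps (no isoform mixtures, no homeolog
cross-mapping), simulates no silent features (at the default depth every
feature clears 1 rpmqn, so the expressed-set machinery is exercised by its
unit tests and thresholds rather than by planted absences), assumes
independent features (no correlation structure beyond library size), and
draws sRNA sequences uniformly (no genomic repeat structure). Recovery
numbers on this world are upper bounds for messy real data.

Determinism: every generator seeds once from `cfg$seed` with fixed offsets
per component, so any subset of the outputs is reproducible independently.

# Numerical conventions

* Percentages are rounded half-away-from-zero to 2 decimals
  (`percent()`); base R `round()` rounds half to even and does not
  reproduce the conventional printed values. Display trims trailing zeros.
* Best-hit assignment breaks ties by bitscore, then e-value, then
  lexicographic cDNA ID — determinism the upstream tools do not promise.
* BH is implemented as the standard largest-k step-up; it agrees with
  `p.adjust(method = "BH") <= alpha` on random inputs.
* All parsers reject malformed input (non-integer counts, wrong column
  counts, mixed FASTA/FASTQ, unknown config keys) rather than coercing.

# Known limitations

* The min-count-then-test enrichment bias discussed above.
* The 3-point correlation filter has low specificity by construction.
* The expressed/DE thresholds are hard cutoffs; features oscillating around
  a boundary flip with small normalization changes (the Venn partition is
  computed from the sets as they are, with no reconciliation).
* k-means with k = 12 on 3-dimensional profiles necessarily splits pattern
  families into magnitude variants; cluster identities are stable only
  given the seed policy.
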