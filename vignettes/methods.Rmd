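---
title: "Cross-omics differential expression and network inference: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-omics differential expression and network inference: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xomics)
```

This vignette is the package's account of its statistical machinery:
the models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and
the places where the design was genuinely open and a choice had to be
made.

## 1. Paired RNA-seq differential expression

Each of the $n$ sample pairs (default $n = 6$) contributes an
independent two-sided Fisher exact test per gene on the table

$$\begin{pmatrix} x_c & N_c - x_c \\ x_t & N_t - x_t \end{pmatrix},$$

where $x$ is the gene's count and $N$ the library total. This is the
standard single-pair proportion test for count data without replicates;
it asks whether the gene's share of the library differs between the
control and treated sample of the same donor. p-values are
Benjamini–Hochberg corrected *within each pair* — each pair is a
separate family of ~$G$ tests — and the per-pair outcome is reduced to
$\{+, -, 0\}$ at level $\alpha = 0.05$ (adjusted p by default;
`use_adjusted = FALSE` switches to raw p, and the choice is recorded in
the output metadata).

The consensus rule calls a gene up-regulated when at least `min_same =
4` pairs are significant up and at most `max_opposite = 1` pair is
significant down, symmetrically for down-regulation. Over the $3^6 =
729$ possible significance patterns exactly 58 yield an up call; the
test suite verifies the implementation against brute-force enumeration
of all patterns.

Numerical choices: genes with zero counts in both samples of a pair get
$p = 1$ and direction 0; the log2 fold change used for direction and
ranking is the library-share ratio with a 0.5 pseudo-count on zero
cells, and it never feeds the test itself. The two-sided p is the sum
of all hypergeometric point masses not exceeding the observed one
(identical to `fisher.test`, verified against it in tests), computed by
direct enumeration of the support — the support has $x_c + x_t + 1$
points, so this is cheap even for deep libraries and vectorizes over
genes.

A known property of this construction is *compositional bias*: when a
few percent of genes carry strong asymmetric effects, every null gene's
library share shifts slightly in the opposite direction, and at high
depth the Fisher test can detect that shift consistently across pairs.
The consensus rule absorbs most of it; on synthetic data at the default
depth (~150 reads/gene) specificity stays above 0.9. Users analyzing
very deep libraries should be aware that the method, by design, has no
normalization beyond library totals.

## 2. Time-course proteome differential expression

Intensities over time points $\{0, 4, 16, 24\}$ h × 2 replicate
experiments are normalized in two stages: first every value is divided
by the grand mean of all control (time-0) intensities across proteins
(a global scale factor; it cancels in the next stage and is kept only
for reporting), then each protein's post-zero values are divided by
that protein's own control mean, giving per-column ratios.

**Cutoffs.** The two control measurements of a protein are biological
noise only, so the ratio between them calibrates the no-change
distribution. With $\sigma$ the standard deviation of the log2 control
ratios and normality assumed, the two-sided 95% band is

$$c_\text{up} = 2^{1.96\,\sigma}, \qquad c_\text{down} = 2^{-1.96\,\sigma},$$

which are exactly reciprocal ($c_\text{up} c_\text{down} = 1$). A
$\sigma$ of 0.158 gives the pair (1.24, 0.806).

Two subtleties, both deliberate:

* $\sigma$ is estimated on **all** proteins, outliers included — the
  interval is what subsequently *defines* outliers, so it cannot be
  estimated on the post-exclusion set. Control-discordant outliers
  therefore inflate $\sigma$ somewhat; this inflation is what gives the
  any-time-point caller its specificity (see below) and mirrors how the
  estimate behaves on real data.
* Estimation is **pooled**, not per experiment. In this layout each
  experiment has one control column, so the control ratio necessarily
  crosses experiments and a per-experiment $\sigma$ is not
  identifiable; there is exactly one control ratio per protein.

**Outliers** are proteins whose control ratio falls outside
$(c_\text{down}, c_\text{up})$; they are excluded from calling (the
ratio is tested two-sided, so replicate order is irrelevant).

**Calling.** A protein is up-regulated when *any* post-zero ratio in
any experiment exceeds $c_\text{up}$, down-regulated when any falls
below $c_\text{down}$. If both occur, the call takes the sign of the
largest $|\log_2|$ excursion and a conflict flag is set (the source
procedure reports disjoint up/down sets and gives no tie rule; the
flag keeps the ambiguity visible). With a per-ratio two-sided level of
5% and six ratios per protein the naive family-wise false-positive rate
would approach 13%; the outlier-driven inflation of $\sigma$ pushes
the effective per-ratio level down enough that specificity on synthetic
data exceeds 0.97. Proteins with missing control values are dropped at
read time with a message; there is no imputation.

## 3. Cross-omics mapping and intersection

Proteome identifiers are carried onto transcriptome symbols by a
file-based one-to-zero-or-one map. Many-to-one collisions resolve by
*any evidence*: a symbol is DE if any source protein is; sources that
disagree in sign zero the symbol and are reported as conflicts. The
universe is the set of mapped symbols quantified on both platforms, and
both call vectors are restricted to it.

The up∩up and down∩down overlaps get exact hypergeometric
over-enrichment tails $P(X \ge k)$ with universe $N$ and the two
margins as marked/drawn counts — exact summation via the distribution
function, never a normal approximation. Because a single "intersection
p-value" is ambiguous (joint vs per-direction), the output reports
$p_\text{up}$, $p_\text{down}$ and their product, each labeled.

## 4. Modified two-tailed RRHO

Both lists are ranked by signed log fold change (descending; ties break
by score then symbol). Cell $(i, j)$ of the map tests the overlap $k$
of the top-$i$ of list A with the top-$j$ of list B against
Hypergeometric$(N, i, j)$ with $N$ the shared-symbol count. The
displayed value is $-\log_{10}$ of the smaller tail, signed positive
for over-enrichment ($k$ at or above expectation) and negative for
under-enrichment; the two-tailed p per cell is $2\min(\text{over},
\text{under})$ capped at 1. The Benjamini–Yekutieli step-up correction
is applied across all cells — BY is valid under arbitrary dependence,
which the strongly overlapping cells certainly exhibit.

The named modifications are interpretations (the modified upstream
implementation is not recoverable from its description) and are stated
explicitly:

* tails are computed in log space and floored at the smallest
  representable positive double, so no cell reports a literal $p = 0$;
* all cells attaining a quadrant's minimal corrected p are reported,
  not an arbitrary first;
* lists of unequal composition reduce to their shared symbols (logged),
  the grid is rectangular over each list's own length, and $N$ is the
  shared count — which accommodates asymmetric up/down counts between
  the lists;
* quadrant summaries split each axis at half length; the concordant
  quadrants (up-up, down-down) take minima over *over*-enriched cells,
  the discordant quadrants over *under*-enriched cells, since on a
  two-tailed map discordance (one list's top overlapping the other's
  bottom) is exactly depletion of top-top overlap.

The default grid step is $\max(1, \lfloor L/100\rfloor)$ so toy and
realistic inputs both render. Display logs are base 10.

## 5. Prior network assembly

Enrichment exports are thresholded per source convention — adjusted
p < 0.05 for TFBS-enrichment style tables, raw p < 0.001 for
upstream-regulator style tables — and expanded regulator × target-list
into edges. The regulator set is unioned with the DE symbols (overlap
reported), and the prior is the concatenation of all sources restricted
to edges with both endpoints in that augmented set, self-loops dropped,
deduplicated by (regulator, target) while retaining the multiset of
source tags. Symbols compare uppercase; alias resolution is out of
scope. Databases supplying undirected pairs can be marked as such and
are expanded to both orientations. Assembly is idempotent: feeding a
built prior back through produces the same edge list.

## 6. Random-forest network inference

Per-target regression forests score candidate regulators by impurity
importance — the total decrease in residual sum of squares from splits
on the variable, averaged over trees (`randomForest`'s
`IncNodePurity`). Expression is log2-transformed and each feature is
divided by its own standard deviation (zero-variance features are
dropped with a message); for RNA-seq, expression is floored at 0.1
before fold changes are formed.

* **Directed, lagged (time course):** the target vector is the
  feature's values at all post-zero observations and the predictors are
  all other features' values one time step earlier in the same
  replicate; unequal spacing (0→4→16→24 h) is treated as consecutive
  steps, as the observation-label pairing implies.
* **Undirected (fold changes):** all features over the $n$ pairs; the
  score of an unordered pair is the maximum of the two directed scores.

Defaults: 20 000 trees (the reference setting; a few hundred suffice at
these problem sizes and the tests use 300–500), `mtry = floor(p/3)`
with $p$ the number of predictors of the design at hand (a fixed
constant would not generalize across gene-set sizes), self-regulation
excluded.

**Permutation null.** Each permutation shuffles every feature's
observations independently — preserving marginals while destroying all
cross-feature association, which is the stated purpose of the shuffle —
and reruns the identical inference; all scores pool into one null
sample (a single pooled null, matching the singular "null
distribution"; the default is 100 permutations, configurable).
Empirical p-values use the add-one form
$p = (1 + \#\{\text{null} \ge s\})/(1 + n_\text{null})$ so $p = 0$ is
impossible. Selection keeps an edge when $p < 0.001$, or $p < 0.05$
when the edge is in the prior (strict inequalities, as printed;
undirected edges match the prior in either orientation). The two
platform networks merge by unordered pair; edges found in both get
provenance `both` and keep the directed orientation, and the output
carries the provenance × prior breakdown.

## 7. The synthetic-data generators

The generators produce every input the pipeline consumes, with truth
labels, under the study-like default conditions: 6 RNA-seq pairs;
proteome time points 0/4/16/24 h × 2 replicate experiments; control
log2-ratio sd 0.158; outlier fraction 0.055 (the analog of 394/7091
flagged proteins); DE fraction 0.05 at |log2FC| = 2 for counts and
2-fold for proteins.

* **Counts:** negative binomial around gene-specific lognormal
  baselines; both samples of a pair share a donor-specific baseline
  wobble, so the within-pair contrast sees only residual dispersion
  (default 0.05 — within-pair technical plus treatment-response
  variation, deliberately smaller than between-donor biological
  dispersion). Treated means are scaled exactly by $2^{\pm\text{lfc}}$.
  Default depth is ~150 reads/gene with 10% between-sample jitter —
  enough for the consensus caller to reach sensitivity and specificity
  ≥ 0.9, the regime the method is intended for.
* **Proteome:** intensities are baseline × trajectory ×
  $2^{N(0,\sigma/\sqrt2)}$ noise per measurement, so the
  between-control ratio has log2 sd $\sigma$ — the parameterization
  under which the estimated cutoffs reproduce (1.24, 0.806) at the
  default $\sigma = 0.158$, which is how that value was back-derived in
  the first place. Responder trajectories are piecewise monotone: flat
  until a random post-zero onset, then ramping to the full effect at
  the last time point, so early- and late-onset responders both
  exercise the any-time-point rule. Outliers get a ±5σ/2 log2 shift
  split oppositely across the two control columns only — treatment
  columns untouched — so only the control-ratio filter can catch them.
  Optional planted regulation makes targets follow a lagged linear
  response to their regulators' previous-time-point deviations.
* **Maps and priors:** ortholog maps realize unmapped and many-to-one
  fractions exactly (rounded counts); prior edge lists contain exactly
  `round(overlap_fraction × n_edges)` true edges, the rest sampled from
  non-true directed pairs without duplicates.

What the generators do **not** emulate: peptide-level missingness and
rollup, isotope-impurity structure, batch effects, correlated gene
programs beyond the planted network, real dimensions of the motivating
datasets, or annotation alias mess. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under its own
assumptions, not performance on any particular real dataset; the
headline counts of the motivating study (85/122 common genes, 3082
prior edges, 416 merged regulations) depend on its deposited data and
commercial databases and are structural analogies here, not targets.

## 8. Reproducibility and problem sizes

One master seed fans out into fixed per-stage substreams (a pure
arithmetic derivation, no RNG state shared across stages), so any stage
can be regenerated in isolation and two runs of `run_pipeline()` with
the same configuration are byte-identical — the suite asserts this on
the emitted TSVs. The default pipeline configuration scales the
problem down (120 genes, 200 trees, 20 permutations) so a full run
takes seconds; the recovery and calibration tests use 800–2000 features
and 100 permutations with 500 trees, sizes at which the measured
quantities (sensitivity, specificity, AUROC, null calibration) are
stable to well within their acceptance margins.
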