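---
title: "Scoring read-mapping uncertainty: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring read-mapping uncertainty: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its method: what is being
modeled, which knobs matter, what the synthetic-data generator does and
does not emulate, and where a genuinely open design choice was settled —
and why.

## The quantity being estimated

A multi-mapping read (MMR) is a read whose alignments tie at the best
score across two or more genomic locations. For a gene $i$, let
$G_i$ be the set of reads assigned to its genomic span and
$U_i \subseteq G_i$ the uniquely mapping subset. The gene's true read
count lies between $|U_i|$ (discard every ambiguous read) and $|G_i|$
(keep them all). Taking the midpoint of that interval as the working
estimate yields the ambiguous-read proportion

$$D_4 = 1 - \frac{|G_i| + |U_i|}{2\,|G_i|} \in [0, 0.5],$$

which is 0 when every read is unique and reaches its ceiling of 0.5 when
no read is. $D_4$ is observable only where reads were assigned; genes
with $|G_i| = 0$ are excluded from modeling and reported as Low with all
features 0.

$D_4$ is noisy gene by gene, so it is not reported directly. Instead it
is regressed on three stable gene-level features, and the fitted value —
the **D-score** — is the reported uncertainty measure. The regression
borrows strength across genes: two genes with the same duplication
structure get the same score even if read sampling fluctuated
differently in their read sets. Treating the fitted value as the score
is an interpretive choice; the alternative (reporting $D_4$ itself)
would discard the features entirely and with them the ability to score
genes in new samples from sequence structure.

## Features

- **D1, genomic.** For each candidate partner $y$, a local alignment of
  the two gene sequences gives an identity fraction
  $ss_{i,y}$ (matches over aligned columns) and the length $l_{i,y}$ of
  the longest run of consecutive identical bases;
  $D_1 = \max_y ss_{i,y}\, l_{i,y}$. The product deliberately mixes a
  rate and a length: among partners of equal identity, the one with the
  longer uninterrupted match is the more dangerous source of ambiguous
  reads, because reads are contiguous substrings.
- **D2, transcriptomic.** The largest fraction of $G_i$ consisting of
  MMRs shared with one partner,
  $D_2 = \max_y |G_i \cap G_y|_{\mathrm{MMR}} / |G_i|$. This measures
  ambiguity realized in *this* dataset, whereas D1 measures its genomic
  potential.
- **D3, network.** $D_3 = \log_{10}(|S \cup M| + 1)$, where $S$ are
  partners with a significant similarity hit and $M$ partners sharing at
  least one MMR. A gene confusable with many locations is worse off than
  one confusable with a single duplicate, even at equal D1/D2.

The regression consumes min-max-normalized features (each mapped to
$[0,1]$ over the modeled genes); the report prints the raw values, whose
scales (D1 in identity-weighted base pairs, D2 a fraction, D3 a log
degree) are individually interpretable.

### Similarity gates

The similarity engine is a Smith–Waterman local alignment (match $+1$,
mismatch $-1$, gap open $-2$, gap extend $-1$) computed by
`Biostrings::pairwiseAlignment`; both orientations of the partner are
tried, and arguments are ordered canonically so the result is symmetric
under co-optimal-alignment tie-breaking. A hit enters $S$ (and
contributes to D1) only if its alignment score is at least `min_score`
(default 20), its identity at least `min_identity` (default 0.8) and its
match run at least `min_match_len` (default 30 bp, i.e. a substantial
fraction of a read length). Without these gates, any weak local match
would put nearly every gene pair into $S$ and D3 would saturate. The
all-vs-all comparison is bounded by a candidate screen: pairs sharing at
least one MMR, plus pairs sharing at least `min_shared_kmers` (3) exact
`kmer_size`-mers (15) — two random 1 kb sequences share none, while any
biologically meaningful duplication shares many.

### Read handling

Multiplicity is established per countable unit (a read, or one mate of a
pair, identified as `read/1`, `read/2`): the `NH` tag when present,
otherwise the count of that unit's records tying at the maximal `AS`
score, otherwise the record count. Secondary records (flag 0x100) count
toward multiplicity — they encode the alternative locations that define
an MMR — while supplementary records (0x800) do not. Assignment to a
gene requires an aligned CIGAR block (M/=/X/D runs; N splits blocks) to
overlap the gene span by at least `min_overlap_bp` (default 1), so a
spliced read whose intron merely spans a gene is not assigned to it.
Assignment uses the annotated genomic span, not exon structure, because
every feature here is defined over genomic regions; annotations at other
feature levels can be scored by setting `feature_types`.

## The regression

The elastic net minimizes

$$L(\lambda_1, \lambda_2, \beta) =
  \lVert y - X\beta \rVert_2^2 + \lambda_2 \lVert \beta \rVert_2^2
  + \lambda_1 \lVert \beta \rVert_1,$$

with an unpenalized intercept, solved by cyclic coordinate descent
(relative tolerance $10^{-7}$, at most $10^5$ sweeps). The mixing
parameter `alpha` is defined as the **L2 fraction**:
$\lambda_2 = \alpha\,\lambda_{\mathrm{tot}}$ and
$\lambda_1 = (1-\alpha)\,\lambda_{\mathrm{tot}}$, so `alpha = 1` is
ridge and `alpha = 0` the lasso. **This is the reverse of the glmnet
convention**; it is stated on every relevant help page because silently
swapping the two penalties is an easy and damaging mistake. The default
`alpha = 0.5` splits the penalty evenly: the L2 half keeps the three
correlated features grouped (duplicated genes push D1, D2 and D3
together), the L1 half can still zero a feature that carries no signal
in a given dataset.

$\lambda_{\mathrm{tot}}$ has no natural default, so it is chosen by
seeded 5-fold cross-validation over a 50-point logarithmic grid running
from $\lambda_{\max}$ (the smallest all-zeroing penalty,
$2\max_j |x_j^\top y_c| / (1-\alpha)$) down four decades, warm-starting
each fit from the previous penalty's solution. Fold assignment is a
seeded permutation, so a fixed seed reproduces the selection exactly.

Predictions are floored at 0 — the D-score is an uncertainty magnitude —
but not capped: the 0.5 ceiling belongs to $D_4$, and imposing it on
fitted values would hide a badly miscalibrated fit rather than reveal
it.

## Mixture modeling and categorization

D-score distributions are multi-modal in practice: a large mass of
clean genes near 0, and one or more modes of duplicated genes. The
package fits 3-component Gaussian and Gamma mixtures to the positive
D-scores. Initialization is 1-d k-means (`stats::kmeans`, 10 seeded
random restarts, best within-cluster sum of squares); EM then alternates
posterior responsibilities (E) and weighted parameter updates (M) until
the relative log-likelihood change falls below $10^{-6}$ or 500
iterations. Gaussian M-steps are the weighted MLE with biased ($1/N_k$)
variance denominators, matching the k-means-side initialization
formulas. The Gamma M-step uses responsibility-weighted method of
moments ($\mathrm{shape} = m^2/v$, $\mathrm{scale} = v/m$) rather than
digamma Newton iterations: on samples hugging zero the moment update is
robust where the likelihood update is fragile, at the cost of EM
monotonicity holding only to about $10^{-6}$ rather than exactly — the
tolerance the convergence test uses.

Exact zeros are excluded from the fit: genes with no detected
uncertainty form a point mass that degenerates a continuous mixture, and
their category is not in doubt — they are Low by construction. For the
Gamma candidate the remaining values are clipped at $10^{-6}$.

Family selection is by BIC, $p\ln n - 2\hat L$ with $p = 3k - 1$ free
parameters, minimized. A historical variant of this criterion,
$-2k\log n - 2\hat L$, decreases in both $k$ and the fit and therefore
cannot be minimized meaningfully as a complexity penalty; it is kept
available as `mixture_bic(mode = "legacy")` for auditing older outputs,
but plays no role in selection. Ties break toward the Gaussian family,
whose cutoffs have a closed form.

### Cutoffs

The Low/Medium/High boundaries are the equal-density points of adjacent
components. For Gaussians the intersection is the root of a quadratic in
$x$; the root between the two component means is kept, equal-variance
pairs reduce to a linear equation (the midpoint for equal weights), and
if no admissible root exists a grid search between the means takes over
with a warning. For Gammas no closed form exists; both densities are
evaluated on a 10 000-point uniform grid between the two component
modes, and the cutoff is the mean of the last grid point where the lower
component dominates and the first where the upper one does — with a
midpoint-of-modes fallback if they never cross.

The densities are compared **unweighted** (mixing weights omitted) by
default, with the weighted variant behind `weighted_cutoffs = TRUE`. The
unweighted rule is the package's primary definition of the boundary; the
weighted one is the statistically conventional posterior-odds boundary,
and the two differ when component weights are very unequal — exactly the
situation of a dominant Low component — where the unweighted rule moves
the boundary toward the large component and labels more genes Medium.
Both are deliberately exposed.

Boundary ties go to the higher category (left-closed intervals: Low is
$d < c_1$, Medium $c_1 \le d < c_2$, High $d \ge c_2$). If EM prunes a
collapsed component and only two remain, the single cutoff separates Low
from High with no Medium band.

### Alternative likelihood

For a gene categorized into component $i$,
$s_d = \max\{1 - F_{i-1}(d),\, F_{i+1}(d)\}$ — the strongest claim an
adjacent component's CDF can make on the gene's D-score. Edge categories
have one neighbor and use that single term; $s_d$ is clamped to
$[0, 1]$. Genes deep inside a component get $s_d$ near 0, genes near a
cutoff approach the neighbor's tail mass there: within a category's
interval, $s_d$ peaks at the boundary.

## The synthetic-data generator

The generator exists so that every claim in the test suite can be
checked against ground truth. `simulate_genome` places `n_genes` random
genes on one contig with 200 bp spacers and appends a diverged copy of a
`duplicate_fraction` of them; `simulate_reads_sam` draws error-free
reads uniformly from gene bodies at `mean_depth` and emits one SAM
record per exact occurrence of each read (and its reverse complement) in
the genome, with `NH` set to the occurrence count. Multiplicity is
therefore *defined* by exact string occurrence — an unambiguous oracle
for the MMR classifier, which is the point: aligner realism is not
needed to exercise the mathematics.

Default conditions: 200 genes, 30% duplicated, divergence 0 (exact
copies), 1 kb mean gene length, 100 bp reads, depth 20, seed 1.
Individual gene lengths are drawn uniformly between 0.6× and 1.4× the
mean, as real gene families vary in length; this also ensures duplicated
pairs differ in D1, giving the D-score distribution the spread a real
dataset has.

What the generator does **not** emulate: sequencing errors, quality
scores, spliced transcripts, paired-end insert-size structure,
expression-level variation between genes, reverse-strand gene placement,
and partial (domain-level) duplications. Passing the end-to-end tests
therefore demonstrates that the pipeline recovers planted duplication
structure under clean conditions — it does not certify behavior under
aligner-specific artifacts, which is precisely why the feature
extraction accepts any spliced aligner's SAM with `NH`/`AS` tags rather
than assuming the generator's conventions.

## Numerical choices and degenerate inputs

- Gaussian variances are floored at $10^{-10}$; a component whose weight
  falls below $1/(10n)$ is pruned with a warning.
- E-steps run in log space with log-sum-exp normalization, so
  well-separated components do not underflow posteriors.
- Coordinate descent convergence is measured on the largest coefficient
  update relative to the largest coefficient magnitude (with a floor of
  1), not on the objective, which is cheap but flat near the optimum.
- Constant (zero-variance) feature columns keep coefficient 0 rather
  than producing 0/0.
- `min_max_normalize` maps an all-equal vector to all zeros.
- k-means requires at least $k$ distinct values; the pipeline retries
  with $k = 2$ and, failing that, labels every gene Low with a warning
  rather than fabricating a partition.
- The equal-shape Gamma intersection (solvable analytically) anchors the
  grid estimator's test; the grid step bounds its error.

## Problem sizes

The test suite fits mixtures at $n = 10^4$ (parameter recovery within
$\pm 0.01$ on component means), checks the cutoff quadratic against
numeric root finding on 100 random parameter draws at $10^{-8}$
relative agreement, verifies the elastic net against its three
closed-form limits at $10^{-6}$, and runs the full pipeline on the
200-gene default simulation plus a 52-gene variant used for composition
and determinism checks. These sizes were chosen as the smallest at which
the statistical claims are sharp: recovery tolerances scale as
$n^{-1/2}$, so $10^4$ points make $\pm 0.01$ a meaningful bar, while
200 genes with 30% duplication give both a dominant Low mass and enough
duplicated genes for a stable mixture fit.

## Known limitations

- D1 is computed between annotated genes only; ambiguity against
  unannotated repeats shows up in D2/D4 but not in D1.
- The gene-span (rather than exon-level) assignment can attach a read to
  an overlapping gene it does not originate from in compact genomes.
- The Gamma moment M-step is an approximation to the MLE; its bias is
  visible in the shape parameter at small component weights.
- Categories depend on a 3-component assumption; genuinely unimodal
  D-score distributions are better read from the scores directly than
  from the forced categorization.
- The alternative likelihood compares adjacent components only; it is a
  confidence signal, not a calibrated posterior probability.
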