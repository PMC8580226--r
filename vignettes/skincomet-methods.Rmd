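---
title: "skincomet: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{skincomet: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skincomet)
```

## What the package computes

Skin aging involves co-metabolism between the host and its skin microbiota:
bacterial pathways (proteolysis, porphyrin synthesis, fatty-acid and ceramide
metabolism, histidine conversion, and others) intersect host processes that
shape skin appearance. `skincomet` charts this interface. Starting from a
curated table mapping ten co-metabolic pathways to bacterial gene models, it

1. infers orthologous groups across a reference proteome panel of skin
   bacteria and builds one calibrated profile hidden Markov model (HMM) per
   gene family;
2. quantifies those models in genome annotations and metagenome gene
   catalogs, aggregates hits to module/pathway level and applies two
   normalizations for heatmap-style comparison;
3. predicts per-sample gene content from 16S OTU tables by projecting
   through reference-genome gene counts (a PICRUSt-style inference);
4. relates community composition and predicted gene content to a
   phenotype-derived skin-aging (SA) score via constrained ordination (RDA)
   with permutation tests and per-pathway linear models.

A synthetic-data generator with recorded ground truth exercises every stage.

## Orthology and the panel phylogeny

All-vs-all similarity uses exact Smith–Waterman local alignment
(BLOSUM62, affine gaps, open 11 / extend 1; a gap of length $L$ costs
$11 + L$). An optional prefilter skips pairs sharing no 4-mer; at
within-family identities of 70% and above, shared 4-mers are essentially
certain, so the prefilter only removes unrelated pairs. Each pair's
`norm_score` is the raw score divided by the self-score of the shorter
sequence; edges below `min_norm_score = 0.3` are dropped. On the synthetic
fixtures this threshold separates homologous pairs (norm scores
$\gtrsim 0.5$ at 15% divergence) from unrelated ones ($\lesssim 0.1$) by a
wide margin; it is exposed in the configuration because real panels may need
a different operating point.

Groups are reciprocal-best-hit (RBH) clusters: per ordered genome pair, the
best hit per query (ties broken by lexicographic protein id, for
determinism) is marked, edges are kept iff reciprocal, and within-genome
pairs scoring higher than both members' best cross-genome hits are merged as
in-paralogs. Connected components of the kept graph are the orthogroups.
RBH is the simplest method satisfying "common evolutionary origin"; the
module boundary would admit Markov clustering as a drop-in replacement.

The panel tree is neighbor joining (via **ape**) on p-distances from the
concatenated alignments of the single-copy core (groups with exactly one
member in every genome), with negative branch lengths clamped to zero. NJ is
exact on additive distances, which the test suite verifies on 50 random
10-taxon trees; the tree only orders heatmap rows, so approximate-ML
machinery is deliberately avoided.

## Progressive alignment

Each modeled orthogroup is aligned progressively: a UPGMA guide tree on
3-mer distances ($1 - |\mathrm{shared}| / \min(|k_a|, |k_b|)$), then global
profile–profile Needleman–Wunsch merges with the same affine penalties,
terminal gaps penalized, scoring column pairs by the mean substitution score
over their residue pairs (gap-containing pairs contribute zero to the sum
but stay in the denominator, mildly penalizing gappy columns). Once a gap is
introduced it is never removed. UPGMA is implemented in the package rather
than through `hclust` because `hclust`'s tie handling depends on input
order, and the alignment contract here is full input-order invariance with
lexicographic tie-breaks. There is no iterative refinement: the stage stays
deterministic and testable, and refinement could be added behind the same
contract. No attempt is made to reproduce any external aligner
column-for-column.

## Profile HMMs

**Architecture.** Alignment columns with gap fraction strictly below
`max_gap_frac = 0.5` become match states; the rest are insert columns.

**Estimation.** Match emissions are Laplace-smoothed column frequencies,
$(c_a + \alpha) / (n + 20\alpha)$ with pseudocount $\alpha = 1$ by default
(`X` residues are treated as missing). Insert emissions equal the
background. Transitions are counted from per-row state paths through the
flagged architecture, with pseudocount 1 per transition type:
$P(M{\to}M) = (c_{MM}+1)/(c_{M\cdot}+3)$ and similarly for the two-way
I and D rows. Dirichlet-mixture priors (as in mature HMM builders) are an
acknowledged fidelity gap, recorded here; Laplace is the simplest defensible
estimator and the gathering thresholds are calibrated against the same
scores, so downstream counts are internally consistent.

**Background.** Global amino-acid frequencies of the reference panel,
falling back to uniform $1/20$ below 1000 residues.

**Scoring semantics.** One score is used everywhere: full-sequence
log$_2$-odds against the background null, computed by the forward algorithm
over a unihit local architecture. Entry is uniform over match states
(probability $1/M$); exit from $M_k$ has probability $1/(M-k+1)$ (making
fragment end points uniform), with core transitions out of $M_k$ scaled by
the complement so every row still sums to one; $D_M$ exits with probability
1. Residues outside the matched segment are emitted by flanking states at
background frequencies and therefore contribute zero bits, as do `X`
residues and insert emissions. Whether the original study calibrated on
full-sequence or best-domain scores is unknowable from the text; what
matters is that calibration and scanning share one definition, which this
package enforces by construction.

**Numerics.** The production forward works in rescaled linear space (row
maxima divided out, one log per row), which is numerically equivalent to
log-space summation within double precision; a log-space kernel is kept and
cross-checked in the tests, and both are validated against exhaustive path
enumeration on small models ($M \le 3$, sequences $\le 5$) to $10^{-9}$
bits. Viterbi (max instead of sum, in log space) is the diagnostic
companion; forward $\ge$ Viterbi always.

**Gathering threshold.** For each model, all orthogroup members are true
positives and all other panel proteins true negatives;
$\mathrm{GA} = (\min \mathrm{pos} + \max \mathrm{neg})/2$ in bits. Overlap
($\max \mathrm{neg} \ge \min \mathrm{pos}$) raises a flag; an empty negative
set falls back to $\min \mathrm{pos} - 0.5$ bits, flagged. Model files store
GA alongside the emissions/transitions (HMMER3-style text layout, negative
natural-log probabilities, `*` for zero) and round-trip scores to
$10^{-9}$ bits and GA exactly.

## Scanning and normalization

Genome scans count, per model, proteins scoring at or above GA; a protein
may count toward several models, matching independent per-model searches
(documented so module sums are interpreted accordingly). Metagenome
quantification assigns each catalog gene to every model whose GA it passes
and sums read counts; genes hit by no model accumulate in an `UNMAPPED`
accounting column.

Module aggregation sums member-model columns (order: aggregate, then
normalize — fixed because the two normalizations only partially commute
with aggregation). Sample-relative normalization divides each row by its
row sum (the `UNMAPPED` column is excluded from the denominator by default,
so functional columns sum to one; a flag includes it). Module-max
normalization divides each module column by its maximum over the full
combined sample set — all cohorts jointly, so gut and skin samples within
one module end up mutually comparable on $[0, 1]$ — and is idempotent.
Every table carries a `norm_state` tag and the transforms check it, so a
table cannot silently be normalized twice or in the wrong order.

## 16S-based functional inference

OTUs are mapped to panel genomes by deepest matching taxonomy prefix
(rank-delimited strings; greengenes-style `g__` prefixes tolerated), ties
shared as equal weights, OTUs matching no panel genus (default
`min_depth = 6` of the seven-rank convention) or labeled `Unassigned`
unmapped and reported as a per-sample unmapped fraction. Prediction is the
linear projection
$\widehat{G} = A \, W \, C$ (samples × OTUs, OTU→genome weights,
genome × model counts) — exactly linear in abundances by contract. The
pipeline feeds it sample-relative OTU proportions; the operation itself does
not renormalize, so linearity holds and callers choose the scale. 16S
copy-number correction is off by default (the conservative reading of an
"analogous to PICRUSt" method); an optional per-genome copy-number table
divides each genome's contribution when supplied. Taxonomy-prefix matching,
rather than sequence placement, is used because the package ships no 16S
reference alignment and prefix matching is deterministic and testable.

## Skin-aging score and statistics

**SA score.** The exact published formula lives in supplementary material
that the package does not reproduce; the implemented surrogate is the
oriented z-score mean over the eight clinical measurements (pores,
roughness, wrinkles, porphyrins, red features, color evenness, visible and
invisible spots): each column standardized, multiplied by its orientation
(+1 except color evenness, which decreases with aging, −1), averaged per
subject. It is affine-invariant per column, has mean ≈ 0, and higher values
mean older-looking skin. Orientations are fully overridable. Zero-variance
columns are dropped with a warning; an all-constant table yields all-zero
scores.

**RDA.** The response (OTU table or predicted gene table) is
Hellinger-transformed by default (square root of sample-relative
proportions — the standard pre-treatment making abundance data suitable for
Euclidean ordination; `log1p` and `none` are available, and pathway-score
responses are analyzed untransformed), column-centered, and projected onto
the centered constraint (SA score, or a 0/1 age-group indicator).
`var_explained` is the fitted over total sum of squares; the pseudo-F is
$(SS_f / q) / (SS_r / (n - q - 1))$ with $q = 1$; the permutation p-value is
$(1 + \#\{F^\pi \ge F\}) / (1 + n_\mathrm{perm})$ with the constraint
permuted under a mandatory seed (default $n_\mathrm{perm} = 999$). Arrow
scores are the per-variable loadings $b_j = \langle y_j, x_c \rangle /
\lVert x_c \rVert^2$ of the single constrained axis; `top_arrows` ranks by
absolute value (ties lexicographic), with the study-style defaults k = 20
for OTU-level and k = 15 for gene-level runs. Axis scaling conventions
differ between ordination packages by constant factors, so rankings — not
raw loadings — are the tested contract; variance explained and pseudo-F are
cross-checked against **vegan** in the suite.

**Pathway models.** Pathway scores sum member-gene columns; each is
regressed on the SA score by OLS (slope, intercept, $r^2$, two-sided slope
p). Benjamini–Hochberg q-values are optional and off by default, since the
original per-pathway reporting does not state a correction; both behaviors
are exposed. The heatmap export transposes to pathways × subjects, orders
subjects by increasing SA score and normalizes each row to its maximum.

## The synthetic world

Defaults state the emulated conditions, fixed once:

| parameter | default | rationale |
|---|---|---|
| panel | 10 genomes × 12 families | desk-scale reference panel |
| seed sequence length | 250 aa | typical bacterial enzyme |
| within-family divergence | 0.15 | separable but non-trivial families |
| duplicate divergence | 0.03 | duplicates are *recent* in-paralogs |
| copy-number distribution | 0/1/2 at 15/70/15% | presence/absence + duplications |
| decoys per genome | 8 | background proteome |
| community design | 50 samples, 2 groups | the 2 × 25 two-age-group design |
| sequencing depth | 10,000 reads | small-amplicon-run scale |
| phenotype noise sd | 0.5 | moderate measurement noise |

Duplicated copies evolve from their co-resident copy, not independently
from the family seed: independent duplicates are statistically
indistinguishable from cross-genome orthologs, so no in-paralog rule could
merge them — "recent duplicate" is the biological situation the in-paralog
concept describes. Communities draw log-normal base abundances, apply a
multiplicative group effect to designated OTUs and sample multinomially;
phenotypes load linearly on a standard-normal latent age with Gaussian
noise, color evenness negative.

What the generator does **not** emulate: indel-rich divergence between real
annotation pipelines, horizontal transfer, strain-level pangenome variation,
16S copy-number variation, compositional zero-inflation beyond multinomial
sampling, and correlated phenotype measurement error. A green recovery test
therefore establishes the pipeline's internal correctness (planted truth in,
planted truth out) — not that the thresholds are optimal for real skin
metagenomes. The study's own printed effect sizes (≈1–8% of community
variance explained) derive from its deposited 16S dataset and Qiime-era OTU
picking and are not reproducible at desk scale; correspondingly, the
package's acceptance tests are property- and oracle-based.

## Numerical choices and degenerate inputs

- Natural log internally, bits (log$_2$) at every interface.
- Probabilities are written to model files with 17 significant digits
  (`%.17g`), so read/write round-trips are exact for doubles.
- Ties anywhere (best hits, guide-tree merges, arrow rankings) break
  lexicographically; every stochastic operation takes an explicit seed, and
  pipeline reruns with an identical configuration are byte-identical.
- Zero-sum samples stay zero (with a warning) under sample-relative
  normalization; all-zero module columns and pathway rows pass through
  max-normalizations unchanged; an all-constant phenotype table yields
  all-zero SA scores.
- Ambiguous residues: `X` accepted and scored as background everywhere;
  `B`, `Z`, `U`, `J` map to `X` with a warning on read. Rejecting them would
  block scans of real annotation files.
- `labeled_matrix` forbids NA/negative values at construction, so failures
  surface where they arise, not downstream.

## Known limitations

- Laplace rather than Dirichlet-mixture priors; no E-value calibration (GA
  thresholds only, as in the original design); no multi-domain envelopes.
- RBH + in-paralog merging can over-merge families that share long
  conserved domains; Markov clustering would be the next step up.
- Taxonomy-prefix OTU mapping inherits the taxonomy's resolution; two
  panel genomes in one genus are indistinguishable to it.
- The SA surrogate weights all eight measurements equally; the published
  score may weight them differently.
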