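---
title: "Community metabolic potential scoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community metabolic potential scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A microbial community's taxonomic profile and its metabolome are usually
measured side by side but analyzed apart. A correlation between a species
and a metabolite is ambiguous — the species may synthesize the compound,
degrade it, or simply respond to the same environmental driver. `cmpscore`
resolves part of this ambiguity by injecting reference knowledge of
enzymatic capability: which gene families act on which compounds and in
which direction. It asks, metabolite by metabolite, whether the measured
between-sample variation is consistent with variation in the community's
genomically encoded capacity to make or destroy that compound.

## The stoichiometric impact matrix

The core object is a signed metabolite × gene matrix **M** built from
pathway-context reaction annotations in the KEGG `reaction_mapformula.lst`
dialect plus a KO → reaction map.

For each single-direction reaction catalyzed by an enzyme encoded by gene
$x$ transforming metabolite $A$ (stoichiometric coefficient $c$) into
metabolite $B$ (coefficient $d$), we set
$M_{Ax} \mathrel{-}= c$ and $M_{Bx} \mathrel{+}= d$, accumulating over all
reactions a gene maps to. Construction applies four steps, in this order:

1. **Directionality.** A reaction written with one consistent direction in
   every pathway context is usable; a reaction annotated reversible
   anywhere, or written in conflicting directions across contexts, is
   treated as reversible and contributes nothing. Treating conflicts as
   reversible is the conservative reading: a conflicting annotation gives
   no trustworthy net direction. (Direction inference from thermodynamics
   or flux modeling is out of scope.)
2. **Currency filter.** Compounds whose remaining reactions associate with
   30 or more distinct genes (cofactors and other ubiquitous currency
   metabolites) are removed: their scores would aggregate half the
   network and predict nothing specific. The count is taken *after* the
   directionality filter, on the reactions that actually enter the matrix
   — a metabolite connected only through reversible reactions should not
   be disqualified by genes that never contribute to it. The cutoff of 30
   and its strict boundary (29 associated genes is kept) are exercised in
   the test suite.
3. **Pruning.** All-zero rows (including exact cancellations) and columns
   are dropped; an empty result is an error, not an empty object.
4. **Normalization.** Each row is scaled so negative entries sum to −1 and
   positive entries sum to +1 (within 1e−9, asserted on every built
   model). This equalizes metabolites across very different network
   connectivities; a gene's entry is its *relative* share of the
   production or consumption capacity for that metabolite.

The mapformula dialect carries no coefficients, so they default to 1; an
optional per-(reaction, compound) coefficient table overrides them, and an
entry naming a compound foreign to its reaction is an error rather than a
silent skip. Compound identifiers are opaque strings — KEGG C-numbers are
expected but not enforced.

Every nonzero cell keeps provenance records (reaction, role
produces/consumes, raw coefficient), which later ground the key-reaction
analysis and the synthesis/degradation classification.

## From taxa to genes to CMP scores

When shotgun gene abundances are unavailable, the metagenome is inferred
as `G = t(genomes) %*% taxa`: copy numbers times abundances, summed over
taxa. The operation is deliberately linear — additivity over taxa is what
makes single-taxon attribution well-defined. An optional per-sample
normalizer hook accommodates external corrections (e.g. MUSiCC-style
average-copy-number scaling); it defaults to a no-op and is intentionally
bypassed in single-taxon calculations so that single-taxon tables still
sum to the community table.

CMP scores are then `CMP = M %*% G` over the genes shared by both
matrices. Genes on only one side are dropped with a logged count — the
model defines the enzymatic scope. CMP is a relative potential, not a
flux or concentration prediction; every downstream statistic uses only
between-sample contrasts.

## Comparing CMP variation with measured variation

Metabolomic tables are first cleaned: duplicate rows per compound ID are
summed (missing + number = number; all-missing stays missing) and
metabolites with nonzero abundance in fewer than 5 samples are discarded.

For each metabolite we form the vector of signed pairwise differences
$d_{ij} = v_i - v_j$ over sample pairs $i < j$, for both the CMP row and
the measured row, and correlate the two vectors (Spearman by default;
Pearson available). Signed differences — not absolute distances — keep
the direction of coupling, which is what distinguishes well-predicted
from anti-predicted metabolites. Pair signs are fixed by a canonical
(alphabetical) sample order, so results do not depend on column order.

Significance uses a Mantel permutation test: sample labels of the
measured vector are permuted (n = 10,000 by default; the validation suite
uses 999), the difference vector and correlation are recomputed each
time, and one-sided empirical p-values use the add-one estimator
$p = (k + 1)/(n_{perm} + 1)$. Permuting samples rather than pairs
respects the dependence among pairs sharing a sample; permuting pair
entries independently would be anticonservative. Samples with a missing
measurement are excluded before pair formation (missingness here is
per-sample, so pair exclusion and sample exclusion coincide); fewer than
3 usable samples, or a zero-variance difference vector, yields
`not_evaluable` rather than a number.

The upper-tail and lower-tail p-value vectors are corrected *separately*
across metabolites with Storey q-values: $\pi_0$ is estimated on a
$\lambda$ grid (0.05–0.95 by 0.05) with a df-3 smoothing spline evaluated
at the largest usable $\lambda$, clamped to (0, 1]; below 10 p-values the
estimate is unstable and $\pi_0 = 1$ is used, which reduces to
Benjamini–Hochberg. A tail-area q-value was chosen over a local-FDR
density estimate as the primary correction: it is monotone, closed-form,
and stable at the few-hundred-test scale typical of metabolomic panels;
local FDR is noted as an alternative. Classification requires both
p < 0.01 and q < 0.01, with the sign of the correlation deciding
well-predicted (positive) versus anti-predicted (negative).

## Attributing predictions to species, genes, and reactions

*Key species*: for each taxon, CMP is recomputed from that taxon alone and
correlated (Pearson) with the community CMP row; correlation > 0.5 marks
a key contributor. A constant single-taxon row (taxon absent or lacking
relevant genes) has undefined correlation and is *not* key — no evidence
of contribution. *Key genes*: for each gene with a nonzero link to a
metabolite, that single entry is zeroed (the row is **not** renormalized
— the perturbation deletes a link, it does not rebuild the model) and the
perturbed CMP row is correlated with the original; correlation < 0.5
marks a key gene. Here the undefined case flips: zeroing the only link of
a single-gene metabolite leaves a constant row, and the gene *is* key —
deleting the only link destroys the score. Both conventions are the
limiting behavior of the thresholds. Reactions behind key genes (via
provenance) become key reactions; a metabolite whose key reactions all
produce it is synthesis-driven, all consume it degradation-driven,
otherwise mixed.

## Null models

Two complementary nulls address the worry that apparent predictability is
an artifact of the data covariance structure.

**Network randomization.** The pre-normalization matrix is treated as a
signed bipartite gene–metabolite graph and shuffled with double-edge
swaps restricted to same-sign edge pairs (5,000 successful swaps per
network by default, bounded by 100× as many proposals; weights travel
with edges; duplicate- or sign-conflicting edges are rejected). Every
node therefore keeps its signed degree — each metabolite retains its
number of producing and consuming links, each gene its substrate/product
role balance — while the specific gene–metabolite assignments are
destroyed. Rows are renormalized after the shuffle, since normalization
is part of model construction. The full prediction pipeline is rerun per
randomized network and the observed well-predicted count is compared
against the randomized counts with an add-one upper-tail p-value.
Operating on the signed weighted matrix (rather than an unweighted
reaction graph rebuilt into a matrix) keeps each randomized network a
drop-in replacement for the real one.

**Label permutation on fixed topology.** Typed metabolite adjacency is
derived from reactions: a forward reaction yields a `synthesizing` record
from each substrate to each product and the mirrored `depleting` record
(the consumed partner read against the produced one); reversible
reactions yield `reversible` records in both orientations. The test
counts distinct metabolite pairs in which an anti-predicted metabolite is
adjacent to a well-predicted one, per link type and in total, then
permutes class labels over network node positions with topology fixed.
With no anti-predicted or no well-predicted metabolites the result is
degenerate by construction (counts 0, p = 1).

## The synthetic community generator

`generate_fixture()` produces complete, file-format-faithful inputs with
planted truth, used by the test suite and the acceptance script. It
emulates: sparse log-normal taxon abundances (lognormal(0, 1) with 30%
zero-inflation — heavy-tailed dominance patterns typical of amplicon
surveys); binary genome gene content; a reaction network in which each
metabolite is produced from a dedicated precursor by one or two
single-gene reactions carried by a single generating taxon; currency
decoys (compounds consumed by 32 single-gene reactions, which the
currency filter must remove); and reversible decoys (compound pairs the
directionality filter must drop). Measured abundances are
`±coupling × standardize(CMP_true) + Normal(0, noise_sd)` for planted
producer/consumer metabolites and pure noise for the independent rest.

Defaults encode the intended study conditions: 20 samples, 60
metabolites, 30% producer-controlled, 20% consumer-controlled, coupling 3
against unit noise (3:1 signal-to-noise). The gene pool default (200) is
sized so planted reactions plus decoys always fit. The planting uses the
package's own model-construction path to avoid oracle drift; the test
suite keeps independent naive implementations (triple-loop accumulation
and matrix product, exhaustive permutation enumeration) as the actual
oracles.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: measurement-technology error structure
(qPCR vs 16S compositionality, MS peak artifacts), strain-level variation
in gene content, correlated metabolite panels, shared genes between
metabolites, host-derived compounds, and incomplete or wrong reference
annotation. Recovery rates on fixtures are upper bounds, not forecasts.

## Numerical choices and degenerate inputs

- Empirical p-values use the add-one estimator, so p ∈ [1/(n+1), 1] and a
  permutation test can never report zero.
- Tie handling in permuted Spearman correlations uses average ranks; a
  permuted difference vector with zero variance contributes a correlation
  of 0 (such permutations arise only from near-constant inputs).
- Comparisons of permuted statistics to the observed one use a 1e−12
  tolerance so exact ties (e.g. the identity permutation) count as
  extreme.
- Malformed reaction lines are skipped and counted, not fatal; an empty
  parse, an all-filtered model, or an empty gene overlap is fatal.
- Validation problem sizes: 999 permutations per Mantel test, 19
  randomized networks in the null test, 100 random reaction sets for the
  construction oracle, 200 metabolites for the type-I fixture — sizes at
  which every check completes in seconds to a few minutes while keeping
  p-value resolution (1/1000) an order of magnitude finer than the 0.01
  decision threshold.

## Limitations

CMP scoring ignores expression, regulation, kinetics, and flux bounds; it
deliberately discards reversible reactions, which removes real capacity
along with directional ambiguity. Anti-predictions conflate
environment-controlled metabolites with gaps in reference knowledge. The
taxonomic inference path assumes reference genomes represent the strains
present. These are properties of the modeling approach itself, not of
this implementation, and they bound what any downstream interpretation
should claim.
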