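# cmpscore

Mechanistic integration of microbial community composition and metabolomic
profiles.

Paired taxonomic and metabolomic surveys of microbial communities (vaginal
microbiome, gut microbiome, environmental samples) usually stop at
correlation: a species co-varies with a metabolite, with no way to say
whether the species produces it, degrades it, or is merely along for the
ride. `cmpscore` is for researchers who have a taxa-by-sample abundance
table (16S, qPCR) plus a metabolite-by-sample table (LC/GC-MS with KEGG
compound identifications), and who want to ask a mechanistic question:
*how much of the observed metabolite variation is explained by what the
community is genomically capable of doing?*

## The model

From KEGG-style reaction annotations the package builds a signed
stoichiometric impact matrix **M** (metabolites × genes). For every
single-direction reaction catalyzed by an enzyme encoded by KO *x* that
converts metabolite *A* (coefficient *c*) into metabolite *B* (coefficient
*d*), it subtracts *c* from `M[A, x]` and adds *d* to `M[B, x]`. Reversible
reactions carry no directional information and are dropped, ubiquitous
"currency" compounds (touched by reactions associated with ≥ 30 genes) are
excluded, and each row is normalized so its negative entries sum to −1 and
its positive entries sum to +1.

Community gene content **G** (KOs × samples) is either measured directly
(shotgun data) or inferred as genome copy numbers × taxon abundances.
The **community-based metabolite potential** is then

    CMP = M · G

a relative, per-sample score of the community's capacity to accumulate
(positive) or deplete (negative) each metabolite. CMP is *not* a
concentration or flux prediction; only between-sample differences are
meaningful. Accordingly, for each metabolite the signed pairwise
differences in CMP across all sample pairs are correlated (Spearman, by
default) with the pairwise differences in measured abundance, significance
is assessed with a Mantel permutation test (sample labels are the
permutation unit), and the two one-sided p-value vectors are corrected
with Storey q-values. Metabolites with p < 0.01 and q < 0.01 are
**well-predicted** (positive correlation: the community makes it) or
**anti-predicted** (negative: likely environment- or consumer-controlled).

On top of the scores, perturbation analyses identify the mechanism behind
each prediction: *key species* (single-taxon CMP correlates > 0.5 with the
community CMP), *key genes* (zeroing the gene's link drops the correlation
between original and perturbed CMP below 0.5), the key reactions those
genes catalyze, and whether each metabolite is driven by synthesis,
degradation, or both. Two null models guard against artifacts of the data
covariance structure: degree-preserving randomization of the
gene–metabolite network, and metabolite-label permutation on fixed network
topology.

## Worked example

The package ships a synthetic community generator with planted ground
truth, which doubles as a quick tour:

```r
library(cmpscore)

fx <- generate_fixture(fixture_spec(rng_seed = 7))
fx$model
#> Stoichiometric impact model: 184 metabolites x 145 genes
#>   nonzero cells: 226 | currency metabolites removed: 2

res <- predict_metabolites(fx$cmp, fx$metabolites,
                           prediction_config(n_permutations = 999, rng_seed = 1))
table(res$class)
#>  anti_predicted not_significant  well_predicted
#>              12              32              16

head(res[order(res$p_pos), ], 5)
#>    metabolite   rho p_pos p_neg q_pos q_neg n_pairs          class
#> 2      C00002 0.941 0.001     1 0.004     1     190 well_predicted
#> 8      C00008 0.949 0.001     1 0.004     1     190 well_predicted
#> 9      C00009 0.669 0.001     1 0.004     1     190 well_predicted
#> 14     C00014 0.830 0.001     1 0.004     1     190 well_predicted
#> 18     C00018 0.894 0.001     1 0.004     1     190 well_predicted
```

Sixty metabolites were measured across 20 samples; 18 were planted as
producer-controlled (their abundance tracks the community's capacity to
make them) and 12 as consumer/environment-controlled (negative coupling).
The classifier recovers them — `rho` is the Spearman correlation of
pairwise differences, `p_pos` the upper-tail Mantel p at 999 permutations
(0.001 is the smallest attainable value), `q_pos` its Storey q-value:

```r
str(evaluate_recovery(fx$truth, res)[1:3])
#> $ sensitivity_producer: num 0.889
#> $ sensitivity_consumer: num 1
#> $ specificity_null    : num 1

ks <- key_species(fx$model, fx$taxa, fx$genomes)
head(ks[ks$is_key, ], 3)
#>    metabolite taxon correlation is_key
#> 81     C10041  T001           1   TRUE
#> 82     C00041  T001           1   TRUE
#> 97     C10049  T001           1   TRUE
```

Every key-species call points at the taxon that actually carries the
planted genes. With real data the same steps start from files:
`parse_reaction_map()` + `build_model()` on a `reaction_mapformula.lst`
dialect file and a KO→reaction map, `infer_gene_abundance()` on taxon and
genome tables, then `compute_cmp()` and `predict_metabolites()` — or a
single `run_pipeline()` call driven by a YAML config (see
`inst/cli/cmpscore.R` for the command-line front end with subcommands
`build-network`, `infer-genes`, `cmp`, `predict`, `contributors`,
`null-network`, `adjacency-test`, `fixture`, `run`).

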