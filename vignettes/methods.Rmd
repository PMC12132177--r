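---
title: "Imputing expression across a brain-tissue hierarchy: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing expression across a brain-tissue hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurimpute)
```

# The problem

Genotype-matched brain expression cohorts profile a small panel of coarse
tissues ("composites" here), and most donors are missing several of them.
Anatomical expression atlases profile a hundred-plus fine-grained structures
("leaves"), annotated with an ontology of tissue organisation, but in only a
few individuals and without genotypes. `neurimpute` transfers the atlas's
structural knowledge to the cohort: for each cohort subject it predicts
expression of every gene in every leaf tissue, and aggregates leaves back to
composites where a measured value exists to learn from or to impute.

# Model

The predictor for gene $g$, leaf tissue $t$, subject $s$ is a multi-layer
perceptron over three concatenated inputs:

$$\hat x(s,t,g) = f_\theta\big([\,e_t;\, e_g;\, p_{s,g}\,]\big).$$

**Tissue embeddings $e_t$.** A graph convolutional network on the ontology
tree. All nodes (internal and leaf) are graph nodes; edges are the
symmetrised parent–child links, unweighted. The propagation operator is the
symmetric-normalised adjacency with self-loops,
$\hat A = D^{-1/2}(A+I)D^{-1/2}$, the standard first-order convention; its
spectrum lies in $[-1,1]$, which keeps repeated propagation contractive.
Input features are the one-hot identity over nodes, so the first weight
matrix is effectively a free embedding table that the graph operator
smooths; hidden layers use ReLU and the last layer is linear. Only leaf
embeddings feed the predictor, but internal nodes shape them through the
convolution — that is the point of using the hierarchy. Letting the ontology
inform the embeddings encodes the core biological assumption: anatomically
related tissues express genes similarly.

**Gene embeddings $e_g$.** Pretrained so that the Pearson correlation
between two genes' embedding vectors (across embedding coordinates, $d_g \ge
2$) matches the Pearson correlation of their expression across the atlas
leaf tissues, for each atlas subject in turn. The loss is the squared
difference per sampled pair, minimised with Adam over uniformly sampled gene
pairs, cycling atlas subjects round-robin; squared error was chosen because
nothing in the problem demands a different divergence. Genes with zero
across-tissue variance in a subject contribute no pairs for that subject
(counted, warned once). After pretraining the gene embeddings are frozen;
the tissue network and MLP train jointly with the predictor. This two-phase
reading — pretrain genes, co-train tissues — is the design choice that makes
the tissue embeddings specialise to the prediction task while the gene
embeddings stay a stable description of co-expression structure.

**Subject input $p_{s,g}$.** The gene's measured expression across the
composite panel (10 slots in the motivating setting; 9 for extended models).
Atlas subjects have no measured composite profile, so theirs is constructed
as the mean of each composite's subordinate leaf values — the only
construction consistent with the aggregation rule below.

**Aggregation.** A composite prediction is the arithmetic mean of
`predict_expression` over its subordinate leaves, exactly and by
construction (`predict_composite`); tests assert the identity structurally.

**Training.** Phase 1 minimises squared error against atlas leaf values.
Phase 2 fine-tunes against the cohort's measured composite values through
the leaf-mean aggregation. Whether fine-tuning should update the graph
network, the MLP, or both is genuinely open; here *all* trainable weights
update, at a 10× reduced learning rate, because there is no principled
reason to freeze either block and the reduced rate protects the atlas-learnt
structure. Loss is MSE; minibatches of 1024 (subject, gene, tissue) triples
are reshuffled each epoch under the run seed. Training is plain vectorised
backpropagation, deterministic given the seed, so identical runs are
bitwise identical.

**Missing-tissue imputation.** One *extended* model per composite, with that
composite's slot removed from the profile (remaining composites in canonical
ontology order) and trained to predict the target's subordinate leaves. The
extended models are trained independently of the base model — whether they
could share weights is unknown, and independence is the simpler contract.
For subjects missing several tissues, a two-step procedure is used: for each
missing tissue $m$, every *other* missing tissue is first filled by a
per-gene ordinary-least-squares model (fitted across complete-profile
training subjects, predictors = the observed composites), then the extended
model for $m$ runs on the completed profile. With exactly one missing
tissue, step 1 is a no-op. The linear-model bank fits requests lazily and
caches them because observed subsets are combinatorial; a rank-deficient
design falls back to ridge with penalty $10^{-6}$. Subjects with fewer than
5 observed composites are refused by default (the eligibility rule of the
motivating analyses; overridable).

# Tunable parameters

| parameter | default | notes |
|---|---|---|
| tissue embedding width `dim_t` | 32 | unitless; 16 suffices at desk scale |
| GCN hidden width | 32 | one hidden + one linear layer |
| gene embedding width `dim_g` | 64 | must be ≥ 2 for embedding correlations |
| gene-embedding steps / pairs | 400 / 4096 | Adam, lr $10^{-3}$ |
| MLP hidden widths | 256, 128, 64, 32 | "two blocks"; widths are a free choice |
| learning rate / fine-tune factor | $10^{-3}$ / 0.1 | Adam |
| batch size | 1024 | (subject, gene, tissue) triples |
| min observed composites | 5 | imputation eligibility |
| cis-window | 1 Mb | eQTL scan |
| permutations | 1000 | gene-level p; add-one estimator |
| clump window / $r^2$ | 10,000 kb / 0.001 | greedy, ties by variant id |
| coloc priors | $p_1{=}p_2{=}10^{-4}$, $p_{12}{=}10^{-5}$ | plus per-region $1/n$, $1/(10n)$ |
| coloc effect-sd $W$ | 0.15 / 0.2 | quantitative / binary traits |
| PP4 threshold | 0.7 | either prior configuration |
| coloc region | 100 kb | centered on the primary variant |

The network sizes are the package's own choices: the architecture family
(two hidden blocks, ReLU, linear head) is fixed by design, the widths are
not critical and are configurable. The genetics constants are the
conventional values of the respective analyses.

# Downstream statistics

*Evaluation.* Per-gene Spearman correlation across subjects (ties by average
rank; zero-variance genes are reported, never imputed as 0). The
differential-stability (DS) score of a gene is the mean Pearson correlation
of its across-tissue profile over all subject pairs — the reproducibility of
tissue patterning. Module agreement uses the permutation-model adjusted Rand
index from the label contingency table, with a label-permutation null
(module sizes preserved by construction) and the add-one (never-zero)
p-value estimator $p = (1 + \#\{ARI_{perm} \ge ARI\})/(1+n_{perm})$. The
degenerate ARI denominator (two identical trivial partitions) is defined as
1. A convenience clustering utility (average linkage on $1-|r|$, fixed cut)
exists solely to generate test partitions; it is not a weighted
co-expression pipeline.

*Genetics.* The cis-eQTL scan is an additive OLS per (variant, gene) within
the window, with a min-p permutation gene-level p-value — deliberately the
testing logic, not a reimplementation of any production eQTL software
(adaptive permutations and beta-approximated p-values are out of scope).
Sharing statistics take the tissue with the largest $|\beta|$ as reference:
shared-by-sign counts same-sign tissues; shared-by-magnitude additionally
requires $|\beta|$ within a factor 2 of the reference. Wald-ratio MR divides
the outcome effect by the exposure effect, with the first-order delta-method
standard error (exposure uncertainty ignored — the standard single-SNP
convention); BH-FDR is applied once across the full variant × tissue × trait
family. Colocalization uses Wakefield approximate Bayes factors and
evaluates both stated prior configurations, calling a region colocalized
when either yields PP4 > 0.7. Harmonization follows forward-strand
("action 1") semantics: swapped alleles negate the outcome effect, strand
flips are never attempted, palindromic pairs pass through with a warning.
LD $r^2$ is computed from the supplied cohort dosages (no external reference
panel), and coordinates are 1-based with inclusive windows.

# The synthetic generator

The generator produces the two structures the evaluation measures and
nothing more. Per gene, a tissue archetype $a_g$ follows Brownian motion on
the ontology tree (child = parent + $\mathcal N(0, \text{step}^2)$), giving
tree-local tissue correlation. Each subject observes

$$x(s,t,g) = \rho_g\, a_g(t) + (1-\rho_g)\, b_{s,g}(t) + f\, u_{s,g} + \varepsilon,$$

with $b$ an independent per-subject Brownian pattern, so $\rho_g \in [0,1]$
is precisely the cross-subject stability that the DS score estimates;
$u_{s,g}$ is a subject–gene scalar shift scaled by the subject-signal
fraction $f$, and $\varepsilon$ is Gaussian noise. Defaults: a balanced
depth-4 binary tree (16 leaves, 31 nodes) with 6 composites, 6 atlas and 40
cohort subjects, 200 genes, $\rho_g \sim U(0,1)$, $f = 0.5$, step 1, noise
sd 0.25 — a noise floor an experimentalist would call optimistic but not
absurd for normalized array data on the unit scale of the tree process.
Genotypes are block-LD dosages (founder haplotype pair per block, per-variant
copy-flip probability controlling within-block $r^2$); planted cis-eQTLs add
$\beta \cdot$ dosage to chosen (gene, tissue) cells; GWAS summary statistics
are marginal OLS on a simulated phenotype with chosen causal variants,
shared or LD-independent of the eQTL variant.

What the generator does *not* emulate: realistic LD beyond blocks, realistic
allele-frequency spectra, microarray noise models, batch structure,
non-Gaussian expression, and any relationship between the gene-gene
correlation structure and genetic effects. Passing tests therefore
demonstrate that the machinery recovers the structures it assumes, at desk
scale — not that it matches any particular real dataset's performance.

# Numerical choices and degenerate inputs

* Quantile normalization per gene pools the mean of order statistics across
  genes over the flattened (subject, tissue) axis; with unequal observed
  counts each gene's reference comes from linear interpolation of the pooled
  quantile function. Ties receive the average of tied reference values;
  constant genes map to the mean reference value; all-missing genes are
  skipped with a warning. The map is idempotent.
* The permutation p-value is never zero (add-one estimator); the min-p
  permutation uses max $|r|$, equivalent at fixed sample size.
* Coloc log-evidence sums use log-sum-exp; the two-distinct-variants term is
  the log-difference $\log(\sum_j \sum_k - \sum_{j=k})$, and a single-variant
  region has PP3 = 0 exactly.
* Monomorphic variants are skipped (counted); LD clumping breaks p ties by
  variant id; checkpoints serialise weights as JSON at full precision
  (round-trip agreement to ~$10^{-15}$).
* Tree operations validate single-rootedness and acyclicity on load;
  composite maps must reference known leaves, and overlapping composite leaf
  sets are flagged.

# Problem sizes used by the test and acceptance suites

All suites run on one CPU in minutes. The recovery analyses train with
`dim_t = 16`, `dim_g = 16`, hidden widths 64/32/32/16, 15 pretraining and 6
fine-tuning epochs — small enough to train in seconds, while the loss curve
and held-out metrics show the same qualitative behaviour as larger settings.
Held-out imputation uses 30 training and 10 test cohort subjects.
The missing-tissue robustness analysis uses a 10-composite ontology
(matching the 10-tissue panel and the ≥5-observed rule, which a 6-composite
tree cannot satisfy when 5 tissues are masked), evaluates the degradation
curve on all 40 cohort subjects, and averages it over four nested
mask orderings: the expected degradation is monotone, and averaging
orderings removes the ordering-specific wobble that a single 10-subject
split would show. The DS-recovery analysis uses a depth-5 tree (32 leaves),
150 genes and 6 subjects. Colocalization discrimination plants causal
variants with allele frequencies in [0.25, 0.45] and effect 0.28 at
$n = 1000$, so the causal-variant z-score sits near 6 in both traits by
construction. Null calibration uses 2000 nominal tests, 500 permutation
genes, and 200 ARI replicates.

# Known limitations

* Imputation quality is bounded by what the composite profile carries; genes
  whose variation is purely leaf-specific and subject-specific cannot be
  recovered from a coarse panel by any method.
* The extended models are trained per composite and never share weights; at
  a 10-composite panel that is 10 trainings.
* The eQTL scan is a single-variant additive model without covariates; the
  permutation scheme is the plain min-p estimator, conservative at small
  permutation counts.
* In-cohort LD estimates at desk-scale sample sizes are noisy around an
  $r^2$ cutoff as strict as 0.001; with a few hundred subjects the sampling
  floor of $r^2$ is of the same order as the cutoff, and clumping then
  over-claims. The cutoff is meant for reference-panel-grade estimates.
* The two-step fill uses the observed composites only; it never iterates
  (no chained-equations refinement), by design — the extended model, not the
  linear fill, carries the tissue-specific signal.
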