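---
title: "Methods: subclone analysis of single-cell tumor transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subclone analysis of single-cell tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scSubclone)
```

# The analysis in one paragraph

A tumor single-cell RNA-seq experiment yields TPM expression profiles
and, at covered variant positions, allele read counts per cell. This
package (i) quantifies how heterogeneous the population is and how many
cells a pooled profile needs before it explains the bulk, (ii) reduces
RNA-level variant calls to tumor-specific expressed SNVs and genotypes
each cell at them, (iii) scores every cell with a survival-trained
prognostic risk score (RS), (iv) crosses the driver genotype with the
RS label to assign each cell to one of four subclonal groups, and (v)
asks which group a control or drug-surviving bulk population resembles,
by projecting bulks into the single-cell PC space and classifying them
with an SVM trained on the cells. A synthetic-data generator emulates
all inputs with known ground truth, which is what the test suite and
the acceptance script run against.

# The synthetic population

`sim_config()` fixes the study conditions; the generators are pure
functions of it (identical seed, identical bytes).

**Cells.** `n_cells = 66` cells fall into four groups with expected
fractions 3/66, 25/66, 3/66, 35/66 — a dominant mutant/high-risk clone
(G4), a sizable mutant/low-risk clone (G2), and two small wild-type
groups. The 2×2 design axes are: expression of the driver-mutant allele
(G2/G4) and activation of a 69-gene risk program, shifted by
`risk_effect = 1` log2 unit in G3/G4. Expression is log-normal TPM:
per-gene baseline `mu_g ~ N(3, 1.5^2)` on the log2 scale, per-cell
size factor `N(0, 0.2^2)`, per-gene-per-cell noise `N(0, 1)`; columns
are renormalized to 1e6 and values below 1 TPM are truncated to 0, so
expression zeros arise from the log-normal tail rather than from a
separate dropout process. The driver gene is planted at 3000 TPM —
driver genotyping from RNA is only reliable for abundant transcripts,
and a hotspot oncogene with copy-number gain is expected to be highly
expressed.

**Group membership is mutant-allele expression.** The default
`mutant_allele_fraction = (0, 1, 0, 1)` makes carrying (and expressing)
the driver-mutant allele *definitional* for G2/G4, so RNA-level
non-detection is attributable to read-level dropout alone and "recover
the planted groups" is well-posed. Real data conflate genetics with
dropout (a cell may carry mutant DNA and express none of it); the
generator deliberately separates the two, and lowering the G2/G4
fractions below 1 re-introduces the conflation if desired.

**Read counts and dropout.** A variant inherits its host gene's
expression: depth is Poisson with mean
`depth_mean * TPM_host / (1e6 / n_genes)` (so `depth_mean = 30` is the
depth at an averagely expressed host). Mutant reads are binomial
(p = 0.5 het, 1 hom) with zero-inflation
`dropout(d) = dropout_scale * exp(-d / dropout_d0)`, `d0 = 10`:
dropout is negligible above ~30 reads and dominant below ~5, placing
dropouts on rare transcripts. Passenger variants get per-variant
prevalences U(0.2, 0.8) and 10 % homozygotes to produce heterogeneous
mutation patterns.

**Survival cohort.** `cohort_n = 200` patients share the gene universe;
event times are exponential with hazard
`h_i = baseline_hazard * exp(sum_g beta_g (x_gi - mu_g))`, where
`beta_g = cohort_beta = 0.3` on each risk-program gene (0 when
`risk_effect = 0`, so a null program is null everywhere); censoring is
an independent exponential (`censor_rate = 0.05`, about 20–25 %
censored). Centering the covariates in the hazard only rescales the
baseline and keeps the planted coefficients recoverable.

**Variant call set.** True somatic variants (50 non-synonymous, 15
synonymous) and 20 germline variants are placed ≥100 bp apart on a toy
contig so no accidental cluster forms; planted artifacts are RNA-only
(absent from both exome sets): 4 editing-type records alternating
between the site blacklist and a covering repeat interval, 2 clusters
of three variants spanning 30 bp, and 6 records cycling through failing
Q/FS/QD annotations. Germline variants appear in both the tumor and the
normal exome key sets, so they survive every filter until the somatic
selection — which is exactly the stage meant to remove them.

**What the generator does not emulate.** No read-level simulation, UMIs,
amplification or positional bias; no copy-number variation (the
observed mutant/wild-type expression imbalance in real tumors partly
reflects copy gains); expression noise is homoscedastic log-normal
rather than count-based; variants sit on one toy contig. Passing tests
therefore demonstrate correctness of the analysis logic under the
stated statistical model, not robustness to every artifact of real
libraries.

# Filter cascade conventions

Stages run in the order quality → clusters → FS/QD → blacklists → exome
overlap → somatic non-synonymous; each stage only removes records and
logs its removal count. Boundary conventions, all tested: quality keeps
`qual >= 20`; the cluster rule removes every member of a run of ≥3
variants whose first-to-last position difference is ≤35 (the
GATK-style window semantics; positions 100/120/134 die, 100/120/140
survive); FS strictly greater than 30 and QD strictly less than 2 are
removed; BED intervals are 0-based half-open (interval [100, 101)
covers 1-based position 101) and site lists 1-based; variant identity
is the (contig, pos, ref, alt) key. The published screening pipeline
this imitates also realigns junction-spanning reads; that step needs
BAMs and is out of scope — the blacklist plus cluster/FS/QD filters are
the declared approximation.

# Genotyping and ddPCR

The trinary call is `NO_CALL` when `ref + alt < 3` reads (ambiguous,
kept in denominators of mutation fractions), else `MUT_EXPRESSED` when
`alt >= 2` and `alt / (ref + alt) >= 0.1`, else `WT_EXPRESSED`. The
thresholds are package choices (no published read-count rule exists for
the ambiguity class): ≥2 mutant reads suppress single-read sequencing
errors, and the 10 % fraction floor guards high-depth sites; all three
are arguments. RNA-vs-DNA concordance is reported under both NO_CALL
policies (excluded, or counted as discordant unless both sides are
NO_CALL) because published concordance figures rarely state which was
used. ddPCR counts invert Poisson droplet occupancy,
`copies = -ln(1 - positives/total) * total`; an all-positive channel is
saturated and rejected rather than silently truncated; zygosity is
homozygous only *strictly* above 90 % VAF.

# The risk model

Each marker gene is fit by univariate Cox regression: Newton–Raphson on
the Breslow-tie partial likelihood, score tolerance 1e-8, at most 50
iterations, fits with `|beta| > 20` flagged as monotone-likelihood
divergence rather than returned as converged. Breslow is the simplest
consistent tie convention and matches `survival::coxph(ties =
"breslow")`, which the test suite uses as an independent cross-check
alongside a brute-force grid search of the partial likelihood. The RS
is the linear combination `RS_j = sum_g beta_g x_gj`; the per-gene
p-value ordering is stored for display but never alters the score.

**Cutoff and normalization.** The offset is the 60th-percentile
(type-7, linear-interpolation) quantile of the training scores;
normalized RS is `RS - offset` and high risk means strictly positive —
the top 40 % of the reference distribution, exact for distinct scores
when n is divisible by 5. Single cells are scored with the
*training-derived* offset after location/scale batch adjustment against
the cohort, not with a re-derived per-cohort cutoff: a cutoff learned
on patients is a fixed decision boundary, and the high-risk cell
fraction is then free to differ from 40 % (as it does, both here and in
real tumor populations). Self-offset mode remains available for
standalone cohorts.

**Batch adjustment.** Per gene, each batch is standardized and rescaled
to a common location and scale defined as the mean of the two batch
means and the root-mean of the two batch variances — chosen so that
identical batches pass through exactly. This is a deliberate
location/scale simplification of empirical-Bayes batch correction; it
does not shrink gene-wise estimates and assumes batches share the
biological signal up to affine distortion.

# Subgroups, discriminating genes, gene-set scores

Group assignment is deterministic thresholding on the two supervised
axes (driver call × risk label): no further clustering step is
described for the published analysis, so none is invented. NO_CALL
driver cells are either treated as wild type (default, flagged) or
excluded. Discriminating genes use one-vs-rest contrasts — "genes
exclusive to each group" reads most naturally as one-vs-rest, and
pairwise contrasts are available — with the fold criterion on mean TPM
(pseudocount 1, either direction) and the t-test on log2(TPM+1): fold
changes are conventionally quoted on the TPM ratio scale while
location tests behave far better on the log scale. Because the t-test
is applied only to fold-passing genes, the null false-selection rate
sits between `alpha * P(fold)` and `P(fold)`; the suite checks the
boundary behavior and that selection requires both criteria.

Single-sample gene-set activity is a closed-form rank z-score: with G
genes ranked within a sample (mean ranks on ties) and a set S, the
score is `(mean rank of S - (G+1)/2) / sqrt((G^2-1)/(12 |S|))`. The
published analysis used an external gene-set variation method "in
default mode"; that method's internal kernel estimates make its exact
output configuration-dependent, so this package substitutes a fully
specified statistic with the same qualitative behavior (zero-centered
under random sets, invariant to monotone within-sample transforms) and
documents the substitution here. Scores from the two methods are
comparable in sign and ordering, not numerically interchangeable.

# PC projection and SVM classification

PCA runs on log2(TPM+1), gene-centered, unscaled; component signs are
fixed by making each component's largest-magnitude loading positive so
scores are bit-reproducible. Bulk profiles are projected with the
frozen loadings and training gene means — never refit.

**Pooling-bias correction.** A bulk is a (weighted) *linear* mean of
cell TPMs, so `log2(bulk + 1)` exceeds the mean of the cells'
log-profiles by a per-gene convexity gap of roughly half the
cell-to-cell log variance. Uncorrected, every pooled bulk is displaced
along a fixed gene-space direction, which can move it across decision
boundaries. `project_bulk(pool_correction = TRUE)` subtracts the gap
estimated from the training cells; when subgroup labels are supplied to
`pca_expression()`, the estimate is the cell-weighted mean of
*within-group* gaps. That choice is deliberate: the within-group gap is
the correct correction for a clonally pure pool (the drug-survivor
case), while the between-clone part of the variance is real biology —
a mixed-clone bulk keeps it and projects toward its dominant
contributors, which is exactly how bulk profiles of heterogeneous
tumors behave. The default is no correction, preserving the plain
projection contract.

**Classifier.** C-classification SVM with the cited implementation's
defaults: radial kernel, cost 1, kernel width 1/dimensions, inputs
standardized (the kernel is scale-sensitive; on unstandardized PC
scores spanning ±8 the radial kernel vanishes at bulk-projection
distances and the class vote degenerates to the bias terms).
Standardization uses the population (1/n) standard deviation so that
duplicating every training point leaves the boundary exactly unchanged
up to the soft-margin cost equivalence (duplication equals doubling the
cost, so points lying essentially on a boundary may still flip — the
suite asserts equivalence away from the boundary shell). Classification
uses the first two components by default, matching a PC1–PC2 readout;
the count is an argument.

**The control-bulk readout.** The control bulk pools all cells, so its
corrected projection sits near the population centroid. Whether that
point is classified as the largest group depends on a few-cell margin
when two groups are nearly balanced — at the default 25:35 composition
of the two large groups, the drawn counts invert their order in a
non-negligible fraction of populations, and a pooled profile differing
by ~3 % of the cluster separation cannot resolve that. The benchmark
therefore compares the control label against the group *planted* as
dominant (the largest configured fraction), reporting the drawn counts
alongside; the drug-survivor readout has no such ambiguity.

# Numerical choices and degenerate inputs

Quantiles are type-7 throughout (the 40 % high-risk claim depends on
the convention). Pooled-regression pools are sampled without
replacement within a permutation and independently across permutations;
genes zero in all regressors and the bulk are dropped (count logged)
before OLS; `n >= N - 1` regressors raise an ill-posed error rather
than a silent rank-deficient fit. Zero-variance cells make their
correlation pairs flagged-undefined, not NaN. An empty SNV union makes
the overlap undefined rather than 0. Constant Cox covariates, all-zero
bulk weights, empty survivor sets, saturated ddPCR channels,
single-group SVM training and zero-variance PCA input all raise typed
errors. Two-sample comparisons of two constant, equal groups return
p = 1 with a degeneracy flag.

# Problem sizes used by the tests

The suite and acceptance script run the full pipeline at the default
population size (66 cells × 2000 genes, 20 replicate seeds for the
recovery and drug-response benchmarks; 500-patient cohorts for
parameter recovery; 1000-replicate null calibrations), and scaled-down
configurations (40 cells × 400 genes) for per-stage unit tests — sizes
chosen so the whole suite completes in about a minute while keeping
every statistical check adequately powered.

# Known limitations

- The dropout model is a single exponential in depth; real dropout also
  depends on amplification chemistry and transcript structure.
- The location/scale batch adjustment does not shrink per-gene
  estimates; with few samples per batch it is noisier than
  empirical-Bayes correction.
- The gene-set score is a substitute statistic, not a reimplementation
  of the published gene-set variation method.
- Bulk profiles are treated as noiseless cell mixtures up to log-normal
  noise; amplified-RNA biases are not modeled, and no correction for
  them is attempted at projection time beyond the pooling-convexity
  gap.
- The Cox stage fits univariate models only; multivariate signatures
  and external-cohort validation are architectural extensions, not
  shipped features.
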