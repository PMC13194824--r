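---
title: "cfDNA fragmentomics with cfFragSig: models, parameters and design choices"
author: "cfFragSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfDNA fragmentomics with cfFragSig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

cfFragSig implements a fragment-level analysis of low-pass plasma
whole-genome sequencing for cancer detection. Three feature families are
extracted per sample — copy-number log2 ratios (CNV), fragment size
distributions (FSD) and promoter fragmentation entropy (PFE) — and
combined by an out-of-fold-ranked ensemble into a single risk score that
is dichotomized at a cutoff fixed on the training cohort. A synthetic
cohort generator on a 1/1000-scale genome provides labelled data with the
statistical structure the analysis assumes, so the entire workflow is
testable on a desktop without any sequencing data.

# The feature models

## Copy-number log2 ratios

The genome is partitioned into uniform bins taken from the `GenomeModel`
(10 kb on the scaled genome, the analogue of 1 Mb bins at full scale).
Each fragment is assigned to the bin containing its midpoint. Per-bin
counts are normalized to proportions `r_t` (which removes sequencing
depth), and compared with a healthy baseline `h_t` — the per-bin median
of a panel of at least two healthy samples, renormalized, with zero-median
bins masked as unusable. The bin-level statistic is

    l_t = log2(r_t / h_t),

masked bins carrying a missing marker rather than infinities. A simplified
three-state smoother is available: hidden states {loss, neutral, gain}
with Gaussian emissions centred at −mu, 0, +mu (shared sigma) and
symmetric transitions with a high stay-probability, decoded by Viterbi.
Defaults `mu = 0.3`, `sigma = 0.15`, `stay = 0.99` are deliberately
conservative so single-bin noise does not segment; the unit suite checks
the decoder against exhaustive path enumeration on all instances of up to
eight bins. The model matrix for the classifier uses bin-level `l_t`
values (missing imputed to 0 = neutral) plus the 39 per-arm means; per-arm
means stabilize the scaled genome, and segment means are available as an
option. GC correction is not applied by default — the synthetic data have
no GC bias — but a hook accepts an external per-bin GC track.

## Fragment size distribution

Fragment lengths between 100 and 219 bp are binned in 24 five-bp
intervals (100–104, …, 215–219) separately within each of the 39
chromosome arms (all autosomal arms except the five acrocentric p arms),
giving a fixed 936-entry vector of per-arm proportions. Lengths of
220 bp and above fall outside the last bin and are excluded. The vector
is then z-scored *within the sample* over all 936 entries, using the
population (divisor n) standard deviation; a degenerate constant vector
maps to zeros. Two open choices were resolved as follows: proportions use
per-arm denominators (the per-genome alternative is available behind
`denominator = "genome"`), and normalization is purely within-sample —
that is the only reading under which the features are portable across
cohorts without a reference distribution, which is their stated purpose.
Arms absent from a reduced scaled model still occupy (zero-valued) slots
so the schema is always 936.

## Promoter fragmentation entropy

PFE quantifies the diversity of fragment lengths at a gene's promoter,
which increases when nucleosomes are displaced at active transcription
start sites. Lengths are histogrammed at 1-bp resolution over 100–220 bp
(121 cells; the finest resolution consistent with the global length
filter). Per sample:

1. **Prior.** A genome-wide fragment-length prior is the pooled,
   normalized histogram of fragments whose midpoints fall 750 bp – 1 kb
   beyond each nucleosome-depleted region (NDR) edge.
2. **Controls.** Five control entropies are obtained by drawing five
   sets of 20 genes from a 330-gene background panel (low-expressed,
   tissue-specific genes), pooling each set's TSS±1 kb fragments and
   taking the Shannon entropy (natural log; the base cancels in ratios)
   of the pooled distribution. The gene sets are drawn once from the
   configuration seed so controls are comparable across samples.
3. **Gene score.** The gene's count histogram is combined with the prior
   as Dirichlet pseudo-counts, `alpha = 20 * p_prior + counts`
   (the "weighted sum, weight 20" combined with "parameter for a
   Dirichlet distribution" forces the pseudo-count reading); 2000
   distributions are drawn from `Dirichlet(alpha)` and the Shannon
   entropy `E_j` of each draw is compared with the controls. With a
   margin `k ~ Gamma(shape 0.5, rate 1)` shared across the five
   controls, the probability that all five ratios `E_j / c_i` exceed
   `1 + k` is the closed form `F_Gamma(min_i E_j / c_i − 1)` when the
   minimum ratio exceeds one, and zero otherwise. The score is the mean
   over the 2000 draws — a value in [0, 1]. The unit suite checks the
   closed form against a 10^6-draw Monte-Carlo of `k`.
4. **Normalization.** Gene scores are z-scored across genes within the
   sample; genes with no TSS-window fragments are missing and, when a
   model matrix is needed, imputed to the sample mean (0 after
   normalization).

Two ambiguities were resolved and both alternatives kept accessible: the
margin `k` is shared across the five controls (an independent-`k` product
form sits behind `shared_k = FALSE`), and each control repeat pools the
20 genes' fragments before one entropy is computed (not an average of 20
per-gene entropies). Feature selection — performed on training data only
— keeps genes with a two-sided Wilcoxon rank-sum `p < 0.01` (exact when
both groups have ≤ 12 samples and no ties, otherwise normal approximation
with continuity correction) *and* a positive cancer-minus-non-cancer mean
difference. `pfeSummary()` exposes the mean of the selected normalized
features as a one-number promoter-entropy summary.

# The ensemble

For each of the three feature matrices, a randomized search generates
candidate classifiers spanning regularized logistic regression,
gradient-boosted trees, random forests and stacked logistic combiners
over random subsets of the other candidates (roughly one sixth of the
candidates once at least six exist). Every candidate is trained on the
complement of each of five stratified folds; the held-out predictions
form one out-of-fold (OOF) vector per candidate — each training sample
predicted exactly once by a model that never saw it. Candidates are
ranked by OOF AUC (ties broken by candidate id) and the top 10 per family
are kept, refit on the full training data; the family score is their
unweighted mean prediction and the risk score is the equal-weight mean of
the three family scores. The default of 30 candidates per family is a
desk-scale surrogate for a much larger automated search; the
search → rank → average architecture, not the candidate count, is the
load-bearing design, and the count is configurable.

Two leakage guards are structural: fold assignment is a deterministic
function of (seed, sample id) — independent of input order — and
`predictRisk()` refuses samples whose ids occurred in training;
training-cohort scores are only available through the OOF pathway
(`trainingScores()`), which is also the sole input to cutoff selection.
Validation predictions come from the refit models; OOF predictions are
used only for ranking and the cutoff (the CV-model-averaging alternative
was considered and rejected as needlessly stateful — the refit is the
simplest leak-free reading).

The decision cutoff is the largest threshold whose training OOF
sensitivity (rule: score ≥ cutoff ⇒ cancer, closed on the cancer side)
is at least the 0.95 target; by construction this maximizes specificity
among qualifying thresholds.

# Evaluation suite

AUC uses the Mann–Whitney pairwise formulation with ties counting one
half; variance and CIs come from DeLong's structural components, and the
paired DeLong test compares correlated AUCs. Confusion metrics
(sensitivity, specificity, PPV, NPV, accuracy) carry exact
Clopper–Pearson 95% CIs. Prevalence-adjusted predictive values follow
Bayes' theorem over a prevalence grid. Group comparisons use the Wilcoxon
rank-sum test with effect size `r = |Z|/sqrt(n)` and a 2000-replicate
within-group percentile bootstrap CI; multiplicity is handled by
Benjamini–Hochberg. Calibration reports the Brier score, the calibration
intercept (logistic recalibration with the score logit as offset, scores
clipped to [1e-6, 1−1e-6]) and slope, plus an equal-width reliability
table. Ordered-group trends use the Jonckheere–Terpstra statistic with a
seeded permutation p-value (normal approximation beyond 200
observations). Report tables round to three decimals for display only.

# Depth stability

To ask whether PFE survives shallow sequencing, same-stratum samples
(cancer and non-cancer never mixed) are merged into composite references
of ten times the nominal per-sample fragment count — the scaled analogue
of 50× composites built from 5× samples; on a scaled genome, "depth" maps
to fragment count with ratios preserved. Each composite is downsampled to
fractions 40/50 … 5/50 and the full PFE pipeline — prior, controls, gene
scores, normalization — is recomputed from scratch at every depth (the
stricter reading; reusing the reference prior is available behind
`reuse_prior = TRUE`). Concordance is the Pearson correlation between
each depth's gene-level vector and the reference vector, dropped pairwise
over genes missing at either depth.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions and are not adjusted per analysis.

**Genome.** 39 arms of 100 kb (1/1000 scale), 10 kb CNV bins, 40 scored
(target) genes and 330 background genes on a promoter grid whose spacing
guarantees disjoint TSS windows and NDR flanks. NDRs are TSS ± 150 bp.

**Fragment lengths.** A two-component mixture: mononucleosomal
N(167, 10) truncated to [100, 220] and a short uniform component on
100–150 bp with baseline weight 0.12, growing in tumours as
`0.12 * (1 + tumor_fraction * short_fragment_boost)` (boost default 3).
These are the simplest forms producing the documented phenomena — a
mononucleosomal mode with tumour-associated short-fragment enrichment.

**Promoters.** Each gene has an `activity` in [0, 1]. Promoter fragments
are drawn narrow (N(167, 3); a strongly positioned nucleosome) except
that with probability `0.6 * openness` they come from a widened
open-chromatin component N(167, 25), where openness equals the baseline
activity, raised towards one by the tumour fraction for the designated
cancer-active genes. Short fragments are depleted at protected promoter
cores (weight 0.04 inside TSS windows). Background genes and the
cancer-active set are quiet at baseline (activity uniform on [0, 0.25]);
other target genes have bimodal Beta(0.25, 0.25) activity, reflecting
the essentially on/off character of gene expression. This baseline
heterogeneity matters: it gives healthy samples a stable between-gene
promoter-entropy structure, without which a depth-concordance analysis
on non-cancer strata would correlate pure noise. The narrowness of
silent promoters relative to the NDR-flank prior is equally load-bearing:
the PFE margin rule scores a gene against control entropies from silent
promoters, so those controls must sit at the low end of the promoter
entropy spectrum for the statistic to be informative at all.

**Copy number.** Arm placement probabilities are proportional to
`arm_length * (1 + tumor_fraction * (factor − 1))` — the coverage
expectation of a diploid background mixed with a tumour clone. Cohort
simulation applies recurrent gains (1q, 5p, 6q; factor 1.5) and losses
(4p, 6p, 8p; factor 0.5) to cancer samples.

**Depth and seeds.** The nominal fragment count is 117,000 per sample —
5× coverage of the 3.9 Mb scaled genome with 167 bp fragments, mirroring
5× sequencing depth. `tumor_fraction = 0` forces every distortion to be
neutral. Per-sample seeds derive from the master seed by a documented
counter scheme (`deriveSeed`), so cohorts replay identically and in any
order. Stage maps to tumour fraction through the configurable default
{I: 0.02, II: 0.05, III: 0.12}, which claims no fidelity to any
particular cohort.

**What the generator does not emulate** — GC bias, sequencing errors,
duplicates, real genome coordinates, inter-individual germline
variation, and benign-inflammation signal (benign samples are
tumour-fraction-zero). Passing tests therefore demonstrate the internal
consistency and statistical behaviour of the pipeline under its stated
assumptions, not clinical performance on real plasma.

# Problem sizes and numerical choices

The test suite exercises reduced configurations (8 arms, 16 target
genes, 8–15k fragments) wherever the property under test is
size-independent, and the full study conditions (39 arms, 370 genes,
117k fragments; training 40 cancer vs 40 non-cancer, validation 20 vs
20, tumour fraction 0.2; ten composites for depth stability) where the
claim is about the study-scale behaviour. Entropies are in nats;
z-scores use population SD; degenerate vectors z-score to zero; Viterbi
ties resolve to the first maximal state; the PFE score of a gene with no
fragments is missing, never zero. All randomness flows from explicit
seeds through `deriveSeed`, and reruns with the same configuration are
bit-identical.

# Known limitations

The simplified three-state smoother is not a calibrated copy-number
caller (no tumour-fraction or ploidy estimation). The candidate search is
a scaled surrogate of an industrial AutoML run. PFE scores at 5×-depth
fragment counts are strongly shrunk toward the prior — concordance with
the reference remains high, but absolute scores compress, so analyses
should compare normalized vectors, never raw scores across depths.
Survival analysis and gene-set enrichment of selected PFE genes are out
of scope.
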