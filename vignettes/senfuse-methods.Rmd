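---
title: "Fused self-expressive networks for SNP-phenotype association: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused self-expressive networks for SNP-phenotype association: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Imaging-genetics association asks how a genetic variant relates to brain
phenotypes. `senfuse` targets the single-SNP, multi-modality version of that
question: given per-subject regional brain features from two imaging
modalities — node features (mean gray-matter volume per ROI, from structural
MRI) and edge features (per-ROI weighted clustering coefficients of the
Pearson functional-connectivity graph, from resting-state fMRI) — and an
additively coded genotype $y \in \{0,1,2\}^N$, find a sparse, *consistent*
set of ROIs whose multi-modality profile predicts the genotype, exploiting
the diagnosis labels (e.g. healthy control, moderate, severe depression)
that structure the cohort.

The pipeline has four stages, each a module of this package:

1. **Features.** $X^m \in \mathbb{R}^{N \times d}$ per modality, $d$ = number
   of ROIs. Functional connectivity is the Pearson correlation of ROI-mean
   BOLD series; the edge feature of ROI $i$ is its threshold-free weighted
   clustering coefficient.
2. **Self-expressive networks.** For each modality, every subject is written
   as a nonnegative sparse combination of *same-diagnosis* subjects, giving a
   symmetric, nonnegative, zero-diagonal subject network $W^m$ supported on
   the diagnosis blocks.
3. **Fusion.** The $M$ networks are diffused through their fixed within-class
   local affinities and averaged into a single fused network $W^f$.
4. **Association.** The genotype is regressed on the network-reconstructed
   features $W^f X^m$ with an $L_{2,1}$ penalty that selects ROI rows jointly
   across modalities; nested cross-validation picks the penalty and scores
   generalization by the Pearson correlation (CC) between predicted and true
   codes on held-out subjects.

# Models and estimators

## Weighted clustering coefficient

The paper-facing literature leaves the weighted form of the local clustering
coefficient open; we use the Onnela geometric-mean-of-triangles statistic on
the fully weighted graph,

$$c_i = \frac{1}{k_i(k_i-1)} \sum_{j \ne h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3},
\qquad \hat w = |w| / \max |w|,$$

with $k_i$ the number of nonzero weights at node $i$. It is threshold-free,
bounded in $[0,1]$, invariant to global positive rescaling, and by default
uses absolute correlations (a `negatives = "zero"` option discards negative
edges instead). Nodes with fewer than two neighbours get $c_i = 0$.

## Diagnosis-restricted sparse self-expression

Subject $i$'s code solves

$$\min_{w \ge 0} \tfrac12 \lVert x_i - X_{C_i \setminus \{i\}} w \rVert^2
  + \lambda \lVert w \rVert_1,$$

a nonnegative lasso over same-class donors, solved by cyclic coordinate
descent on the donor Gram matrix (nonnegativity is a constraint in the
solver, not post-hoc truncation; coordinate order is fixed by subject index
so ties resolve deterministically; convergence when the largest coordinate
change falls below $10^{-8}$, capped at 10,000 sweeps). The network is the
symmetrization $W = \tilde W + \tilde W^\top$ with zero diagonal.

**Penalty default.** Each coding problem has its own critical penalty
$\lambda^{\max}_i = \max_j \langle x_j, x_i \rangle_+$ above which subject
$i$'s code is identically zero. The default penalty is the subject-adaptive
$0.1\,\lambda^{\max}_i$. We deliberately scale per subject rather than using
a single dataset-level $0.1 \max_i \lambda^{\max}_i$: the dataset-level value
is set by the single most correlated pair, starving weakly correlated
subjects down to two or three donors and producing fragile, sometimes
near-periodic diffusion graphs whose fusion iteration converges very slowly
(measured 23–400 iterations to a $10^{-6}$ relative change on 60-subject
class-subspace data, against 18–24 with the per-subject default). A scalar
override is available wherever a network is built.

## Class-guided fusion

The local affinity row-normalizes each network within classes,
$A^m(i,j) = W^m(i,j) / \sum_{k \in C_i} W^m(i,k)$ for $j \in C_i$ and zero
otherwise (all-zero rows stay zero, with a warning). With $A^m$ held fixed,
the update

$$W^m_{t+1}(i,j) = \sum_{k,l \in C_i} A^m(i,k)\, A^m(j,l)\,
\frac{\sum_{q \ne m} W^q_t(k,l)}{M-1}$$

is iterated, and after each step the fused network is the off-diagonal
modality average with zero diagonal. Convergence is monitored by the
relative Frobenius change of $W^f$; iteration stops below $10^{-6}$ or at
the configured cap (default 10 steps, hard cap 25; a zero-norm fused matrix
stops immediately with change defined as 0). Because both summation indices
range within $C_i$ and the inputs are class-restricted, every iterate is
symmetric, nonnegative, and exactly zero across classes; an alternative
`mode = "cross"` (second index in $C_j$, as in classical similarity-network
fusion) provably coincides with the default on class-restricted inputs and
is exposed for completeness.

## Multi-modality association

$$\min_W \tfrac12 \sum_{m=1}^M \lVert y - \tilde X^m w^m \rVert^2
  + \lambda \lVert W \rVert_{2,1},
\qquad \lVert W \rVert_{2,1} = \sum_{j=1}^d \lVert W_{j\cdot} \rVert_2,$$

with $\tilde X^m$ either the raw ($X^m$) or reconstructed ($W^f X^m$)
features. The row penalty zeroes ROI rows jointly across modalities, so
selected supports coincide between modalities by construction. The solver is
FISTA with backtracking line search, a monotone restart (an overshooting
momentum step is discarded and the iteration restarts from the current
iterate, so the objective trace is non-increasing by construction), a
deterministic $W = 0$ (or warm-start) initialization, and an objective-based
stop (relative change below $10^{-10}$ by default, 5,000 iterations cap).
The loss and gradient are evaluated through residuals rather than the Gram
quadratic form: the latter carries absolute rounding noise
$\sim \varepsilon \lVert y \rVert^2$ that floors attainable weight accuracy
near $10^{-7}$, while the residual form leaves only relative error. The
response is centered before fitting; the intercept is implicit and
irrelevant to the correlation metric. No sign constraint is placed on $W$.
The single-modality lasso baseline is the exact $M = 1$ special case (the
row norm degenerates to $|w_j|$); the concatenated baseline stacks
modalities column-wise first.

# Evaluation protocol

`run_variant()` implements repeated, class-stratified, nested
cross-validation for the nine-rung comparison ladder
$\{$SM, CM, MM$\} \times \{$raw, SN, FSN$\}$. Within each outer training
fold: features are z-scored with training-fold moments (applied unchanged to
the held-out fold); networks are estimated from training subjects only;
training features are reconstructed; the penalty is chosen on an inner
stratified split by maximizing the mean inner-fold test correlation summed
over modalities (exact ties go to the smaller penalty, and the grid is
walked from large to small with warm starts); the model is refit on the full
training fold and scored on the held-out fold. Per-repeat scores are fold
averages; reports give mean and SD across repeats. The correlation of a
zero-variance prediction is defined as 0, penalizing degenerate all-zero
fits rather than producing NaN. The default penalty grid spans
$10^{-5}$ to $3$ in alternating $1\times/3\times$ steps.

**Held-out subjects and the reconstruction.** The training-fold networks
cannot contain test subjects, and test diagnoses must not be used. The
default (`sparse_code_on_train`) codes each held-out subject as a
nonnegative sparse combination of *all* training subjects, label-free, and
maps it through the same reconstruction the training features received
($\hat x = c^\top \tilde X_{\text{train}}$). `raw` skips test
reconstruction; `transductive` reproduces the literal all-subjects reading
of the fused model and is documented as label-leaking — use it only for
diagnostics. Networks are estimated once per outer fold; the inner split
tunes the regression penalty only.

`screen_snps()` loops the chosen variant over a genotype table (skipping
monomorphic SNPs and dropping missing calls per SNP), `rank_rois()`
aggregates absolute association weights over repeats and folds,
max-normalizes, and reports per-modality, overall (row-group norm), and
consistent (intersection) rankings, and `top_edges()` returns the strongest
group-mean connectivity edges at a chosen ROI.

# The synthetic cohort generator

No subject-level data from the motivating study are public, so
`simulate_dataset()` emulates its structure: $c$ diagnosis classes
(defaults 64/78/29, the study's pooled class sizes), $M = 2$ modalities,
$d = 116$ ROI features carrying the AAL-116 labels. Each class and modality
gets a random orthonormal `subspace_dim`-basis (default 4); subjects are
Gaussian combinations of their class basis, scaled to roughly unit feature
variance, plus i.i.d. measurement noise (`noise_sd_features`, default 0.5).
A `support_size`-row coefficient matrix (default 6) with support shared
across modalities drives the latent response from the *noise-free*
features — genotype influences the underlying phenotype; scanner noise
cannot flow back into the genome. The additive mode thresholds the latent
response at its empirical tertiles onto $\{0,1,2\}$, a deliberate
simplification (balanced codes, monotone link) of an allele-frequency
model.

Two generator choices deserve justification:

- **Severity gradient (`class_sep`, default 0.3).** The support ROIs also
  carry a class-mean shift $\mathrm{class\_sep} \cdot g_c \cdot
  \mathrm{sign}(w_{jm})$ with centered class grades $g_c$. Without it,
  diagnosis labels are statistically independent of the response, and a
  diagnosis-guided method could not possibly help — contradicting the
  premise the framework is built on (the same regions that separate severity
  grades carry the genotype association). The default 0.3 puts roughly a
  quarter of the latent response variance between classes, consistent with
  the magnitude of held-out correlations around 0.4 that diagnosis-guided
  association studies report: much larger values make the genotype a
  deterministic function of the diagnosis, much smaller ones make diagnosis
  uninformative.
- **What the generator does not emulate.** Site effects, covariate structure
  (age, sex, education), linkage disequilibrium between SNPs, non-Gaussian
  BOLD artefacts, and unbalanced missingness. Tests passing on this
  generator show the estimators and protocol are correct and calibrated on
  clean class-subspace data; they do not certify performance on real
  cohorts.

Fixture sizes used by the end-to-end property checks (chosen once, stated
here as the package's own choices): solver-oracle checks use 50+ random
instances at $N \le 40$, $d \le 15$; diffusion convergence uses 60 subjects
(3 x 20), $d = 60$; support recovery uses 150 subjects (3 x 50), $d = 60$,
$k = 6$, noise 0.5 over 20 seeds; null calibration uses permuted responses
on 60 subjects, $d = 40$, feature noise 2.0, all nine ladder variants over
20 seeds; the ladder-ordering comparison runs the study-sized generator
defaults with feature noise 2.0 (a weak raw-feature regime matching the
small raw-modality correlations such studies print) over 20 seeds.

# Numerical and degenerate-input conventions

- Zero-variance ROI time series, constant feature columns, subject-id
  mismatches, >2 alleles at a SNP, and penalty grids that are not strictly
  increasing are hard errors naming the offender.
- Classes of size one, subjects with no within-class affinity mass, and
  monomorphic SNPs degrade gracefully (zero rows / skipped columns) with
  warnings.
- Heterozygote calls are order-insensitive; a 50/50 allele tie takes the
  lexicographically smaller allele as major. Missing calls drop the subject
  for that SNP only, with counts recorded.
- All randomness flows from explicit integer seeds (fold assignment uses
  `seed + repeat`; inner splits derive deterministically from the outer
  seed), making every report bitwise-reproducible.

# Known limitations

- **Prototype collapse of the fused reconstruction.** The diffusion with a
  fixed row-stochastic within-class kernel converges geometrically to a
  per-class-constant matrix, so at convergence the reconstructed features
  are class prototypes: within-class variation is discarded. Two
  consequences, both visible in the acceptance checks: (i) with three
  classes the between-class mean space is two-dimensional, so planted-ROI
  sets larger than ~2 become mutually redundant after fusion and a
  group-sparse fit correctly selects only one or two of them — per-ROI
  support recovery through the fused model is structurally limited, while
  the identical pipeline on raw or single-network-reconstructed features
  recovers the full planted support; (ii) the single-network (SN)
  reconstruction, whose rows are least-squares codes of each subject,
  retains subject-level signal that the fused reconstruction loses, and on
  the synthetic cohorts it scores at least as well. Fast diffusion
  convergence and subject-level fidelity of the fused features are mutually
  exclusive under these update equations; the package implements them as
  printed and documents the trade-off rather than altering the model.
- The $\{0,1,2\}$ response is treated as numeric in a squared-error model
  (as in the motivating framework); ordinal/logistic losses are out of
  scope.
- Affine or kernelized self-expression and fusion of more than ~10
  modalities are out of scope.
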