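---
title: "Scrambled-edge ensemble classification of wavelet connectomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scrambled-edge ensemble classification of wavelet connectomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoscramble)
```

## The problem

Functional connectomes — inter-regional correlation matrices of the BOLD
signal on a fixed parcellation — can be classified by phenotype (here: sex)
with convolutional networks, but two methodological problems dominate the
design space. First, any fixed spatial encoding of a graph (rows, columns,
cross-shaped filters) biases gradient-based saliency toward whole rows or
columns rather than individual connections. Second, covariates such as
intracranial volume (ICV) and head motion differ systematically between the
classes, so a classifier can reach high accuracy without learning anything
about brain function.

This package implements a pipeline that addresses both: every classifier in
an ensemble sees the unique edges of the connectome in its *own random
order* laid out on a grid (removing spatial priors and decorrelating the
encoding bias across members), and every member trains on a subsample in
which five covariates have been made statistically indistinguishable
between classes. Interpretability comes from two independent probes: guided
gradient class-activation maps (CAMs) carried back through each member's
permutation to edge space, and paired include/exclude occlusion experiments
on a-priori brain networks.

All components are exercised end-to-end on synthetic cohorts with known,
plantable class effects; no restricted data are required anywhere.

## Wavelet-band connectomes

Parcel time series (116 AAL regions) are decomposed into three frequency
bands — 0.05–0.1, 0.03–0.05 and 0.01–0.03 Hz — and the Pearson correlation
of the coefficients between all parcel pairs forms one symmetric
116×116 matrix per band.

The decomposition is a maximal-overlap discrete wavelet *packet* transform
(MODWPT; Daubechies db4 by default, periodic boundary, non-decimated). We
use packets rather than plain MODWT scales for a concrete numerical
reason: the dyadic scale-j passband is $[1/(2^{j+1}\Delta t), 1/(2^j\Delta
t)]$ Hz, and at a typical sampling interval ($\Delta t = 0.735$ s) the
target band edges fall *on* dyadic boundaries — a 0.04 Hz oscillation sits
at the scale-4/5 boundary, where every finite orthogonal filter (we
checked the squared-gain cascades of db4 through db38) splits its energy
roughly 60/40 between neighbouring scales. Depth-$J$ packets subdivide
$[0, \text{Nyquist}]$ into $2^J$ equal spans; with the depth chosen so one
packet is about half the narrowest target band, the packet edges track the
band edges closely and a 0.04 Hz tone lands >99% inside its band with the
8-tap db4 filter. Each band receives every packet overlapping it by at
least half a packet width; `band_spec()` prints the resolved assignment.

Two caveats documented as behaviour, not bugs:

* Wavelet coefficients are band-limited, hence autocorrelated. For
  independent white-noise parcels the null standard deviation of an edge
  correlation is $\approx\sqrt{2^J/T}$ (effective sample size
  $T\times$ bandwidth/Nyquist), not $1/\sqrt{T}$; tests use the corrected
  bound.
* The first $(2^J-1)(L-1)+1$ coefficients of each packet are affected by
  the periodic boundary; they are retained (deterministic, length
  preserving) and counted in the `n_boundary` attribute.

## The synthetic cohort generator

The generator emulates what the pipeline assumes about a large
population-imaging cohort, with one master seed driving covariates, time
series and connectomes through independent derived substreams.

**Covariates.** Five balancing covariates (age, ICV, mean framewise
displacement, DVARS, spike percentage) are drawn from class-conditional
normal models per sex × condition cell. Defaults: male ICV 1.6×10⁶ mm³ vs
female 1.4×10⁶ mm³ (sd 10⁵) — a deliberately strong ~2 sd confound —
and motion summaries higher at rest than during the task with a small male
excess. Age is identical across cells.

**Connectomes.** A per-band population mean is generated on the Fisher-z
scale from a rank-4 latent-factor model ($z_0 = LL^\top$, loadings
$\mathcal N(0, 0.35^2)$), so matrices are realistic correlation-like
objects with shared structure rather than i.i.d. edges (which would make
classification trivially easy). Each subject adds i.i.d. symmetric edge
noise (sd 0.1 in z), and class effects are planted *additively in z* on
the inner edges of a chosen node set: males shifted by $+d/2$, females by
$-d/2$ noise-sd units, only in the stated condition and bands. The
back-transform $r = \tanh(z)$ keeps every value inside $(-1, 1)$, and
because $\tanh$ is smooth and monotone the standardized effect measured on
the $r$ scale recovers the planted $d$ closely (verified to ±0.15 at
n = 1000 in the tests). No public characterisation of the target
population's edge-weight distribution exists, so the base-model parameters
are exposed in `cohort_spec()` rather than fixed.

**What the generator does not emulate:** voxel-level imaging, scanner
artifacts, motion spikes in image space, any coupling between the
covariates and the connectome. Passing tests therefore demonstrate that
the *pipeline machinery* recovers known truths — not that real data would
behave this way.

## Confound balancing

Covariates are discretized into equal-width bins spanning each covariate's
full range; within every multivariate bin, subjects are drawn at random
from each class — `min(nA, nB)` per class under the forced 1:1 ratio, which
makes the retained classes *exactly* equal for any seed. Starting at one
bin per covariate, the covariate with the smallest two-sided Mann-Whitney
p-value between the retained classes is refined by one bin and matching is
re-run from scratch (stateless), until every p exceeds 0.10 — the first,
i.e. minimum-total-bins, passing configuration is kept. Worst-covariate-
first refinement is a deterministic greedy choice; bin edges are computed
on the full table so the bins define a cross-class correspondence. The
Mann-Whitney test is the tie-corrected two-sided normal approximation and
is evaluated on the *retained* subset — that is the quantity the
certificate claims.

Two-factor balancing applies the algorithm twice: by sex with the forced
1:1 ratio, then by rest/task condition with no forced ratio. For the
unforced stage each bin retains subjects in (approximately) the overall
input class ratio ($k_B = \min(n_B, \lfloor n_A/r\rfloor)$,
$k_A = \min(n_A, \mathrm{round}(k_B r))$ with $r$ the global ratio), which
preserves the original rest/task mix while still equalising covariate
distributions as bins refine. Note the second stage can perturb the exact
1:1 sex ratio of the first — the certificates report what holds on the
final subset.

## The scrambled-CNN member and ensemble

Each member draws a seeded bijection of the 6,670 unique edges (the strict
upper triangle of the 116-node matrix; the unit diagonal carries no
information) onto a 115×58 grid, row-major, with the *same* permutation in
all three bands, which stack as channels. The classifier is deliberately
small and fixed: 256 filters, each spanning one full grid row across the
bands (58×3 = 174 values per application), batch normalization, ReLU,
flatten, then three dense layers of 64 units with batch norm, ReLU and 0.5
dropout, into a two-way softmax trained with Adam (step 10⁻³) under
categorical cross-entropy. On a scrambled grid a "row" is just a random
sample of edges, so the convolution is pure weight sharing — a regularizer,
not a spatial prior. Data split 4:1:1 (train:validation:test) at subject
level, stratified by class, floor for validation/test with the remainder
to train; the epoch with the highest validation accuracy is restored, ties
to the earliest epoch. Batch size (64) is a package default; the batch-norm
epsilon (10⁻³) and momentum (0.99) follow common framework defaults. The
forward/backward passes are written in base matrix algebra and checked
against central finite differences in the test suite; a `use_conv = FALSE`
switch gives the fully-connected baseline with the same dense stack.

K members train on independently drawn balanced subsamples (fixed global
bins, fresh seeded draw and fresh codec per member). A subject's ensemble
vote is the mean class-1 probability over the members in whose *held-out
test set* it appeared; members never evaluate test data during training,
so no vote mixes train and test information and no subject is counted
twice in any AUROC. AUROC is the rank-sum estimator (ties counted ½),
cross-checked against an independent implementation in the tests.

The ensemble-size curve (AUROC of the first j members, in seeded training
order) is fitted with the logistic growth model $y = a/(1 + be^{-kx})$,
$k>0$, $a \le 1$ (an AUROC cannot exceed 1), by Levenberg–Marquardt least
squares over a small start grid; 95% bounds on the asymptote $a$ come from
the asymptotic covariance. A flat series returns $a$ equal to the level
with $k$ flagged unidentifiable; a decreasing series warns and falls back
to a level fit rather than erroring.

## Saliency: guided Grad-CAM in edge space

For one member and subject, Grad-CAM computes channel weights
$\alpha_f$ as the spatial (row-)average of $\partial y_c/\partial A_{rf}$
at the conv feature maps using *plain* gradients, and the row map
$\mathrm{ReLU}(\sum_f \alpha_f A_{rf})$; this is broadcast over each row
and multiplied by the guided-backpropagation input gradient, then mapped
through the member's inverse permutation to (edge, band) space.

Two implementation decisions deviate from the obvious reading and were
forced by measurement on planted-effect cohorts:

* **Plain gradients for $\alpha$.** Using the guided (gate-filtered)
  dense-path gradients for the Grad-CAM weights degrades recovery of
  planted edges (measured standardized recovery 0.66 vs 1.0 on a trained
  member); proper Grad-CAM uses unmodified gradients, and so do we.
* **Magnitude at the input layer.** The guided rule zeroes negative
  gradients *at ReLU layers*; the first (input) layer is not a ReLU, so
  the guided input gradient is still signed. For the female class the
  gradient on male-shifted edges is negative; clamping it to zero
  anti-selects exactly the informative edges and the class-averaged map
  loses the planted effect entirely. Taking the absolute value at the
  input layer only keeps the map non-negative and class-symmetric while
  preserving recovery.

Per subject, maps are averaged over the members holding the subject in
their test set, both target classes (equal weight) and the three bands,
giving one symmetric 116×116 CAM with zero diagonal; per-class maps remain
available through `member_cam()`. Network comparisons report pooled-sd
Cohen's d of in-set versus out-of-set CAM values per stratum — an effect
size, not a significance test, because the pooled value counts are
enormous. A property worth knowing: CAMs reflect what the *model* attends
to, so a rest-only planted effect also elevates CAM values of task
subjects' maps on those edges; the occlusion probe, not the CAM, is the
stratum-specific instrument.

## Occlusion

For each network and encoding (inner: 45 edges; connecting: 1,105), paired
member sets train on half of the edges — `floor(6670/2) = 3335`, the odd
edge left to the random fill — where the include arm's half always
contains the network's edge set and the exclude arm's never does, with a
fresh random fill per member. The masked grid is 115×29 and the filter
still spans one full row. Arms are compared per stratum by a two-sided
Mann-Whitney U test on the member AUROCs, Holm-corrected across all
network × mode × stratum tests in the report (the correction family is the
whole report — a documented choice). Mask constraints are verified
structurally, and a test confirms occluded edges never influence
predictions (zeroing them changes nothing).

## Problem sizes and numerical choices in the shipped tests

The test-suite experiments are scaled-down analogues chosen as the
package's own study conditions: cohorts of 150–2,000 subjects; a planted
salience-network rest-only effect of d = 2.0, sized so a single member
reaches a rest-stratum AUROC near 0.85; members with 24–32 filters and
20–35 epochs (the reference configuration is 256 filters and 100 epochs);
K = 16–30 members; occlusion with 20 members per arm on the salience
inner-edge cell. Balancing runs at the full n = 2000 with the default
strong ICV confound. The Mann-Whitney threshold (p > 0.10), split ratio
(4:1:1), grid shapes (115×58, 115×29) and the edge-count combinatorics
(45 / 1,105 / 6,670) are fixed properties of the design, not tuning knobs.

## Known limitations

* The networks shipped in `networks.yaml` resolve named regions to AAL-116
  parcels by a documented, overridable table; in particular the subgenual
  anterior cingulate has no dedicated AAL-116 parcel (the medial
  orbitofrontal pair stands in), and the DMN/CEN share the inferior
  parietal pair. Pass your own YAML to `load_networks()` to change any of
  this.
* Training is plain single-threaded R matrix algebra — adequate for the
  scaled-down experiments here, not for hundreds of members at full size.
* The generator's covariates are independent of its connectomes, so
  balancing can be validated only as a *distributional* contract; nothing
  in the synthetic world lets a classifier cheat via covariates.
* `wilcox.test`'s normal approximation is used throughout (cohorts here
  are large); exact small-sample p-values are not.

## A minimal worked run

```{r example, eval = FALSE}
nets <- load_networks()
spec <- cohort_spec(400, seed = 7,
                    effect_plan = list(effect_entry(nets$SAL$nodes,
                                                    condition = "rest",
                                                    d = 2)))
ph <- generate_phenotypes(spec)
wc <- generate_connectomes(ph, spec)
bal <- balance_two_factor(ph, balance_config(seed = 7))
ens <- run_ensemble(wc$edges, ph, k = 10,
                    member_config(n_filters = 32, epochs = 25,
                                  batch_size = 32),
                    balance_cfg = balance_config(seed = 7), seed = 7)
cams <- aggregate_cams(ens$members, wc$edges)
network_effect_sizes(cams, nets, ph$condition)
```
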