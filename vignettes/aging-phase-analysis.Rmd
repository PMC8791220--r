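---
title: "Aging-phase analysis of age-course transcriptomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aging-phase analysis of age-course transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agephase)
```

## The problem

Bulk RNA-seq age courses in mouse skeletal muscle suggest that "old age"
is not one phase: gene expression drifts gradually up to about 24 months
(the *young-old* state) and then changes abruptly between 24 and 28
months (the *old-old* state). `agephase` implements the analysis chain
that makes this distinction quantitative:

1. **Differential expression** between age groups with a
   negative-binomial (NB) Wald test on median-of-ratios-normalized
   counts.
2. **Phase classification** of every gene from the two interval
   contrasts — early aging E (2 → 24 months) and late aging L
   (24 → 28 months) — into E, L, EL (changed in both), or none, with EL
   genes subtyped as *downturn* (up then down), *upturn* (down then up),
   or continuous.
3. **Trajectory quantification**: Euclidean distances between group
   mean transcriptomes, per-month divergence rates, PCA, and a
   nearest-group (reversion) index that detects the return of old-old
   expression profiles toward young levels.
4. **Gene-set inference**: pre-ranked enrichment with permutation
   p-values, per-sample enrichment scores with differential-enrichment
   calls between age groups, and hypergeometric over-representation.
5. **qPCR copy number**: ΔΔCT relative quantification and the
   mitochondrial-to-nuclear copy ratio, correlated with gene-set mean
   expression across ages.

Because no public dataset accompanies this design at desk scale, the
package ships a first-class synthetic-data module that generates
age-course count matrices with *planted truth*, so that every stage of
the pipeline can be validated end to end: sensitivity and false
discovery of the phase classifier, calibration of the DE test, recovery
of planted divergence-rate ratios, detection of coordinated gene sets,
and the coupled copy-number correlation.

## The synthetic age course

`sim_config()` fixes the study conditions: five age groups at 2, 10, 18,
24 and 28 months with 6 replicates each (4–6 per group is supported; the
emulated design used 4–6 mice per age). Counts are drawn as

$$K_{gs} \sim \mathrm{NB}\!\left(\mu_{gs},\ \alpha_g\right),\qquad
\mu_{gs} = m_g \, f_s \, 2^{\,c_g(a_s)},\qquad
\mathrm{Var} = \mu + \alpha\mu^2,$$

with per-gene baseline means $m_g$ log-normal (location $\log 200$,
scale 1 — a typical moderately expressed transcriptome slice), per-gene
dispersions $\alpha_g$ gamma-distributed around 0.05 (shape 20), and
library-size factors $f_s$ log-uniform on $[0.5, 2]$ (no library-size
distribution is implied by real data; log-uniform spans the usual
two-fold spread). $c_g(a)$ is the planted cumulative log2 fold change of
gene $g$ at age $a$.

Planted classes fix the interval effects $(\mathrm{lfc}_E,
\mathrm{lfc}_L)$ at magnitude `effect_lfc` (default 2): `E_up`/`E_down`
change in E only, `L_up`/`L_down` in L only, `EL_downturn` $(+e, -e)$,
`EL_upturn` $(-e, +e)$, and `cont_up`/`cont_down` $(\pm e, \pm e)$.
Intermediate ages (10, 18 months) interpolate the E effect *linearly in
log2 space* between the 2- and 24-month anchors — the simplest monotone
choice; only the endpoints are constrained by the emulated design. The
biphasic classes therefore return exactly to young levels at 28 months,
which is what produces the reversion-toward-the-young geometry.

One master seed feeds three documented substreams (counts, gene sets,
qPCR) so the modules can be regenerated independently; identical
configurations give byte-identical outputs, and the caller's RNG stream
is never disturbed.

What the generator does **not** emulate: sex and strain covariates,
batch structure, gene–gene correlation beyond the planted sets,
length/GC biases, and count outliers. Passing tests on this data
therefore demonstrate the correctness and calibration of the
*algorithms*, not robustness to every artifact of real libraries.

## Differential expression

Size factors are median-of-ratios: with reference genes $R$ (strictly
positive in every sample) and geometric means $g_r$,
$f_s = \mathrm{median}_{r \in R}\, K_{rs} / g_r$. No further rescaling is
applied. This is the field's standard normalization restated as math.

Dispersion is a plain per-gene method-of-moments estimate on normalized
counts, $\hat\alpha_g = \max\{(\hat v_g - \hat\mu_g)/\hat\mu_g^2,\
10^{-8}\}$, with $\hat v_g$ the within-group variance pooled across all
age groups (23 residual degrees of freedom at the default design). No
trend or shrinkage is applied; relative to moderated estimators this
costs a little power at low counts but keeps the estimator transparent,
and the test remains calibrated (see below).

Group means are fitted as the mean of size-factor-normalized counts,
$\hat q = \frac{1}{n}\sum_s K_s/f_s$ — each observation inversely
weighted by its size factor — so the fit is invariant to rescaling any
one sample's library. The reported effect is the pseudocounted ratio
$\log_2\frac{\hat q_B + 0.5}{\hat q_A + 0.5}$ (pseudocount 0.5 avoids
infinities on zero groups), the standard error follows from the NB
variance at the fitted means,

$$\mathrm{Var}(\log_2 \hat q) =
\frac{1}{\ln^2 2}\left(\frac{\sum_s 1/f_s}{n^2\,\hat\mu} +
\frac{\alpha}{n}\right),$$

and the Wald statistic $\log_2\mathrm{FC}/\mathrm{SE}$ is referred to
the standard normal, two-sided, with BH adjustment across genes.
All-zero genes are emitted with $p = 1$ and flagged rather than dropped.
On pure-null simulations at the default design, the p-value distribution
is uniform to Kolmogorov–Smirnov distance ≈ 0.01 and the type-I error at
nominal 0.05 is ≈ 0.054 (recomputed by the test suite and the acceptance
script).

Two DEG definitions coexist in this analysis tradition and both are
exposed in `call_degs()` rather than one being guessed as canonical: the
volcano criterion (fold change > 2 and raw $p < 10^{-5}$) and the
default criterion (fold change > 2 and adjusted $p < 0.001$). All
inequalities are strict.

## Phase classification

With interval tables $E$ (24m vs 2m) and $L$ (28m vs 24m):

* **E**: $p^{adj}_E < 0.001$ and $p^{adj}_L > 0.1$;
* **L**: symmetric;
* **EL**: $p^{adj}_E < 0.001$ and $p^{adj}_L < 0.001$;
* **none**: everything else.

The grey zone $0.001 \le p^{adj} \le 0.1$ in the "other" interval
deliberately maps to **none**: the rule requires clear non-significance
($p^{adj} > 0.1$) for a single-phase label, so the gap is unclassified
by construction, not by accident. A relaxed significance cut (0.05) is
available for sensitivity re-counts and can only grow the EL set on
fixed tables (a tested monotonicity property). EL subtypes come from the
signs of the reported fold changes — significance in both intervals is
already guaranteed by EL membership, so no extra test is run; exact-zero
fold changes on EL genes are flagged indeterminate and excluded from
subtype counts. The full-span 28m-vs-2m contrast is computed for
reporting but plays no role in classification. No minimum-expression
filter is applied before classification.

## Trajectory, distance and reversion

Distances operate on $\log_2(x + 1)$-transformed normalized counts. The
emulated analysis used a variance-stabilizing transformation; its exact
parameters are data-dependent, and every quantity derived here (distance
ratios, rankings, PC geometry) depends only on a monotone
variance-flattening transform, so the explicit $\log_2(x+1)$ surrogate
is used and documented as a deliberate deviation. Whether distances are
taken on transformed or merely normalized counts was ambiguous in the
source analysis; transformed is used here.

The transcriptomic distance between age groups is the Euclidean distance
between group mean profiles over the **whole gene universe**; PCA, in
contrast, uses the top 5,000 most variable genes (both config-exposed).
Per-month divergence rates divide consecutive-interval distances by the
age gap in months, and the rate ratio reports the last interval against
the preceding one. The reversion index ranks groups by distance to a
reference (youngest) group, ties broken youngest-first for
reproducibility; PC signs are fixed so each loading's
largest-magnitude entry is positive.

Two geometric facts about the synthetic design are worth stating
explicitly because they shape what "reversion-toward-the-young" means
here. First, with linear interpolation the 10-month group sits only 36%
of the way along the E effect for *all* changed genes, so on the whole
universe the 10m group is always the nearest to 2m — the whole-universe
reversion of real data (where 28m was nearest even against 10m) reflects
maturation drift between 2 and 10 months that the generator does not
plant. Second, the reversion signature is carried by the biphasic EL
genes, whose 28-month means return to young levels; continuous EL genes
keep drifting. The acceptance experiment therefore plants the changed
genes as two-thirds biphasic EL (mirroring the emulated proportions),
classifies phases, and computes the reversion index on the EL-labeled
subset — the chain of operations that defines the assimilation readout.

## Gene-set inference

`preranked_es()` is the classic weighted running-sum score on the
fold-change-ranked gene list (ties broken lexicographically by gene id
for determinism): hits add $|r|^w / \sum_{hits} |r|^w$ (default
$w = 1$), misses subtract $1/(N - N_{set})$, and the score is the
running-sum value of largest magnitude; the leading edge is the set
members at or before (positive score) / at or after (negative score) the
extremum. Permutation p-values use **gene-label sampling** — random
same-size sets — rather than sample permutation, matching the fast
pre-ranked approach; the two nulls are not the same thing, and the
choice is stated here deliberately. P-values are sign-consistent,
$(1 + \#\{|ES_{null}| \ge |ES|,\ \mathrm{sign\ match}\})/(n_{perm}+1)$,
never zero, and deterministic under a fixed seed.

`per_sample_scores()` ranks genes *within* each sample and scores each
set by the normalized integral of the hit-minus-miss running sum,
$\mathrm{score} = \sum_i \mathrm{run}(i) \,/\, \frac{N+1}{2}$, with
unweighted increments by default. At weight 0 this equals a scaled
difference between the mean rank of non-members and members, so it is
bounded in $[-1, 1]$, symmetric for up- and down-shifts, exactly
invariant under monotone transforms of a sample, and — unlike the
max-deviation statistic — responds *linearly* when a set's members shift
coherently in rank while remaining scattered across the distribution.
That linearity is what makes group comparisons of set activity sensitive
to planted coordinated programs; the max-deviation score measures
absolute concentration at an extreme and barely moves for such shifts.

Differential enrichment between two sample groups applies a Welch
two-sample test per set to the per-sample scores, BH across sets, and
calls sets at $p^{adj} < 10^{-5}$ with an absolute score difference
above 0.5. The "fold-enrichment" of the emulated analysis is undefined
for non-positive scores; the difference of group mean scores on the
bounded symmetric scale is the documented operationalization. A plain
Welch test replaces the moderated test of the original toolchain — with
at least 4 samples per group and thresholds this large the calls are
expected to coincide, and the substitution is deliberate.

One saturation effect is intrinsic: sets planted from the *continuous*
classes are already at $\pm$`effect_lfc` by 24 months, so their
additional late-interval shift is compressed at the tails of the rank
distribution, and no rank-based score can move them by > 0.5 on a
$[-1,1]$ scale. Detection claims are therefore stated for sets planted
from the four phase-defining late-active classes (`L_up`, `L_down`,
`EL_downturn`, `EL_upturn`), whose members traverse the bulk of the
ranking within the tested interval.

Over-representation uses the one-sided hypergeometric upper tail via
`stats::phyper`, BH across sets, reporting the overlap/set-size
fraction.

## qPCR quantification

`delta_delta_ct()` averages replicate Cts per (sample, target), forms
$\Delta Ct = Ct_{target} - Ct_{ref}$, centers on the *arithmetic mean*
$\Delta Ct$ of the calibrator group (the standard ΔΔCT convention —
equivalently, the calibrator's geometric-mean quantity is exactly 1),
and reports $2^{-\Delta\Delta Ct}$. Amplification efficiency is assumed
to be exactly 2 (no efficiency correction), per the classical formula.
The mitochondrial copy ratio is $2^{Ct_{nuclear} - Ct_{mito}}$ without
the ×2 diploid-genome correction: it cancels in every trend and
correlation analysis. The copy–expression correlation is computed on
per-age-group means (five points at the default design) — computing it
per sample instead is possible but was not the convention adopted here;
at least three matched groups are required.

The simulated plate couples the planted log2 copy ratio to the mean
planted expression shift of the `EL_downturn` class (a downturn shape
over age) around a baseline of $2^{10}$ mitochondrial genomes per
nuclear genome — the order observed in muscle — with replicate noise of
0.15 cycles.

## Numerical and reproducibility choices

* Dispersion floor $10^{-8}$; zero-mean genes are floored with a log
  note rather than dropped.
* Strict threshold inequalities everywhere thresholds appear.
* Ranking ties broken lexicographically by gene id; reversion ties by
  age, youngest first; PC signs fixed by the largest-magnitude loading.
* All randomness flows from explicit seeds; `run_all()` with the same
  config and seed produces byte-identical TSVs, and a manifest records
  inputs, a config hash and the seed.
* Problem sizes used by the validation suite — 10,000 genes, 200 genes
  per planted class, 6 replicates per group, 20 replicate simulations
  for the rate-ratio and reversion experiments, 200 random sets for
  false-positive control — were chosen to make recovery margins and
  calibration measurable at desk scale.

## Known limitations

* The NB Wald test with unshrunken MoM dispersions is slightly
  conservative for weakly expressed genes; at the planted effect sizes
  this costs little, but real low-count genes near thresholds would
  benefit from trend shrinkage.
* The $\log_2(x+1)$ transform is a surrogate for a fitted
  variance-stabilizing transform; absolute distances are therefore not
  comparable across datasets, only within an analysis.
* Gene-label permutation nulls for pre-ranked enrichment understate
  inter-gene correlation; p-values for strongly correlated sets are
  optimistic relative to sample-permutation nulls.
* The per-sample score's mean-rank linearity trades away sensitivity to
  *concentration-only* changes (a set tightening at an extreme without
  changing its mean rank).
* No covariates: sex, strain, batch and library-preparation effects are
  out of scope end to end.
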