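---
title: "Models and methods in thyrex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in thyrex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrex)
```

`thyrex` packages the quantitative machinery used to study how thyroid
hormone (T3) shifts mice toward exploratory decision-making: a two-armed
bandit task (2ABT) simulator, a Q-learning model of choice with
maximum-likelihood fitting, the behavioral statistics built on session
logs, a pseudocell differential-expression procedure for calling
thyroid-responsive genes (TRGs) from single-nucleus counts, entropy
metrics over behavioral-syllable streams, and Hill-sigmoid fitting of
optogenetically evoked post-synaptic charge. Every stage has a seeded
synthetic-data generator that emits ground truth, so the whole pipeline is
testable against known answers.

## The bandit task

On each trial a mouse chooses a left or right spout. One spout — the
"high" spout — rewards a lick with probability `p_high` (default 0.8), the
other with `p_low` (0.2). The high-spout identity reverses, without any
cue, at block boundaries. Two block schemes are first-class: a fixed
length of 20 trials, and a variable scheme drawing 20, 30 or 40 trials
with probabilities 0.43 / 0.32 / 0.25. The simulator (`run_session()`)
samples rewards independently per trial, produces timeouts only when the
supplied policy emits them, and records each block's true sampled length
even when the session ends mid-block.

Two choices the task description leaves open are fixed here and
documented rather than inferred: the initial high spout is drawn uniformly
at random per session (removing side bias from simulations), and block
boundaries never span sessions.

## The Q-learning choice model

Spout values evolve by
$$Q_{c}(t+1) = Q_c(t) + \alpha\,(R - Q_c(t)), \qquad
  Q_{u}(t+1) = (1-\zeta)\,Q_u(t),$$
for chosen spout $c$ and unchosen $u$, with reward $R \in \{0,1\}$,
learning rate $\alpha$ and forgetting rate $\zeta$, both in $[0,1]$.
Choice follows a logistic (softmax) policy with the right spout as the
reference:
$$P(\text{right}) = \frac{1}{1 + e^{-[\beta\,(Q_R - Q_L) + b]}},$$
where the inverse temperature $\beta \ge 0$ sets how strongly choice
exploits the value difference — low $\beta$ means stochastic, exploratory
choice — and $b$ is an additive side bias (flipping the reference spout
only flips the sign of $b$). With rewards in $\{0,1\}$ and initial values
in $[0,1]^2$, values remain in $[0,1]$ for all admissible parameters.

**Fitting.** `fit_q()` maximizes the likelihood of observed choices.
Each session is split into 4 contiguous trial-quarters; a seeded random 3
of 4 (75%) train the model and the remaining quarter is held out. The
training objective is the mean negative log-likelihood per trial, with
values propagated over all trials in order (so held-out trials still move
the value recursion, they just contribute no loss). Timeout trials are
excluded from both likelihood and updates. The default optimizer is
full-batch gradient descent with step size 0.1 for 10,000 iterations —
mirroring the reference procedure — on transformed parameters (logistic
for $\alpha$ and $\zeta$, softplus for $\beta$, identity for $b$) so the
bounds hold without projection; an optional BFGS polish using the same
analytic gradient is on by default. Convergence is declared when the loss
changes by less than 1e-9 over 100 iterations. Held-out accuracy scores
the argmax prediction; a tie at probability exactly 0.5 counts as
incorrect (conservative and deterministic).

Decisions taken where the procedure was under-specified: values reset to
$(0,0)$ at each session start (no cross-session carryover, no leakage);
one fit per mouse per epoch, pooling that epoch's sessions; argmax rather
than sampled predictions for held-out accuracy. The likelihood and
gradient recursion is implemented in C++ for speed; the analytic gradient
is checked against central finite differences to 1e-5 relative in the
test suite.

## Behavioral statistics

All statistics are ratios of integer tallies reproducible by a one-pass
scan of the logs, and are computed per mouse first, then aggregated.

- **Normalized reward rate** — rewards per non-timeout trial, per day,
  excluding the first block of each session (task re-acquaintance);
  reported as percent change from the mouse's habituation-median rate.
- **Transition curves** — p(high) by trial offset around block
  transitions; offset 0 is the first trial of the new block, scored
  against the new high spout, negative offsets against the old one.
  Offsets are confined to the two adjacent blocks, and offsets with no
  eligible trials are `NA`, never fabricated.
- **Recovery time constant** — unweighted least squares of
  $p(n) = A - (A - p_0)\,e^{-n/\tau}$ over post-transition offsets, all
  three parameters free (the reference analysis does not state whether
  the asymptote was constrained; fitting all three is this package's
  choice). Near-constant curves and nonpositive $\tau$ are flagged
  invalid rather than reported.
- **Conditional switch probabilities** — over two-trial same-spout
  histories with outcomes RR, RU, UR, UU ordered older to newer; the
  outcome is the next non-timeout trial (timeouts are transparent, the
  consistent extension of the global timeout exclusion). Histories with
  50 or fewer occurrences per mouse are excluded (strict "> 50").
- **Performance criterion** — any 5-day window with mean daily p(high)
  strictly above 0.6; fewer than 5 days is "not evaluable", distinct from
  failure.

## Pseudocell differential expression

Within one cell type, nuclei are randomly partitioned — within each
(sample, condition, and Cre status when present) stratum — into groups
averaging 30 nuclei, each with at least 15; cell types with fewer than 15
nuclei or fewer than 6 pseudocells are excluded as an outcome, not an
error. Raw UMI counts are summed per group; pseudocell %MT is the
count-weighted mean of member nuclei (weighting is this package's choice
where the rule was unstated). Background genes are those detected in
strictly more than 1% of the subtype's nuclei.

Expression is normalized to counts per 100,000 and log2-transformed with
a pseudocount of 1 (the CP100k log2 scale is named by the procedure; the
pseudocount is ours). Per gene, a linear model regresses expression on
condition plus pseudocell-level covariates (%MT and log2 nGene). Residual
variances are moderated by an empirical-Bayes rule,
$$s^2_{\mathrm{post}} = \frac{d_0\,s_0^2(g) + d\,s^2_g}{d_0 + d},$$
with the trend $s_0^2(g)$ from a lowess fit of log variance on mean
expression and $d_0$ estimated by moments from the spread of log
variances (inverting the trigamma function). The moderated t uses
$d_0 + d$ degrees of freedom; p-values are Benjamini–Hochberg adjusted
within the background set. Setting `d0 = 0` disables shrinkage and
reproduces ordinary per-gene t-tests exactly, which the tests verify
gene by gene. The "robust" outlier down-weighting variant of the
moderated statistic is omitted in this version: its tuning constants are
not specified in the source procedure, and the plain trended moderated t
is the documented core.

**The sample random effect.** Pseudocells from one sample share that
sample's biological state, so treating them as independent replicates
pseudo-replicates the design. When every sample contains both conditions,
sample id enters as a fixed blocking factor. In the usual nested design
(each sample entirely T3 or control) a fixed factor would alias the
contrast, so the package estimates the within-sample correlation of
residual expression per gene by an ANOVA moment method, stabilizes it
with a lowess trend on mean expression (counting noise dilutes the
correlation for weakly expressed genes, so it rises with expression), and
fits by generalized least squares under an equicorrelated model, genes
grouped into small correlation bins. This is the duplicate-correlation
device familiar from the limma ecosystem, extended with the expression
trend; without it, simulated null data with realistic sample-level
variability produced dozens of false TRG calls, and with it the null
yields essentially zero while recall of 2-fold spikes stays above 80%.

**Robustness scores and TRG calls.** For each gene, over all
(T3 sample × control sample) pairs, `robScore_logFC` is
$(n_{\mathrm{up}} - n_{\mathrm{down}})/n_{\mathrm{pairs}}$ computed on
per-sample mean normalized expression (ties contribute zero);
`robScore_pct` is the same on percent-nonzero expression. Only
cross-condition pairs count — the reading consistent with the stated
equivalence that $|\mathrm{robScore}| \ge 0.5$ means concordance in at
least 75% of comparisons (12 of 16 pairs at 4v4). A TRG is any gene with
FDR < 0.05 and $|\mathrm{robScore_{logFC}}| \ge 0.5$; the non-TRG
reference set is the top 10,000 most-expressed genes with FDR > 0.05 and
both robustness scores exactly zero. Cross-cell-type structure is
summarized by Spearman correlations (average ranks) of log2 fold-changes
over the TRG union, clustered with Ward's criterion ("ward.D2") on
Euclidean distances of the correlation matrix. Receptor-manipulation
effects (e.g. dominant-negative THR in Cre+ cells) are summarized by OLS
regression of the manipulation-induced change in log2 fold-change on the
original TRG log2 fold-change — slope near −1 with high R² is the
program-reversal signature — with the disrupted set requiring contrast
FDR < 0.05 and at least a 25% fractional expression change
($|2^{\Delta} - 1| \ge 0.25$).

## Syllable entropies

Frame-level syllable labels are collapsed to instances (maximal runs).
Syllables making up strictly more than 1% of pooled instances across all
sessions are retained; per-session usage is renormalized over the
retained set (the renormalization is this package's choice). Usage
entropy is the Shannon entropy of the usage distribution, in bits (the
base is unstated in the source; bits are conventional). Outgoing entropy
per syllable is the entropy of the next-instance distribution, counted
only between originally adjacent retained instances — so the run-length
construction guarantees no self-transitions even after filtering — and
the session value is the unweighted mean over syllables with at least one
outgoing transition.

## Post-synaptic response profiles

Evoked charge is the baseline-subtracted trapezoidal integral of current
over the 10 ms after stimulus onset, divided by membrane capacitance
(pC/pF); the baseline is the mean over the 100 ms before onset
(configurable; recordings hold a 1 s baseline, of which 100 ms is ample
for synthetic traces). Response profiles versus laser power are fit by
nonlinear least squares to the Hill sigmoid
$$q(x) = \frac{a}{1 + (b/x)^{c}},$$
with saturation amplitude $a$, half-maximum power $b$ and slope $c$ — the
printed formula in the source is typographically corrupted ("a1+bxc"),
and the Hill form is the unique standard sigmoid in which $b$ is a
half-maximum inflection point and $a$ a saturation amplitude, as the
figure legend describes; this reading is a documented decision. The fit
runs in log-parameter space from a 3×3 multi-start grid (best residual
wins, ties to the smaller slope) and is scale-equivariant. Per-cell
effects are reported as log2 fold-changes of each coefficient against the
control-condition median. The paired-pulse ratio divides the second
pulse's 10 ms charge — isolated by subtracting the averaged single-pulse
trace from the paired trace — by the first pulse's. Recording quality
control requires Rm variation < 20%, holding current not more negative
than −400 pA at −70 mV, Rs variation < 25% and a saturating peak above
250 pA, and names every violated criterion.

## Synthetic data: the stated world

Generators are pure functions of their specs (seed included) and always
emit ground truth.

- **Cohorts** (`gen_cohort()`): default 12 mice, 4 sessions per epoch,
  350 trials per session on the 80/20 task with the variable 20–40 block
  scheme. Per-mouse parameters are drawn once from uniform priors chosen
  to span well-trained performers: $\alpha \sim U(0.4, 0.8)$,
  $\zeta \sim U(0.1, 0.5)$, $\beta \sim U(2, 5)$,
  $b \sim N(0, 0.1)$. Treatment multiplies $\beta$ by 0.7, the size of
  decrease that reproduces the qualitative treatment signatures at
  simulation scale.
- **Counts** (`gen_counts()`): 5,000 genes, 4 vs 4 samples, 250 nuclei
  per sample (≈8 pseudocells of 30 each) — far below a real ~10⁵-nucleus
  dataset, sized so a full DE run takes seconds. Gene abundances are
  heavy-tailed (gamma), library sizes log-normal (median 2,500 UMIs),
  counts negative binomial (dispersion 0.15), with per-sample, per-gene
  log-normal intercepts of sd 0.1 — the realistic biological-replicate
  variability that makes the sample random effect matter. 4% of genes are
  spiked at $|log_2FC| \in [1, 2]$ with random sign. Mild gene-specific
  loadings on %MT exercise the covariates.
- **Sweeps** (`gen_psc_sweeps()`): Hill curves on 8 log-spaced powers
  (0.03–4 mW) with 15% per-cell parameter jitter and 5% multiplicative
  noise; T3 scales amplitude ×1.5 and half-power ×0.7, the direction of
  the reported synaptic effects.
- **Syllables** (`gen_syllable_streams()`): first-order Markov chains
  mixing a deterministic cycle with the uniform no-self-transition matrix
  (`stochasticity` interpolates), geometric run lengths of mean 12 frames
  (sub-second at ~30 Hz).

What a green test does and does not establish: the generators emulate the
*structure* of the real inputs (trial bookkeeping, UMI sparsity and
sample variability, multiplicative sweep noise, instance-level syllable
dynamics), not their full richness — no session-to-session learning
drift, no ambient RNA or doublets, no correlated gene programs, no
trace-level electrophysiology artifacts. Green tests establish that the
implementations compute their definitions correctly and that effects of
the stated sizes are recoverable at the stated scales; they do not
reproduce the animal-data effect sizes, which require the original
recordings.

## Numerical choices

Optimizers use generous iteration budgets with tight relative tolerances
(1e-12 to 1e-15) and multi-start where the surface warrants it; the
exponential-recovery and sigmoid fits declare failure (with diagnostics)
rather than return implausible parameters ($\tau \le 0$, nonpositive Hill
coefficients). The trigamma inversion in the variance-shrinkage moment
estimator uses Newton iterations with closed-form endpoints; a
nonpositive moment spread maps to $d_0 = \infty$ (complete shrinkage to
the trend). The BH adjustment is verified against a brute-force step-up
oracle; the Ward clustering against a brute-force Lance–Williams
agglomeration.

## Known limitations

One consensus-trend correlation per cell type cannot capture fully
gene-specific within-sample correlation; strongly outlying genes may
remain slightly anti-conservative. The robust (outlier down-weighted)
moderated t is not implemented. Hierarchical or Bayesian fitting across
mice, alternative RL model comparison, and hypothesis tests between
cohorts are out of scope; downstream tools expect the tidy outputs this
package writes.
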