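---
title: "Mixed condensation-rule diagnosis models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed condensation-rule diagnosis models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Cognitive diagnosis models are restricted latent class models: each of $N$
respondents carries a binary attribute profile $\alpha_n \in \{0,1\}^K$, and
a Q-matrix $q_{ik}$ declares which of the $K$ attributes item $i$ requires.
A condensation rule maps profile and requirements to a latent response
$\omega_{ni}$, and a noisy response function turns it into a probability:

$$P(y_{ni}=1) = g_i + (1 - s_i - g_i)\,\Psi_{ni},\qquad 0 < g_i < 1 - s_i < 1,$$

where $g_i$ (guessing) is the success probability with latent response 0 and
$1 - s_i$ (one minus slip) the success probability with latent response 1.
The three classical rules are conjunctive
($\omega = \prod_k \alpha_{nk}^{q_{ik}}$; DINA), disjunctive
($\omega = 1-\prod_k (1-\alpha_{nk})^{q_{ik}}$; DINO), and ratio
($\omega = \sum_k \alpha_{nk}q_{ik} / \sum_k q_{ik}$; DINR). The mixed model
replaces the committed rule by a convex combination with item-level mixing
proportions $\tau_i$ on the simplex:

$$\Psi_{ni} = \tau_{i1}\,\omega^{\mathrm{conj}}_{ni} +
             \tau_{i2}\,\omega^{\mathrm{disj}}_{ni} +
             \tau_{i3}\,\omega^{\mathrm{ratio}}_{ni}.$$

Unit vectors recover the pure models exactly, a property the test suite
checks over all $2^K$ profiles. For an item requiring only one attribute all
rules coincide, so $\tau_i \equiv (1,0,0)$ is fixed at construction, never
estimated. Any of these models — including the additive ACDM
(intercept + main effects on the identity link) and the saturated GDINA
(intercept, mains, and all interactions; equivalently one free probability
per reduced attribute pattern) — is representable by its vector of
$2^{K^*_i}$ reduced-pattern probabilities, which is how the package
evaluates likelihoods uniformly (`pattern_probabilities()`). For the mixed
model this whole vector is generated by four free numbers
($g_i, s_i, \tau_{i1}, \tau_{i2}$), making it a heavily constrained special
case of the saturated model. Reduced patterns are enumerated in binary order
with the *first required attribute as the least significant bit*; all
pattern-indexed outputs are labelled with their bit strings so the
convention is visible rather than implicit.

## Estimation

`dcm_fit()` runs an explicit Metropolis-within-Gibbs sampler (Rcpp /
Armadillo). Priors are deliberately flat: uniform $(g_i, s_i)$ truncated to
$g_i < 1 - s_i$; Dirichlet(1,1,1) on $\tau_i$; Dirichlet(1,…,1) on the
$2^K$ class proportions $\pi$ (a saturated estimation-side latent structural
model); Beta(1,1) on GDINA pattern probabilities; uniform on the ACDM
constraint polytope. Flat priors keep posterior means comparable with
likelihood-based fits and add no information the data do not carry.

One sweep:

1. **Collapsed refreshes.** With attribute classes integrated out (given
   $\pi$), each item's parameter block receives Metropolis updates: a
   repeated random walk on $(\mathrm{logit}\,g_i, \mathrm{logit}\,s_i)$, an
   independence refresh of $\tau_i$ from its flat prior (acceptance ratio =
   likelihood ratio), and a local additive-log-ratio walk on the simplex.
   $\pi$ itself gets an independence refresh from its conditional Dirichlet,
   accepted against the class-marginalised likelihood. Because classes are
   redrawn from their exact full conditional immediately afterwards, this is
   a valid partially collapsed Gibbs scheme; it exists because the plain
   conditional sampler mixes slowly through the strong coupling between item
   parameters, classes, and class proportions. All marginal-likelihood
   ratios are computed from a per-sweep table $E_{cn} =
   \exp\{\ell_{nc} - \max_c \ell_{nc}\}$ via dot products, so a proposal
   costs one length-$2^K$ exponentiation, not $N \times 2^K$.
2. **Classes.** Each person's class is sampled from its full conditional
   over all $2^K$ classes (no marginalisation), reusing $E$.
3. **Class proportions.** Conjugate Dirichlet draw.
4. **Conditional item updates.** Given the sampled classes, per-item
   sufficient statistics (successes and counts per reduced pattern) drive
   cheap Metropolis updates of $(g_i, s_i, \tau_i)$ on transformed scales,
   conjugate Beta draws for GDINA pattern probabilities, and bound-rejected
   walks for ACDM effects.

Proposal scales adapt per item and block during burn-in (Robbins-Monro
toward 44% acceptance for scalar blocks, 30% for vector blocks) and freeze
afterwards. Tunables with defaults: `chains = 2`, `iter = 10000`,
`burnin = 5000`, `gs_reps = 20` and `tau_reps = 3` collapsed refreshes per
sweep. The refresh counts trade CPU for autocorrelation; the defaults are
sized so that split-chain PSRFs reach the 1.01 convention even at half-length
chains, and model-comparison work can safely lower them since index rankings
stabilise long before per-parameter Monte-Carlo error does.

**Identification and monotonicity.** The saturated GDINA with free pattern
probabilities is invariant to flipping an attribute's polarity (relabel
$\alpha_k$ to $1-\alpha_k$ and permute each item's pattern probabilities);
chains happily settle in flipped labelings, which scrambles profile
estimates, and unconstrained pattern probabilities can drift to extremes on
sparsely occupied patterns, making leave-one-out predictive ordinates
explode. The package therefore imposes the monotonicity constraint that is
the default in the field's GDINA estimators: each pattern probability is
non-decreasing in the mastery partial order, sampled by conjugate Beta draws
truncated to the interval its immediate sub- and super-patterns allow. This
simultaneously pins attribute polarity and regularises the saturated fit.
ACDM main effects are likewise constrained non-negative. The
deterministic-input family needs no anchor: mastery cannot lower its success
probability by construction, and $g < 1-s$ is enforced at every accepted
proposal. Label switching across classes does not arise for the same
reason.

**Numerics.** Bernoulli probabilities are clipped to $[10^{-12},
1-10^{-12}]$ before logs; ACDM/GDINA parameters may legitimately touch the
0/1 boundaries during sampling. A marginal posterior mastery probability of
exactly 0.5 classifies as mastery (documented, arbitrary, fixed). Modal
profiles break frequency ties toward the lower class index. The conditional
predictive ordinate accumulator sums $1/p_{nid}$ directly: with clipping the
summands are bounded by $10^{12}$ and retained draws by $10^4$, so the sum
stays far inside double range and the direct sum is exact — no
log-sum-exp machinery is needed.

## Fit indices and recovery metrics

The deviance is $-2$ times the Bernoulli log-likelihood *conditional on the
sampled attribute classes* — the convention of general-purpose Gibbs
software — so latent classes contribute to the effective parameter count
$p_D$. The plug-in deviance uses posterior-mean item parameters and modal
profiles; DIC $= \bar D + p_D$. The per-response CPO is the harmonic mean of
per-draw likelihoods; item-level $-2\mathrm{LCPO}$ values sum to the
test-level index by construction. Recovery metrics follow the standard
definitions (bias and RMSE across replications; ACCR per attribute; PCCR for
exact profiles; per-profile RMSE of class proportions), and `pccr()` is
provably bounded above by every attribute's `accr()` — a property test.
Whether classification uses element-wise posterior means or modal profiles
is a real choice; both are returned, and element-wise is the default
used by the metrics.

## What the generators emulate

`sim_study1()` reproduces the parameter-recovery design: item quality drawn
on the logit scale from a bivariate normal with means $-2.197$ (mean
guessing/slip 0.100) or $-1.386$ (0.200), unit variances, correlation
$-0.6$, with whole-pair redraws on monotonicity violations (redraw preserves
the marginal shape; the design itself is silent on enforcement); mixing
proportions fixed by block (unidimensional prefix $(1,0,0)$; uniform
$(1/3,1/3,1/3)$; or the skew blocks $(0.6,0.2,0.2)$, $(0.2,0.6,0.2)$,
$(0.2,0.2,0.6)$ at the $8I/15$ and $11I/15$ boundaries); attribute profiles
either equiprobable over all $2^K$ patterns or thresholded at zero from a
multivariate normal with common correlation 0.6 ($\alpha_{nk} = 1$ iff
$\theta_{nk} \ge 0$), giving marginal mastery 0.5 and tetrachoric
correlation ≈ 0.6. `sim_study2()` reproduces the model-comparison design:
$K = 5$, 30 items, two identity blocks, five four-item blocks with shared
q-vectors, and the printed fixed parameter sets with success probabilities
bounded in $[0.1, 0.9]$. The published Q-matrices are figures, not tables;
the shipped matrices are canonical constructions satisfying every textual
constraint (identity submatrices, each attribute measured at least three
times, unidimensional prefix, 2- and 3-dimensional remainder). Exact cell
agreement with the figures is neither recoverable nor required by any
printed number.

What the generators do *not* emulate: attribute hierarchies, Q-matrix
misspecification, polytomous items or attributes, within-item dependence of
$g$ and $s$, or real-data quirks (missingness, speededness, person misfit).
Passing recovery tests therefore demonstrates internal consistency of
model, generator, and sampler under the stated designs — not robustness on
messy empirical data.

## Desk-scale choices

The validation experiments in `tests/testthat/test-acceptance.R` scale the
published designs down to sizes a single CPU handles comfortably:

- recovery: one condition (N = 500, I = 15, higher quality, uniform mixing,
  unstructured profiles), 5 replications, 2 chains × 4,000 iterations
  (2,000 burn-in);
- model comparison: six test situations, 3 replications each at N = 500,
  2 chains × 1,000 iterations with lighter collapsed refreshes;
- generator calibration: $10^5$ Monte-Carlo draws.

Published recovery tables use 30 replications and 2 × 10,000 iterations, so
the tests assert tolerance bands rather than reproducing table cells:
mean RMSE ≤ 0.08 for guessing/slip and ≤ 0.15 for mixing proportions
(the matched full-scale cell reports ≈ 0.05 and ≈ 0.10), and rankings — not
values — of DIC and $-2$LCPO. For profile classification there is no printed
value for the matched condition, so the test compares the fitted-model PCCR
with the accuracy of the Bayes classifier evaluated at the true generating
parameters on the same data (the ceiling the design permits), requiring
agreement within 0.05. The convergence check asserts the 1.01 split-chain
PSRF convention on the recovery fits; `scripts/acceptance.R` also reports it
at the full 2 × 10,000 setting.

## Known limitations

- The saturated estimation-side latent structural model (free $\pi$ over
  $2^K$ classes) matches the unstructured generator but is inefficient when
  attributes are strongly correlated; a structured higher-order model is out
  of scope.
- $\tau_{i3} = 1 - \tau_{i1} - \tau_{i2}$ absorbs both estimation errors,
  so ratio-rule proportions recover worst — visible in the recovery runs and
  consistent with the published tables.
- Maximum-likelihood/EM estimation, Wald-test model selection, and Q-matrix
  validation are deliberately not implemented.
- The rule-identification threshold (default 0.9) applies to the
  conjunctive/disjunctive calls only; no cut-point exists for the ratio
  share, which is judged by strict dominance. `classify_rules()` optionally
  reports posterior exceedance probabilities as an uncertainty-aware
  companion.
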