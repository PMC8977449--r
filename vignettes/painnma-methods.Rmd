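---
title: "Methods: the painnma network meta-analysis model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the painnma network meta-analysis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`painnma` synthesizes a connected network of randomized controlled trials
of drug therapies — its motivating evidence base is pharmacotherapy for
neuropathic pain after spinal cord injury, with placebo as the network
reference — into relative treatment effects, treatment rankings, and
consistency diagnostics. The unit of input is the trial *arm*: a row with
study id, treatment, randomized `n`, and per outcome either events
(dichotomous) or mean change-from-baseline with its SD (continuous).
Validation enforces unique arms, two or more arms per study, positive
integer sizes, `events <= n`, one outcome kind per study/outcome, and a
connected comparison graph; row order never affects the stored object.

When a study reports an outcome at several follow-up times, one record is
selected per study: the record nearest the 4-week target inside a 3–17
week window, with ties broken toward the *earlier* time point (the target
and window are arguments, so the long-term outcome can use a target of 8
weeks and a window starting at 8). The tie rule is a package decision —
the selection priorities are stated by the evidence base, a tie rule is
not — and the earlier record is chosen because it is closer to the acute
phase the primary outcome addresses.

## Effect sizes

Continuous outcomes are standardized because trials use different rating
scales (VAS-10, VAS-100, NRS, …). We use Hedges' *g* rather than plain
Cohen's *d*:

$$g = J \cdot \frac{\bar\Delta_t - \bar\Delta_c}{s_p}, \qquad
  J = 1 - \frac{3}{4(n_t+n_c-2)-1}, \qquad
  \widehat{se}^2 = \frac{1}{n_t}+\frac{1}{n_c}+\frac{g^2}{2(n_t+n_c)}$$

because many trials in this area randomize fewer than 25 participants per
arm, where the small-sample bias of *d* is material. Change scores are
taken as reported; no baseline–endpoint correlation is imputed (none is
available, and the synthetic generator produces change scores directly).
Orientation is normalized at the effect-size level: a negative SMD always
means more symptom relief under treatment, so `higher-is-better` scales
are negated once, in `smd()`, and nowhere else.

Dichotomous outcomes use the Woolf log odds ratio with
$se = \sqrt{\sum 1/\text{cell}}$; when any cell of a study's 2×2 table is
zero, 0.5 is added to all four cells of *that study only* (Haldane
correction, single-study scope — the standard practice).

## Pairwise pooling as the deterministic oracle

`dl_pool()` implements DerSimonian–Laird random effects in closed form
($\tau^2_{DL} = \max(0,(Q-df)/C)$). It serves two roles: the "pairwise"
column of forest tables, and an *independent, deterministic* oracle for
the Bayesian engine — on a two-treatment network with the heterogeneity
matched, the NMA posterior must agree with the DL pool to within Monte
Carlo error, and the test suite enforces exactly that. DL was chosen for
the oracle precisely because it is closed-form: no estimator choice was
stated for the original pairwise analyses, and this divergence is
documented rather than hidden. Comparison-adjusted funnel points center
each study on its own comparison's DL pool; asymmetry is summarized
descriptively by an OLS slope of centered effect on standard error, with
no trim-and-fill.

## The Bayesian model

The consistency model is the standard arm-based random-effects
formulation. Arm $k$ of study $i$ has linear predictor
$\mu_i + \delta_{i,bk}$, where $b(i)$ is the study's anchor arm (placebo
when present, else the alphabetically first treatment) and

$$\delta_{i,bk} \sim N\!\left(d_k - d_{b(i)},\ \tau^2\right),$$

with $d$ the basic parameters relative to the network reference
($d_{ref} \equiv 0$) and a single $\tau$ shared across comparisons.
Multi-arm trials draw the vector $\delta_i$ with pairwise correlation
0.5, the value implied by exchangeable trial effects. Continuous data
enter as anchor-based SMD contrasts with a normal likelihood — the
covariance between two contrasts sharing an anchor arm is approximated by
$1/n_{anchor}$ — while dichotomous data enter as raw arm counts with a
binomial-logit likelihood. Priors, unstated in the motivating analysis
(an OpenBUGS-era workflow), are the conventional vague choices for that
software generation: $d_k, \mu_i \sim N(0, 100^2)$ and
$\tau \sim U(0, 5)$ on the SD scale. A `fixed` tau prior is supported;
`value = 0` collapses the model to fixed effect and is used by the
conjugate-limit tests.

### Sampler

The sampler is purpose-built (no BUGS/JAGS/Stan dependency) in
RcppArmadillo. Wherever a full conditional is normal it is updated by
Gibbs: $\delta$ blocks and $d$ in the normal-likelihood model, and $d$
given $\delta$ in the binomial model. The non-conjugate coordinates
($\mu_i$, binomial $\delta$, and $\tau$) use random-walk Metropolis with
proposal scales adapted toward 44% acceptance during burn-in and frozen
afterwards, preserving detailed balance for the retained draws. The
sampler consumes R's RNG, so a single integer seed (one per chain,
derived as `seed + 7919 * chain`) makes runs bitwise reproducible on one
platform.

Defaults follow the production profile: 3 chains, 100,000 updates per
chain with the first 50,000 discarded. The `"test"` profile (3 × 10,000,
half discarded) is used throughout the test suite; simulation-heavy
operating-characteristic tests reduce further (2 × 2,500) and say so in
the test file. Convergence is declared when split-chain R-hat is below
1.05 for every basic parameter and $\tau$; under `strict` (the production
default) violation is an error carrying the diagnostics, otherwise a
warning — reduced-length test fits legitimately warn on $\tau$.

### DIC

$DIC = \bar D + p_D$ with $p_D = \bar D - D(\hat\theta)$, where deviance
is the residual deviance (quadratic form for the normal likelihood,
saturated-model deviance for the binomial) and $\hat\theta$ plugs in the
posterior means of the fitted arm effects ($\delta$, and $\mu$ for
binomial) — the convention under which $p_D$ counts effective parameters
of the fitted values. On a single-study model with $\tau$ fixed at 0 the
measured $p_D$ is 1 to within Monte Carlo error, which the suite checks.

## Inconsistency

Node splitting gives the direct evidence on one comparison $(a,b)$ its
own parameter: two-arm studies containing both $a$ and $b$ (and, in a
multi-arm study containing both, the $a$-vs-$b$ contrast after anchoring
the study at $b$) inform `d_direct`, while everything else informs the
network as usual, so $d_a - d_b$ from the same fit is the indirect
estimate. The inconsistency factor is the posterior of direct − indirect
and $p = 2\min\{\Pr(IF>0), \Pr(IF<0)\}$. We implement the conventional
reading — $p < 0.05$ flags inconsistency (the motivating text's sentence
on this is self-contradictory and is not followed literally). Comparisons
outside any loop return a not-applicable result; no p-value is invented.
Direct evidence is removed from the split edge only, not the studies
wholesale (the Dias-style definition).

The global check fits the unrelated-mean-effects model (one mean per
observed design comparison, same $\tau$) as the inconsistency model and
reports both DICs and `delta = DIC(incons) − DIC(cons)`. The decision
label applies the "< 5" convention in its only coherent direction:
consistency is acceptable unless the inconsistency model *improves* DIC
by 5 or more. The raw delta is always reported so any other rule can be
applied downstream. On a loopless network the two models coincide; a
single fit is used and delta is exactly 0 by construction, flagged as
structural.

## Ranking

For each retained draw, treatments are ranked by oriented effect (lower
SMD is better for pain and mental/sleep relief; lower log-OR is better
for adverse and serious adverse events — all five outcomes of the
motivating analysis are lower-is-better). Exact ties — measure-zero for
continuous posteriors but possible in degenerate inputs — share averaged
ranks, splitting mass uniformly, which keeps the matrix doubly stochastic
and the procedure deterministic. SUCRA is computed from the cumulative
rank distribution and equals $(T-\bar r)/(T-1)$; its identities
($\sum_t SUCRA_t = T/2$, direction flip $\mapsto 1 - SUCRA$, invariance
to relabeling) are enforced as exact tests against a brute-force recount
oracle. The multi-outcome heat map grid holds mean SUCRA and mean rank
per treatment × outcome, leaves treatments absent from an outcome as
`NA` (never imputed), and orders treatments by the *unweighted* mean of
available SUCRAs — the only averaging rule consistent with a "mean SUCRA
value" label, adopted here as the documented assumption.

## The synthetic world

`nma_scenario()`/`generate_network()` state a complete data-generating
world: star, star-plus-edges, triangle, complete or custom geometry;
per-trial effects $\theta_i \sim N(d_k - d_b + \omega\,[\text{edge}],
\tau^2)$ with the 0.5 multi-arm correlation; continuous arms simulate
participant-level change scores $N(\text{baseline} + \theta\,\sigma,
\sigma^2)$ and summarize them, dichotomous arms draw binomial events on
the logit scale. One integer seed drives a single generator stream and
the global RNG state is restored afterwards.

`sci_like_scenario()` mirrors the bundled 20-trial network exactly in
geometry (14 placebo-anchored + 5 head-to-head two-arm trials, one
three-arm trial, 11 drugs + placebo) with per-arm sizes uniform on 5–55,
chosen so the expected total (~1,230) sits near the real network's 1,198
participants; true effects default to an even spread over 0 to −1.2 with
$\tau = 0.2$ — a moderate heterogeneity typical of pain-scale SMD
networks. These defaults are the stated world; they are not tuned to test
outcomes.

What a green simulation test establishes — and what it does not: the
generator reproduces the *statistical structure the model assumes*
(normal random effects, shared $\tau$, exact consistency except for an
explicit $\omega$). Real trial networks additionally contain scale
heterogeneity, selective reporting, dropout, dose variation and
risk-of-bias gradients, none of which are simulated; risk-of-bias labels
are carried as pass-through metadata only. Green tests therefore
establish correctness of the machinery, not robustness to violations the
model does not express.

## Known limitations and honest failure

* **Sparse-network recovery.** One acceptance property asks that, in the
  bundled-like geometry with $\tau = 0.2$ and 200 participants per arm,
  every basic parameter be recovered within ±0.15 of truth in at least
  4 of 5 seeds. Five drugs in that geometry are informed by a single
  trial each; for them the posterior median sits on the realized trial
  effect, which deviates from the true $d$ with SD $\tau = 0.2$ before
  any sampling noise, so the per-drug pass probability is about one half
  and the all-drug criterion is unattainable in this stated world. The
  test implements the criterion as stated and fails; the failure is a
  property of single-trial evidence under heterogeneity, not of the
  sampler — with the same geometry and $\tau = 0$, or with several
  trials per edge, recovery passes easily (see the oracle-equivalence
  and large-sample tests).
* The per-study effect data behind the real network's league tables are
  not public; the bundled fixture carries composition only, so published
  league-table values are out of reach and acceptance rests on
  composition counts plus synthetic ground truth.
* Exact BUGS priors of the original workflow are unknown; small
  divergences from OpenBUGS defaults are possible and documented above
  rather than resolved.
* Configuration files are JSON (the environment provides no YAML
  reader); the config surface is otherwise as designed.
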