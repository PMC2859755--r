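---
title: "One prior for generative and discriminative sequence classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One prior for generative and discriminative sequence classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmrf)
```

## The problem

Recognition of short signal sequences in genomic DNA — transcription factor
binding sites (TFBSs), donor and acceptor splice sites, and similar motifs —
is usually cast as a two-class problem: a *foreground* class of aligned,
fixed-length sites versus a *background* class of decoy sequence windows.
Most of the models used for this task are Markov random fields (MRFs) over a
sequence--class pair: position weight matrices (PWMs), weight array matrices
(WAMs), higher-order inhomogeneous Markov chains, Bayesian trees and moral
Bayesian networks are all special cases, as are general log-linear models
with pairwise indicator features and mixtures of all of the above.

The parameters of such models can be trained *generatively* — maximising the
posterior, prior × joint likelihood, the MAP principle — or
*discriminatively* — maximising the supervised posterior, prior × conditional
likelihood of the class labels, the MSP principle.  Historically the two
camps used different priors (product-Dirichlet for MAP; Gaussian or Laplace
for MSP), so comparisons between learning principles confounded the
principle with the prior.  The core of this package is a single conjugate
prior that serves both principles for every model in the MRF family, plus
the training, evaluation and simulation machinery needed to run clean
comparisons.

## Model and parameterizations

A sequence is $x = (x_1, \dots, x_L)$ over $\Sigma = \{1, \dots, S\}$
($S = 4$ for DNA) with class $c \in \{1, \dots, C\}$ (here $C = 2$).  The
joint likelihood in natural parameters is the log-linear form
$$
p(x, c \mid \lambda) \;=\; \frac{\exp\!\big(\lambda_c + \textstyle\sum_i
  \lambda_{c,i}\, f_{c,i}(x)\big)}{Z(\lambda)},
$$
where the $f_{c,i} \in \{0,1\}$ are indicator features and $Z(\lambda)$ sums
the numerator over all classes and all $S^L$ sequences.  For a moral
Bayesian network the features are indexed by (position $\ell$, symbol $b$,
parent realization $a$); for the all-pairs MRF they are
$\delta(x_{\ell_1} = b_1)\,\delta(x_{\ell_2} = b_2)$, giving
$\binom{L}{2} S^2$ features (336 for $L = 7$, $S = 4$).  One parameter per
simplex-equivalent group is anchored to zero — the last class parameter and
the last entry of every $(c, \ell, a)$ or $(c, \ell_1, \ell_2)$ block — so
the free-parameter count equals that of the probability parameterization
$\theta$ (class probabilities and conditional probability tables).

The two parameterizations are linked by a bijection on strictly positive
$\theta$.  The direction $\lambda \to \theta$ is marginalisation: class
marginals and conditionals of $p_\lambda$, computed exactly by a
forward–backward sum–product recursion for chain structures (any Markov
order) and by guarded enumeration ($S^L \le 2^{20}$ states) otherwise.  The
direction $\theta \to \lambda$ is constructed in reverse topological order:
each block is anchored by subtracting the log-probability of the anchor
symbol, and the subtracted term — a function of the block's parents — is
absorbed into the conditional table of the topologically last parent, whose
own parent set contains the remaining parents precisely because the network
is moral.  The round trip is exact to numerical precision, which the test
suite asserts together with the pointwise equality of the two likelihoods.

## The transformed Dirichlet prior

The standard conjugate prior for $\theta$ is the product-Dirichlet:
independent Dirichlet densities on the class simplex and on every
conditional block, with pseudo-counts $\alpha_{c,\ell,b,a}$.  Pushing that
prior through the $\theta(\lambda)$ change of variables gives, when the
pseudo-counts satisfy the BDe consistency condition, the unnormalized log
density
$$
\log h(\lambda \mid \alpha) \;=\; \sum_c \alpha_c \lambda_c
  + \sum_{c,i} \alpha_{c,i} \lambda_{c,i} - \alpha \log Z(\lambda)
  + \text{const}, \qquad \alpha = \textstyle\sum_c \alpha_c .
$$
The same expression defines a proper conjugate prior for *any* MRF feature
set — it is the conjugate prior of the exponential family — which is what
lets a pairwise-MRF classifier and a Markov-model classifier be trained
under the same a-priori information.  Two numerical validators back the
analytic form:

* `pushforward_check()` evaluates the product-Dirichlet density at
  $\theta(\lambda)$ plus the log-Jacobian (central finite differences,
  step $10^{-5}(1 + |\lambda|)$) at random points and verifies the
  difference to the analytic expression is a single constant; with
  consistency-violating pseudo-counts it correctly stops being constant.
* `prior_equivalence_check()` verifies likelihood equivalence: a
  left-to-right and a right-to-left order-1 factorization of the same joint
  distribution receive the same prior density once both are transformed to
  the joint-table parameterization.

The prior is evaluated unnormalized throughout: training uses only its
gradient, so the dropped constant is irrelevant, and the validators treat it
as a free offset.  `prior_curvature_profile()` exposes its shape: strictly
log-concave, near-constant curvature within $|\lambda| < 0.1$ of the maximum
(Gaussian-like) and curvature decaying to zero in the far tails
(Laplace-like, with asymptotic slopes $\alpha_i$ and $\alpha_i - \alpha
\cdot$ group share).

## Hyper-parameters: BDeu from an equivalent sample size

All pseudo-counts derive from one interpretable number per class, the
equivalent sample size (ESS) $\alpha_c$: a uniform pseudo-data mass over all
$S^L$ sequences, giving $\alpha_{c,\ell,b,a} = \alpha_c / (S \cdot
S^{|\mathrm{Pa}(\ell)|})$ for moral-BN features and $\alpha_c / S^2$ per
pairwise feature group.  With $\alpha_c = 32$ on DNA this yields
pseudo-counts of 8 for every PWM entry and 8 / 2 for the first-position /
conditional entries of a WAM — the same pseudo-data seen through two model
structures:

```{r bdeu}
h <- bdeu_hyperparameters(make_markov_structure(16, 1, 4), ess = 32, C = 2)
print(h)
```

For mixtures, each component carries the full per-class ESS and the
component weights get a symmetric Dirichlet($\alpha_c / M$) prior.  This
preserves the pseudo-data reading per component; it also means the mixture
objective is *not* exactly nested in the single-model objective on unimodal
data (the extra per-component prior mass can outweigh a negligible fit
gain), which is the expected behaviour and is exercised in the tests: on
data with two genuine subclasses the $M = 2$ objective dominates.

How ESS should interact with mixture components is genuinely ambiguous
(per-model versus per-component); we chose per-component, documented here as
the package's own reading.

## Training

MAP for single moral-BN models is closed form — smoothed relative
frequencies $(n + \alpha)/(N + \alpha)$ mapped through
`theta_to_lambda()` — and exactly matches the gradient-based optimum, which
the acceptance tests verify for PWM, WAM and order-2 structures.  Every
other case (MSP; pairwise MRFs; mixtures) maximises the objective by
L-BFGS-B with analytic gradients: the data term of MSP is partition-free
(softmax residuals), while the prior and MAP terms need the model
expectations $E_p[f_i]$, which come from the same chain recursion or
enumeration as the partition constant.  Implementation choices that matter:

* gradient tolerance $10^{-6}$ (max-abs projected gradient) and up to 5000
  iterations by default; experiment drivers use looser, faster settings
  ($10^{-3}$, 300 iterations) since ranking metrics do not require
  convergence in the flat directions of rarely-realised parent contexts;
* single models start at $\lambda = 0$; mixtures break symmetry with seeded
  $N(0, 0.05^2)$ jitter and take the best of (default) 4 restarts, 2 in the
  experiment drivers;
* mixtures are trained by direct gradient ascent on the full (supervised)
  posterior with responsibility-weighted gradients rather than EM, so MAP
  and MSP share one code path;
* all per-sequence and per-state feature algebra runs through sparse
  indicator matrices; probability arithmetic never leaves the log domain.

Everything is deterministic given the training seed, and analytic gradients
are checked against central finite differences in the test suite.

## Evaluation

`performance_report()` computes the case-study measure suite: FPR at
sensitivity 0.95, sensitivity at specificity 0.999, PPV at sensitivity 0.95,
AUC-ROC and AUC-PR.  Thresholding conventions are explicit choices (the
largest threshold attaining the sensitivity target; the smallest threshold
keeping the specificity target), since tie handling on finite test sets is
otherwise ambiguous.  AUC-PR uses achievable-point interpolation — true
positives stepped one at a time with false positives linear, each segment
integrated in closed form — with a trapezoidal variant behind a flag for
sensitivity analysis; AUC-ROC is the tie-aware trapezoid, equal to the
Mann–Whitney statistic.  `run_holdout_experiment()` implements repeated
stratified holdout with a training-fraction sweep in which all classifiers
see the same training subsets and test sets; summary tables report means and
standard errors (figures conventionally show $2\times$SE whiskers).

## What the synthetic benchmarks emulate

Because the original TFBS and splice-site data sets are external downloads,
the package ships generators that emulate their *shapes*:

* `tfbs_like`: 257 aligned 16 bp sites against windows cut from 267
  background sequences of 255 bp (cut into 100-mers, then into 16-mers,
  ~68 kb total).  Foreground positions draw from
  Dirichlet($\kappa e_{\mathrm{cons}} + 1$) with $\kappa = 4 \times$
  divergence scaled by a per-position informativeness factor in
  $[0.3, 1.7]$; at the default divergence 1 the planted motifs carry 8–10
  bits of information, the range typical of real TFBS.  The background is a
  homogeneous order-3 Markov chain with a mild AT-rich composition bias.
* `splice_like`: 800 donor-like 7 bp sites with a near-obligate central
  `G-T` dinucleotide, two latent subclasses, and a strong coupling on one
  *non-adjacent* position pair per subclass (pairs (1,6) and (2,7)); decoy
  background windows also carry the central `G-T`, as real non-donor decoy
  sets do.  This is exactly the data shape where pairwise MRFs beat
  adjacent-dependency Markov models and mixtures beat single models, and
  the acceptance suite confirms that mean-AUC ordering over 20 seeds.

The divergence knob scales every planted departure from uniformity; at 0
both classes are uniform and classifiers sit at chance, the null control.
What these generators do *not* emulate: phylogenetic correlation between
sites, alignment error, genomic repeat structure, or the specific empirical
composition of any real data set.  Passing the desk-scale replications
therefore shows that the machinery reproduces the *qualitative* case-study
findings under the planted assumptions, not that it reproduces the published
numbers on the original data — those require the original downloads, for
which the command-line `compare` presets can be pointed at any FASTA pair.

Desk-scale problem sizes used by the test suite: 30 holdout repeats over
training fractions $\{0.05, 0.25, 1\}$ for the TFBS protocol and 20 seeds
for the splice protocol; these were chosen so standard errors are small
relative to the effects being ranked.

## Numerical choices and degenerate inputs

* Enumeration guard: exact inference for non-chain structures refuses more
  than $2^{20}$ states and fails loudly rather than approximate ($L = 7$,
  $S = 4$ splice MRFs need $1.6\times10^4$).
* Boundary parameters: $\theta$ entries equal to zero have no finite
  $\lambda$ image; `theta_to_lambda()` rejects them and points at positive
  priors (which is why the prior exists: zero-occurrence counts are common
  in small site collections).
* Holdout rounding is half-up (`floor(x + 0.5)`), so a 10% holdout of 257
  sites yields 26 test sequences; training subsets are
  `max(1, round(fraction * pool))`.
* Background chunking is non-overlapping with remainders discarded;
  reverse strands are never added implicitly.
* FASTA parsing upper-cases and rejects IUPAC ambiguity codes with the
  record and offset named.

## Known limitations

Exact inference restricts general MRFs to short sites (no pseudo-likelihood
or MCMC fallback); variable-length sequences are handled only by chunking;
structure learning is out of scope; and the per-component ESS convention for
mixtures, while defensible, is one of two plausible readings.
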