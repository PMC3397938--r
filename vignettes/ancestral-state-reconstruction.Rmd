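---
title: "Bayesian ancestral state reconstruction with mkasr: model, priors and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian ancestral state reconstruction with mkasr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkasr)
```

## The inference problem

Given a posterior sample of rooted trees with branch lengths (in expected
substitutions per site) and a discrete character scored at the tips,
`mkasr` estimates the joint posterior of (i) the rate model and rates of
character change, (ii) the branch-length transform κ, and (iii) the
marginal state probabilities at internal nodes addressed as MRCAs of
named taxon sets.  The motivating application is the evolution of growth
habit (lianescent/arborescent/herbaceous), inflorescence architecture
(headed/non-headed), flower size (large/small, coded from the corolla
tube/lobe ratio) and fruit type (simple/fused) across a clade of about
sixty taxa, but nothing in the engine is specific to those characters.

## Model and likelihood

A k-state character (k = 2 or 3) evolves as a continuous-time Markov
chain with generator $Q$, off-diagonal entries $q_{ij} \ge 0$ and rows
summing to zero.  Branch lengths are transformed as $b \mapsto b^\kappa$
before the transition probabilities $P(t) = e^{Qt}$ are applied; $0^0$ is
defined as 1, so κ = 0 gives every branch unit length and makes change
purely topology-dependent, while κ = 1 leaves change proportional to
branch length.  For k = 2 the transition matrix is computed in closed
form; for k = 3 by a scaling-and-squaring matrix exponential (one
eigendecomposition per likelihood call in the compiled path, with an
`expm` fallback when the eigenvector matrix is ill-conditioned).

The likelihood of the tip data is computed by Felsenstein's pruning
algorithm (post-order conditional likelihoods), with per-node rescaling
accumulated in log space so that sixty-tip trees with short branches do
not underflow.  Missing tip states enter as all-ones partial vectors, so
a fully missing character has likelihood exactly 1 and the posterior
collapses onto the priors — a property the test-suite exploits.
Polytomies are supported throughout; trees are used as rooted as read and
never re-rooted, because MRCA queries presuppose the sampler's root.

At the root the conditional likelihoods are combined with a root state
distribution.  The engine defaults to the uniform distribution; the
stationary distribution of the current $Q$ is available as an option.
This is a genuine design choice, not an inference: the choice is recorded
in every summary (`rootPrior` slot) and matters mainly for strongly
asymmetric rates, where the root marginal under a uniform prior differs
visibly from the stationary one.

Marginal probabilities at a node combine the conditional likelihood of
the data below the node with the likelihood of the rest of the tree given
each node state (an up–down pass, equivalent to virtual re-rooting).  A
tip with an observed state returns the degenerate unit vector.

## Priors and the model space

For a binary character the sampler moves over exactly four rate models:
both rates free, both constrained equal, and the two one-way models with
the opposite rate fixed to zero, under a uniform model prior.  Free rates
carry an exponential prior with mean $m$, and $m$ is itself sampled under
a uniform hyperprior on (0, 10) — moderate rates are a priori more
plausible than large ones, and the hierarchy lets the data set the scale.
κ has a uniform prior on (0, 5).  The description of the hyperprior as
"seeding" the rate-prior mean is ambiguous between hierarchical sampling
and per-run fixing; `mkasr` samples $m$ hierarchically within the chain
and offers `fixM` for the fixed-mean reading.  For a three-state
character the engine uses the single all-rates-free model (six rates) and
no reversible jump; partitioning multistate rate classes into a larger
jump space is deliberately out of scope.

## The MCMC kernel

Each generation draws one move from a mixture (default weights in
parentheses, configurable):

* **rates (0.40)** — every free rate perturbed by Normal(0, d) noise,
  reflected at zero; the equal-rates model perturbs its single shared
  rate, so constraints are preserved by construction;
* **κ (0.20)** and **m (0.10)** — the same kernel, reflected (with
  folding) into the prior support;
* **model jump (0.15)** — a different model chosen uniformly, with all
  free rates of the proposed model drawn fresh from the current
  Exponential(m) prior.  Because the independence proposal equals the
  prior, the dimension-matching correction reduces to the prior density
  ratio of the replaced parameters and the acceptance ratio to the
  likelihood ratio.  (A partial-redraw variant that retains rates shared
  by name between models was considered; redrawing the full free-rate
  vector avoids an ambiguous correspondence between, say, the shared rate
  of the equal-rates model and the two free rates, and its correctness is
  checked against numerical integration of each model's marginal
  likelihood rather than against any particular reference sampler.)
* **tree move (0.15)** — a tree index proposed uniformly from the sample
  and accepted through the likelihood ratio, keeping the chain one
  reversible kernel over the finite index set rather than cycling
  deterministically.

The shared proposal deviation d is tuned only during burn-in: every
`tuneInterval` generations the realised acceptance of the within-model
parameter moves is compared to the 20–40% target band and d is scaled by
0.8 (below) or 1.25 (above), clamped to [1e-6, 1e3].  Tuning freezes at
the end of burn-in so the sampling phase satisfies detailed balance.
Per-move acceptance rates and the tuning trajectory are kept in the
returned chain and logged by `reconstruct()`, because the acceptance band
is a protocol requirement worth auditing.

Run-length profiles: the full-scale protocol (220 million generations, 20
million burn-in, a sample saved every 1000 generations, three replicate
runs) ships as `runConfigProfile("paper")`; the package default
(`"desk"`) is 2 million generations with the same thinning, and `"test"`
is sized for unit tests.  The desk and test scales were chosen so that
the Monte Carlo error of the reported summaries, not wall-clock heroism,
sets the precision; the vignette's and test-suite's problem sizes (3–63
taxa, 2e4–1e5 saved samples) are stated wherever they are used.

## Reported quantities

`summarizeChain()` mirrors the standard reporting layout: the ratio of
the posterior-average q01 to the posterior-average q10 (a ratio of
averages, not an average of ratios; samples whose model fixes a rate to
zero contribute those zeros, because they are legitimate posterior mass
under model averaging), the posterior mean and 95% HPD of κ (shortest
order-statistic window), posterior model frequencies, effective sample
sizes (initial-positive-sequence truncation), and per-query marginal
state probabilities.  Node probabilities are computed per saved sample on
that sample's tree with that sample's parameters, then averaged with
equal weights — the samples are already posterior-weighted, so no
per-tree reweighting is applied.  For binary characters the state-0
probability is reported, state 1 being its complement.  Replicate runs
are pooled for the reported summaries after a per-run agreement check
(kappa means within Monte Carlo error); the HPD is computed on the pooled
chain.

## Synthetic data: what it emulates, and what it does not

`simulateTreeSample()` draws one Yule (pure-birth) focal topology,
rescales it to a root-to-tip depth of 1 (a typical scale, in expected
substitutions per site, for the ribosomal/chloroplast data sets this
method is applied to), and emulates posterior uncertainty by multiplying
every branch by independent lognormal jitter (mean 1, sdlog 0.1 by
default) and optionally applying one random NNI move per tree.
`simulateCharacter()` is the generative twin of the likelihood: root
state from a given distribution, then transitions along each
κ-transformed branch.

The named fixtures fix the study conditions used across the tests: the
`asymmetric-ratio5` fixture simulates 20 replicate binary characters on a
60-tip jittered sample with q01 = 2.5, q10 = 0.5 (ratio 5) and κ = 1 —
rates on the order of 1 per unit depth give characters that change a
handful of times on the tree, which is what makes a morphological
character informative but not saturated.  The `morindeae-like` fixture
reproduces the *shape* of the study data (61 ingroup taxa in four
genus-like clades plus two outgroup taxa, clade-biased character states,
seven MRCA queries A–G); its codings are deterministic and synthetic, so
it exercises the machinery without standing in for the real data.

A jittered Yule sample is a smooth caricature of a real Bayesian
posterior: it has no correlation between branch-length and topology
uncertainty, no among-partition rate heterogeneity, and no alignment
error.  Passing the recovery tests therefore demonstrates that the
inference machinery is correct under its own model assumptions — it does
not certify behaviour under model misspecification on empirical data.

## Numerical choices and degenerate inputs

* Zero-length branches are legal; the transition matrix at t = 0 is the
  identity.
* An all-zero generator yields the identity transition matrix with a
  warning.
* A corolla tube/lobe ratio of exactly 1 is not covered by the
  large/small coding rule and is returned as missing with a warning
  rather than silently assigned.
* Characters with fewer than two observed states run (the posterior
  follows the priors) but are flagged in the log.
* The per-sample ratio q01/q10 is 0 or infinite under the one-way
  models; credible intervals for the ratio therefore use equal-tail
  quantiles of the model-averaged per-sample ratio, which handle the
  point masses gracefully, while the headline point estimate is the
  ratio of averages.
* HPD intervals require at least 20 samples, ESS estimates at least 50;
  both error rather than extrapolate.

## Known limitations

No covarion or hidden-rate models; no correlated-character (dependent)
models; no stochastic character mapping; no polymorphic tip codings
beyond missing; no tree inference or consensus computation — the engine
consumes a tree sample, it never produces one.  Whether κ should be
applied before or after outgroup pruning is not a question the engine
answers: κ transforms whatever tree it is given, and pruning is a
data-preparation step performed first.
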