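---
title: "The Bayesian alphabet for genomic prediction: models, samplers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Bayesian alphabet for genomic prediction: models, samplers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

All methods in this package fit the whole-genome regression

$$ y = X\beta + \sum_{k=1}^{K} z_k a_k + Z_u u + e, $$

where $y$ holds $n$ trait phenotypes (or de-regressed-proof-style
pseudo-phenotypes), the only fixed effect in $\beta$ is the overall mean
$\mu$, $z_k$ is the genotype column of SNP $k$ coded as the count of one
allele (0, 1 or 2), $a_k$ is its additive effect, $u$ is an optional vector
of pedigree polygenic effects with $u \sim N(0, A\sigma^2_u)$, and residuals
have $\mathrm{var}(e_i) = \sigma^2_e / w_i$ with user-supplied weights
(default 1; with de-regressed proofs the square root of the reliability is
the conventional weight).

The marker-effect prior is a spike-and-slab mixture: with probability $\pi$
the effect is exactly zero; with probability $1 - \pi$ it is normal with
mean zero and a variance whose treatment distinguishes the four methods.

* **BayesA** — every marker has its own variance $\sigma^2_{a_k}$ with a
  scaled-inverse-chi-square prior $(\nu_a, S^2_a)$, and $\pi = 0$: all
  markers stay in the model.
* **BayesB** — the same locus-specific variances, but $\pi$ fixed at a high
  value (default 0.99).
* **BayesCpi** — a single variance $\sigma^2_a$ common to all fitted
  markers, itself scaled-inverse-chi-square, and $\pi$ unknown with a
  uniform(0, 1) prior.
* **BayesDpi** — locus-specific variances whose common scale $S^2$ is
  unknown with a Gamma(1, 1) prior, and $\pi$ unknown with a uniform prior.

## Prior construction

Users supply the additive-genetic variance the markers are assumed to
explain, $\sigma^2_a$ (for the simulators, $h^2/(1-h^2)$ with unit residual
variance). The variance of a single fitted marker effect is

$$ \bar\sigma^2_a = \frac{\sigma^2_a}{(1-\pi)\sum_k 2 p_k (1 - p_k)}, $$

with $p_k$ the allele frequency in the training panel, and every
scaled-inverse-chi-square scale is derived from its intended mean through
$S^2 = \bar\sigma^2 (\nu - 2)/\nu$. The degrees of freedom $\nu_a$, $\nu_e$
and $\nu_u$ all default to 4.2 — small enough to express weak prior belief
while keeping the prior mean finite. For the pi-unknown methods the scale is
evaluated at the starting value $\pi_0$ (default 0.5) and then held fixed
for the whole chain: re-deriving it from the current $\pi$ would make the
prior data-dependent, and a larger $\pi_0$ deliberately yields a larger
per-marker scale (less shrinkage through the variance, compensated by more
shrinkage through $\pi$). `build_prior_config()` implements exactly this
composition and nothing else.

The residual and polygenic prior means default to
$\mathrm{var}(y) - \sigma^2_a$ and $0.05\,\mathrm{var}(y)$ when not given;
these are package defaults chosen to be weakly informative at the observed
phenotypic scale, and both are user-overridable.

## The two samplers

`run_mcmc()` dispatches to a single compiled engine. One iteration updates,
in order: $\mu$; each marker in ascending index; $u$ and $\sigma^2_u$ when a
pedigree is fitted; $\sigma^2_e$; the common variance (BayesCpi) or unknown
scale (BayesDpi); and $\pi$. The engine maintains the running adjusted
phenotype $y_{adj} = y - \mu - \sum_k z_k a_k - Z_u u$ and verifies every
100 iterations that it reconstructs $y$ to within $10^{-8}$ relative.

**BayesCpi locus step (Gibbs).** The inclusion indicator $\delta_k$ is drawn
from its full conditional, with the effect integrated out analytically:
$P(\delta_k = 1 \mid \cdot) \propto (1-\pi) f_1$ and
$P(\delta_k = 0 \mid \cdot) \propto \pi f_0$, where $f_1$ is the marginal
density of $y_{adj}$ under
$N(0,\, z_k z_k^\top \sigma^2_a + W^{-1}\sigma^2_e)$, evaluated through the
rank-one Gaussian identity, and $f_0$ omits marker $k$. All density ratios
are computed in the log domain. If included, $a_k$ is drawn from its
conjugate normal $N(z_k^\top W y_{adj} / c_k,\; \sigma^2_e / c_k)$ with
$c_k = z_k^\top W z_k + \sigma^2_e/\sigma^2_a$. The common variance then has
the scaled-inverse-chi-square full conditional with $\nu_a + m$ degrees of
freedom and scale $(a^\top a + \nu_a S^2_a)/(\nu_a + m)$, $m$ being the
fitted count — the "learning" behaviour that distinguishes it from the
locus-specific-variance methods, whose variance posteriors gain only one
degree of freedom over their prior no matter how much data accrue.

**BayesA/B/Dpi locus step (Metropolis-Hastings).** The pair
$(\delta_k, \sigma^2_{a_k})$ is updated jointly, again with $a_k$ integrated
out of the acceptance ratio. The proposal is a 50/50 mixture of a point mass
at zero (marker out) and a scaled inverse chi-square with $\nu_a$ degrees of
freedom. The proposal scale depends on the state the move starts from: the
prior scale when the marker is currently out, and
$\sigma^2_{a_k}(\nu_a - 2)/\nu_a$ (centring the proposal mean on the current
value) when it is in. Because the proposal depends on the state, the
acceptance ratio evaluates the reverse-move density at the scale implied by
the *proposed* state; this makes each repetition a reversible kernel with
the joint posterior invariant. An alternative sometimes seen — evaluating
both proposal densities at the forward scale — over-accepts removals of
large-variance markers and does not preserve the target. The step is
repeated `mh_reps` times per marker and iteration (default 10; 2 for
BayesA, which never needs to traverse the in/out boundary because its prior
has no point mass, so fewer repetitions suffice to refresh the variance).
After the variance update, $a_k$ is redrawn from the same conjugate normal,
or set to zero if the marker is out.

**Shared draws.** $\mu$ has a conjugate normal full conditional;
$\sigma^2_e$ is scaled-inverse-chi-square with $\nu_e + n$ degrees of
freedom and scale $(e^\top W e + \nu_e S^2_e)/(\nu_e + n)$; the BayesDpi
scale has the conjugate Gamma full conditional
$\Gamma(m\nu_a/2 + 1,\; (\nu_a/2)\sum_{fitted} 1/\sigma^2_{a_k} + 1)$ under
its Gamma(1, 1) prior, pooling information across all fitted loci; and
$\pi \sim \mathrm{Beta}(K - m + 1,\; m + 1)$. Polygenic effects are drawn
jointly and exactly from their Gaussian full conditional by Cholesky
factorisation of the precision
$Z_u^\top W Z_u/\sigma^2_e + A^{-1}/\sigma^2_u$, with $A^{-1}$ assembled by
Henderson's rules; at the problem sizes this package targets the direct
factorisation is preferable to iterative solvers with randomised right-hand
sides, and it is verified against closed-form multivariate-normal moments in
the tests.

## Numerical and implementation choices

* Genotype columns are mean-centred inside the engine. With a free
  intercept the likelihood is invariant to this reparameterisation — marker
  effects are unchanged, only $\mu$ shifts — and it decouples the intercept
  from the marker updates, improving mixing when many markers are fitted.
* Initial state: $a = 0$, $\delta = 0$ ($\delta = 1$ for BayesA),
  $\pi = \pi_0$, variances at their prior means, $\mu$ at the weighted
  phenotype mean.
* All randomness flows through R's RNG, so a single `seed` makes every
  run — including the compiled loops — bit-reproducible.
* Inclusion decisions compare a uniform variate against the computed
  probability with strict inequality; density ratios are accumulated in log
  space with explicit guards for the $\pi \in \{0, 1\}$ limits.
* Missing genotypes are mean-imputed (to $2p_k$) after QC filtering, which
  preserves the observed allele frequency exactly; entries are therefore
  real dosages in $[0, 2]$ after imputation.

## The simulators

Two generators produce the package's study conditions.

**Ideal (linkage equilibrium).** `simulate_ideal()` draws each locus
independently as Binomial(2, 0.5) — as if every locus sat on its own
chromosome — designates a random subset as QTL, samples effects either from
a standard normal or as gamma(shape 0.4, scale 1.66) magnitudes with random
signs, rescales them by one scalar so the realized variance of the true
breeding values equals $h^2/(1-h^2)$ exactly, and adds standard-normal
residuals. Both QTL and null loci enter the analysis panel, so the true
$\pi$ is known ($1 - n_{qtl}/n_{loci}$). Defaults: 2,000 loci, $h^2 = 0.5$.

**Realistic (drift-mutation LD).** `simulate_population()` runs a
monoecious, randomly mating population (selfing allowed, constant size
1,500) for 1,000 discrete generations on a 1-Morgan chromosome with evenly
spaced SNPs and uniformly placed QTL, recurrent two-allele mutation at
$2.5\times10^{-5}$ per locus per gamete, and a binomial recombination map
(crossover count Binomial(4, 0.25), i.e. one expected crossover with
interference through the cap). About 98% of loci remain segregating after
1,000 generations under these defaults. `simulate_realistic()` then mates
disjoint random parent pairs from the final generation (each parent used
once) to produce the training cohort, selects one SNP with minor allele
frequency above 0.05 from each of 2,000 evenly spaced bins, and attaches
the trait; only the selected panel — not the QTL — is modelled, so the true
$\pi$ is unknown, as in real data.

What these generators do *not* emulate: multi-chromosome genomes, selection
during history, non-additive gene action, heterogeneous SNP ascertainment
and genotyping error. Passing tests on these data therefore demonstrate
correctness of the samplers and the stated sampling distributions, not
robustness to those real-data features.

## Evaluation

`compute_gebv()` scores individuals as $\sum_k z_{ik}\hat a_k$ with raw 0/1/2
codes; `accuracy()` divides the correlation with the reference values by the
mean square-root reliability (1 for simulated true breeding values);
`nsnp_summary()` reports the posterior mean and sd of the fitted-marker
count alongside $(1-\bar\pi)K$; and `window_variance()` computes the
variance across individuals of the GEBV contribution of sliding marker
windows — windows are defined in marker counts (the simulated genome has no
physical coordinates) with a default step of 1.

## Problem sizes used by the test suite

The replicated experiments run 6 replicates of 10,000-iteration chains with
4,000 burn-in on 1,000 individuals by 2,000 loci, and the historical
simulator runs 400 loci at full population size and generation count; these
sizes give replicate-level standard errors a few times larger than the
full-size experiment (acceptance bands are widened by $\sqrt{24/6}$
accordingly) while keeping a complete run on a single CPU in minutes.
Distributional unit checks use $10^4$–$10^6$ Monte-Carlo draws with
4-standard-error bands, and the exact enumeration oracles use $K = 3$
markers on 12 records so all $2^3$ models can be integrated in closed form.

## Known limitations

* **BayesDpi fitted-locus counts.** On sparse architectures (e.g. 10 QTL
  among 2,000 unlinked loci) the BayesDpi posterior, sampled with the
  reversible kernel above, concentrates at essentially the same fitted-locus
  count as BayesCpi: every spuriously included null locus costs a factor
  below one in marginal likelihood, so the posterior of $m$ decays rapidly.
  Published BayesDpi analyses often report much larger counts together with
  poor mixing of $\pi$; a slowly mixing chain started at $\pi_0 = 0.5$
  spends its averaging window far from the mode and inflates the reported
  count. Users comparing against such numbers should inspect the $\pi$
  trace (`autoplot(fit, "trace")`) before trusting either figure.
* The Henderson $A^{-1}$ omits the inbreeding adjustment, so pedigrees with
  inbred parents get a slightly misspecified polygenic precision (the dense
  $A$ from `build_A()` is exact and is what `pblup()` uses).
* Variance components for the BLUP baselines are user-supplied, not
  REML-estimated.
* The samplers hold the full genotype matrix as doubles in memory
  (`n x K x 8` bytes), which is the right trade-off up to a few tens of
  thousands of markers and individuals but not beyond.
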