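---
title: "Methods: candidate-gene association analysis of milk beta-carotene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene association analysis of milk beta-carotene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcassoc)
```

## The problem

Beta-carotene (BC) in milk is a provitamin A source of real nutritional
consequence in regions where vitamin A deficiency is widespread. Three genes
central to carotenoid metabolism — *BCMO1* and *BCO2* (cleavage) and
*SCARB1* (cellular uptake) — carry variants associated with milk BC
concentration in dairy cattle and buffalo. `bcassoc` implements the full
analysis chain for a sparse candidate-gene SNP panel genotyped across
multiple breeds: genotype quality control and linkage disequilibrium,
a staged fixed-effects model-selection procedure yielding allele
substitution effects, gene-wise joint tests and the extreme-genotype
contrast, and Bayesian whole-genome regression with posterior-probability
inference. Because the motivating study's raw records are not publicly
deposited, the package also ships a first-class synthetic-data generator
that emulates the study design, so every stage is exercised end to end
without any download.

## Data model

Genotypes are additive dosages: at each SNP one allele is designated the
*counted* allele, and an animal's value is its number of copies (0/1/2, `NA`
for failed assays). Which homozygote is coded 0 is arbitrary; the choice
flips the sign of the substitution effect and nothing else, and every
downstream quantity that matters (recommended allele, |beta| in the D
contrast, R^2, F-tests) is invariant to it — a property the test suite
checks explicitly. When a panel is attached, the counted allele defaults to
the alternate allele of the printed 1-based coordinate.

Phenotype records carry the BC concentration (ug/100 mL) and the management
structure used as fixed effects: breed, place, farmer nested in place, an
optional two-period collection batch (the buffalo data were gathered in two
seasons with very different rainfall), lactation number and daily milk
yield.

## Quality control and LD

SNP are retained within a breed when their call rate is at least 0.90; the
boundary is inclusive (9 of 10 typed animals passes). Pooled within-species
analyses only use SNP that pass in *every* breed of the species. Remaining
sporadic missingness is imputed breed by breed with Binomial(2, p-hat)
draws from the breed allele frequency. This deliberately ignores linkage:
the panel is a few dozen mostly unlinked loci and imputation only fills
isolated holes after a stringent call-rate filter, so haplotype-based
imputation machinery would add dependencies without changing results
materially.

Pairwise LD is computed as r^2 from two-locus haplotype frequencies
estimated by EM over unphased genotypes (the approach of the standard
haplotype-browser tools). Only the double-heterozygote class is phase
ambiguous; its split between the *cis* and *trans* resolutions is
recomputed each E-step. Numerical choices: initialization at linkage
equilibrium, at most 100 iterations, convergence when no haplotype
frequency moves by more than 1e-8. On data without double heterozygotes the
EM reproduces the closed-form haplotype-count r^2 exactly. Pairs with
r^2 > 0.6 (strict) are flagged as in strong LD; monomorphic loci yield `NA`
because LD is undefined there. A composite (dosage-correlation) r^2 is
available as a fast fallback.

## The staged linear-model procedure

For each breed, and for each species pooled across breeds, four ordinary
least-squares fits are compared on the same rows:

1. management effects only (e.g. `farmer + place + lactation + yield` for a
   single breed; `breed + place(breed) + farmer(place x breed)` pooled;
   buffalo models add the batch effect);
2. model 1 plus *all* QC-passing SNP as dosage covariates;
3. model 1 plus only the protein-changing (nonsynonymous/stop/missense)
   SNP;
4. the final model keeping the SNP whose two-sided P-value in model 2 is
   strictly below 0.30.

The deliberately liberal 0.30 screen keeps weakly supported markers in the
final joint fit rather than discarding them; significance statements are
then made at the usual 0.05 level on the final model. When no SNP clears
the screen the hierarchy reports an explicit empty selection — a real
outcome for one buffalo breed in the motivating study — rather than
failing. One panel source labels a protein-changing variant "Missense"
where others say "Nonsynonymous"; the two labels are treated as synonyms.

Whether the screening P-values should come from the all-SNP joint model or
from single-SNP scans is genuinely open; the package defaults to the joint
model (the natural reading of "all SNP added as covariates, then pruned")
and offers `selection = "marginal"` for the scan alternative.

Designs are built with treatment coding; nested terms are coded through the
child-within-parent interaction and the resulting redundancy with parent
main effects is removed by a column-pivoted QR in which earlier columns
take precedence, so the removal is deterministic and logged. Dropping
aliased management dummies never affects the estimable SNP contrasts. Rows
missing lactation or yield are list-wise dropped for models that use them,
and counted.

## Substitution effects, recommended alleles, and the D contrast

The substitution effect `beta_j` is the final-model coefficient of SNP
`j`'s dosage: the expected change in BC per additional copy of the counted
allele. The *recommended* allele is whichever allele raises predicted BC —
the counted allele when `beta_j > 0`, the other allele when negative; an
exactly zero estimate is a tie, resolved to the counted allele and flagged.

With dosages coded 0/1/2, the two homozygotes at locus `j` differ by
`2|beta_j|`, so the predicted gap between an animal homozygous for the
favorable allele everywhere and one homozygous for the unfavorable allele
everywhere is

D = 2 * sum_j |beta_j|,

estimated by plugging in the fitted coefficients. The package asserts the
defining identity directly: the prediction difference between the two
constructed extreme genotypes equals D-hat to machine precision. The
standard error treats the estimated signs as fixed — D-hat is the linear
contrast `c'beta` with `c_j = 2 sign(beta_j)`, evaluated with the final
model's coefficient covariance. Sign uncertainty is not propagated; this
mirrors how such contrasts are stated as linear "estimate" statements in
practice, and the per-SNP standard errors make the sign uncertainty
visible where it exists. Gene-wise significance is a Wald F-test that all
retained coefficients of the gene vanish jointly; for a single-SNP gene it
collapses to the square of that SNP's t-statistic.

A Benjamini–Hochberg adjustment is available (`adjust_fdr()`) but is never
used for selection: with a small pre-filtered candidate panel, a
multiplicity correction mostly deletes information, so adjusted values are
advisory output only.

## Bayesian whole-genome regression

Both samplers fit `y = X b + M alpha + e` with flat priors on the
management effects `b`, which are drawn jointly from their multivariate
normal full conditional (scalar updates mix poorly with many nested
farmer dummies). The marker set entering the Bayesian stage defaults to
the SNP that passed the frequentist 0.30 screen.

**Bayes A.** Each `alpha_j` is normal with its own variance, and each
variance has a scaled-inverse-chi-square prior with `nu_alpha = 4` degrees
of freedom — marginally, i.i.d. scaled-t effects, so every marker is
assumed to have *some* effect. Updates are single-site Gibbs draws;
`sigma2_j | alpha_j` is scaled-inverse-chi-square with
`nu_alpha + 1` df and scale `(nu_alpha s2_alpha + alpha_j^2)/(nu_alpha+1)`.

**Bayes C-pi.** Each `alpha_j` is exactly zero with probability `pi` or
normal with a variance common to all included markers. The inclusion
indicator is sampled from its conditional Bernoulli with the effect
integrated out (a marginal-likelihood ratio), included effects share a
scaled-inverse-chi-square variance update, and `pi` has a Uniform(0,1)
prior, giving the Beta(#excluded+1, #included+1) full conditional. With no
markers the `pi` chain is exactly its uniform prior — a degenerate case the
tests use. The posterior mean of the indicator is the marker's posterior
probability of association.

No hyperparameter values accompany the original analyses, so the prior
scales follow the convention of the genomic-prediction literature:
`s2_alpha` is derived so that markers are a priori expected to explain
`var_fraction` (default 0.5) of the phenotypic variance spread over
`sum_j 2 p_j (1-p_j)`, and the residual scale matches the remaining
fraction; both are overridable, and both variances can be *fixed* to make
the sampler exactly conjugate for closed-form verification. The residual
variance uses the standard scaled-inverse-chi-square conditional. Defaults
of 50,000 iterations, 5,000 burn-in and thinning 10 are comfortable for
panel-sized problems; the test suite uses shorter chains sized to the tiny
designs it checks. Chains are bitwise reproducible from the seed.

Posterior summaries report, per SNP, the posterior mean, SD, the
probabilities of a positive and of a negative effect (sign PPs, used with
thresholds 0.8/0.7/0.5), and for the spike-and-slab prior the inclusion PP
(thresholds 0/0.1/0.2 by default; small breeds whose `pi` posterior stays
near its prior are more legible at 0.4/0.5, so the threshold set is an
argument). All thresholds are strict. For every threshold the posterior of
`D = 2 sum |alpha_j|` over the listed SNP set is recomputed sample by
sample — in the spike-and-slab case excluded draws contribute exactly
zero, which is why its totals sit below the Bayes A totals. The tables
report the posterior SD of D; the reported spread could arguably be
something else (e.g. the SD of a plug-in estimate), but the posterior SD
is the coherent choice for a posterior summary.

## The prior-comparison benchmark

`run_prior_comparison()` repeats, per replicate: simulate a 500-observation,
20-marker dataset (intercept-only fixed structure), fit both priors, and
score the posterior-mean D-hat against the known truth, for the two
scenarios "no causal markers" and "25% causal markers". Bayes A never sets
an effect to exactly zero, so summing |alpha| across 20 markers accumulates
noise and overestimates D when few or no markers are causal; the
spike-and-slab prior can zero markers out and lands closer. The replicate
errors and per-scenario RMSEs quantify exactly that. Unstated details are
package choices: marker frequencies Uniform(0.1, 0.9) per replicate,
causal effects of equal magnitude `0.5 * resid_sd` with alternating sign,
20 replicates by default.

## What the synthetic generator does and does not emulate

`default_sim_spec()` reproduces the study's shape: five cattle and five
buffalo breeds with the published per-breed sample sizes and mean BC
concentrations, and per-SNP allele frequencies and substitution effects
transcribed from the published combined-analysis results. Management
structure is place and farmer-within-place with effects drawn once per
level and then treated as fixed — matching their fixed-effect treatment in
the analysis — plus a 0.5 ug/100 mL second-batch shift for buffalo.
Covariates (lactation 1–5, yield around 5 L/day) enter centered so the
specified breed means remain the expected breed means; SNP contributions
are likewise expressed as deviations from the population mean genotype.

Values the study does not state are fixed once here: residual SD
2.5 ug/100 mL (chosen so that breed-level standard errors land on the
scale of the published breed summary), place SD 0.8, farmer SD 0.5,
slopes 0.15 (lactation) and 0.1 (yield). Concentrations are truncated at
zero, as a concentration must be; with these settings the truncated mass
is a few percent and shifts breed means by well under their standard
errors.

Not emulated: LD structure among panel SNP (loci are simulated
independently, so LD-driven phenomena like haplotype effects cannot arise),
pedigree relationships, heterogeneous residual variance across herds, and
genotyping error beyond missingness. Passing tests on this generator
therefore validate the *procedures* — estimator algebra, calibration under
the null, sampler correctness, selection behavior — not the published
real-data coefficients, which cannot be reproduced without the undeposited
records.

## Randomness, determinism, and problem sizes

Every stochastic step derives a stream-specific seed from one master
integer via a Lehmer step plus a hash of the stream name, so adding noise
never perturbs the genotype draw, and any run is reproducible from its
seed (the CLI serializes the resolved configuration next to its outputs).
The test suite sizes its simulations for a laptop-class machine: the null
calibration uses 500 replicates of a 150-animal, 20-SNP design; sampler
calibration uses 20 replicates of the 500 x 20 benchmark with
3,000-iteration chains; the prior benchmark in the tests runs 12
null-scenario replicates. These sizes are the package's choices for a
routinely runnable suite; all of them are parameters.

## Known limitations

Management effects are strictly fixed; no random-herd mixed models.
Association is single-marker additive (no dominance term, no haplotype
tests). The imputation is frequency-based, adequate only for sporadic
missingness. The D contrast is a prediction about idealized extreme
homozygotes under the additive model — with effect signs estimated, not
known — and its standard error conditions on those signs. Bayesian model
choice is limited to the two implemented priors.
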