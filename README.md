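# haplotypeEM

Outcome-guided EM reconstruction of haplotypes from ambiguous,
copy-number-variable genotype data.

## The problem

Some gene regions — the human killer-cell immunoglobulin-like receptor
(*KIR*) cluster is the motivating case — are hard to genotype: a
measurement at a locus is often compatible with several alleles, phase
(which allele sits on which chromosome) is unobserved, a gene may be
absent altogether (the "NEG" allele), and one chromosome can carry
several gene copies (a compound CNV allele such as `E^F`).  An observed
multi-locus genotype `g` therefore corresponds to a whole set
`{h1|h2} ~ g` of possible diplotypes (unordered haplotype pairs), and
reconstructing diplotypes and their population frequencies is a missing
data problem.

Under Hardy-Weinberg equilibrium the haplotype frequencies `π` maximize
the observed-data likelihood

    L(π) = ∏_i  Σ_{ {h1|h2} ~ g_i }  π_{h1} π_{h2} c_h ,

with `c_h = 2` for heterozygote diplotypes and 1 otherwise.  This package
implements a profile EM algorithm for this likelihood — with iterative
locus addition, collapsing of rare haplotypes into a profiled synthetic
category (`CLPS`), and protection of a candidate list — and its
extension to outcome-dependent reconstruction: when an outcome `Y`
(continuous or binary) depends on the diplotype through a regression
model with parameters `τ`, the joint likelihood factorizes as

    L(θ; Y, H) = ∏_i  L_o(τ; Y_i | h_i) · π_{h_i1} π_{h_i2} c_{h_i} ,

and the EM alternates between fitting a *working outcome model* by
weighted regression on the posterior-expanded dataset (each individual
entered once per compatible diplotype, weighted by its posterior
probability) and recomputing diplotype posteriors

    P(d | g_i, y_i) ∝ P(y_i | d; τ) · π_{h1} π_{h2} c_h .

Three working-model strategies are available inside the EM: allele main
effects only (`allelic`), forward-backward selection of haplotype terms
(`forward_backward`, entry/removal at p = 0.1), and an elastic-net
penalized saturated model (`penalized`, α = 0.5, λ by cross-validation).
Substantive models for the actual research question are fitted *after*
reconstruction on expected dosages.  A simulator generates
LD-structured haplotype distributions (Lewontin D′ on a standardized
0–1 scale), Hardy-Weinberg diplotype draws, MAR ambiguity injection and
outcomes; metrics include RMSE, a phase-insensitive haplotype
reconstruction measure (HTR) on per-locus allele-dose vectors, and
Kullback-Leibler divergences against the true distribution.

## Worked example

Simulate the proof-of-concept scenario (three loci, strong effects
multiplied by 3, medium LD and ambiguity), then reconstruct with and
without the outcome:

```r
library(haplotypeEM)

spec <- scenario_poc("A", ld_level = 0.4, ambiguity_level = 0.4,
                     N = 500, effect_multiplier = 3)
dat <- simulate_dataset(spec, seed = 42)

cfg  <- em_config(protected_haplotypes = candidate_haplotypes(dat$truth$htf))
base <- run_profile_em(dat$genotypes, cfg)                  # no outcome
fit  <- run_outcome_em(dat$genotypes, dat$outcomes,
                       family = "gaussian", strategy = "allelic",
                       config = cfg, init_fit = base)

fit$tau
#> Outcome model (gaussian), 7 terms, phi = 1.063
#> (Intercept)           A           B           E           F           G
#>      0.0551     15.0643    -14.9879     10.4996    -10.5791      7.3906
#>           H
#>     -7.4526

c(htr_no_outcome = htr(base$counts, dat$truth$diplotypes),
  htr_allelic    = htr(fit$counts,  dat$truth$diplotypes))
#> htr_no_outcome    htr_allelic
#>         0.2252         0.0015
```

The working model recovers the generating effects (±15, ±10.5, ±7.5 with
unit error variance), and using it inside the EM cuts the individual
reconstruction error (HTR) by two orders of magnitude — ambiguous calls
are resolved by how well each candidate diplotype explains the
individual's outcome.  The corresponding KLD ratio (baseline divergence
from the truth over outcome-model divergence) is 3.97, i.e. the
outcome-guided frequencies are much closer to the truth.  With weak or
misspecified effects the advantage disappears and can reverse, which is
why the baseline fit should always be run alongside.

A thin command-line front end covers the same workflow
(`inst/cli/hapem.R` with subcommands `simulate`, `reconstruct`,
`evaluate`, `grid`; see the commented scenario file
`inst/extdata/poc_scenarioA.yaml`).

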