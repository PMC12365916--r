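---
title: "Models and methods behind dohaplo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dohaplo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dohaplo)
```

# The problem

Diversity Outbred (DO) mice descend from eight inbred founder strains
(labelled `A`–`H`; `A`–`E` are classical laboratory strains, `F` = CAST,
`G` = PWK, `H` = WSB are wild-derived). Each DO genome is a fine-grained
mosaic of founder haplotypes, and most genetic analyses — QTL mapping above
all — work on *founder allele probabilities*: at every locus, the
probability that a sample carries each founder's haplotype. Those
probabilities are classically derived from dense genotyping arrays
(GigaMUGA-like); low-coverage whole-genome sequencing (lcWGS, down to well
below 1×) is a cheaper alternative, but its genotype information per site
is weak and must be pooled across sites through a reference panel.

`dohaplo` provides a self-contained, fully tested benchmarking pipeline for
this question: it simulates DO cohorts with known truth, reconstructs
founder haplotypes from sparse read counts and from array-style hard calls
with one shared hidden Markov model (HMM) engine, and implements the
evaluation machinery used to compare genotyping methods — cosine-similarity
concordance, adaptive marker filters, coverage down-sampling, founder
identity-by-descent (IBD) analysis of discordant regions, crossover
accounting, and an expression-QTL scan with founder allele-effect
estimation.

# The synthetic cohort generator

The generator defines the study conditions; every stochastic step takes an
explicit seed and is bit-reproducible.

**Founder panel.** One chromosome of biallelic SNPs, positions uniform,
genetic map linear at 0.5 cM/Mb by default (configurable; real maps vary
regionally, which we do not emulate). Founder alternate-allele counts are
drawn in a configurable range (default 1–7 of 8 carriers), so every marker
segregates. Engineered IBD blocks copy one founder's alleles onto another
over a declared interval, mimicking the extensive sequence identity among
the classical founders.

**Diplotype mosaics.** Each sample carries two homologs; per homolog,
breakpoints form a Poisson process on the genetic map with intensity
`xo_rate_scale * n_gen` per Morgan, and founder identities are uniform over
the eight founders with self-transitions forbidden. The default
`xo_rate_scale` (≈ 0.973) is calibrated analytically so that a 1400-cM
genome at outbreeding generation 41 accumulates the expected ≈ 1117
observed crossovers implied by the linear accumulation model (≈ 400
crossovers at generation 11 plus 23.9 per additional generation). The
published per-generation rate already corrects for crossovers that are
invisible in genetic data; the exact correction is not published, so the
rate is an exposed parameter rather than a derivation. The simulator
records true junction counts and observable junction counts (those that
change the unordered founder pair); with self-transitions forbidden the two
coincide except for measure-zero coincidences, and both are kept for
transparency.

**Reads and arrays.** Sequencing is emulated at the depth level: per-marker
total depth is Poisson(coverage) and the alternate count is binomial with
success probability `base_error`, 0.5, or `1 - base_error` for true dose 0,
1, 2. Read-level artifacts (mapping error, duplicates, restriction-site
bias of ddRADseq) are out of scope; a ddRADseq-like arm can be emulated as
"fewer markers, higher depth" through a marker subset. Down-sampling thins
each read independently (binomial thinning), the depth-level equivalent of
down-sampling alignments by a percentage; thinning composes, which the
tests verify distributionally. Arrays are hard 0/1/2 calls on a sparser
marker grid, correct with probability `1 - call_error` and otherwise one of
the two other doses.

**Expression.** A gene's latent trait is
`sum_j f_ij beta_j + sex*beta_sex + gen*beta_gen + e`, with `f_ij` the true
founder allele probability at the marker nearest the gene midpoint and
`e ~ N(0,1)`, so planted effects are in latent-SD units. Counts are
negative-binomial around `size_factor * exp(log_mu0 + 0.5 * latent)`. The
default planted effect for a causal gene is +2.5 / −2.5 on a random founder
pair: a strong local-eQTL-like allele contrast. At n = 183 this gives an
expected genetic variance fraction near 0.4 (expected LOD around 20),
chosen a priori by power calculation to represent clearly mappable local
eQTL rather than threshold-straddling ones. Defaults for the nuisance
parameters (dispersion 0.02, baseline mean 500, size-factor spread 10%,
sex/generation effects 0.25 and 0.05 latent-SD) are ordinary values for a
well-powered expression study. Real expression data depart from this model
in many ways (trans-regulation, batch structure, non-NB noise), so passing
recovery tests demonstrates the machinery, not real-data effect sizes.

# The diplotype HMM

The engine is a 36-state HMM over unordered founder pairs (8 homozygous +
28 heterozygous diplotypes), the same state space whether the observations
are sequencing genotype likelihoods or array calls.

**Transitions.** Over an interval of `d` cM each homolog independently
keeps its founder with probability `exp(-r) + (1 - exp(-r))/8` and switches
to each specific other founder with probability `(1 - exp(-r))/8`, where
`r = n_gen * d / 100`. Diplotype transitions are the symmetrized product of
the two homolog processes. This exponential-switch approximation has the
correct limits — identity at `d = 0`, the stationary diplotype distribution
(1/64 per homozygote, 2/64 per heterozygote) as `d → ∞` — and one tunable
scale (`n_gen`), which is what the benchmarking claims need; it does not
reproduce the exact DO-generation-specific transition probabilities of
specialized software, nor crossover interference. The X chromosome is
treated as autosomal.

**Emissions.** Each state implies an alternate-allele dose at each marker
through the founder alleles. Sequencing observations enter as binomial
genotype likelihoods (log-scale, max-renormalized per site; depth 0 gives a
flat triple). Array calls emit `1 - error` for the called dose and
`error/2` for each other dose; missing calls are uninformative.

**Inference.** Scaled forward–backward with a uniform initial distribution;
posteriors match exhaustive path enumeration to 1e-10 on small instances
(tested). Diplotype posteriors are condensed to 8-founder allele
probabilities (`P(ii) + half of each het involving i`), which conserves row
sums exactly. Dose posteriors and expected dosages come from grouping
states by implied dose. The maximum-marginal path calls the argmax state
where its posterior reaches `minprob` (default 0.95), ties to the lowest
state index, and leaves other markers uncalled.

**Crossovers.** Adjacent called states are compared as founder multisets:
one shared founder means one crossover, disjoint pairs mean two; uncalled
markers are bridged by comparing the nearest called flanks (the choice is
ours; alternatives would shift boundaries by at most the uncalled span).
Boundaries live on the inter-marker interval; block lengths partition the
marker span at boundary midpoints.

**Imputation.** For a population fully described by an eight-founder
reference, haplotype-level low-coverage imputation collapses naturally onto
the same diplotype HMM, so `impute_cohort()` reuses the engine and returns
dosages and per-site INFO scores. One consequence is that imputation and
reconstruction share failure modes; there is no separate haplotype-cloud
machinery (and no counterpart of read-shuffling window parameters used by
external imputation tools — intentionally dropped).

**INFO score.** The IMPUTE-style measure:
`info = 1 - sum_i Var_i(dose) / (2N * theta * (1 - theta))` with `theta`
the posterior mean allele frequency, clamped to [0, 1] and defined as 1 at
monomorphic sites. The upstream publication does not define its formula;
this is the standard choice and is pinned by closed-form tests (point-mass
posteriors give 1; all-prior posteriors at frequency 0.5 give 0).

# Marker filtering

`hwe_pvalue()` is the 1-df chi-square goodness-of-fit test on hard-call
genotype counts (an exact conditional test is available as an option);
monomorphic sites are defined to pass. DO genotype frequencies genuinely
violate Hardy–Weinberg, and the filter is used pragmatically anyway,
mirroring field practice. `adaptive_info_filter()` keeps HWE-passing sites
(`p > 0.05`) and relaxes the INFO cutoff from 0.95 in steps of 0.01 until
strictly more than `min_snps` sites pass (strict ">" by design), recording
the final cutoff; if no cutoff reaches the target, all HWE-passing sites
are returned with a warning flag. `min_snps` is exposed because synthetic
chromosomes are far smaller than the 10,000-SNP real-data target. Whether
the original HWE test used imputed dosages or hard calls is unstated; hard
calls (argmax dose posterior) are used here.

# Founder IBD segments

For each founder pair, markers score a log10 likelihood ratio of IBD versus
independence: matches score `log10((1 - err)/p_match)` with
`p_match = p0^2 + p1^2` from the founder allele frequencies (computed over
the eight founders, not a cohort), mismatches score
`log10(err/(1 - p_match))`. Maximal-scoring runs come from Ruzzo–Tompa
maximal-scoring-subsequence decomposition — verified against exhaustive
O(n²) subinterval search — and runs with total LOD ≥ 10 (default) are
reported. The `err` parameter governs tolerance of internal mismatches,
which the reference analysis leaves unstated. Per pair, reported segments
are disjoint, and lowering the LOD floor never removes a segment.

# Concordance and discordance classification

Two reconstructions are compared per locus by the cosine similarity of
their 8-founder probability vectors — scale-insensitive, 1 for identical
direction, 0 for disjoint founder support. The discordance threshold 0.87
is the cosine between the canonical vector pair
`(0,0,0,0,0,0,.5,.5)` and `(0,0,0,0,0,.25,.25,.5)` — one reconstruction
splitting one of two heterozygous founders' probability with a third
founder (computed value 0.8660). Array probabilities are interpolated onto
the sequencing map linearly in bp with row renormalization (a step dialect
is available behind a flag; positions outside the span take the nearest end
row). Discordant regions are maximal sub-threshold marker runs —
single-marker runs are kept, consistent with the short median lengths such
regions show in practice — with span measured marker-to-marker (not
inter-marker midpoints; a declared choice).

A region is *explained by IBD* when an IBD segment overlapping it by at
least 10 kb (1-based inclusive overlap) involves a founder pair that
touches the founders on which the two reconstructions disagree (the
symmetric difference of the founder sets with region-mean probability above
`prob_floor`, default 0.1) and lies within the union of the two sets — the
two methods swapped probability between founders that are locally
indistinguishable. The explaining pair's class gives the sharing category:
classical-only, classical+WSB, PWK–CAST, or other. "Discordant founders"
are operationalized via the probability floor because the source describes
them only verbally.

# The eQTL scan

Traits are variance-stabilized as `log2(count/size_factor + 1)` (size
factors default to library size over its mean; the original analysis used a
model-based VST, but the subsequent rank-Z transform absorbs any monotone
difference), filtered to genes with summed counts strictly above 3000 and
at least 100 unique values, and rank-Z transformed
(`qnorm((rank - 0.5)/n)`, average ties). "Counts exceeding 3000 across all
samples" is read as total-across-samples (configurable). Generation enters
as a numeric covariate.

At each marker the scan compares `y ~ intercept + sex + generation` against
the model adding the eight founder allele probabilities (one column dropped
for identifiability): `LOD = (n/2) log10(RSS0/RSS1)`. With kinship, a
one-random-effect mixed model is used: leave-one-chromosome-out (LOCO)
allele-probability kinship matrices, null-model heritability estimated once
per trait per chromosome by maximum likelihood in the kinship eigenbasis,
then GLS at every marker with the implied weights. The no-kinship OLS mode
is the default for synthetic benchmarking (cohorts are simulated
unrelated); the LMM mode exists for realistic relatedness structure.

Peaks require LOD ≥ 8; twin summits merge unless the valley between them
drops at least 5 below the smaller; support intervals extend to the
outermost contiguous markers within 1.5 LOD of the summit, bounded by the
separating valleys (interval endpoints at markers; exact tie handling of
external packages is not reproduced). A peak is local when it lies within
2 Mb (inclusive) of the gene midpoint on the gene's chromosome; per gene
the closest local peak is selected, catalogs match 1-to-1 by gene when
support intervals overlap by ≥ 1 bp, and founder allele effects at a peak
are the centered coefficients of the trait regressed on the eight
probabilities plus covariates (no intercept; the probabilities sum to 1).
Cross-method effect similarity is the same cosine metric applied to effect
vectors.

# Numerical choices and degenerate inputs

Forward–backward is scaled per marker (no log-space needed); zero forward
mass raises an error rather than propagating NaN. Emission triples are
max-renormalized in log space before exponentiation. Posterior rows are
renormalized at output; condensation conserves normalization exactly.
Monomorphic conventions: HWE p = 1, INFO = 1. Cosine similarity errors on
zero-norm vectors. `rankz` refuses constant traits and fewer than 3 values.
Grid selection collapses duplicate nearest markers and reports fewer
indices. Ties in `maxmarg` go to the lowest state index; ties in grid
nearest-marker search to the earlier marker.

# Problem sizes used by the test suite

The packaged checks run on deliberately scaled-down instances chosen to
keep the full suite fast while leaving clear statistical margins: synthetic
chromosomes of 50–100 Mb with 400–5,000 markers (≈ 100 markers/cM for
coverage-ladder work — the same order of information per cM as real
filtered imputation grids), cohorts of 2–20 samples for
reconstruction properties, 100–183 samples for scan properties, five
coverage levels from 1× to 0.001×, and 50-gene expression panels with 25
planted local eQTL. The crossover-calibration check simulates 14
chromosomes of 100 cM for 200 mice.

# Known limitations

- The transition model is an exponential-switch approximation, not the
  exact DO-generation transition matrix; absolute crossover counts from
  reconstructed paths inherit this approximation.
- Uniform genetic maps and uniform founder usage ignore real recombination
  hotspots and founder-frequency distortions.
- Read-level artifacts (alignment, duplicates, reference bias) are not
  modeled; coverage is the only sequencing variable.
- Single-chromosome objects are the unit of work; multi-chromosome analyses
  compose them (as `scan1()` does) but there is no X-specific handling.
- The expression model is additive and local-only; trans-eQTL networks and
  permutation-based significance thresholds are out of scope.
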