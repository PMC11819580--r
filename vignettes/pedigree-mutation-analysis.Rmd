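---
title: "Methods: pedigree mutation rates and sex-specific age effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree mutation rates and sex-specific age effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedmut)
```

This vignette explains the models implemented in `pedmut`, the assumptions
behind them, the tunable parameters, what the synthetic-data generator does
and does not emulate, and the design decisions taken where more than one
reasonable convention exists.

## The calling model

A de novo mutation (DNM) in a trio is expected to appear as a Mendelian
violation of one specific kind: both parents homozygous for the reference
allele, the child heterozygous. Restricting discovery to this configuration
discards a small fraction of true events (e.g. a DNM recreating a standing
allele) but removes the error modes that dominate naive violation counts.
Discovery operates on biallelic SNVs only; indels and multiallelic records
are dropped at ingestion.

Each candidate is then screened by seven per-candidate filters. All
verdicts are recorded per filter (`pass` / `fail` / `not_evaluable`) and
the order of evaluation is irrelevant:

1. **Depth** — every trio member must have between 15 and
   `mean + 4*sqrt(mean)` reads (`max_depth_mode = "sigma4"`). The upper
   bound is a Poisson four-sigma cut against collapsed repeats; a
   `"fivex"` alternative (5 × mean) is exposed, but at typical 40X
   coverage it removes almost nothing, which is why four-sigma is the
   default.
2. **Genotype quality** — GQ strictly greater than 60 in all members.
3. **Caller concordance** — the child call must be heterozygous under both
   callers; concordance is consumed as an annotation (`CC` FORMAT field),
   not recomputed.
4. **Strand support** — at least one forward and one reverse read carrying
   the alt allele in the child.
5. **Parental reads** — zero alt-supporting reads in either parent (a
   single read fails the candidate).
6. **Cohort absence** — the alt allele absent from every other sample,
   read-level by default (`presence = "read"`), with a genotype-level
   switch. Full siblings are exempt (a germline mosaic or shared early
   mutation can legitimately recur in siblings) and so are the child's own
   descendants: a transmitted DNM is necessarily present in the next
   generation, and a cohort with ~50% transmission would otherwise filter
   away exactly the mutations it later uses to validate itself.
7. **Allelic balance** — child alt fraction strictly greater than 0.35, a
   guard against somatic mosaics and mapping artefacts.

The strict inequalities in filters 2 and 7 are deliberate: a candidate at
GQ = 60 or AB = 0.35 exactly is rejected. Sites are prefiltered cohort-wide
by mean heterozygote allelic balance (ABHet = ref/(ref+alt) within
[0.2, 0.8]), and contigs are classified before calling: a contig is
X-linked when male/female read depth or heterozygosity differ (two-sided
Welch t-test, P < 0.05 — the test choice is ours; any two-sample location
test would serve) *and* male depth is below 25X; significant contigs with
higher male depth are flagged but not used as X.

## Callability and the rate denominator

Filters that remove errors also remove true mutations, so the naive rate
`N / (2 × depth-passing sites)` is biased downward. The correction factors
the probability that a true DNM configuration survives the screen into
per-member callabilities, assumed independent:

\[ C = C_{child} \cdot C_{father} \cdot C_{mother}. \]

`C_child` is estimated at sites where one parent is homozygous reference
and the other homozygous alternate — the child is then guaranteed
heterozygous — as the fraction of such child calls passing the child-side
filters (depth, GQ, concordance, strand, AB). Parent-side callabilities use
the mirror configuration (that parent homozygous reference, the other
homozygous alternate, child het) and the parent-side filters (depth, GQ,
zero alt reads). The per-trio rate is

\[ \mu_i = \frac{N_{mut,i}}{2 \sum_x C_i^x}, \]

with the callable-site sum equal to depth-passing sites × C. Two
conventions worth making explicit:

- the cohort rate is the **unweighted mean of per-trio rates**, not pooled
  counts over pooled callable sites — the per-trio rate is the
  per-generation estimand, and trios are the replication unit;
- the shipped cohort tables store the *haploid* callable sum; the diploid
  factor 2 lives in the rate denominator, and the regression covariate
  `L = 2 ×` callable sum is the diploid quantity.

The estimator assumes a negligible false-positive rate and site-constant
callability within a trio. The cohort-absence filter's losses are *not*
captured by C (it is a cohort-level screen, not a genotype-calling step);
with realistic sequencing error rates its false-negative contribution is
small, but in the simulator it can be made exactly zero
(`error_alt_rate = 0`) for bias tests.

## Read-tracing phasing

A DNM is assigned to a parent only through sequencing reads. An
informative site is a child-heterozygous site within 1,000 bp of the DNM
whose parental genotypes force each child allele to a unique parent —
exactly the configurations with at most one heterozygous parent. Reads (or
read pairs) carrying the DNM alt allele vote through the informative
alleles they also carry; the DNM is assigned only on a **unanimous** vote
with at least one linking read (`min_votes = 1`). Conflicting reads leave
the mutation unphased rather than triggering a majority rule: with typical
per-DNM coverage a single conflicting read is better evidence of a mapping
problem than a phase signal, and unanimity is the convention that the
assignment be unambiguous. Genotype-only phasing is never performed. A
generic `phase_diff()` compares two phasers' assignments (e.g. read-pair
tracing against an extended haplotype-bridging method).

## Parental-age models

Both regressions are Poisson with an **identity** link, so coefficients
are additive mutation counts rather than rate ratios — the natural scale
for "extra mutations per year". Identity-link Poisson likelihoods are
well-defined only where the linear predictor is positive; `pedmut` fits
them by constrained maximum likelihood (`poisson_identity_fit()`), with
the positivity constraints enforced by a log-barrier over the observed
design points, never by switching to a log link. Covariates are rescaled
internally to unit maximum for optimizer stability; standard errors come
from the observed information; p-values are two-sided Wald. The fitter's
estimates match `glm(family = poisson(identity))` and direct Nelder–Mead
likelihood maximisation to at least four significant digits on cohort-size
problems (tested), and a constant covariate is detected and its slope
fixed at zero rather than letting the information matrix blow up.

**Phased model.** For each parent separately,
`N_phased + 1 ~ Poisson(β₀ + β ζ)` with `ζ = L·S·X`: diploid callable size
× the trio's phased fraction × that parent's age. The pseudocount of 1
keeps the response positive under the identity link. `S` is implemented as
the **fraction** of the trio's mutations that were phased: with that
scaling, β has units of mutations per bp·year on the *total*-count scale,
and the expected phased count is the thinned total. The alternative
literal reading (S = the trio's total mutation count) is exposed as
`s_convention = "count"` but is dimensionally awkward; the two give
noticeably different fits, which is worth knowing when comparing against
other implementations of the same design.

**Total model.** `N ~ Poisson(β₀ + β_P·L·X_P + β_M·L·X_M)`. The headline
effect `effect_per_year()` is `β_parent × L̄` at the cohort mean diploid
callable size, with a delta-method (Wald) CI. This effect is invariant to
how L is scaled *as long as the same L enters the fit and the evaluation*;
evaluating β at a different genome size (say, depth-passing sites before
callability correction, ~1.6× larger here) scales the reported
mutations-per-year accordingly. `pedmut` always evaluates at the same
callability-corrected L used in the fit — the self-consistent choice —
and exposes `L_ref` so users can reproduce other conventions explicitly.

**Equal-age solver.** Assuming both parents conceive at the same age and
each sex's contribution is linear in age, `solve_equal_age_alpha()` finds
the age where the predicted paternal/maternal ratio equals a target (e.g.
a phylogenetic α). Predictions subtract the fitting pseudocount by default
(`subtract_pseudocount = TRUE`) — the fitted mean estimates `E[N+1]`, and
the ratio of interest is between actual counts; the raw-mean variant is a
keyword away. The search runs on a grid over ages with a positive maternal
prediction, refined by `uniroot`; a constant ratio (identical fits) is
flagged as degenerate and returns the leftmost age. Ratios of fitted
linear functions are sensitive to the intercepts, so small convention
changes (pseudocount handling, S convention) move the root by years; the
solver output should always be read together with the two fits.

## Spectrum and test statistics

Mutation types are strand-collapsed to the six pyrimidine-reference
classes; CpG status is a reference C followed by G after collapsing, and
the APOBEC signature is TpC>TpT. The enrichment tests are two-sided Fisher
tests reported with the *unconditional sample* odds ratio `ad/bc` (the
conditional-MLE OR of `fisher.test` is also returned); the comparison
class keeps the signature subset inside the C>T class, matching the usual
presentation, with a `disjoint = TRUE` variant. The young/old maternal
split is strictly at 15 years; a trio exactly at the split is unclassified.
Transmission tests are exact binomial, two-sided by the minimum-likelihood
convention (`binom.test`'s convention; verified against full enumeration in
the tests). Spectrum homogeneity uses the chi-square test with a
Monte-Carlo p-value whenever an expected cell is below 5. Relatedness is
the shared-heterozygote / IBS0 coefficient
`(N_shared_het − 2·N_IBS0) / min(het_a, het_b)`, ≈0 for unrelated pairs,
≈0.5 for parent–child.

## Comparative sex bias

Over many generations the X chromosome spends two thirds of its time in
females, so male-biased mutation depresses X-versus-autosome divergence:

\[ \alpha = \frac{4 - 3\,X/A}{3\,X/A - 2}, \]

valid for `X/A` in (2/3, 4/3]; the lower boundary is the all-male limit
(reported `Inf`), `X/A = 4/3` gives α = 0, and larger ratios are undefined.
The estimator assumes equal per-sex mutation rates on X and autosomes and
ignores selection and ancestral polymorphism. `alpha_with_ci()` takes the
point estimate from the X length against the mean autosomal length and a
95% CI from the per-autosome α values (Student-t on n−1 df by default;
normal quantiles optional); autosomes whose ratio leaves the valid
interval are excluded from both the mean and the CI. One calibration fact,
established by the test suite's Monte-Carlo oracle: because α is convex in
the autosomal length, the mean of per-autosome α values carries a Jensen
offset under multiplicative branch-length noise (about +0.27 at 5% noise
around α = 3.1), so the per-chromosome CI is a CI for that slightly
inflated estimand, not for the generating α. The point estimate, which
averages lengths before transforming, does not have this problem.

## The synthetic cohort generator

`sim_config()` defaults describe a cohort like the aye-aye study:
12 independent trios, ~1.8 Gb of autosomes (12 × 150 Mb), parental ages
uniform on 6.7–30.5 years, 40X Poisson depth, GQ ≈ 75 ± 12, low
polymorphism (`het_rate` 5 × 10⁻⁴ per bp), 1% caller discordance,
10⁻³ per-read error alt rate, 150 bp reads in 500 bp fragments. The
mutation model is the generative counterpart of the total regression: per
trio, `N ~ Poisson(β₀ + β_P·L·X_P + β_M·L·X_M)` with defaults at the scale
fitted from the shipped cohort table, except that the intercept and the
paternal slope are set to the nearest physically valid values (β₀ = 5,
β_P = 3 × 10⁻¹¹) because the fitted intercept is slightly negative, which
an identity-link generator cannot realise. Each DNM's parent of origin is
drawn with probability proportional to that parent's term, the intercept
split evenly between parents — symmetry being the least-informative
attribution of age-independent mutations.

What it emulates: Hardy–Weinberg founder genotypes at polymorphic sites,
Mendelian transmission with one parental haplotype per contig per meiosis,
injected DNMs on the correct haplotype, depth/GQ/allele-depth/strand noise
per call, caller discordance, optional third-generation offspring for
transmission assessment, and haplotype-consistent paired-read evidence.
What it deliberately does not: sequence-level reads (no quality strings or
mapping), intra-contig recombination (which keeps phasing truth exact but
makes transmission co-segregate per contig — transmission fractions
converge to 1/2 over haplotype blocks, not over mutations), site-varying
callability, and population structure among founders. Passing tests on
this generator therefore validate the *logic* of calling, correction,
phasing and regression — not robustness to alignment artefacts or
reference bias, which have no analogue here. An `exact_evidence` mode
fixes depth and balances allele depths exactly, for truth-table tests
where every filter must be satisfiable with certainty; with binomial
allele depths at 40X, the AB > 0.35 screen alone has a ~3–4% intrinsic
false-negative rate, which is precisely what the callability correction
is for (and the correction's unbiasedness is itself tested against the
generator's truth).

All randomness flows from a single integer seed; identical configurations
and seeds reproduce byte-identical output files.

## Problem sizes and numerical choices

The test suite runs the generator at desk scale: genomes of 2–3 Mb across
2–3 contigs, 2–12 trios, heterozygosity 10⁻³–5 × 10⁻³, with 200-replicate
Monte-Carlo loops for coverage and calibration checks and 100-trio
count-level simulations (truth-only, `materialize = FALSE`) for parameter
recovery. These sizes were chosen so each statistical check has enough
events to be sharp (hundreds of DNMs, hundreds of informative sites)
while the whole suite stays fast. Root finding uses a 5,001-point grid
plus `uniroot` at tolerance 10⁻¹⁰; the identity-link fitter uses barrier
constant defaults from `constrOptim` with a relative tolerance of 10⁻¹⁴
and a derivative-free polish.

## Known limitations

- Callability is trio-constant; per-site heterogeneity (GC, mappability)
  is averaged over.
- The phased and total regressions treat trios as independent; siblings
  share parents, and a mixed model would absorb that correlation.
- The equal-age solver inherits every convention of the phased fits;
  alternative conventions move the solution by years (see above), so
  cross-implementation comparisons should fix conventions first.
- The comparative α carries the Jensen offset described above in its
  per-chromosome CI, and assumes the X/autosome contrast reflects
  mutation alone.
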