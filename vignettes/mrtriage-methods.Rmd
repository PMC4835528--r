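---
title: "Methods: summary-data MR and glycemic-burden triage of lipid loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data MR and glycemic-burden triage of lipid loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriage)
```

# The problem

LDL-cholesterol (LDL-C) is causal for coronary artery disease (CAD), and
lowering it is the mainstay of prevention. Statins, however, inhibit
HMGCR and carry an on-target diabetogenic effect. When several classes
of LDL-C-lowering drugs are in development at once, human genetics can
rank their targets: a locus whose variants lower LDL-C and CAD risk
*without* perturbing glycemic traits is a safer bet than one that drags
glucose metabolism along. `mrtriage` turns that reasoning into a tested
pipeline over public GWAS summary statistics: per-trait association
tables in heterogeneous column dialects come in; harmonized effects,
causal-effect estimates, a multi-trait glycemic composite, and a
per-locus classification with drug annotations come out.

This vignette is the package's own account of the statistical model,
the tunable parameters, the synthetic data that make the pipeline
testable, and the design decisions taken where the methodology left
choices open.

# Harmonization

All trait effects are oriented to the *exposure-raising allele*,
per SNP, as defined by the exposure (LDL-C) table: if the reported
exposure beta is negative, the allele pair is swapped, the beta negated
and the effect-allele frequency reflected. Outcome records are then
re-oriented to that reference pair; records whose alleles match in
neither order are dropped and counted in an alignment report, and SNPs
missing from an outcome simply leave that cell empty. Three edge rules:

* **Palindromic SNPs** (A/T, C/G) are *kept and flagged* by default,
  since the harmonization is by allele identity with no strand
  inference; a strict mode (`drop_palindromic = TRUE`) removes them.
  Allele-frequency-based strand inference is deliberately out of scope.
* **Exposure beta exactly zero** cannot define a raising allele; the
  alphabetically first allele becomes the reference and the SNP is
  flagged `zero_exposure`, which bars it from ever serving as an MR
  instrument.
* **SNPs absent from the exposure** are discarded: orientation is
  defined by the exposure, so nothing can be said about them.

Duplicate SNP rows within one source file are resolved at ingest by
keeping the row with the smallest P value (and logging the count);
source files rarely document their own deduplication rule, and smallest
P retains the row most likely to have driven the original analysis.

# The ratio estimator

For SNP $j$, with exposure association $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$) and outcome association $\hat\beta_{Yj}$ (SE
$\sigma_{Yj}$), the Wald ratio and its delta-method SE are

$$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}, \qquad
  se_j = \sqrt{\sigma_{Yj}^2/\hat\beta_{Xj}^2 +
               \hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4},$$

assuming zero covariance between the two estimates, which the
two-sample design (non-overlapping studies) justifies. The second-order
form is the default; the first-order form $\sigma_{Yj}/|\hat\beta_{Xj}|$
is available for comparison and is the exact limit when
$\sigma_{Xj}=0$. Ratios are pooled by fixed-effects inverse-variance
meta-analysis; P values are normal-theory throughout (consistent with
fixed-effects pooling; no small-sample t correction).

Instrument selection: exposure P < 5×10⁻⁸, pruned to pairwise r² below
a bound (0.8 default, 0.2 sensitivity), keeping the smallest exposure P
per correlated group. An optional *exclusion step* afterwards removes
instruments nominally associated with a secondary trait (e.g. T2D at
P < 0.05 or 0.01); it deliberately does **not** trigger re-selection of
replacement instruments, because the scientific question is how the
estimate changes when those same instruments are set aside.

**Assumptions and their failure modes.** The estimator presumes
relevance (strong instruments), independence, and exclusion restriction
(no pleiotropic path to the outcome). Two quantitative consequences
matter for interpreting this package's own calibration studies:

1. Selecting instruments on the same noisy exposure estimates that enter
   the denominator induces a regression-dilution/winner's-curse bias of
   relative order $\sigma_X^2/\beta_X^2$ toward the null. With effects
   around 0.05 SD at biobank-scale noise this is roughly 1%; at 0.25–0.35
   SD it is negligible.
2. The pooled SE shrinks as $1/\sqrt{K}$ with the instrument count $K$
   while that bias does not, so *CI coverage* of the pooled estimate is
   nominal only in the strong-instrument regime. Our coverage study
   (`mr_recovery_config()`: 40 causal SNPs at effect SD 0.35, common
   MAFs, ~37 instruments per replicate) is designed there, and the
   recovery tests allow a 1% systematic margin on top of Monte-Carlo
   error — an estimator property, not an implementation artifact.

Egger regression, median/mode estimators and multivariable MR are out
of scope by design; the package implements the conventional ratio
approach and says so.

# LD clumping and pruning

Greedy, P-value-prioritized: visit SNPs in ascending priority P; each
unassigned SNP becomes a lead and absorbs all unassigned same-chromosome
SNPs within the window whose r² to it exceeds the threshold. Design
choices, all made for determinism and sparse inputs:

* ties in P break by (chromosome, position, SNP id);
* a missing LD pair means r² = 0 (LD tables are sparse user inputs; the
  package never computes r² from genotypes);
* cross-chromosome r² is ignored even if tabulated;
* the clumping window defaults to 250 kb each side (the common
  clumping default), while *pruning to independent loci* uses a
  whole-chromosome window.

A brute-force re-application of these rules serves as the test oracle
for instances up to 12 SNPs, and validity/monotonicity properties are
asserted on random instances at fixed seeds.

# The glycemic burden composite

Each SNP's statistics for fasting glucose, fasting insulin, fasting
proinsulin, HbA1c and T2D are combined into one signal. Two schemes:

* `stderr` (default): inverse-variance meta-analysis of betas and SEs,
  the same kernel as the MR pooling. The contributing traits have
  different units (mmol/l, log-pmol, %, log-odds), so the pooled beta is
  unit-less in any physical sense; the scheme follows the convention of
  meta-analyzing beta/SE pairs directly and is surfaced as such.
* `samplesize`: $z = \sum\sqrt{n_i}z_i/\sqrt{\sum n_i}$, which
  sidesteps units entirely. Results must state which scheme was used.

**Trait-redundancy screening.** Derived traits computed from the same
measurements on the same individuals (HOMA indices from fasting
insulin) add no information and inflate the composite because the same
people are counted twice. Traits are screened by pairwise Kendall τ
(tie-corrected) of their Z vectors: walking the configured trait order,
a trait is excluded when |τ| with an earlier retained trait reaches the
threshold. The default threshold 0.75 is *inclusive* so that a pair at
exactly 0.75 is excluded; trait order is authoritative and documented
as such. Since Kendall τ costs O(n²), panels beyond
`screen_max_snps` (default 5000) are deterministically thinned for the
τ estimate — at 5000 SNPs τ is estimated to about ±0.02, far finer than
the decision threshold.

**Inflation diagnostic.** λ = median(z²)/0.4549364 (the χ²₁ median).
The tests verify λ ∈ [0.9, 1.1] on a 10,000-SNP global-null panel, that
the composite z is Kolmogorov–Smirnov-indistinguishable from standard
normal there, and that adding a planted duplicate trait strictly
inflates λ — the phenomenon the screening exists to prevent.

SNPs present in only a subset of traits are combined over the available
cells (with the count recorded); no minimum-trait filter is imposed by
default.

# Concordance, enrichment and triage

**Directional concordance.** Among loci with a genome-wide-significant
exposure SNP that is also nominally outcome-associated, each locus is
summarized by one representative SNP (smallest outcome P; ties by
exposure P, then SNP id — a single representative because one effect
per locus is what gets reported, with a majority-sign variant left as
configuration). After harmonization the exposure direction is positive
by construction, so the locus is concordant iff the representative
outcome beta is positive; an exactly-zero beta drops the locus with a
warning. The headline statistic is the *exact binomial point mass*
$\binom{n}{k}2^{-n}$ at the observed count under a fair coin: this is
the quantity that reproduces reported concordance probabilities such as
6.85×10⁻⁵ for 22 of 25 concordant loci (and 0.016 for 6 of 6,
0.15 for 6 of 15). One- and two-sided tail versions are provided,
clearly labelled, for users who want a conventional test instead of the
point mass.

**Fisher enrichment.** Per candidate locus, a 2×2 table of
composite-associated vs not, in-locus vs background, tested by Fisher's
exact test (two-sided by the standard minimum-likelihood rule; odds
ratio reported as the sample cross-product ad/bc). Two open choices
were fixed as follows: the background is *all pruned SNPs outside the
locus*, and the in-locus set is the *pruned* SNPs — pruning first
mitigates LD pseudo-replication, where one causal signal masquerades as
many concordant SNPs. A flag allows unpruned input.

**Triage.** Over the pruned set, with all thresholds strict:

* *glycemia-neutral candidate*: ≥1 pruned SNP with exposure P < 5×10⁻⁸,
  CAD P < 0.05 and composite P > 0.05, **and** the locus is not
  over-represented (Fisher P ≥ 0.05 or OR ≤ 1);
* *glycemic liability*: ≥1 such SNP with composite P < 0.05, **and**
  the locus is over-represented;
* everything else among candidate loci: *indeterminate*.

The routes are mutually exclusive because the Fisher verdict gates
them. Drug annotations join by gene label from a static table — a
deliberate stand-in for interactive database queries, with the
pharmacodynamic flag carried as a column of the user's table.

# The synthetic generator

`simulate_gwas()` emulates the two-sample summary-statistic setting at
the level the pipeline consumes — no genotypes anywhere. SNPs come in
blocks (one gene/locus each) with exchangeable allelic correlation
`within_block_rho`; the emitted LD table holds ρ². Marginal true
effects are the LD-smeared block sums (marginal = joint + ρ·Σ others),
and estimation noise is exchangeably correlated within a block with the
same ρ. Standard errors follow the closed forms
$1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$ for quantitative traits and
the same with effective sample size $4/(1/\mathrm{cases} +
1/\mathrm{controls})$ for binary ones (log-odds scale; no
liability-scale conversion). Every trait's rows are emitted with a
random allele orientation (beta and EAF flipped coherently) so the
harmonization stage is genuinely exercised. Blocks carry planted
labels — *neutral candidate* (exposure signal, θ-mediated outcome
effects, no glycemic channel), *glycemic liability* (additionally a
dense glycemic signal on every member SNP, emulating tight local LD
around a shared causal glycemic variant — the statin-target pattern),
or *null* — and `truth_report()` exposes the ground truth for
assertions.

**Default study conditions**, chosen once to mirror the public
consortium datasets the pipeline targets and then left alone:

| parameter | default | rationale |
|---|---|---|
| exposure N | 95,454 | lipid-consortium sample size |
| CAD cases/controls | 63,746 / 130,681 | CAD consortium |
| T2D cases/controls | 34,840 / 114,981 | T2D consortium |
| glycemic trait Ns | 133,010 / 108,557 / 10,701 / 46,368 | fasting glucose, insulin, proinsulin, HbA1c consortium sizes |
| θ(CAD), θ(T2D) | log 1.63, log 0.86 | the causal ORs per SD of LDL-C the pipeline is expected to recover |
| exposure effect SD | 0.05 SD | typical genome-wide-significant lipid-locus effects; leaves a minority of instruments nominally T2D-associated, as observed |
| causal fraction | 0.1 | a handful of causal variants per locus |
| within-block ρ | 0.3 (r² 0.09) | the r² < 0.5 pruned set then retains multi-SNP loci, as the enrichment step requires |
| MAF | U(0.05, 0.5) | common variants |
| glycemic effect SD | 0.02 | mmol/l-scale at loading 1; comfortably detectable at the glycemic Ns |
| duplicate-trait z-noise SD | 0.1 | bivariate-normal τ ≈ 0.94, matching a HOMA-grade near-duplicate |
| fixture size | 2,000 SNPs, 40 blocks (8 neutral, 6 liable, 26 null) | desk-scale end-to-end runs in seconds |

**What it does not emulate:** realistic human LD maps or
allele-frequency spectra, polygenicity beyond the planted blocks,
sample overlap between consortia, strand ambiguity, or proxy-SNP
structure. Passing tests therefore demonstrate the *logic and
calibration* of each stage under the stated generative model, not
performance on real consortium files.

# Study-design configurations

Three exported configurations pin down the simulation studies the tests
and the acceptance script run. Their parameters are design choices,
made from the power analyses sketched here and validated across many
seeds rather than tuned to any single one.

**`triage_fixture_config()`** (2,000 SNPs, 40 blocks, seed 20160305) is
the ground-truth fixture on which triage must recover every planted
label. It deviates from the defaults in three deliberate ways. First,
θ(T2D) = 0: under a *nonzero* causal LDL-C→T2D effect every
exposure-associated locus carries a mediated T2D association, so
"glycemia-neutral" is only ever relative to power — a label that must be
*exactly* recoverable requires loci whose glycemic channel is genuinely
absent. Second, denser and stronger exposure effects (causal fraction
0.2, effect SD 0.1) make every non-null locus contain a
genome-wide-significant SNP with near certainty, so a detection miss
would indicate a method error, not an underpowered fixture. Third,
within-block correlation is zero: the per-locus Fisher enrichment treats
member SNPs as independent, and block-correlated estimation noise shifts
whole blocks at once — an LD-pseudo-replication artifact that the
clumping/pruning tests, not the triage fixture, are the right place to
exercise. The design recovers all 40 labels on every seed tried (21 of
21) before the shipped seed was fixed.

**`mr_recovery_config()`** (80 SNPs, 40 causal at effect SD 0.35, MAF
U(0.2, 0.5)) is the estimator-calibration study: ~37 strong instruments
per replicate, where the selection-induced dilution (≈0.05%) is an
order of magnitude below the pooled SE, so 95% CI coverage is nominal.
The acceptance run uses 500 replicates — more than the conventional 200
— because at 200 replicates a perfectly calibrated 95% interval leaves
the [0.93, 0.97] acceptance band about one run in seven by binomial
noise alone; 500 replicates make the band a ~2σ statement.

**`consortium_scale_config()`** (600 SNPs, ~230 instruments, effect SD
0.1) re-derives the headline ORs in one pipeline run at the real sample
sizes: CAD ≈ 1.63, T2D ≈ 0.86, and CAD ≈ 1.61 after excluding
T2D-associated instruments — the exclusion removes the strongest
instruments (whose mediated T2D signal is detectable) and the estimate
from the survivors is unchanged up to noise, which is precisely the
argument for LDL-C lowering being CAD-protective independent of the
diabetogenic channel. Effect SD 0.1 balances instrument strength
against a partial (not total) exclusion.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive; BED input is converted at the
  boundary. Indels and multi-character alleles are rejected at ingest
  (SNPs only). Out-of-range EAFs are set missing rather than dropping
  the row.
* Missing P values are derived as two-sided normal tails of beta/se;
  supplied P values outside (0, 1] drop the row.
* Tables are serialized at 17 significant digits, so write→read
  round-trips agree to better than 1e-12 relative.
* Duplicate LD pairs keep the maximum r² with a warning; self-pairs are
  implicitly 1; absent pairs 0.
* All classification thresholds are strict inequalities; boundary cases
  fall on the non-significant side. The τ screening threshold is the
  one deliberate exception (inclusive ≥), so that a documented
  redundancy at exactly the threshold is removed.
* Empty instrument sets, all-dropped outcomes, empty estimate lists and
  all-zero Fisher tables raise errors naming the stage that emptied
  them; mismatches and absences accumulate in reports instead of
  failing.

# Problem sizes

The shipped test suite and acceptance script run entirely at desk
scale: the 2,000-SNP default fixture, a 10,000-SNP null panel for the
λ/KS calibration, 500 MR replicates of 80 SNPs, full Fisher enumeration
to margins of 15, and 200 randomized clumping instances of up to 12
SNPs — a few minutes end to end on one core. These sizes were chosen as
the smallest at which each stochastic check is decisive (binomial noise
well inside its acceptance band); scaling the generator up is a matter
of configuration, not code.

# Known limitations

Beyond the generator's simplifications listed above: no proxy-SNP
search for variants missing from an outcome; no correction for sample
overlap between contributing consortia; no conditional/joint multi-SNP
modelling; no liability-scale conversion for binary traits; trait-order
dependence of the redundancy screen (documented, configurable); and the
conventional ratio estimator's pleiotropy sensitivity, for which
multivariable and intercept-based extensions are explicitly left to
other tools.
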