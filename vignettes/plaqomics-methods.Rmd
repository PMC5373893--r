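---
title: "Statistical methods in plaqomics: from plaque ECM proteomics to risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in plaqomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqomics)
```

# Scope

`plaqomics` implements the statistical machinery of a tissue-based biomarker
discovery programme for atherosclerotic plaque instability: differential
expression of extracellular-matrix (ECM) proteins quantified by spectral
counting, transcript-level confirmation, paired secretome testing,
coexpression networks, cross-omics candidate selection, person-based
ultrasound progression classification, and the epidemiological metrics that
quantify how much a biomarker panel adds to standard risk factors. Every
stage can be exercised end-to-end on seed-controlled synthetic data, so the
whole pipeline is testable without access to clinical cohorts or proteomics
repositories.

# Spectral-count differential expression

## NSAF normalization

Spectral counts are a semi-quantitative abundance proxy: longer proteins
yield more peptides and therefore more spectra. The normalized spectral
abundance factor divides each count by protein length and rescales each
sample to sum to one,

$$\mathrm{NSAF}_{ij} = \frac{c_{ij}/L_i}{\sum_k c_{kj}/L_k},$$

which removes both the length bias and per-run depth differences
(`compute_nsaf()`). The sum-to-one constraint makes NSAF compositional: a
strong change in a few abundant proteins shifts every other protein's NSAF
in the opposite direction. The synthetic generator therefore plants
differential abundance in both directions so that null proteins stay
centred; a design in which all regulated proteins move one way would leak
compositional bias into the null (a caveat that applies equally to real
data).

## Zero imputation

Zero counts make the log-scale error model undefined. They are replaced by
a single fractional value $\epsilon \in (0,1)$ chosen empirically: every
candidate on a grid (default step 0.01) is substituted, the matrix is
re-normalized, and the pooled natural-log NSAF values are scored with the
Shapiro-Wilk W statistic; the chosen $\epsilon$ maximizes W with ties
broken toward the smallest value (`impute_zeros()`). Substituting on the
count scale and re-normalizing preserves the column sums. Shapiro-Wilk is
defined for at most 5000 observations; larger pooled vectors are reduced to
5000 evenly spaced order statistics, a deterministic subsample that
preserves the distribution's shape. Proteins with zero counts in every
sample carry no information and are dropped (and reported) before analysis.

## Power-law global error model

With six replicates per group, per-protein variance estimates are too noisy
to use directly. The power-law global error model (PLGEM) pools information
across proteins by assuming
$$\log \mathrm{SD}_i = b + a \log \mu_i,$$
fitted by ordinary least squares across proteins within the replicates of
one condition (`fit_plgem()`); the condition with more replicates is used,
with ties broken toward the first group. The signal-to-noise statistic
uses the *modelled* standard deviations,
$$\mathrm{STN}_i = \frac{\mu_{A,i} - \mu_{B,i}}
{e^{b}\mu_{A,i}^{a} + e^{b}\mu_{B,i}^{a}},$$
so a protein is judged against the dispersion typical of its abundance, not
its own noisy estimate.

Significance comes from a resampling null (`resampling_null()`): pseudo-A
and pseudo-B groups of the real group sizes are drawn with replacement from
the replicates of the fitting condition, STN is recomputed for every
protein, and the absolute null values are pooled across proteins and
iterations (default 500). Two-sided p-values use the
$(\#\{|STN_0| \ge |STN_i|\}+1)/(N+1)$ small-sample correction. Drawing
pseudo-groups at the real group sizes matters: split-half resampling at
half size would double the variance of the null mean difference and make
the test severely conservative. Benjamini-Hochberg FDR (via
`stats::p.adjust`) with a 10% threshold defines the significant set.

# Transcript-level and secretome testing

Transcript contrasts (e.g. symptomatic versus asymptomatic plaques, 84 vs
37 arrays) use a moderated t: per-gene residual variances are shrunk toward
a scaled inverse-chi-square prior whose scale and degrees of freedom are
estimated by the method of moments on the log residual variances (trigamma
inversion), and the moderated statistic gains the prior degrees of freedom
(`moderated_two_group_de()`). The moments estimator is deterministic and
closed-form; the package's tests cross-check it against the established
empirical-Bayes implementation in `limma`. Setting the prior degrees of
freedom to 0 or $\infty$ recovers the ordinary and fully pooled t-tests,
which is also how the implementation is verified.

The secretome comparison is deliberately classical: nine proteins shared
between the plaque ECM proteome and the smooth-muscle-cell secretome are
tested with two-sided paired t-tests across donors and a Bonferroni
correction at a 5% family-wise error rate (`paired_bonferroni_test()`).
Pairing removes the donor random effect, which dominates between-donor
variation in primary cell cultures. With six donors and a family of nine,
the design only has high power for shifts of roughly three paired-difference
standard deviations or more; the package's power test uses a shift in that
regime.

# Coexpression networks

Protein coexpression networks are built from all-pairs Pearson correlations
of NSAF values across the twelve samples pooled (`pearson_with_p()`), with
p-values from the exact t-transform on $n-2$ degrees of freedom.
Edge-level multiplicity is handled with Storey q-values: $\pi_0$ is
estimated by the median of $\hat\pi_0(\lambda)$ over
$\lambda \in \{0.05, \ldots, 0.95\}$ and q-values are
$\pi_0$-scaled step-up quantities (`storey_qvalues()`); edges require
q < 0.20. With fewer than ten p-values the $\pi_0$ estimate is unstable
and the function falls back to $\pi_0 = 1$, i.e. Benjamini-Hochberg, with
a warning. Nodes are sized by differential-expression confidence
($-\log_{10}$ FDR); node classes (collagen, protease, and so on) come from
a user-supplied annotation, never from inference.

# Cross-omics candidate selection

A protein becomes a biomarker candidate when it is detected by plaque
proteomics *and* at least one of the two orthogonal approaches — plaque
transcriptomics or the lipid-loaded smooth-muscle-cell secretome
(`select_candidates()`). All set operations are case-normalized and
order-stable, and selection is monotone: adding evidence can only add
members. The package ships small synthetic stand-in discovery lists
(`inst/extdata/synthetic_*`) whose constrained facts (list sizes, the
two shared fraction members, the five-gene protein-transcript overlap and
the seven-member candidate set) reproduce the published integration counts;
the unconstrained members are illustrative ECM proteins, as the original
tables are not distributed with the package.

# Ultrasound progression model

Carotid atherosclerosis is scored by summing the maximum axial plaque
thickness (near and far wall) over eight vessel segments, counting only
sites with at least 0.5 mm wall widening — the protocol's plaque
definition (`atherosclerosis_score()`). Between two visits,
`classify_progression()` distinguishes:

* **advanced complicated atherogenesis** — an existing plaque grows by more
  than twice the sonographic measurement error (internal carotid 24.8%,
  common carotid 17%) *and* the same artery reaches at least 40% lumen
  narrowing. The conjunction is evaluated within one artery because the
  phenotype is a solitary stenotic lesion;
* **early atherogenesis** — any new plaque or any growth of an existing
  plaque that does not meet the advanced rule at that site (non-stenotic
  progression);
* **incipient atherosclerosis** — early progression in a subject free of
  plaque at baseline.

The thresholds are package constants (`progression_thresholds()`),
overridable only explicitly. "Maximum plaque diameter" is interpreted as
the per-site maximum axial thickness — the only diameter-like quantity the
scanning protocol records — and a site crossing the 0.5 mm floor between
visits counts as a new plaque, not as growth. Reproducibility of the
categorical calls is quantified with Cohen's kappa (`cohens_kappa()`).

# Risk prediction and incremental value

Biomarkers are standardized on the natural-log scale
(`standardize_biomarker()`), so effect estimates read as odds or hazard
ratios per 1 SD of the log level. Logistic models use `stats::glm` with
Wald intervals; apparent separation is reported as an error rather than
silently clipped. Cox models use `survival::coxph` with the Efron tie
approximation, optional robust sandwich errors, and time-fixed weights.
Proportional hazards are checked on scaled Schoenfeld residuals against
untransformed time (`schoenfeld_check()`).

Signature selection is forward-stepwise with likelihood-ratio tests,
p-enter 0.05 and p-remove 0.10 — conventional inclusion/exclusion
criteria — with a deterministic tie-break by candidate order and a full
decision log (`forward_stepwise()`).

The case-cohort design (random subcohort plus all cases) is analysed with
Prentice weighting (`prentice_case_cohort()`): subcohort members are at
risk from time zero, cases outside the subcohort enter the risk set just
before their own event; the implementation is a counting-process Cox model
with mandatory robust errors clustered on subject, and it reduces exactly
to the full-cohort fit when the subcohort is the whole cohort.

Incremental value of added markers (`compare_risk_models()`) is quantified
by:

* the C-statistic (binary outcomes: concordance over case/non-case pairs
  with half credit for ties) or Harrell's C-index (survival: usable pairs
  where the earlier failure is observed), each with leave-one-subject-out
  jackknife standard errors computed in closed form from per-subject pair
  sums (`c_statistic()`);
* the DeLong test for paired AUC differences from structural components
  (`delong_compare()`), applied to binary outcomes; survival differences
  use the jackknife z-test instead;
* categorical net reclassification improvement over the 10-year risk
  categories <5%, 5 to <7.5%, and ≥7.5% (intervals closed on the left), and
  the category-free continuous NRI (`nri()`);
* the integrated discrimination improvement, the difference of
  discrimination slopes (`idi()`).

Ten-year absolute risks from Cox fits use the Breslow baseline cumulative
hazard at the horizon. Missing data are handled by complete-case analysis
per model, with the analysis n reported.

# The synthetic-data module

`simulate_spectral_counts()` draws per-protein abundances from a log-normal
distribution (median count about 20), adds replicate noise with the
power-law SD $e^b\mu^a$ (defaults $a = 0.7$, $b = -0.5$, giving replicate
CVs around 25-50%), rounds and clips to non-negative integers, and injects
structural zeros with probability proportional to the inverse abundance
rank — zeros in spectral counting concentrate in low-abundance proteins.
The within-group dispersion of the motivating experiment is not published,
so the power-law defaults are free parameters of the simulation, not
estimates of real data. Count discretization slightly attenuates the
fitted slope at low means; recovery tests use tolerances (±0.07 at
$a = 0.7$) that absorb this.

`simulate_cohort()` emulates a community cohort: ages uniform on 40-79,
balanced sex, conventional risk-factor distributions, biomarkers
multivariate log-normal with a configurable correlation matrix (default
exchangeable, r = 0.3), an advanced-progression outcome drawn from a
logistic model whose coefficients are the configured log odds ratios (the
intercept is solved numerically so the marginal rate matches 102/560), an
early-progression outcome driven by standard risk factors (371/560), and
exponential event times with log-linear hazards censored administratively
at 10 years (91/685 events). Two-visit ultrasound exams are constructed so
that the truth labels satisfy the progression rules by construction —
advanced subjects receive one index plaque grown 1.3-2 times past its
artery's threshold in an artery narrowed to 45-75%, early subjects a new
plaque or sub-threshold growth — after which Gaussian measurement noise
(default 0.1 mm) is added. In the noise-free limit the classifier
reproduces the generator's labels essentially perfectly, which is a
construction-consistency check, not evidence about real sonography. There
are no competing risks and censoring is administrative only.

What the generator does *not* emulate: peptide-level identification noise,
shared-peptide ambiguity, batch effects, array probe-level structure,
informative censoring, or visit non-attendance. Passing tests therefore
demonstrate the correctness and calibration of the estimators under the
stated models, not robustness to those real-data complications.

# Problem sizes and numerical choices

The test-suite and acceptance computations use 300-1000 proteins at 6
replicates per group with 300-500 resampling iterations, transcriptomes of
2000 genes at 84 vs 37 samples, cohorts of 300-2000 subjects with 50-seed
replication for effect-recovery studies and 200-seed replication for CI
coverage — sizes chosen so every distributional claim has enough Monte
Carlo resolution while a full run stays comfortably on one CPU core.
Other numerical choices: the imputation grid step is 0.01; correlation
p-values clip $1 - r^2$ away from zero before the t-transform; q-value
$\pi_0$ is clipped to $[1/n, 1]$; the case-cohort entry offset is 1% of
the smallest gap between distinct event times (with `timefix` disabled, as
recommended for counting-process constructions); jackknife standard errors
use the $(n-1)/n$ convention.

# Known limitations

* NSAF compositionality is mitigated in simulation but not corrected in
  inference; strongly asymmetric regulation in real data would bias the
  null, as it does for any closed compositional normalization.
* The moments estimator of the variance prior can differ from
  marginal-likelihood fits when genes are few; with fewer than ~100 genes
  the prior degrees of freedom are noisy.
* Harrell's C with administrative censoring is estimated over usable pairs
  only; heavy censoring reduces the effective pair count and widens the
  jackknife intervals.
* The DeLong test applies to pre-specified scores; comparing nested models
  refitted on the same data is conservative (the package's calibration
  tests use pre-specified scores for exactly this reason).
* Stepwise selection inherits the usual instability of variable selection;
  the full decision path is logged so that selections can be audited.
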