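---
title: "Choosing a scan-sampling interval: the scanopt methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a scan-sampling interval: the scanopt methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous behavioral recording — noting the start and end of every bout of
every animal — is the gold standard for group ethology, but for studies with
many pens, long sessions and large ethograms it is rarely feasible.  Scan
sampling replaces it with periodic instantaneous censuses: every
`interval_s` seconds an observer counts, for each behavior, how many visible
animals are engaged in it.  The occurrence of a behavior is then the mean
over scans of the percentage of visible animals performing it.

The interval length is a real design decision, not a nuisance parameter.
Long intervals are cheap but sparse: a 2-h session scanned every 30 min
yields 4 data points, and behaviors whose bouts last a few seconds
(aggression, startle, social grooming) are mostly missed.  scanopt
implements a multistep workflow for making this trade-off explicit:

1. **Reference selection.**  Candidate intervals are compared against
   continuous recording on matched (session, behavior) occurrence pairs
   using the R² of the regression of continuous on candidate values, the
   mean absolute error and the root mean square error.  The interval winning
   a majority of the three criteria becomes the *reference* — the best
   feasible estimate of the truth (ties go to the shortest interval).
2. **Reliability.**  Two-way intraclass correlation coefficients quantify
   agreement, between observers (per-scan data) or between sampling methods
   (session-level occurrences, methods as raters).
3. **Accuracy.**  Signed error scores (test minus reference, in percentage
   points) are summarized by occurrence category with t-based confidence
   intervals, and Bland–Altman bias and 95% limits of agreement are
   computed in raw and percent modes.
4. **Validity.**  The scientific conclusions themselves are compared: a
   group effect (e.g. a genotype contrast) is estimated per sampling method
   with a Tweedie GLM, and the log-scale estimates are tested for equality
   with a normal z-test.

Every stage is exercised against simulated ground truth, because a flock
simulator with known time budgets makes each claim checkable: we know the
true occupancies, the true group effects, and the exact information loss of
any subsampling scheme.

## The flock simulator

Each animal is an independent renewal sequence of behavior segments.  A
segment's behavior $b$ is drawn with probability

$$w_b \propto \frac{\pi_b}{m_b},$$

where $\pi_b$ is the target occupancy (long-run fraction of time, summing
to 1) and $m_b$ the mean bout duration in seconds; the segment length is
exponential with mean $m_b$.  By the renewal–reward theorem the long-run
fraction of time in $b$ is $w_b m_b / \sum_c w_c m_c = \pi_b$ — the target
occupancy is recovered *exactly in expectation*, which is what makes the
simulator usable as ground truth.  The first segment is drawn from the
time-stationary distribution ($\pi$ itself, with a memoryless residual
duration), so there is no burn-in bias at the start of a session.  Adjacent
identical behaviors are merged into bouts.

Visibility — whether an animal can be scored at all — is an independent
alternating on/off renewal process with stationary on-fraction
`visible_fraction` and exponential spell lengths.  Because visibility is
independent of behavior, restricting occurrence denominators to visible
animal-time is unbiased; the tests confirm this by comparing occurrences at
`visible_fraction` 0.8 and 1.0.

Group effects act multiplicatively on occupancy and are then renormalized:
a factor $f$ on behavior $b$ gives group occupancy $f\pi_b / (1 + (f-1)\pi_b)$.
For rare behaviors the renormalization is negligible and the realized mean
ratio is essentially $f$, matching the rate-ratio scale of the log-link
models in the validity stage.

**What the simulator does not model:** diurnal rhythm within a session,
social contagion (animals are independent), spatial structure, and observer
error in the continuous record.  Bout durations are exponential because the
workflow needs only correct time budgets, not realistic bout-length
distributions; no field data inform the bout means, which are a simulator
choice (static behaviors long, interaction behaviors short) exposed in the
configuration.  Consequently, passing tests show that the *statistical
machinery* behaves as claimed under a controlled data-generating process —
they do not certify any particular real-world interval choice, which always
depends on the animals, housing and ethogram at hand.

The packaged `broiler_preset()` emulates a free-range broiler study: a
20-behavior ethogram, 50-animal pens, 2-h sessions, and an occurrence
spectrum spanning roughly 0.05% to 31% of visible animals per scan, so that
all three occurrence categories are populated the way they are in pasture
poultry data.

## Sampling conventions

* **Scan times** follow the end-of-interval convention $t = k\Delta$,
  $k = 1, \dots, \lfloor D/\Delta \rfloor$: a 2-h session gives 12 scans at
  10 min, 8 at 15 min, 4 at 30 min, 24 at 5 min.  With this anchor the
  30-min grid is a subset of the 15- and 10-min grids; a configurable
  `offset_s` shifts the grid for software that anchors differently.
* **Instantaneous mode** (default) reads each animal's behavior and
  visibility off at the scan instant.  Human observers actually watch a
  short window (typically 10 s); the optional `window_majority` mode scores
  the behavior occupying the largest share of the window (ties go to the
  behavior active at the scan instant) and counts an animal visible if it
  can be seen for at least half the window.  For simulated data the
  instantaneous state is exact, so the default stays instantaneous.
* **Zero-visible scans** contribute an undefined 0/0 proportion and are
  dropped from the occurrence mean (and logged), rather than being treated
  as zeros.
* Time is continuous in seconds; all intervals are half-open
  `[start_s, end_s)`, so bout tilings and state lookups are unambiguous at
  boundaries.
* Occurrences are carried on the 0–100 percent scale throughout.

## Reliability: intraclass correlation

The two-way crossed ANOVA without replication (subjects × raters) yields
mean squares $MS_R$ (subjects), $MS_C$ (raters), $MS_E$ (error), from which
the Shrout–Fleiss coefficients follow.  Consistency, single measure:

$$ICC(C,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E},$$

absolute agreement adds the rater-offset term $k(MS_C - MS_E)/n$ to the
denominator, and average-measure forms are the Spearman–Brown step-up of
the single forms.  Confidence bounds are the exact F-based ones
(Satterthwaite degrees of freedom for absolute agreement), and the F test
of the subject effect supplies the p-value.  Values are labelled poor
(< 0.40), fair (0.40–0.60), good (0.60–0.75) or excellent (≥ 0.75), with
the lower bound inclusive in the upper class.

Two flavors matter in practice and the choice is exposed rather than
hidden: `consistency` ignores a systematic offset between raters,
`absolute_agreement` penalizes it.  Widely used GUI software defaults
two-way mixed models to consistency while the word "agreement" suggests the
absolute form, so `icc()` implements both and the pipeline records which
one it used (default `absolute_agreement`, `average` across methods).  A
behavior with no variance anywhere (never expressed under any method) has
an undefined ICC and is reported as such — forcing 0 or 1 would fabricate
information.

## Accuracy: error scores and Bland–Altman

Behaviors are first binned by their mean occurrence under the reference
method: low (≤ 0.49%), medium (0.49–3.50%), high (> 3.50% of visible
animals per scan).  The boundaries are tunable; the defaults are the
conventional cut-points for pasture-poultry ethograms.  A catch-all bucket
("Others") can be flagged `excluded_from_binning`: it still contributes to
occurrence totals but not to category summaries.

Error scores are signed raw differences in percentage points,
`test − reference`, so negative means the longer interval underestimates.
Per category they are summarized by the mean and a t-based 95% CI; an
interval excluding zero flags systematic bias.  Paired error distributions
(e.g. 15-min vs 30-min errors) are compared with related-samples Wilcoxon
signed-rank tests — exact when ≤ 25 untied non-zero pairs remain, normal
approximation with continuity correction otherwise.

Bland–Altman analysis reports the bias (mean difference), the SD of the
differences, and limits of agreement at bias ± 1.96 SD (the multiplier is
fixed at 1.96 by convention; no small-sample t correction is applied).  Two
modes are provided because they answer different questions:

* **raw** — differences in percentage points; dominated by the
  high-occurrence behaviors.
* **percent** — differences relative to the *reference* value,
  $100(a - b)/a$: the practical impact of a bias on a rare behavior.  The
  denominator could alternatively be the pair mean; the reference value is
  used because it is the workflow's best estimate of the truth, and the
  choice is documented rather than silent.  Pairs with a zero reference
  value are undefined, dropped, and counted in `n_dropped`.

On simulated data the percent-mode plot shows the characteristic funnel:
mean absolute relative differences are largest for low-occurrence
behaviors and shrink monotonically through medium to high — rare behaviors
can be over- or under-estimated by a factor of two while common behaviors
are barely affected.

## Validity: Tweedie GLMs and effect comparison

Occurrence values are non-negative with exact zeros, which rules out both
Gaussian and log-transformed models for rare behaviors.  The Tweedie family
with variance $V(\mu) = \mu^p$, $1 < p < 2$, and a log link treats the data
as compound Poisson–gamma: a point mass at zero plus a continuous positive
part.  Estimation is by IRLS as a quasi-likelihood (no density series is
needed); the dispersion is Pearson $\chi^2$ over residual degrees of
freedom, and Wald z-tests and CIs follow.  The variance power is not
identifiable from the small per-behavior datasets this stage sees, so it is
fixed at $p = 1.5$ by default and exposed in the configuration; the
intercept-only and saturated-factor fixed points (fitted means equal sample
means for any $p$) make the estimator's behavior easy to audit.

Exponentiated coefficients are labelled `or` because that is what applied
reports call them, but with a log link they are ratios of expected
occurrences (mean ratios), not odds ratios; the documentation says so
explicitly.  The sampling-day covariate enters as a fixed numeric
covariate; no working-correlation (GEE) structure is fitted — repeated
measures on the same pen are acknowledged as a simplification, appropriate
here because the simulator generates sessions independently.

Whether two sampling methods support the same conclusion is tested on the
log scale: $z = (\hat\beta_a - \hat\beta_b)/\sqrt{SE_a^2 + SE_b^2}$, with a
two-sided normal p-value.  Strictly, the test assumes independent
estimates; applied to two subsamplings of the same sessions it is
conservative (the estimates are positively correlated), which is the safe
direction for declaring methods interchangeable.  Calibration is verified
on genuinely independent null pairs.

## Numerical and testing choices

* **Exact small-sample tests.**  The Friedman statistic uses average ranks
  and the tie-corrected denominator; for untied data with ≤ 12 blocks and
  ≤ 5 methods the p-value is exact, computed by a dynamic program over the
  distribution of column rank sums (equivalent to enumerating all
  $(k!)^n$ within-block permutations).  Pairwise post-hocs are Bonferroni
  multiplied and capped at 1, with a compact letter display built from
  maximal cliques of the not-significantly-different graph.
* **Degenerate inputs.**  All-zero ratings → ICC undefined ("zero
  variance"); all paired differences zero → Wilcoxon p = 1 with a warning;
  a group with all-zero responses → the Tweedie fit refuses with an
  explanation instead of diverging; zero-reference Bland–Altman pairs are
  dropped and counted.
* **Determinism.**  Every simulation is reproducible from a single integer
  seed; multi-session studies spawn per-session child seeds
  deterministically, and the pipeline itself is RNG-free, so a report is a
  pure function of (timelines, configuration).
* **Problem sizes in the test suite.**  Parameter recovery is checked at
  10 sessions of 20 animals × 2 h (tolerances ±2 occupancy points for
  behaviors ≥ 5%, ±0.5 below); the interval-ordering property on 50
  replicate studies of 6 sessions × 12 animals; the rare-behavior detection
  contrast on 100 replicate two-group studies at the preset's full pen size
  (50 animals, 10 sessions/group); and the z-test calibration on 200
  independent null pairs of small studies.  These sizes were chosen as the
  smallest at which the Monte-Carlo error is clearly inside each stated
  tolerance.

## Limitations

The simulator's independence assumptions (between animals, and between
behavior and visibility) are favorable to scan sampling; synchronized
behaviors (e.g. whole-flock alarm) or visibility that correlates with
behavior (hiding!) would change the error structure and are not modeled.
The accuracy stage treats the chosen reference interval as truth for error
scoring, which understates the error of all intervals by the reference's
own error; the reference-selection stage quantifies precisely that gap
against continuous data.  Finally, the Tweedie stage deliberately stops
short of mixed-effects or GEE machinery: with few sessions per group the
extra variance parameters would be poorly identified, but users with large
designs should treat the per-pen repeated measures properly.
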