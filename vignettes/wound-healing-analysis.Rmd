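---
title: "Quantifying collective cell migration from wound-healing assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective cell migration from wound-healing assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

In wound-healing-like assays a confluent cell layer is allowed to move into
a cell-free region — created either by scratching the layer (the classical
wound-healing assay) or with a removable barrier at seeding time (the cell
exclusion zone assay, which avoids cell damage). Automated microscopy and
image segmentation then yield, for each well of a multi-well plate, the
cell-free (or cell-covered) area as a function of time. Everything upstream
of those per-well `(time, area)` tables — imaging and image processing — is
out of scope here; `cellmigrate` covers the analysis path from those tables
to condition-level statistics.

The package models the experiment itself (plate geometry, biological
conditions with cell line / treatment / dose annotation, technical
replicate wells), imports the per-well tab-separated files, and exchanges
complete experiments as a single validated XML document so a collaborator
can re-run exactly the same analysis.

## The model

For one technical replicate (one well), the trajectory is first normalized
to its value at time zero,

$$y(t) = 100 \cdot \frac{A(t)}{A(0)} \quad [\% \text{ of } t_0 \text{ area}],$$

so every replicate starts at 100% and absolute areas (which depend on
magnification, wound width, and segmentation calibration) cancel. Migration
velocity is the ordinary least-squares slope of \(y\) on \(t\), in percent
of the t0 area per time unit, with the fit quality summarized by \(R^2\).
The velocity of a biological condition is the **median** slope over its
technical replicates. Conditions are compared pairwise with the two-sided
Mann–Whitney U test applied to the replicate slope lists (a rank test needs
samples, and the replicate slopes are the samples whose medians are
reported), with Bonferroni or Benjamini–Hochberg correction over the pairs
actually tested.

The slope is reported signed: negative when an open wound closes,
positive in covered-area read-outs. Each condition records its
`assay_kind` (`open_area` or `covered_area`) so consumers can interpret
the sign; nothing is ever sign-flipped.

The Mann–Whitney p-value is exact — full enumeration of all
\(\binom{n_a+n_b}{n_a}\) group assignments — whenever the two groups
together hold at most 12 observations and contain no ties, which covers
the replicate counts (3–6) typical of plate experiments; otherwise the
normal approximation with tie-corrected variance and continuity correction
is used. The switch point keeps enumeration instant while making the small
samples that matter exact.

## Quality control

Two stages, both producing *flags* that are resolved by explicit
accept/reject decisions (a blanket policy or a per-flag decision file —
the library replaces an interactive dialog with a reproducible record;
nothing is destructive and the raw data are always retained).

**Artifact time steps.** Segmentation and imaging errors typically show up
as a step where the area moves *against* the expected trend — e.g. the
cell-free area suddenly grows while the wound is closing. A step is
flagged when (a) its per-step change runs against the expected trend for
the assay kind, and (b) the change lies in the extreme against-trend tail
of a kernel density estimate of the per-step changes: tail probability
below `alpha` (default 0.05). The KDE (Gaussian kernel, Silverman
bandwidth \(h = 0.9\min(s, \mathrm{IQR}/1.34)n^{-1/5}\); both pluggable)
is fitted on the deltas pooled across the condition's replicates, which
stabilizes it at 3–6 replicates; per-replicate fitting is available. The
whole `alpha` tail is placed in the against-trend direction: the direction
test already excludes the with-trend tail, and a one-sided cutoff keeps
sensitivity when a few artifacts contaminate the pooled density — under a
central two-sided reading, moderate spikes can hide below the
\(\alpha/2\) quantile. An accepted flag is corrected by time-weighted
linear interpolation of the offending point between its neighbours (the
terminal point is dropped instead); the pre-correction trajectory is kept
for audit.

Because the cutoff is a tail-mass criterion on the pooled density, the
detector is designed for *sparse* contamination: it can flag at most about
an `alpha` fraction of its own reference mass, so when artifact steps
exceed that fraction of a condition's deltas the lowest spikes are
necessarily absorbed into the density. The validation scenarios therefore
inject spikes at a mean rate of about 0.5 per pooled condition (1% of
steps), well under the 5% tail.

**Divergent replicates.** Technical replicates of one condition should
trace similar normalized trajectories. All pairwise Euclidean distances
between replicate trajectories are computed on their exactly shared time
points (no interpolation across grids by default — that would invent
data), each replicate's mean distance to the others is taken, and a
replicate is flagged when its mean distance exceeds
\(\mathrm{median} + k \cdot \mathrm{MAD}\) (scaled MAD, \(k = 3\)) — a
robust rule that the outlier itself cannot mask. An accepted replicate
flag excludes the well from the velocity analysis but never from the
archive.

A caveat worth knowing: at typical replicate counts the MAD is estimated
from 4–6 numbers and occasionally underestimates the spread, so a clean
replicate is sometimes flagged alongside a true divergent one (about 6–7%
of simulated runs at 6 replicates). A genuinely divergent replicate is
essentially always flagged; uniqueness of the flag is the property that
occasionally fails. This is intrinsic to robust cutoffs at small n; treat
replicate flags as suggestions to review, which is exactly what the
accept/reject mechanism is for.

## The synthetic-data generator

Validation runs entirely on simulated experiments with known ground
truth. A replicate trajectory is generated as

$$A(t) = A_0\left(1 + \frac{s}{100}t\right) + \varepsilon_t,
\qquad \varepsilon_t \sim \mathcal{N}(0, (\sigma A_0/100)^2),$$

truncated below at a small positive floor, where \(s\) is the true slope
(% per hour) and \(\sigma\) the noise SD in percent of the t0 area. The
defaults are one scientist's choice of realistic study conditions, fixed
once: baseline area \(A_0 = 10^4\) area units; hourly imaging over 0–8 h,
over which a typical wound closing at \(-10\%/h\) reaches ~20% without
touching the positivity floor; \(\sigma = 2\%\), the few-percent
segmentation jitter typical of automated wound detection. Optional
features: *artifact spikes* — at a randomly chosen, isolated step the
measured area jumps against the trend by a magnitude drawn from
\(\mathcal{N}(15, 3^2)\)% (truncated positive), emulating a momentary
segmentation failure, with positions and magnitudes recorded as ground
truth; *divergent replicates* — designated wells get slope \(s + 8\)%/h,
emulating a technically failed well. All randomness derives from one
master seed through a fixed per-replicate derivation, so adding a
condition never perturbs another condition's draws, and identical specs
yield byte-identical exported XML.

What the generator does *not* emulate: logistic slow-down as the wound
closes (a logistic trajectory would exercise \(R^2\) under model mismatch
but the estimator fits a line, so validation uses the linear regime),
spatially correlated segmentation noise, drift in imaging position, or
edge effects across the plate. Passing the simulation-based tests
therefore demonstrates correctness of the estimators and QC rules under
the stated model, not robustness to every real-world pathology.

## Worked example

```{r}
library(cellmigrate)

spec <- sim_spec(
  conditions = list(
    list(name = "ctrl",  true_slope = -10, n_replicates = 6),
    list(name = "drugA", true_slope = -6,  n_replicates = 6),
    list(name = "drugB", true_slope = -2,  n_replicates = 6)),
  noise_sd = 2, artifact_rate = 0.01, seed = 1)
loaded <- simulate_experiment(spec)

ana <- analyze_experiment(loaded, correction = "benjamini_hochberg")
ana
```

The replicate fits, condition medians and pairwise tests are available as
plain data frames, and the whole analysis renders to a deterministic
markdown report:

```{r}
tabs <- results_tables(ana)
tabs$conditions
head(tabs$comparisons)
```

```{r, eval = FALSE}
render_report(build_report(ana, config = list(seed = 1)),
              format = "markdown", path = "report.md")
```

## Numerical and design choices

- **Percent normalization.** Normalized values carry the ×100 factor
  (t0 = 100%), the convention used throughout wound-healing work; it is
  isolated in one place and slopes are therefore "% of t0 area per hour".
- **Exact XML round trips.** All numbers are serialized with 17
  significant digits, so export → import reproduces every double
  bit-for-bit and re-analysis of a shared file equals the original
  analysis.
- **Time grids.** Trajectories are compared only on time points two
  series share exactly (1e-9 relative tolerance). Files with out-of-order
  rows are sorted; duplicate time points are rejected rather than
  averaged.
- **Degenerate fits.** A perfectly flat trajectory has zero response
  variance; its \(R^2\) is defined as 1 when the residuals are zero (the
  line explains everything there is to explain) and 0 otherwise.
- **Tie handling.** Midranks in the U statistic, tie-corrected variance in
  the normal approximation; `auto` mode never uses enumeration on tied
  data.
- **Decision semantics.** `accept` on a step flag applies the
  interpolation correction; `accept` on a replicate flag excludes the
  replicate from velocity analysis. `reject` keeps the data as measured.
  Under policy `ask`, analysis refuses to proceed while any flag lacks a
  decision-file entry.
- **Problem sizes in validation.** The simulation-based checks use 500
  replicate trajectories for artifact recovery, 200 runs for replicate
  screening and 500 runs for velocity recovery — enough for stable rate
  estimates while keeping the whole suite fast.

## Limitations

- The linear velocity model is deliberate (it is what the downstream
  statistics consume) but wrong late in wound closure; restrict the time
  window to the linear regime or expect depressed \(R^2\).
- Replicate screening needs at least two replicates and at least three
  exactly-shared time points per pair; experiments on disjoint grids
  require the (off by default) interpolation alignment.
- `mode = "auto"` switches the Mann–Whitney test to the normal
  approximation beyond 12 total observations or in the presence of ties;
  `mode = "exact"` always enumerates and is exponential in the sample
  sizes, so reserve it for small groups.
- PDF report rendering shells out to `pandoc` and fails with a clear
  capability error when no converter is installed; markdown is the
  canonical format.
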