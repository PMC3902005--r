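---
title: "Models and methods behind meafdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meafdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meafdr)
```

`meafdr` turns longitudinal MEA stimulation recordings into
connectivity trajectories: which electrode pairs respond to stimulation,
how far those functional connections reach, and how hubs emerge as a
dissociated culture matures. This vignette documents the statistical
models, the estimators and their defaults, the synthetic data model used
for validation, and the design decisions that were genuinely open.

## The response matrix

A stimulation session delivers 50 pulses to each of the 59 analysis
electrodes of a standard 8×8-minus-corners MEA grid, one pulse every
300 ms. For stimulated electrode $k$, recording electrode $j$ and trial
$t$, the pipeline counts spikes at $j$ in the interval
$(\text{pulse} + b,\ \text{pulse} + w]$, where $w$ is the counting window
and $b$ an optional artifact blank (default 0). Three windows matter
scientifically: 50 ms isolates direct responses (0–20 ms latencies),
100 ms adds early post-synaptic spikes, and 150 ms reaches into
culture-wide barrages (latencies beyond 100 ms). Windows longer than the
300 ms inter-pulse interval are allowed but warned about, since they
overlap the next pulse's responses.

Counts are averaged over trials and normalized by spontaneous activity
recorded the same day from the same culture:
$$Z_{kj} = \overline{\text{count}}_{kj} - \hat{\mu}_j,$$
where $\hat{\mu}_j$ is electrode $j$'s mean spike count in windows of the
same effective length $(w - b)$ tiled contiguously over the spontaneous
session (a deterministic, lowest-variance placement; random placement is
available). The baseline is per-electrode rather than a single scalar —
the natural reading of per-channel normalization, and the one that makes
$E[Z] = 0$ hold channel-wise for stationary activity. Negative $Z$ values
are legal and meaningful (suppression below the spontaneous rate).

**Burst exclusion.** Cultured networks emit spontaneous network-wide
bursts. A burst landing inside one trial's window inflates counts at
*every* electrode for that trial, producing a row of spuriously elevated
$Z$ values that the mixture model (which assumes exchangeable entries)
misreads as a broadly connected stimulation site. The pipeline therefore
flags any trial whose network-wide spike total exceeds
$5 \times \text{median} + 10$ (median over the session's trials) and
excludes it from the trial average; spontaneous baseline windows are
filtered by the identical rule so the normalization stays unbiased. The
threshold separates bursts (tens of times the background total per
window) from genuine evoked responses (a few times background) by a wide
margin at the defaults. In simulation this step is what makes the
quiescent phase read as quiescent: without it a handful of burst rows per
session pass selection and contaminate early-day metrics. Both the
multiplier and the offset are configurable, and the step can be disabled.

**Diagonal policy.** The stimulated electrode's own channel is dominated
by the stimulus artifact in real recordings. By default $Z_{kk}$ is set
to 0 and excluded from testing (the number of tests drops from $59^2$ to
$59 \times 58$); a compatibility switch keeps the full matrix.

## The two-group model and local FDR

Each $Z_{kj}$ is modeled as a draw from the mixture
$$f(z) = (1-\varepsilon) f_0(z) + \varepsilon f_1(z), \qquad
  f_0 = N(0, \sigma^2),$$
with non-null proportion $\varepsilon$ expected to be small (few genuine
connections among all ordered pairs). The local FDR statistic
$$T_{kj} = \frac{(1-\varepsilon) f_0(Z_{kj})}{f(Z_{kj})}$$
is the posterior probability of the null given the observed value;
$f_1$ is never estimated directly — only the marginal $f$ is needed.
Numerically the ratio can exceed 1 and is clipped to $[0, 1]$.

Selection ranks the $T$ values ascending ($T_{(1)} \le \dots \le
T_{(p)}$, ties broken by matrix position for determinism) and reports the
largest prefix whose mean stays at or below the target level
$\alpha$ (default 0.05):
$$k^\ast = \max\Big\{k : \tfrac{1}{k}\textstyle\sum_{i \le k} T_{(i)}
  \le \alpha\Big\}.$$
Since the mean of the selected posteriors estimates the expected false
discovery proportion of the selected set, this controls the FDR at
$\alpha$. With $k^\ast = 0$ nothing is reported; in validation the
empirical false discovery proportion uses the $V/\max(R,1)$ convention.

### Estimators

The three unknowns are estimated from the data before computing $T$; each
choice is a documented default and swappable.

* **Null scale $\sigma$** (`estimate_null_sigma`): a truncated-Gaussian
  maximum-likelihood fit to the central region $|z| \le 2\hat\sigma$,
  iterated to a fixed point from a low-quantile initial value
  ($q_{0.25}(|z|)/\Phi^{-1}(0.625)$). The familiar median-absolute-
  deviation-about-0 estimate (available as `method = "central-mad"`) is
  systematically inflated by several percent as soon as a few percent of
  entries are genuinely non-null, because all non-null mass sits above
  the median of $|z|$; the central MLE ignores the tails and removes that
  bias (to ~0.3% at $\varepsilon = 0.05$ with well-separated
  alternatives), which in turn keeps the Storey estimate of
  $\varepsilon$ from collapsing. The iteration also survives large
  non-null fractions (at $\varepsilon = 0.5$ with strong separation it
  still recovers $\sigma$ to a few percent, where any single-pass
  quantile estimator fails outright).
* **Non-null proportion $\varepsilon$** (`estimate_epsilon`): Storey's
  estimator with $\lambda = 0.5$ on two-sided p-values from
  $N(0, \hat\sigma^2)$: $\hat\varepsilon = 1 - \#\{p > \lambda\} /
  ((1-\lambda)\, p_{\text{total}})$, clipped to $[0, 1 - 10^{-6}]$.
* **Marginal density $f$** (`estimate_marginal_density`): Gaussian kernel
  density estimate with Silverman's rule-of-thumb bandwidth, evaluated by
  linear interpolation on a 2048-point grid and floored at the smallest
  positive double. When $T$ is computed at the same points the density
  was fitted on (the usual case), the evaluation is leave-one-out: each
  point's own kernel mass $K(0)/(nh)$ is removed. A point's own kernel
  otherwise inflates $\hat f$ exactly at the isolated tail values being
  tested, biasing $T$ low and making the procedure measurably
  anti-conservative. The correction is capped at half the raw estimate so
  that an extreme isolated outlier — where the kernel estimate carries no
  neighborhood information at all — keeps a positive density and a
  near-zero $T$ instead of underflowing.

With these defaults, on 59×59 matrices from the mixture with
$\varepsilon = 0.05$ and $f_1 = N(4,1)$, the empirical FDR averages at
the nominal 5% (the test suite verifies this over 200 replicates, along
with parameter recovery: $\hat\sigma$ within 5%, $\hat\varepsilon$ within
±0.02).

## Connectivity metrics

Significant pairs define a directed graph (stimulated → recording) over
the electrode grid. Edge length is the straight-line distance between
electrode centers — the only geometry available; a significant pair may
of course ride on multi-synaptic paths. The two tracked metrics are the
arithmetic mean edge length (undefined, reported as missing, for empty
graphs) and the supernode counts: electrodes with in-degree ≥ 4
(incoming supernodes) and out-degree ≥ 4 (outgoing supernodes), counted
per direction because the two are biologically distinct (convergence hubs
vs. divergence hubs) and are tracked separately; a total-degree variant
is available. The threshold of four connections is the study convention
for calling an electrode a hub.

## Longitudinal statistics

Per-batch daily summaries average each metric over the cultures recorded
that day, with standard error $sd/\sqrt{n}$ ($n = 1$ days report SE 0 and
are flagged; configurable to missing). Days without recordings appear as
explicit gap rows and never enter any statistic.

The within/across-batch question — do cultures from the same tissue
evolve more similarly than cultures from different tissues? — is asked
with two one-way fixed-effects ANOVA designs, both labeled in the output
because the observational units are a genuine modeling choice:

* **across**: one observation per culture (its time-averaged metric),
  batch as factor — significance means batches differ;
* **within**: per batch, the per-day values with culture as factor —
  non-significance means cultures inside a batch track each other.

Counting-window effects use, per batch, a one-way ANOVA of the per-day
batch-averaged metric with window (50/100/150 ms) as factor, followed by
Tukey–Kramer pairwise comparisons at 95%; a window is flagged different
when its interval excludes zero, matching the usual CI-overlap reading of
multiple-comparison displays. Degenerate inputs follow fixed conventions:
zero total variation reports $F = 0$, $p = 1$; groups with fewer than two
observations, or fewer than two groups, are errors.

## The synthetic data model

The generator produces data with the statistical structure the analysis
assumes — it is a test harness with ground truth, not a biophysical
simulation.

* **Latent network.** A directed graph over the 59 electrodes grows over
  40 simulated days: no edges during a quiescent phase (default 5 days),
  linear-in-expectation accumulation across a growth phase (default 12
  days, within the 10–15-day range typical of rapid network maturation)
  up to a plateau density (default 7% of ordered pairs, ≈240 edges), then
  constant. New edges are drawn with probability
  $\propto \exp(-d/\lambda(\text{day}))$ in electrode distance $d$, with
  $\lambda$ widening from 250 to 800 µm across the growth phase — so mean
  connection length rises as the network matures, the signature the
  pipeline is supposed to recover. A fraction of electrodes (15%) gets a
  4× attachment bias so degree-4 hubs reliably emerge by plateau. Each
  edge carries a response probability (uniform on 0.4–0.9) and a latency
  class — direct (0–20 ms), early post-synaptic, or barrage (>100 ms) —
  with mixture weights 0.5/0.35/0.15. The early band defaults to
  5–100 ms and is exposed as a parameter, since its upper edge is a
  windowing convention rather than a biological constant.
* **Spontaneous activity.** Per-electrode Poisson firing at 1 Hz
  baseline, plus network-wide burst epochs (onset rate 0.05 Hz, duration
  0.3 s, 20× rate multiplier) shared by all electrodes — the bursting
  phenomenology that makes baseline normalization and burst exclusion
  necessary. Values are typical of mature dissociated cortical cultures.
* **Stimulation sessions.** The full protocol (59 electrodes × 50
  pulses, 300 ms spacing, electrodes stimulated in sequence); each pulse
  triggers, per outgoing edge, a Bernoulli evoked spike at a latency
  drawn from the edge's class band, superimposed on spontaneous
  background. Evoked spikes never precede their pulse.
* **Study structure.** Plating classes reproduce the design arithmetic —
  dense: 20 µL × 2500 cells/µL = 50,000 nominal cells; small: 5 µL ×
  2500 = 12,500; sparse: 20 µL × 625 = 12,500 — and scale the plateau
  density by the square root of relative cell count (connectivity grows
  sub-linearly with plated cells; a modeling choice, not a measured law).
  Batches share log-normal multipliers on plateau density and on the
  distance-kernel scale (SD 0.25 by default), cultures add small jitter
  (SD 0.05), **and cultures within a batch share the latent network
  template** (the realization seed of the trajectory). Sharing only
  parameters proved insufficient to emulate the within-batch similarity
  the analysis is meant to detect: two cultures with identical parameters
  still differ persistently by ~20–30 µm in plateau mean length (the
  sampling noise of a ~240-edge draw), and a one-way ANOVA over dozens of
  recorded days detects such a difference essentially always. Treating
  same-tissue cultures as noisy expressions of one latent network — in
  line with the interpretation that dissociated neurons retain
  tissue-level structure — reproduces the qualitative pattern: across
  batches significant, within batches not.
* **Determinism.** Every generator is a pure function of its parameters
  and a seed. Study generation derives one seed per session from the
  master seed via a documented integer-hash scheme (`derive_seed`), so
  any single session can be regenerated in isolation. All hash
  arithmetic stays below $2^{53}$ and all seeds below $2^{31}$.

What the generator does **not** model: biophysical membrane dynamics,
synaptic plasticity, electrode artifacts, spike sorting errors,
inhibition, or the late-phase decline in responsiveness seen in very old
cultures. Passing tests therefore demonstrate that the statistical
machinery recovers the structure it assumes — not that real cultures
satisfy those assumptions.

## Validation scales

The test suite validates at deliberately chosen problem sizes: FDR
control and parameter recovery on 59×59 matrices over 100–200 replicates;
ranked-selection equivalence against an exhaustive prefix scan on 1,000
random vectors up to length 10,000; trajectory recovery on full 40-day
single-culture studies (three replicate studies, Spearman ρ between
recovered and latent mean connection length over the growth phase,
averaged, must exceed 0.7); and the batch-ANOVA pattern on 100 replicate
six-culture studies with strong batch offsets (SD 0.5) and no
within-batch parameter jitter, recorded on five days spanning growth and
plateau — a designed simulation in which the correct qualitative outcome
is known.

## Known limitations

* FDR control is validated under independent mixture draws; strong
  residual correlation between pairs (e.g. unexcluded bursts, shared
  slow drifts) can inflate the realized false discovery proportion.
* The empirical-null estimators assume the null component dominates the
  center of the $Z$ distribution; they degrade when genuine connections
  are both very numerous and weakly separated.
* Connection length is electrode-to-electrode geometry; it says nothing
  about axonal path length or mono- vs. poly-synaptic routing.
* The ANOVA designs treat days as exchangeable replicates; serial
  correlation across days is not modeled (a repeated-measures extension
  would be the natural next step).
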