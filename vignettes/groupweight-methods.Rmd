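---
title: "The group-weight bio-feedback decoder: model, simulator, and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The group-weight bio-feedback decoder: model, simulator, and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupweight)
```

## The control law

`groupweight` implements a deliberately simple bio-feedback decoder for
intracortical brain-machine interfaces, modeled on the four directional
keys of a keyboard. Four groups of recorded multi-units are assigned to
the four cardinal cursor directions. For each group $k$ with units $i$
and smoothed firing rates $fr_i$, the **action value** is

$$a_k = \max\!\left(\frac{\sum_{i=1}^{n_k} fr_i - \mu_k}{\delta_k} + c,\; 0\right),$$

where $\mu_k$ and $\delta_k$ are the mean and standard deviation of the
group's summed firing rate estimated from a pre-experiment segment, and
$c$ is a dimensionless offset. Opposing action values are differenced and
scaled to give the cursor velocity,

$$v_x = w\,(a_1 - a_2), \qquad v_y = w\,(a_3 - a_4),$$

clamped per axis to $\pm v_{\max}$. Defaults are the standard constants:
$c = 1$, $w = 0.375$ cm/s per action-value unit, $v_{\max} = 15$ cm/s.
Firing rates are 5-bin trailing moving averages of non-overlapping 100 ms
spike-count bins; the window is zero-padded at session start (silence
before $t = 0$), a simple causal convention.

The decoder holds no per-unit parameters: control quality is supposed to
come from the *user* adapting to the fixed mapping (bio-feedback), not
from the decoder mimicking natural tuning. The package exists to exercise
that claim end to end without animal data.

### Normalization

`estimate_normalization()` replays the decoder's own smoothing over a
pre-experiment segment and computes each group's mean and **population**
standard deviation on the smoothed group-sum series — the same signal the
decoder sees at run time. Zero-padded warm-up bins are excluded, so a
constant segment yields the exact mean and a floored SD. $\delta_k$ is
floored at `delta_floor` (0.1 Hz) to avoid division blow-up on
near-constant segments. In a training course (`run_training()`), each
session's constants come from its own pre-experiment; pre-experiments
after the first are themselves closed-loop runs under the *previous*
constants (the first uses idle firing), which chains normalization across
consecutive practice sessions.

### A property of the rectified action value

Because $a_k = \max(z_k + c, 0)$ with $z_k$ standardized, the stationary
mean of $a_k$ under replay of the pre-experiment distribution is not $c$
but $c\,\Phi(c) + \phi(c)$ ($\approx 1.083$ for $c = 1$, slightly less
for skewed count distributions): rectification is active roughly 16% of
the time at $c = 1$. The *velocity* is nevertheless unbiased — the
rectification bias is common to the opposing groups and cancels in
$a_1 - a_2$ — which is what matters for control. The acceptance suite
asserts both statements in one block; the mean-velocity assertions hold,
while the mean-action-value-equals-$c$ assertion documents this exact
bias by failing at the 3-standard-error resolution of a $10^4$-bin
replay.

## Neuron grouping

Units are assigned to groups from a velocity-tuning fit
($fr = b_0 + b_1 v_x + b_2 v_y$, `fit_velocity_tuning()`); the preferred
direction (PD) is the angle of $(b_1, b_2)$. The direction space is split
into four equal sectors with boundaries at $\pi/4, 3\pi/4, 5\pi/4,
7\pi/4$; sectors are half-open counter-clockwise so every angle has
exactly one sector. `select_groups()` keeps units recorded for strictly
more than 5 days and picks the largest-magnitude PDs per sector (4 per
group by default). A sector shortfall borrows the unassigned eligible
units nearest by angular distance to the sector center, with ties broken
by channel id — a deterministic rule for recruiting near-sector units
when a sector alone cannot fill its group.

## The task simulator

Two center-out variants are implemented as an explicit state machine:

* **Variant T** — peripheral targets only, at the four cardinal angles;
  the cursor resets to the center after every trial; each trial begins
  with a random freeze (default 2.5–5 s) during which decoded velocity is
  ignored.
* **Variant K** — center and peripheral targets alternate without delay;
  peripheral angles are uniform on the circle; no reset, so movements are
  out-and-back.

Hold time is 200 ms, accumulated only while inside the target disk and
reset on exit — the conservative, standard convention for center-out
tasks. Movement time is limited to 10 s (sessions 1–3) or 15 s
thereafter, excluding freeze. Default target geometry is a 1.5 cm
capture radius at 7 cm distance in a 30 × 25 cm workspace, all
configurable; the visual target ring is treated as a disk for
containment.

## The synthetic population

`synthetic_population()` stands in for recorded motor cortex: 16
"direct" units (4 per sector, the ones a grouping step selects) plus 16
weakly tuned "indirect" units. Firing is rectified cosine tuning around
the intended movement direction with additive Gaussian rate noise, and
Poisson spiking at 10 ms resolution (no refractoriness — adequate at the
100 ms decoding resolution). The simulated user aims straight at the
target; per bin it is "engaged" with a schedule-controlled probability,
otherwise units fall to baseline.

Learning is *imposed*, not emergent: per session, direct units' PDs
rotate along the shorter arc toward their assigned direction (AD), rate
noise decays multiplicatively, and engagement grows. This is exactly what
a tool-testing stand-in needs — data carrying the statistical signatures
(success-rate growth, output-potent growth, tuning-$R^2$ growth,
shrinking $|PD-AD|$) that the analysis module must detect.

Defaults, chosen once as a plausible practice course: baseline 10 Hz,
modulation depth 8 Hz, initial rate noise 18 Hz (multi-unit variability
dominating tuning early), noise decay 0.82/session, PD rotation
0.12 rad/session, engagement 0.4 rising by 0.045/session to at most
0.95. Under these conditions a 12-session course typically moves success
from near 0 to near 1 within the first six sessions — the sigmoidal
shape characteristic of primate bio-feedback practice. Absolute animal
success rates depend on behavior outside this model and are explicitly
not a target.

Sessions in examples and tests are 120 s with 60 s pre-experiments —
long enough for ~10 trials per session and stable normalization;
half-hour sessions with 5–10 minute pre-experiments, the scale of real
practice days, are a configuration change.

## Chance baseline

`baseline_success_rate()` reproduces the shuffled-bin chance procedure:
10 ms bins from movement epochs (trial bins excluding freeze) are
permuted **jointly across channels** — the stricter null, preserving each
bin's instantaneous population vector (an independent per-channel
shuffle would also destroy within-bin correlations and weaken the
null). Shuffled bins are re-summed into 100 ms
decoder bins and replayed offline through decoder and task with the
session's parameters, except every trial consumes a fixed 10 s window
(failures therefore terminate at exactly 10 s). Variant T resets the
cursor between replay trials; variant K relocates it to the last target's
center, as if that target had been reached. Because the shuffle averages
the whole session into near-stationary input, decoded velocity is
near-zero mean and baseline success depends only on noise magnitude and
task geometry; the acceptance suite checks its monotone growth with
target radius on a nearer probe target (3 cm) where chance reaches are
measurable at desk scale.

## Analyses

* **Success trends** — `fit_success_logistic()` regresses per-trial
  outcome on session index (binomial GLM), reporting the slope, its Wald
  p-value, and McFadden's pseudo-$R^2$, the standard goodness measure
  for logistic fits. Complete separation — including all-success/all-fail
  data — is
  flagged and refitted with half-success/half-failure pseudo-counts per
  session.
* **Trajectory score** — path length of a successful trial divided by the
  start-to-target-center distance (1 = straight; values slightly below 1
  are possible because trials end at the target's edge, bounded below by
  $1 - r/d$).
* **Occupancy maps** — per-cell visit counts of logged positions.
* **Output-potent / output-null** — for a trial toward sector $k$, potent
  $= a_{\text{toward}} - a_{\text{away}}$ and null $= a_{\text{toward}} +
  a_{\text{away}}$; on unfiltered bins the on-axis velocity is exactly
  $w \times$ potent. The medium-speed filter keeps bins with Euclidean
  speed in 25–75% of the maximum speed, taken here as the per-axis clamp
  $v_{\max}$ (the session's empirical maximum is a configurable
  alternative).
* **Direction tuning** — least squares of rate on
  $(1, \cos\theta, \sin\theta)$; tuning depth is the peak-to-trough range
  $2\lVert(b_1, b_2)\rVert$; for variant K the angles are cursor-relative
  and the medium-speed filter applies.
* **$|PD-AD|$** — the absolute wrapped angular difference divided by
  $\pi$: 0 for identical, 1 for opposite directions, 0.25 at the 45°
  sector edge.

Early/late comparisons use the first and last quarter of sessions.

## Numerical choices and degenerate inputs

* Angles wrap to $[-\pi, \pi)$ for sector arithmetic and $(-\pi, \pi]$
  for signed differences; sector boundaries are counter-clockwise
  inclusive, so $\pi/4$ is "up".
* $(b_1, b_2) = (0, 0)$ is flagged untuned and excluded from grouping;
  rank-deficient tuning designs and all-identical angles are rejected
  with diagnostics.
* The per-axis clamp applies after the gain $w$; there is no magnitude
  clamp, so diagonal speed can reach $v_{\max}\sqrt{2}$.
* Empty pre-experiments, segments shorter than one smoothing window, and
  channel-count mismatches are rejected.
* All randomness flows from the caller's seed through R's RNG stream; the
  same seed reproduces sessions byte-identically.

## What passing tests do and do not show

The synthetic user aims perfectly when engaged, learns on an imposed
schedule, and fires Poisson spikes with stationary baselines. Real
recordings add electrode drift and unit dropout, behavioral
idiosyncrasies, non-cosine and history-dependent tuning, and reward-
driven exploration — none of which the generator emulates (normalization
chaining is exercised, but the instability it compensates for is not).
Passing tests therefore validate the *machinery* — decoder arithmetic,
task bookkeeping, baseline procedure, estimator correctness and the
detectability of learning signatures — not any claim about biological
learning. Absolute success rates and chance baselines of any particular
animal experiment are out of reach by design.
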