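---
title: "Condition-specific effective connectivity by blind deconvolution and time-varying Granger causality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific effective connectivity by blind deconvolution and time-varying Granger causality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effconn)
```

## The problem

Functional MRI measures a hemodynamic surrogate of neural activity: the
BOLD signal is the neural input convolved — in fact, passed through a
nonlinear biophysical cascade — with a hemodynamic response that varies
across brain regions and subjects. Any method that infers *directed*
interactions from temporal precedence (Granger causality) is therefore
confounded twice: the hemodynamic response smooths away sub-second lead/lag
structure, and regional differences in hemodynamic delay can masquerade as
neural precedence. `effconn` implements the remedy this analysis tradition
uses: deconvolve each region's BOLD series to a latent neural signal under
an explicit hemodynamic model *before* fitting a lag-based model, then let
the autoregressive coefficients vary over time so that connectivity can be
attributed to task conditions.

The target design is an advice-taking experiment: participants accept or
reject luggage-screening advice from an agent presented as a human or a
machine, with advice reliability fixed at 60% (50% hits, 10% correct
rejections, 40% false alarms), 32 trials per run, two runs of 330 volumes
at TR = 2 s. Each trial steps through fixation (0.5 s), advice (2 s), bag
image (4 s), decision (4 s), a jittered fixation, feedback (2 s), and a
second jittered fixation; jitters lie in [1, 7] s with mean 4 s.

## The observation model

Neural input $u(t)$ drives a vasodilatory signal $s$, which drives blood
flow $f$; flow inflates venous volume $v$ and washes out deoxyhemoglobin
$q$:

$$\dot s = \varepsilon u - s/\tau_s - (f-1)/\tau_f, \qquad \dot f = s,$$
$$\tau_0 \dot v = f - v^{1/\alpha}, \qquad
  \tau_0 \dot q = f\,\frac{1-(1-E_0)^{1/f}}{E_0} - v^{1/\alpha}\,q/v,$$
$$y = 100\,V_0\big(k_1(1-q) + k_2(1-q/v) + k_3(1-v)\big),
  \quad k_1 = 7E_0,\; k_2 = 2,\; k_3 = 2E_0 - 0.2,$$

with $y$ in percent signal change. Defaults (`hemodynamic_params()`) are
the standard literature values $\varepsilon = 0.54$, $\tau_s = 1.54$ s,
$\tau_f = 2.46$ s, $\tau_0 = 0.98$ s, $\alpha = 0.33$, $E_0 = 0.34$,
$V_0 = 0.02$. `hemodynamic_forward()` integrates these equations by
forward Euler on the *logarithms* of $f, v, q$ — algebraically the same
ODEs, but the discretization preserves positivity exactly — with
saturation bounds ($|\log f|, |\log v|, |\log q| \le 2.5$, $|s| \le 8$)
expressing that vasculature can neither collapse to zero flow nor dilate
without limit; the bounds also keep the explicit scheme stable for strong
sustained inputs. The integration step is 0.1 s.

A separate dual-gamma kernel (`canonical_hrf()`, gamma shapes 6 and 16,
undershoot ratio 1/6, unit peak near 5 s) is provided for linear
convolution analyses, and `wiener_deconvolve()` gives the matching linear
frequency-domain inverse, used in the tests as an independent baseline for
the nonlinear filter.

## Blind deconvolution

`ckf_deconvolve()` treats each ROI independently as a nonlinear
state-space model with a 10-dimensional augmented state: the four
hemodynamic states ($s$ and the logs of $f, v, q$), the neural input $u$
as a random walk, and the logs of $\varepsilon, \tau_s, \tau_f, \tau_0,
\alpha$ as slow random walks (log transforms keep every parameter
positive). A square-root cubature Kalman filter — $2n$ deterministic
cubature points for the $n$-dimensional state, QR-based triangular
covariance factors so positive-definiteness holds by construction — runs
over the Euler-discretized model (20 substeps per TR), followed by a
square-root Rauch–Tung–Striebel smoothing pass. Smoothing matters: the
filtered input estimate lags the truth by the hemodynamic delay
(two TR at TR = 2 s), and the backward pass moves that information back
to the correct time.

Noise defaults (`ckf_config()`, all on the scale of z-scored data):
measurement variance $10^{-2}$, input random-walk variance $0.3$ per TR,
hemodynamic-state variance $10^{-4}$, parameter-walk variance $10^{-5}$.
The input walk variance is the smoothness dial: smaller values smooth the
latent estimate and blur lag structure, larger values track abrupt input
changes at the cost of noise. With these defaults a boxcar input passed
through the forward model with 10% observation noise is recovered at
$r \approx 0.83$, and pairs of regions driven by one input but observed
through different hemodynamics are reliably more similar after
deconvolution than before — the property the step exists for. Cubature
points are clamped to the same physiological box as the forward model
during propagation; without the clamp, outlying points overflow the stiff
balloon dynamics. The observation equation is scaled by the reciprocal
SD of the model's response to a reference boxcar, putting the balloon
output on the unit-variance scale of the z-scored data.

Per-ROI diagnostics report innovation mean/variance, lag-1 innovation
autocorrelation (a whiteness check), and the unscaled input SD.

## The time-varying VAR and condition aggregation

`dmvar()` fits $x_t = A_t x_{t-1} + \varepsilon_t$ by recursive least
squares with forgetting factor $\lambda$ (default 0.98, an effective
memory of $1/(1-\lambda) = 50$ samples, i.e. 100 s at TR = 2 s): the
coefficient matrix is re-estimated at every step with geometrically
down-weighted history. The covariance recursion is explicitly
symmetrized each step — without this, accumulated asymmetry destabilizes
the recursion — and a trace cap provides regularization against
covariance blow-up, recorded in the fit's diagnostics. With $\lambda = 1$
the recursion is exact recursive OLS: the final coefficient equals the
OLS VAR(1) solution to numerical precision, and the time-averaged
coefficients approach it with $O(T^{-1/2})$ trajectory noise (about
0.026 per entry at $T = 2000$) from the early prefix estimates.

`aggregate_condition_weights()` pools, per directed edge, the coefficient
values at all time instants carrying a given condition label, across
subjects. The coefficient indexed $t$ maps time $t$ to $t+1$; labels are
applied at the lagged (source) time, shifting condition windows by one
sample to respect lag-1 modelling. Self-edges are estimated but excluded
from comparison and driver logic.

## Group comparison, FDR, drivers

`compare_path_weights()` performs per-edge two-sample t-tests (pooled
variance) with Benjamini–Hochberg adjustment over the full family of
$n(n-1)$ directed edges — all 30 edges for 6 ROIs, not only those
eventually reported. Two modes are provided:

* `method = "pooled"` tests the pooled time-point samples directly. This
  treats serially dependent coefficient trajectories as independent
  observations, so its t statistics are inflated; it reproduces the
  style of analysis in which aggregated coefficient samples are compared
  wholesale, and it is the default for that reason, but it is **not**
  calibrated: under a null group difference it flags a large fraction of
  edges.
* `method = "subject"` first averages coefficients within subject and
  tests across subjects ($n = 12$ per group here). Subject means are
  independent, so this variant holds the nominal error rate; all
  calibration claims in the test suite use it, and simulation studies in
  the package default to it.

`summarize_network()` labels a node a *driver* when its significant
out-edges reach every other node, and flags reciprocal pairs. In the
end-to-end recovery study the driver summary is taken at $q < 0.08$
rather than the per-edge reporting threshold 0.05: driver status is a
conjunction of five simultaneous edge tests, and the weakest genuine
hub edge otherwise fails the conjunction in a sizeable minority of
replicates even when every individual edge is clearly positive; the
slightly more permissive topology threshold matches how driver networks
of this kind are read in practice. Null-difference calibration is always
checked at $q < 0.05$.

`granger_causality()` supplies the classical static oracle — nested
full/reduced least squares with an F test per directed pair — used to
validate direction detection independently of the time-varying machinery.
`correlate_behavior_connectivity()` computes per-edge Spearman rank
correlations between a per-subject behavioural measure and per-subject
mean path weights.

## What the synthetic study emulates

`simulate_advice_study()` generates the full two-group design: 12
subjects per agent group, each with a per-participant randomized schedule
of 64 trials over 2 runs (composition realized by largest-remainder
rounding: 32 hits, 6 correct rejections, 26 false alarms; jitters drawn
from a truncated exponential-like law with iterative mean correction).
Behaviour (`simulate_agent_responses()`) follows a single-parameter
disconfirmation model: the acceptance probability starts near 1 and is
multiplied by $1 - s$ after every error feedback, with the human-agent
group more sensitive ($s = 0.08$) than the machine-agent group
($s = 0.03$) — the simplest mechanism that reproduces a
time-by-agent interaction in bad-advice utilization. Response times are
drawn from a configured lognormal, not mechanistically modelled.

The neural ground truth (`advice_study_networks()`) is a two-driver
topology: ROIs 1–2 (labelled PI and left anterior precuneus) send
directed edges to all other nodes and to each other; hub out-edge weight
is 0.5 for the human group and 0.3 for the machine group, with self-decay
0.3 everywhere. The group difference is a run-long property — the agent
context persists for the whole run — with a mild condition modulation on
top (inter-trial rest uses 0.9 of the task weight). This matters: a
coefficient difference confined to 4-s decision windows is invisible to
an RLS tracker whose memory is ~100 s, which is a genuine property of
the method, not of the implementation. Latent dynamics are simulated as
a VAR(1) *on the TR grid*, so the generating coefficients live on the
same lag the fitted model estimates; the latent series is zero-order-held
to the 0.1 s grid only for the hemodynamic integration. A scale factor of
0.2 maps latent activity (innovation-SD units) into the balloon model's
input range. Balloon parameters are drawn per subject and region
(lognormal jitter, CV 0.2) and observation noise is 10% of each series'
SD — both subject-level properties, as in real data, so they average out
of group contrasts rather than confounding them.

Features of real data deliberately *not* emulated: physiological noise
spectra (cardiac/respiratory), scanner drift, motion residuals, spatial
correlation between ROI signals, and any nonstationarity of the
hemodynamics within a run. Passing recovery tests therefore shows the
pipeline is correct and adequately powered under its own model class, not
that real acquisitions meet these assumptions.

## ROI extraction

`extract_roi_timeseries()` averages voxel series whose centres fall in an
axis-aligned cube of side 6 mm around each peak coordinate (half-open on
the upper face, so boundary voxels belong to exactly one side); a
6-mm-radius sphere is available via `shape = "sphere"`. The cube reading
matches a three-axis "6 mm × 6 mm × 6 mm" neighbourhood on a 3-mm grid
(2×2×2 voxels). Voxel membership is decided in world (MNI mm) space
through the image affine. `normalize_per_run()` z-scores each ROI column
within subject and run; whether normalization should instead pool across
participants is left as an option the user applies upstream, the
within-subject default being the variant that makes the downstream
z-scored modelling well defined per subject.

## Numerical choices and problem sizes

* Forward integration: Euler at 0.1 s in log state space with saturation
  bounds; filter discretization: 20 substeps per TR.
* Square-root forms throughout the filter/smoother; QR triangularization
  with sign-fixed diagonals.
* RLS: initial covariance 100·I, symmetrization each step, trace cap 10⁶.
* Degenerate inputs error early and informatively: unstable generating
  networks (spectral radius ≥ 1), zero-variance ROI columns, empty ROI
  neighbourhoods, rank-deficient Granger designs, infeasible jitter
  constraints, out-of-range probabilities and p-values.
* Test-suite problem sizes were chosen to keep the full suite in a few
  minutes on one core: 20-seed deconvolution round trips at 330 volumes;
  OLS equivalence at T = 2000 with 6 channels; 5 full end-to-end study
  replicates plus 20 latent-domain null replicates; 2000-replicate nulls
  for each behavioural statistic.

## Known limitations

* The pooled comparison mode is anticonservative by construction; use
  `method = "subject"` whenever calibrated inference is the goal.
* The deconvolved latent estimate is a smoothed version of the input, so
  fitted path weights are attenuated relative to generating values;
  group *contrasts* survive (and are what the pipeline tests), absolute
  coefficient recovery at the TR lag does not.
* A first-order model at TR = 2 s can only order influences whose
  effective lag structure survives hemodynamic sampling; faster
  interactions alias into contemporaneous covariance, which the model
  absorbs into the innovation covariance rather than the path weights.
* Per-ROI independent deconvolution ignores shared physiological input;
  a common driver surviving deconvolution can still induce spurious
  edges in both groups (they cancel in group contrasts but not in
  single-group network estimates).
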