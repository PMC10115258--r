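---
title: "Dissociating hippocampal 4-Hz and theta rhythms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating hippocampal 4-Hz and theta rhythms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When a rat runs on a wheel (stationary locomotion), its dorsal CA1 local
field potential can carry two concurrent rhythms: the classical theta
oscillation (6--10 Hz) and a slower 4-Hz oscillation (3--5 Hz) that is
absent during translational running on a maze.  The two rhythms behave
differently: the 4-Hz amplitude grows with running speed, theta amplitude
does not; and pharmacological inactivation of the medial septum -- the
pacemaker input that drives theta -- abolishes theta while leaving the
4-Hz rhythm (and its speed coupling, and the 4-Hz entrainment of local
spiking) largely intact.  That double dissociation argues that the two
rhythms are generated by independent mechanisms.

This package implements the complete analysis chain used to establish
such a dissociation -- preprocessing, band decomposition, spectral and
autocorrelogram statistics, spike-train rhythmicity screening, and the
correlation/contrast conventions -- together with a synthetic-session
generator whose ground truth makes every stage testable end to end.

## The synthetic session model

A session is a sequence of alternating wheel and maze trials (15 s each
by default; wheel runs fill the intertrial intervals of the alternation
task).  Within a trial:

**Running speed** follows an Ornstein--Uhlenbeck process (mean 60 cm/s on
the wheel, 35 cm/s on the maze; SD 10 cm/s; correlation time 2 s),
reflected at zero.  Maze trials contain two ~1.5-s "stop" segments
realised as smooth raised-cosine dips, so the 10 cm/s locomotion gate is
exercised by realistic pauses.  After septal inactivation ("post") the
mean speed is scaled by 0.85.

**LFP** is the sum of two oscillators over 1/f background noise:

$$x(t) = A_s(t)\sin\phi_s(t) + A_\theta(t)\sin\phi_\theta(t) + \eta(t)$$

with amplitude law $A_x(t) = \max(0,\, a_{x0} + g_x\, v(t))$ and phase
law $\dot\phi_x = 2\pi\left[f_x + h_x\,(v(t) - \bar v)\right] + \text{phase
noise}$, where $v(t)$ is speed and $\bar v$ the context's mean speed.
Defaults: $f_s = 4$ Hz, $f_\theta = 8$ Hz; $a_{s0} = 10$ uV with
$g_s = 1$ uV/(cm/s) (so the slow amplitude is strongly speed-coupled, ~70
uV at typical wheel speeds), $a_{\theta 0} = 30$ uV with $g_\theta = 0$
(theta decoupled; a negative $g_\theta$ enables the opposing-coupling
mode); $h_s = 0.01$, $h_\theta = 0.02$ Hz/(cm/s) keep both frequencies
weakly and positively speed-coupled.  Noise is pink (exponent 1) with
15 uV RMS.

Three modelling choices deserve comment:

* *Frequency centring.*  The frequency law couples to $v(t) - \bar v$
  rather than to raw speed, so the configured $f_x$ *is* the rhythm's
  centre frequency at typical running speed.  Without centring, any
  nonzero frequency--speed gain would silently shift every recovered
  period and peak frequency away from the configured value, making
  ground-truth recovery ill-defined.
* *Context gating.*  The slow oscillator's amplitude is multiplied by
  `slow_in_maze` (default 0) during maze epochs: the defining empirical
  feature being emulated is precisely that the 4-Hz rhythm appears during
  stationary but not translational running.
* *Phase diffusion.*  Each oscillator's phase accumulates Brownian noise
  (slow: 0.2 rad^2/s; theta: 6 rad^2/s).  Real theta loses lag coherence
  within a few cycles -- autocorrelogram envelopes decay strongly by half
  a second -- and a perfectly coherent synthetic theta would ripple
  through the wheel autocorrelogram at all lags and perturb the slow
  rhythm's period estimate, unlike anything seen in real data.  The theta
  value gives a lag-coherence half-life of ~0.23 s (about two cycles);
  the slow rhythm stays coherent across the +/-0.5-s analysis window.

**Spike trains** are inhomogeneous Poisson with a double von Mises
modulation,
$\lambda(t) = r_0\, e^{\kappa_s \cos(\phi_s - \mu_s)}\,
e^{\kappa_\theta \cos(\phi_\theta - \mu_\theta)} / Z$,
simulated by thinning.  $Z$ is the empirical time average of the
modulation factor, so $r_0$ is the mean rate.  Preferred phases are drawn
uniformly per neuron.  Interneurons fire at 15 Hz
($\kappa_s = 1.5, \kappa_\theta = 1.0$), pyramidal cells at 2.5 Hz
($\kappa_s = 1.0, \kappa_\theta = 0.7$).  Pyramidal cells additionally
emit complex-spike bursts (5% of spikes initiate ~1 extra spike at 5-ms
intervals).  Bursting matters for one specific reason: the min--max
normalised autocorrelogram (NormACG, below) is anchored by its global
maximum, and in real pyramidal cells that maximum is the short-lag burst
peak.  That is why reported pyramidal band amplitudes (~0.5--0.66) sit
well below interneurons' (~0.73--0.94), and without a burst anchor the
normalised band amplitude saturates near 1 for any modulation strength
and stops carrying information.

**The post transform** multiplies: theta amplitude by 0 (theta
abolished), both centre frequencies by 0.984 (both rhythms slow slightly;
the value reproduces the reported stability of spike interpeak intervals,
246 vs 250 ms, within a few ms), mean speed by 0.85, interneuron rates by
0.7, all spike concentrations by 0.6, and theta entrainment additionally
by the theta amplitude scale -- locking to an abolished rhythm would be
unphysical.

## The analysis chain

**Preprocessing.**  A zero-phase 4th-order Butterworth band-stop removes
55--65 Hz line noise.  Amplitude artifacts are excluded at 2 session SDs
with flags dilated by 0.25 s.  Two detection dialects are provided: the
plain per-sample rule, and the default "seeded" rule in which artifact
episodes are first detected at 4 SDs (an automated stand-in for the
visual inspection that identifies gross electrical or movement
transients) and then grown out to the 2-SD boundary.  The distinction is
consequential: the per-sample rule fires on 4.55% of any Gaussian-like
signal and, on clean oscillatory LFP, preferentially excises
high-amplitude (high-speed) epochs, which measurably biases downstream
period estimates; the seeded rule leaves artifact-free recordings
untouched, which is the reported behaviour on the original recordings
(artifacts in only one of three animals).  Finally, only samples inside
trial epochs with interpolated speed above 10 cm/s are analysed; the gate
is evaluated on the behavioural clock and up-sampled by zero-order hold.

**Band decomposition.**  The 4-Hz (3--5 Hz) and theta (6--10 Hz)
components are extracted with a zero-phase two-pass least-squares FIR
filter (15% transition bands).  The filter order is `6*floor(fs/lo)`:
with the conventional shorter order (a 1-s filter at 1250 Hz) the
least-squares response across a 2-Hz pass band ripples by ~8%, which
would corrupt amplitude--speed correlations; the doubled order is flat to
within ~2% across the band interior.  Instantaneous amplitude, phase and
frequency come from the FFT-based analytic signal; the frequency is the
median-filtered (0.1 s) derivative of unwrapped phase, clipped to
$[0, f_s/2]$.  The smoothing window suppresses phase-slip spikes without
distorting the 5-s binned means used downstream.

**Spectral estimation.**  Welch averaged periodograms with a Hamming
taper: 1-s windows at 90% overlap for LFP, 5-s non-overlapping
mean-subtracted windows for binned spike counts (5-ms bins, 200 Hz).
Windows are zero-padded 8x and band peak frequencies are refined by
three-point parabolic interpolation: 1-s windows give 1-Hz native bins,
far too coarse for sub-0.1-Hz peak-frequency contrasts.  Relative
(sum-normalised) LFP spectra are normalised over a fixed 0--50 Hz grid so
the denominator does not depend on the estimator's upper limit; spike
spectra are normalised over their full 0--100 Hz grid.  The spike power
index for a band is `max(relative PSD in band) - relative PSD at the
band's upper edge` (4--6 Hz band with 6-Hz edge; 8--15 Hz with 15-Hz
edge, the theta edge chosen by symmetry with the printed 4-Hz formula).

**Autocorrelograms.**  LFP ACGs use the continuous 'coeff' convention
(zero lag = 1) over +/-0.5 s, computed per contiguous kept segment of at
least 1 s and averaged (weighted by segment length) so lags never
straddle excluded data; a trial-averaged trace summarises each stratum.
The rhythm period is the mean spacing of successive positive-lag peaks,
with lag 0 as the zeroth peak; peaks must clear a topographic-prominence
threshold of 0.2x the trace range so low-amplitude ripples from the
secondary rhythm or noise are not counted.  Spike ACGs are lag histograms
(10-ms bins, zero-lag bin removed) divided by the number of reference
spikes -- the spike dialect of 'coeff': each value is the expected number
of spikes per bin at that lag.

**NormACG and the inclusion screen.**  Each neuron's ACG is min--max
rescaled, `NormACG = (ACG - min) / (max - min)`, before group averaging;
band features are the largest local maximum of NormACG within the band's
lag window (200--300 ms for 4-Hz, 100--200 ms for theta) and its lag
(refined by a 3-point parabola, since 10-ms bins would quantise few-ms
interpeak contrasts).  Neurons enter the analysis only if their mean rate
exceeds 1 Hz and their rhythmicity clears a 0.2 threshold.  The
thresholded statistic is the *baseline-normalised modulation depth*: the
ACG is smoothed with a 3-bin boxcar, divided by its mean over 50--500-ms
lags (its asymptotic Poisson level), and the maximum excess over that
baseline within 50--500 ms is compared against 0.2.  Two properties make
this the right reading of a 0.2 threshold "on the normalised ACG": it is
independent of firing rate (a von Mises-modulated train has expected peak
depth $I_0(2\kappa)/I_0(\kappa)^2 - 1$, which is 0.42 at $\kappa = 1$
regardless of $r_0$), and a min--max rescaled trace cannot be thresholded
meaningfully at 0.2 because its maximum is 1 by construction for every
neuron, rhythmic or not.  The lag range excludes the first 50 ms so the
refractory/burst shoulder is not mistaken for rhythmicity.

**Statistics.**  Amplitude/frequency/speed couplings are Spearman
correlations over non-overlapping per-trial bins (5 s by default, 1 s
supported; bins with under 80% kept samples are dropped), with the
t-approximation for p-values (exact permutation null for n <= 10 without
ties).  Two-sample contrasts follow the study's convention: Shapiro--Wilk
on both groups, then t-test if both look normal and the Wilcoxon
signed-rank/rank-sum test otherwise, at alpha = 0.05 with no
multiple-testing correction.  Pre/post wheel comparisons can be
restricted to speed-matched trials: wheel trials with mean speed in
55--63 cm/s, paired across conditions by nearest speed within a 2 cm/s
caliper, with a rank-sum check that no residual speed difference
remains.  The caliper step matters because the two conditions' speed
distributions enter the window from opposite sides, so the window alone
leaves a small residual difference that a well-powered rank-sum test
would detect.

## Problem sizes, tolerances, degenerate inputs

The packaged analyses and tests run on scaled-down sessions chosen to
keep every statistic deeply in its asymptotic regime while remaining
quick: 60 trials for period/peak recovery (the original study analysed
304 pre and 501 post trials), 30 trials per condition for the
inactivation contrast (20 independent seeds), 300 s of spiking at 5--15
Hz for the screen's operating characteristics (50 modulated vs 50
unmodulated neurons), and 10 seeds for the coupling-sign property.
Recovery accuracy at these sizes: wheel 3.1-Hz period within +/-10 ms of
322.6; maze 6.9-Hz period within +/-5 ms of 144.9 (the phase-diffusion
envelope advances ACG peaks by ~1.6 ms -- the decaying-cosine peak shift
$a/\omega^2$); PSD peaks within one interpolated grid step (0.125 Hz).

Degenerate inputs have defined behaviour throughout: zero-variance
signals are a degenerate-input error for artifact rejection, NormACG and
Spearman; empty trial tables yield empty masks; trials with under 1 s of
kept samples are skipped with a log entry; neurons failing the rate,
spike-count or depth screens are excluded with reason codes
(`rate`, `spikes`, `threshold`); identical paired groups compare at
p = 1; ACG feature windows with no local maximum return the boundary
value flagged `boundary = TRUE`; ties in peak picking break toward the
smaller lag.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis relies on: two
concurrent oscillators with the study's coupling signs, 1/f background,
realistic trial/speed structure with stops, phase-locked spiking of both
cell types with burst-anchored pyramidal autocorrelograms, and a post
transform matching every reported direction (theta abolished, both
rhythms slightly slower, speed reduced, interneuron rates reduced,
entrainment weakened).  It does not model biophysics (no
conductance-based LFP), place fields or other spatial coding, respiratory
coupling, electrode drift, or genuine recording artifacts; sessions are
stationary within condition.  Passing tests therefore demonstrate that
the pipeline recovers known ground truth through realistic noise -- not
that real hippocampal data would show these effects, nor that the
generator's parameter values are physiological beyond the features listed
above.

## Known limitations

* The interpeak statistic reads periods off the trial-averaged ACG; with
  two rhythms of comparable amplitude and high mutual coherence the
  secondary rhythm's ripple can still shift the primary peak by a few ms.
* The spike-ACG epoch restriction ignores pair truncation at epoch
  boundaries (a ~3% triangular taper at 0.5-s lags for 15-s trials); the
  baseline-normalised depth statistic is insensitive to it.
* The Dryad-deposit adapter is a documented stub: real recordings can be
  mapped into the session container, but no loader for the original
  archive format is shipped.
* `h_theta_speed > 0` plus speed gating means the realized theta
  frequency in gated maze data sits slightly below the configured centre
  (stop ramps contribute low-speed, low-frequency samples); the effect is
  ~0.05 Hz at the defaults.
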