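---
title: "Estimating corticothalamic gains from postictal EEG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating corticothalamic gains from postictal EEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctgain` estimates the effective synaptic gain parameters of a
four-population corticothalamic mean-field model from EEG power spectra,
minute by minute, across the first postictal hour, and characterizes the
gain regime at which self-orientation returns. This vignette is the
package's account of the underlying science: the model and its
assumptions, the spectrum that is fitted, the estimation machinery, the
synthetic-data generator used for validation, and the numerical and
design choices made where the problem left them open.

## The model

Four interacting neural populations are tracked by their mean membrane
potential and mean firing rate: cortical excitatory (*e*), cortical
inhibitory (*i*), thalamic reticular (*r*) and thalamic relay (*s*). Note
the labels: *r* is the *reticular* nucleus and *s* the *relay* (specific)
nuclei, the convention of the model's source literature; the inhibitory
intrathalamic loop relay → reticular → relay therefore carries the gain
G~srs~.

Three ingredients close the loop:

1. **Activation.** A population's potential maps to a firing rate through
   the sigmoid Q(V) = Q~max~ / (1 + exp(−(V − θ)/σ′)), with maximum rate
   Q~max~ (1/s), threshold θ (mV) and scale σ′ (mV).
2. **Synaptodendritic filtering.** Incoming rates drive the potential
   through the second-order operator
   (1/(αβ)) V″ + (1/α + 1/β) V′ + V = Σ~b~ ν~ab~ φ~b~, whose frequency
   response is the double low-pass L(ω) = (1 − iω/α)^−1^(1 − iω/β)^−1^.
3. **Axonal propagation.** The cortical excitatory field obeys a
   critically damped wave equation, contributing (1 − iω/γ~e~)² in the
   frequency domain; the compact populations (*i*, *r*, *s*) respond
   locally, φ = Q. Thalamocortical conduction is delayed by t₀/2 each
   way, so closed corticothalamic loops pick up e^iωt₀^.

The two cortical populations share afferents (ν~i·~ = ν~e·~, the
random-connectivity symmetry), which makes V~i~ = V~e~ at steady state
and is required for the closed-form spectrum below.

Linearized about the steady state, every connection carries a gain
G~ab~ = S′(V~a~) ν~ab~ — the sigmoid slope at the operating point times
the coupling strength. Five loop gains suffice for the EEG: G~ee~, G~ei~
(cortical feedback), G~ese~ = G~es~G~se~ (corticothalamic loop through
the relay), G~esre~ = G~es~G~sr~G~re~ (the loop routed through the
reticular nucleus, net inhibitory) and G~srs~ = G~sr~G~rs~ (intrathalamic
loop). Their composites

* X = G~ee~ / (1 − G~ei~),
* Y = G~ct~ + G~tc~, with G~ct~ = G~ese~/((1 − G~srs~)(1 − G~ei~)) and
  G~tc~ = G~esre~/((1 − G~srs~)(1 − G~ei~)),
* Z = −G~srs~ αβ/(α + β)²,

measure the cortical excitatory/inhibitory balance, the net
corticothalamic loop gain and the thalamus's intrinsic responsiveness.

## The fitted spectrum

The EEG is generated by the cortical excitatory field; its power spectrum
under white-noise external drive entering at the relay nucleus follows
from the linearization. Writing L = L(ω) and E² = e^iωt₀^, the dispersion
function is

q²r~e~² = (1 − iω/γ~e~)² − [ L G~ee~ + (L² G~ese~ + L³ G~esre~) E² /
(1 − L² G~srs~) ] / (1 − L G~ei~),

and the spectrum is

P(ω) ∝ |L²|² / ( |1 − L² G~srs~|² |1 − L G~ei~|² |q²r~e~²|² ).

At ω = 0 the dispersion reduces to 1 − X − Y, which must be positive. The
published description of this model family does not print the closed
form; it is derived here from the three ingredients above, and a
stochastic time-domain integrator of the full nonlinear delay system is
the arbiter of correctness: the validation suite checks band-integrated
agreement per 1-Hz bin between the analytic spectrum and Welch estimates
from long simulations across random stable parameter sets.

Two normalization decisions matter. First, the package fits *relative*
power: both observed and model spectra are normalized to unit integral
over the fit band before comparison, because amplifier gain and
referencing make absolute EEG power unidentifiable; an overall amplitude
is therefore not a free parameter. Second, the fitted spectrum is the
spatially uniform mode of the cortical field — the channel-median of a
scalp montage approximates it — with an optional spatial mode-sum over a
square cortex available behind an argument (`n_modes`), and an optional
flat noise-floor parameter that is off by default.

### Stability

A parameter set is usable only if the linearized loop has no growing
modes. A minimum over real frequencies of the loop-denominator modulus is
not sufficient: delayed negative feedback can hide a growing complex mode
behind an innocuous real-axis profile. The package therefore applies the
argument principle to the dispersion function: the winding number of
q²r~e~²/(1 − iω/γ~e~)² along the real axis (computed on a dense grid to
150 Hz, using conjugate symmetry) counts unstable zeros; only a winding
number of zero, a positive DC value 1 − X − Y and loop denominators
bounded away from zero qualify as stable. Unstable states receive zero
likelihood in the sampler, and the synthetic generator validates every
minute of every trajectory against the same test.

## Preprocessing

EEG enters as EDF (a minimal 16-bit codec ships with the package) or as
precomputed tidy PSD tables. The preprocessing chain mirrors standard
clinical practice: a first-order Butterworth band-pass (0.5–45 Hz),
applied forward–backward by default (zero phase; a single-pass option
exists since phase handling is a convention), automated artifact
annotation as a surrogate for visual inspection (5-s windows exceeding an
amplitude threshold or flat-lining are rejected; channels with more than
half their windows rejected are dropped entirely), and Welch spectra on
non-overlapping artifact-free 5-s segments (the 5-s segment *is* the
Welch block; Hann window), averaged within each postictal minute and
reduced to the channel median per frequency. Minutes without clean
segments are *missing data*, not errors. Because the analysis filter's
response is known exactly, the Welch stage divides it out, so spectral
fits see the underlying signal spectrum rather than the filter shoulder —
with a first-order filter this matters mostly below 2 Hz, where the
double pass costs up to a factor of three in power. Minute indices are
0-based internally (minute 0 begins at the recording start, taken as
seizure termination) and 1-based in printed reports.

## Estimation

Each minute's channel-median PSD is inverted by random-walk
Metropolis–Hastings over the five gains. The misfit is
χ² = Σ~f~ (log P~obs~ − log P~model~)², unit weights per frequency bin on
the 0.2-Hz grid between 0.5 and 45 Hz (an inverse-variance option using
across-segment variability exists); the likelihood is exp(−χ²/2) with
flat priors inside physiological bounds (defaults G~ee~ ∈ [0, 20],
G~ei~ ∈ [−40, 0], G~ese~ ∈ [0, 40], G~esre~ ∈ [−40, 0],
G~srs~ ∈ [−14, 0], from the model family's literature). Proposals are
per-parameter Gaussians, initialized at 2% of each bound width and
adapted toward a 0.3 acceptance rate during burn-in only — frozen
afterwards, preserving detailed balance — and are reflected at the
bounds, which keeps them symmetric. The default chain runs 20,000
iterations with 5,000 burn-in and thinning 10. The point estimate (MAP)
is the minimum-χ² state visited by the chain; an optional bounded
quasi-Newton polish of the MAP exists but is off by default, since the
estimate is defined as the sampler's output.

Because the χ² landscape is multimodal in the raw gains, a chain started
far from the data's regime can stall on a secondary ridge within the
default budget. When no explicit start is supplied, a coarse
initialization search therefore precedes sampling: candidate gain sets
are drawn across the physiological *composite* region (X, Y, Z, G~ei~,
G~ct~), inverted to loop gains, filtered for stability, and the lowest-χ²
candidate seeds the chain (2,048 draws by default; the search costs a few
tens of milliseconds against seconds for the chain). Within a recording,
minutes are fitted in temporal order and each chain starts at the
previous minute's MAP, which both accelerates convergence and regularizes
the series; failed or missing minutes propagate as missing with a logged
reason. All seeds derive deterministically from a single integer via a
counter-based splitter, so partial re-runs reproduce full runs, and two
runs with the same seed are bit-identical.

The raw gains are only partially identified from a single normalized
spectrum — G~ee~ and G~ei~ trade off along an X ridge, as do G~ese~ and
G~esre~ along Y — whereas the composites X, Y, Z are well determined.
Posterior marginals of the raw gains are therefore wide, and resolving
them to calibrated 95% intervals needs longer chains than the MAP does
(the validation suite uses 80,000 iterations, thinning 20, for its
coverage study; MAP recovery of X, Y, Z is already stable at the default
length).

## Trajectories and regime extraction

Each gain's minute-by-minute MAP series (posterior means are a
configurable alternative; MAP is the default point estimate throughout)
is reduced to one of three parametric curves: saturating exponential
decay and growth, g(t) = g~∞~ + (g₀ − g~∞~)e^−t/τ^ with g₀ > g~∞~
resp. g₀ < g~∞~, and the four-parameter sigmoid
g(t) = g₀ + (g~∞~ − g₀)/(1 + e^−(t−t_m)/s^). Missing minutes are dropped,
not interpolated. Fits use Levenberg–Marquardt least squares from eight
deterministic data-driven starts (endpoint levels, third-life and
steepest-slope heuristics); a profiled linear fallback — both families
are linear in the two levels once the shape parameter is fixed, so a
deterministic grid plus ordinary least squares always yields a candidate
— guarantees a usable fit on short or degenerate series. Families are
compared with the least-squares information criterion
AIC = 2k + n ln(RSS/n), k counting curve coefficients and n the
non-missing minutes; the lowest AIC wins, except that when the two lowest
differ by at most two the fit with fewer coefficients is preferred, exact
ties resolving toward the exponential families. Each selected fit carries
a ledger of all three AICs and the rule applied.

The temporal change of a gain is the fitted curve's value at minute 60
minus its value at minute 0, and the regime values report the curve at
three time points: the first postictal minute (t = 0 on the curve, not
the raw minute-0 estimate), the recording's reorientation minute, and
minute 60. A long-format cohort table (subject, session, gain, timepoint,
value, treatment covariates) is emitted for downstream mixed-effects
regression tooling; those regressions themselves are out of scope here.

## The synthetic cohort generator

No clinical recordings ship with the package, so a generator produces
cohorts with the statistical structure the analysis assumes — and
doubles, at the EEG level, as the time-domain oracle. Its defaults encode
the study conditions the analysis targets: sixty analyzed postictal
minutes per recording; reorientation times drawn from Normal(22.4, 4.8)
minutes truncated to [5, 55]; twelve 5-s Welch segments per minute;
composite-gain trajectories running from an early-postictal regime —
X = 0.95 (cortical balance near criticality), Y = −0.30
(inhibition-dominated corticothalamic loop), Z = 0.02 (nearly
unresponsive thalamus) — toward a late regime closer to baseline
(X = 0.72, Y = −0.08, Z = 0.12) with saturating-exponential time
constants of 20–25 minutes, which places the cohort-mean cortical balance
near 0.8 at typical reorientation times. Between-subject and
between-session variability enter as Gaussian perturbations of the regime
anchors (sd 0.02/0.03/0.015 at the subject level, half that between
sessions) — assumed scales, stated here as the package's choice since no
inter-subject gain noise model is available — truncated to the feasible
(spectrally stable, in-bounds) region by rejection, exactly as the
reorientation distribution is truncated to its range.

The composite-to-constituent inversion is under-determined (three
composite targets, five gains), so two constituents follow their own
smooth anchored paths: G~ei~ from −1.5 to −2.0 and G~ct~ from 0.10 to
0.08. Then G~srs~ = −Z(α+β)²/(αβ), G~ee~ = X(1 − G~ei~),
G~ese~ = G~ct~(1 − G~srs~)(1 − G~ei~) and
G~esre~ = (Y − G~ct~)(1 − G~srs~)(1 − G~ei~). These anchors were chosen
for two reasons: they reproduce the expected directions of the partial
gains over recovery (corticothalamic G~ct~ decreasing, thalamocortical
G~tc~ increasing), and they keep every minute of the default trajectory
spectrally stable — strongly negative G~ei~ values of the magnitude seen
in awake-state modelling make the early-postictal composite regime
(X ≈ 0.95 with strongly negative Y) Nyquist-unstable, i.e. unrealizable
as a stationary spectrum, so the generator uses weak cortical inhibition
during recovery.

Cohorts are generated at PSD level by default: each minute's observed
spectrum is drawn around the analytic model spectrum with independent
Gamma(n~segments~, n~segments~) multiplicative noise per bin, the
sampling law of an average of that many independent periodograms. The
EEG level instead synthesizes time-domain signal per minute and runs the
actual Welch stage; the two pathways agree within Welch sampling error
(tested), and PSD level is the default for runtime symmetry with the
analysis. What the generator does *not* emulate: residual artifacts,
volume conduction and montage geometry (all channels are copies of the
uniform mode plus independent sensor noise), non-stationarity within a
minute, spectral features outside the model class (e.g. spindles, EMG),
and real inter-subject physiology beyond anchor shifts. Passing the
validation suite therefore demonstrates internal consistency of the
estimation machinery under the model's own assumptions, not fidelity of
the model to clinical EEG.

## Numerical choices

* **Time-domain integration**: stochastic Heun with step dt = 1/(8·f~s~)
  (1/2048 s at the default 256 Hz), a linearly interpolated ring buffer
  for the 40-ms conduction delay, white drive noise entering the relay
  population, and a 2-s discarded transient. The integrator preserves an
  exact fixed point to 10^−8^ over 10 s with zero noise.
* **Drive noise scale**: sd 0.3 s^−1^·√s on the external rate, keeping
  potential excursions well inside the sigmoid's linear range at the
  default operating point; the spectrum's shape (all that is fitted) is
  insensitive to this choice within the linear regime.
* **Operating point**: synthetic parameter sets pin the steady state at
  prescribed firing rates (defaults 10/10/15/15 s^−1^ for e/i/r/s)
  through the external-drive column of ν, and the composite split uses
  G~es~ = 2, G~sr~ = −1.
* **Steady-state solver**: damped iteration from θ − 3σ′ (selecting the
  low-firing branch), tolerance 10^−10^ mV, with a bracketing scan of the
  1-D cortical reduction as fallback that takes the lowest root.
* **Sigmoid scale**: the source convention relates σ′ to the threshold
  spread's standard deviation by a factor π/√3; `sigma_prime` here is the
  logistic scale in mV directly (default 3.8 mV), configurable, so either
  reading of that convention can be expressed.
* **Nominal parameters** (`inst/extdata/default_params.yaml`): Q~max~ =
  340 s^−1^, θ = 12.9 mV, σ′ = 3.8 mV, α = 60 s^−1^, β = 240 s^−1^,
  γ~e~ = 116 s^−1^, t₀ = 80 ms, values in the range of the model's source
  literature. The synaptic rates were chosen so that the corticothalamic
  resonance of a net-excitatory loop falls inside the empirical alpha
  band (8–13 Hz); slower rate pairs push it below 8 Hz. The ν matrix in
  the config realizes a baseline regime (X ≈ 0.68, Y ≈ +0.22, Z ≈ 0.09)
  whose spectrum carries an alpha peak, as an eyes-closed baseline
  should. These values are used for synthesis and initialization only —
  every computation takes its parameters explicitly.
* **Alpha-peak detection** (`alpha_peak()`): a local maximum of log-power
  in 8–13 Hz with at least 1 nat (a factor e) of prominence above the
  6–15 Hz log-power chord. The prominence requirement is essential: the
  conduction delay imprints a shallow comb on *every* spectrum, including
  inhibition-dominated ones, and a bare local-maximum test would detect
  those ripples. With it, a net-excitatory loop (Y > 0) shows a peak and
  the matched net-inhibitory loop does not.
* **Fit band**: 0.5–45 Hz (matching the acquisition filter) on the 0.2-Hz
  grid of 5-s segments; configurable.
* **Degenerate inputs**: all-missing recordings yield empty series;
  constant gain series short-circuit to the exact degenerate fit; fits
  that violate a family's direction constraint or fail to converge carry
  infinite AIC rather than errors.

## Validation problem sizes

The validation suite and `scripts/acceptance.R` use: five random stable
parameter sets with 9,600-s simulations for the spectrum oracle (the
band-integrated per-1-Hz-bin comparison needs long averages because a
Welch estimate's bin noise shrinks only as the square root of duration);
1,000 random draws for the gain-algebra identities; twenty replicate
single-minute recoveries at 80,000-iteration chains; and a ten-recording
cohort fitted at 6,000 iterations per minute with warm starts for the
end-to-end directional check. These sizes are the package's validation
design; the underlying functions accept arbitrary sizes.

## Known limitations

* The five raw gains are not separately identified from one normalized
  spectrum; conclusions should rest on X, Y, Z and the partial loop
  gains, as the analysis intends.
* Unit-integral normalization of sharply peaked spectra is itself noisy
  (the lowest-frequency bins dominate the integral), which adds a
  common-mode component to the χ² of very-low-frequency-dominated
  minutes.
* The automated artifact thresholds are a surrogate for visual
  inspection and cannot be validated against expert markings from within
  this package.
* The spatially uniform mode ignores montage geometry and volume
  conduction; the optional mode-sum relaxes only the first of these.
* Rates α, β and delay t₀ are fixed at their nominal values by default;
  fitting them alongside the gains is available (`fit_rates`) but widens
  the ridge structure further.
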