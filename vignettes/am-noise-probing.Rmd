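---
title: "Noise-probing the music/speech boundary: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-probing the music/speech boundary: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(amnoise)
```

`amnoise` implements a reductionist auditory-psychophysics paradigm: noise
stimuli carry *only* a designed amplitude-modulation (AM) structure — their
spectral content is uniform noise — and listeners judge whether each sounds
more like music or speech. Because the stimuli are parametric, every stage
(synthesis, screening, scheduling, response generation, analysis) can be
verified end to end without human data. This vignette records the models,
the tunable parameters, and the design decisions that were genuinely open,
in the order the pipeline runs.

## 1. The stimulus model

### Designed AM spectrum

The target AM spectrum is a shifted lognormal in modulation frequency
$x$ (Hz):

$$\mathrm{Lognormal}(x;\mu,\sigma^2,b) =
\frac{1}{(x-b)\,\sigma\sqrt{2\pi}}
\exp\!\left(-\frac{(\ln(x-b)-\mu)^2}{2\sigma^2}\right),$$

with the shift tied to the peak frequency by $b = -1.2813\,m$ and the
location by $\mu = \ln(m-b) + \sigma^2$. These couplings make the mode of
the continuous curve land exactly at $m$ (the identity
$b + e^{\mu-\sigma^2} = m$ holds algebraically and is tested), while the
negative shift gives the curve a nonzero intercept at low frequency, as
empirical envelope spectra of music and speech recordings show.
Parameters and units:

* `m` — peak AM frequency, Hz. Music-typical ≈ 1–2 Hz; speech-typical
  ≈ 3.5–5.5 Hz. Experiment grids span 0.6–6 Hz.
* `sigma` — log-SD of the lognormal, unitless. Smaller values concentrate
  power at one modulation rate, producing more isochronous envelopes.
  0.35 is the package-wide reference (the fixed value in the
  peak-frequency experiments).

The curve is then divided by $x$ (`apply_one_over_f()`): natural envelope
spectra carry a $1/f$ tilt which analysis pipelines remove by multiplying
by frequency, so synthesis must install it by dividing. Consequently the
designated peak is defined on the *compensated* spectrum
(`power * freq`), and the verification functions compensate before locating
peaks. We target the compensated spectrum because the ×1/x step exists
precisely to invert the analysis normalization; the raw spectrum's argmax
sits below `m` by construction.

### From spectrum to waveform

1. The weighted curve is evaluated on the FFT bin grid of a 20-s signal
   (spacing 1/20 Hz) from 1/20 Hz up to `fmax = 64` Hz and zero elsewhere;
   the DC bin is zero. 64 Hz comfortably contains the AM band of interest;
   no upper limit is dictated by the design, so this is a package choice.
2. A conjugate-symmetric complex spectrum with i.i.d. uniform phases on
   $[0, 2\pi)$ is inverse-transformed (`spectrum_to_envelope()`). The
   synthesis grid runs at `env_rate = 1000` Hz: AM content lives below
   64 Hz, so synthesizing the modulator at audio rate would waste three
   orders of magnitude of computation.
3. The zero-mean signal is min–max rescaled to $[0,1]$ to serve as an
   amplitude envelope. The rescaling is affine, so it preserves the designed
   spectrum shape up to a DC term and a gain. The alternative — taking a
   magnitude (e.g. Hilbert) transform — would distort the designed spectrum
   and was rejected. How the original procedure mapped the signed signal to
   an envelope is not fully determined by its description; min–max rescaling
   is this package's choice and is flagged as such.
4. The envelope is upsampled to the audio rate by exact band-limited (FFT
   zero-padding) interpolation, then clipped to $[0,1]$ to remove
   interpolation overshoot.
5. The envelope multiplies a low-noise-noise (LNN) carrier, and the middle
   4 s of the 20-s product are extracted (`synthesize_stimulus()`).

### The LNN carrier

LNN is broadband noise whose instantaneous envelope is iteratively
flattened, so that none of a finished stimulus's amplitude fluctuation comes
from the carrier. The published description cites the technique without an
algorithm; this package iterates, 10 times by default: divide the signal by
its Hilbert envelope (analytic-signal magnitude), then re-band-limit to
20–20,000 Hz. Band-limiting is done by zeroing FFT bins outside the band
rather than with an IIR filter: at 44.1 kHz the 20-Hz edge corresponds to a
normalized frequency of 9·10⁻⁴, where recursive filters in
transfer-function form are numerically fragile, while the frequency-domain
operation is exact and leaves out-of-band power identically zero. The
envelope coefficient of variation (CV) decreases monotonically over
iterations (tracked in the `cv_history` attribute and tested); over a
three-decade band it plateaus around 0.12 — perfect flatness is only
attainable for narrowband signals, and ending the loop on a division
instead of a band-limit does not measurably flatten the *delivered*
envelope either, so the band-limit-last order is kept and out-of-band
purity is exact.

Within a stimulus pool (`synthesize_pool()`), one carrier — seeded from the
pool seed — is shared by all stimuli, and per-stimulus variation comes from
the modulator phases. Because the carrier is envelope-flat by design, it
contributes no AM of its own; sharing it keeps full-pool synthesis cheap
and is this package's choice (the original procedure does not state whether
carriers were per-stimulus). `synthesize_stimulus()` called without a
carrier still builds a fresh one from the stimulus seed.

Stimuli are RMS-equalized within an experiment (`equalize_rms()`), default
target 0.05 full-scale, which leaves headroom after modulation so 16-bit
WAV export cannot clip. Only RMS is equalized — no perceptual loudness
model.

### Verifying delivered peaks

`estimate_am_spectrum()` recovers a model-free AM amplitude spectrum from
audio: Hilbert envelope, band-limited resampling to `env_rate = 256` Hz,
mean removal, zero-padded magnitude FFT up to 64 Hz (DC excluded by
construction). It is accurate for strong narrow modulations (a 3-Hz
sinusoidal test modulation is located to within one bin).

Locating the *broadband* designed peak from a single 4-s excerpt is harder:
the native resolution is 0.25 Hz, bin magnitudes fluctuate (Rayleigh), and
an argmax of so short a window is both noisy and biased by asymmetric
leakage under the ×f compensation. `estimate_am_peak()` therefore uses a
measurement model:

* the envelope is differentiated in the time domain before windowing
  effects are compounded — differentiation multiplies the spectrum by
  $2\pi f$, i.e. it applies the 1/f compensation in the order the physics
  applies the window, which removes the leakage-then-compensate bias;
* derivative power spectra are averaged across the stimuli of a condition
  (power averaging is unbiased under phase randomization);
* the known spectral family — squared lognormal lines smeared by the Fejér
  kernel of the rectangular 4-s excerpt — is least-squares fitted to the
  average on the amplitude scale, with the design σ assumed known and two
  nuisance regressors: the pool carrier's own envelope-derivative spectrum
  and an $f^2$ noise floor. The fitted peak location is reported.

A grid search over $\log m \in [\log 0.3, \log 10]$ followed by local
refinement guards against local minima. The per-condition pool (50 stimuli
in the detection experiments) is the natural averaging unit and the scale
at which the package's whole-pipeline tests verify peaks, with a ±10%
tolerance across the 0.6–6 Hz grid.

## 2. Headphone screening

Three 1-s 200-Hz tones with 100-ms raised-cosine ramps: in-phase loud,
antiphase loud, in-phase quiet. The "loud" amplitude is 0.5 full-scale (an
open choice; only relative levels matter to scoring) and the quiet gain is
exactly $10^{-6/20}$, so the −6 dB target is exact rather than the
½-amplitude ≈ −6.02 dB convention. The ramp shape is unstated in the
original description; a Hann half-window is used. Playback physics are
idealized: headphones deliver each channel unchanged; a loudspeaker sums
the channels in air (`(L+R)/2`), cancelling the antiphase tone exactly, so
an intensity-picking listener chooses the antiphase tone and fails. The six
trials counterbalance all six orderings of the three positions; pass
requires ≥ 5/6 correct. Scoring is purely ordinal on RMS — absolute level
and inter-stimulus timing are not modeled.

## 3. Experiment designs

| Exp | Manipulated | Levels | Fixed | Pool/cond | Draws/cond | Unique |
|----:|-------------|--------|-------|----------:|-----------:|-------:|
| 1 | peak `m` | 10, log-spaced 0.6–6 Hz | σ = 0.35 | 100 | 15 | 150 |
| 2 | regularity σ | 5, log-spaced 0.10–1.00 | m ∈ {1, 2.5, 4} Hz | 50 | 10 | 150 |
| 3 | peak `m` | 5, log-spaced 0.6–6 Hz | σ = 0.35 | 50 | 15 | 75 |
| 4 | regularity σ | 5, log-spaced 0.10–1.00 | m = 2 Hz | 50 | 15 | 75 |

Only the extremes (0.6 and 6.0 Hz) and Experiment 2's three peak
frequencies are pinned by the published designs; interior levels are
log-spaced defaults (log spacing matches how both AM rate and σ act
perceptually) and the σ grid — never printed — is centred on the 0.35
reference within [0.10, 1.00]. All are overridable in `condition_grid()`.

Schedules (`build_schedule()`): Experiments 1–2 present each of the
participant's 150 drawn stimuli once per session half, shuffled within each
half (300 testing trials). Experiments 3–4 run four blocks — one music and
one speech block per half, order randomized within half — each block
presenting the same 75 drawn stimuli in fresh random order (150 trials per
task). Twelve probe trials (1–4 brief tones in a 2-s window; report the
count) are stratified one per consecutive run of 25 testing trials,
uniformly within the middle half of each run, so consecutive gaps can never
exceed twice the mean gap ("roughly even"). Breaks follow every 10 testing
trials. Four practice trials at geometric midpoints of adjacent testing
levels (inside the range, never equal to a tested value) open the session
and are repeated before the first block of the second task in Experiments
3–4; practice repetition until comfort is not modeled.

## 4. The simulated population

Each participant carries:

* `beta` — true response slope, probability per Hz (or per σ unit);
* `alpha` — intercept: response probability at the grid's reference level;
* `lapse` λ — probability of answering at random, mixed in as
  $p \mapsto \lambda/2 + (1-\lambda)p$;
* `msi` — a General Musical Sophistication score on 18–126;
* an archetype: compliant, all-same responder, probe-failer (50% probe
  accuracy), or biased responder (fixed response-1 rate, default 0.8).

`(beta, msi)` are bivariate normal with correlation ρ; `msi` is truncated
to [18, 126] by resampling (clipping would pile mass at the boundaries).
The generative psychometric function is **linear** (clipped to [0, 1]), not
logistic, reflecting the finding that the linear model fits such judgments
better; `fit_logistic()` exists for the model-comparison analysis, and
simulating from a logistic is possible by transforming probabilities
upstream if needed.

Defaults and why:

* `beta_mean = 0.08` per Hz with `beta_sd = beta_mean / 0.68`, so the
  population's standardized slope effect equals the published Cohen's
  d = 0.68 and the mean response spans a realistic ~0.43 of the probability
  scale across the 0.6–6 Hz grid.
* `msi_mean = 81.58`, `msi_sd = 20.62` — the published norm of the
  sophistication index; `rho = 0.2`, matching the observed
  slope–sophistication correlation after outlier removal (r ≈ 0.20).
* `alpha_sd = 0.12`: response-bias heterogeneity such that roughly a fifth
  of simulated participants fall outside the 50 ± 15% response-rate band —
  the order of the bias-exclusion rates reported for the detection
  experiments (16 and 23 of ≈ 100 recruited).
* `lapse_max = 0.1`: lapses uniform on [0, 0.1], a conventional ceiling for
  attentive online participants.
* Archetype fractions default to 0; tests switch them on explicitly to
  exercise each exclusion filter.

What the generator does *not* emulate: sequential/order effects, response
times, drift in attention, any cognitive process model, and any genuine
mechanism linking sophistication to slope — the bivariate-normal link is a
modeling convenience. Passing tests therefore certify the pipeline's
statistics and plumbing, not the psychology of real listeners.

## 5. The analysis pipeline

Exclusions (`apply_exclusions()`), applied in order with a participant
counted under the first matching criterion: incomplete experiment or
questionnaire; headphone-screen failure; all-same responses; probe accuracy
below 90%; and — detection experiments only — response rate outside
[35%, 65%] in any task. The ledger reports per-criterion counts, and
`reconcile_exclusion_counts()` checks recruitment arithmetic.

Per-participant fits are at the trial level (binary responses). Whether the
original analysis regressed trials or level means is not determinable from
its description; slopes are identical under balanced designs (tested to
1e-10) but R² is not, and trial-level R² of binary data is intrinsically
much smaller than level-mean R², so the package's R² values are not
comparable to level-mean ones. `fit_linear()` is OLS; responses with zero
variance get slope 0 and R² defined as 0 (such participants are excluded
upstream anyway). `fit_logistic()` least-squares fits
$f(x;a,\beta) = 1/(1+e^{-\beta(x-a)})$ with the midpoint $a$ box-constrained
to the tested range (L-BFGS-B), 25 multi-starts over an $(a, \beta)$ grid;
least squares rather than likelihood keeps its R² on the same
sum-of-squares basis as the linear fit, which is the point of the
comparison. Non-convergence across all starts is flagged, not erroneous.

Group inference uses definitional formulas (all property-tested against the
`stats` package on random inputs): one-sample t with d = mean/SD; Pearson r
with df = n − 2; Welch t with Welch–Satterthwaite fractional df and pooled-SD
Cohen's d (the variant is unstated in the source; pooled SD is the common
default). The correlation's outlier rule is likewise unstated; points with
|standardized residual| > 3 from the OLS line are flagged
(config-overridable), and both with- and without-outlier estimates are
always reported. Subscale screening applies a Bonferroni threshold of 0.01
(five subscales at family α = 0.05).

`power_required_n()` searches integers against the exact noncentral-t power
function (noncentrality $d\sqrt{n}$, df $n-1$). At d = 0.68, α = 0.05,
power = 0.8 the solution is knife-edged: power(19) = 0.8004, so tools
disagree between 19 and 20 at the fourth decimal; the package returns the
exact smallest n (19) and its tests accept ±1 around the published values.

`simulate_slope_experiments()` is a vectorized calibration driver: it draws
populations, generates trial-level Bernoulli matrices, computes OLS slopes
in closed form (algebraically the `fit_linear()` slope), and t-tests them.
The type-I calibration check runs 2,000 replicate 48-participant null
experiments; the slope-recovery check uses a fixed `beta` (no population
spread), no lapses, and homogeneous intercepts, because lapses shrink
slopes multiplicatively and probability clipping censors extreme-bias
participants — both real properties of the generative model, not estimator
bias, which is the property under test.

## 6. Numerical conventions and degenerate inputs

* All randomness flows through integer seeds; sub-streams are derived with
  `sample.int` under a temporarily seeded RNG, and the caller's RNG state
  is always restored. Fixed seed ⇒ byte-identical outputs (tested for the
  whole pipeline's CSV/JSON artifacts).
* FFT-based resampling halves a Nyquist-edge bin to keep signals real;
  envelopes are clipped, not renormalized, after interpolation.
* `spectrum_to_envelope()` rejects curves whose support exceeds the
  envelope Nyquist (aliasing) and requires integer `duration × env_rate`.
* Silent stimuli cannot be RMS-equalized (error); zero-variance responses
  have R² ≡ 0; empty slope-sign groups make the Welch split an error rather
  than a NaN.
* JSON reports are written with stable key order and full precision; CSVs
  are UTF-8, comma-separated, "." decimal. Every artifact directory gets a
  `manifest.json` sidecar with the seed and package version.

## 7. Problem sizes used by the tests

The suite verifies the synthesis contract at the detection-experiment pool
scale (50 stimuli per condition across the five-point 0.6–6 Hz grid, one
shared carrier), statistical calibration with 2,000 replicate simulated
experiments of 48 participants, slope recovery at tenfold trial counts, and
property checks of the inferential statistics on 1,000 random vectors.
These sizes are the package's chosen verification conditions: large enough
for the stated tolerances (±10% delivered peak; rejection rate within
[0.035, 0.065]; < 5% slope bias) to be meaningful, small enough to run
routinely.

## 8. Known limitations

* The S1-style deposited-data reader (`read_s1_data()`) is written against
  a documented normalized long layout with a remappable column map; the
  deposited workbook's internal sheet layout can only be confirmed against
  the actual file, which is not shipped. The reader is tested on synthetic
  stand-ins only.
* The delivered-peak verifier assumes the design family (known σ per
  condition); it is a calibration instrument, not a general AM-spectrum
  peak picker — `estimate_am_spectrum()` plus `am_peak()` serve that looser
  role.
* LNN flatness over a three-decade band plateaus at envelope CV ≈ 0.12;
  residual carrier envelope noise is handled statistically in verification
  rather than eliminated physically.
* Simulated detection tasks (Experiments 3–4) reuse one slope per
  participant across music and speech tasks; task-specific slopes (e.g.
  opposite signs, as real listeners show) must be injected by simulating
  tasks with separate profiles.
* Perceptual loudness is not modeled (RMS only), and no spectral or
  frequency-modulation manipulations are provided — the paradigm is
  deliberately AM-only.
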