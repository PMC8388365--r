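---
title: "Methods: denoising broiler vocalizations and scoring the result"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: denoising broiler vocalizations and scoring the result}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sound is a non-invasive window on poultry health: broilers crow when hungry,
cough when ill, purr with throat irritation and flap their wings when
fighting. Any automatic monitor built on farm recordings must first remove
the background — ventilation hum and the footsteps of people in the walkway —
without destroying the calls it is supposed to classify. `broilersound`
implements five classical single-channel denoisers and scores them from two
angles:

* the **signal angle** — SNR against a known clean reference
  ($\mathrm{SNR} = 10\log_{10}\sum s^2 / \sum (x-s)^2$, in dB) and the RMSE
  between the signal before and after filtering
  ($\sqrt{\tfrac1N\sum(x-f)^2}$);
* the **recognition angle** — accuracy of kNN and random-forest classifiers
  trained on 39-dimensional MFCC features extracted from the filtered audio.

Real farm recordings have no clean reference, so the package ships a seeded
scene generator that does: every evaluation is run against synthetic
soundscapes whose clean signal, noise and event boundaries are known exactly.

## The synthetic soundscape

A scene is a noise-only preamble (default 0.5 s, enough for ~39 noise frames
at the default framing) followed by non-overlapping call events, with
additive noise over the whole duration (`y(n) = s(n) + d(n)`). The four call
classes are modelled from their qualitative field descriptions:

| class | model | default duration | rationale |
|---|---|---|---|
| crow  | decaying FM chirp 2.5 to 4 kHz | 0.3 s | short, loud, sharp, high-pitched |
| cough | band-limited noise 300-1200 Hz, slow decay | 0.5 s | prolonged low croak |
| purr  | 400 Hz carrier, 8 Hz AM (depth 0.5) | 1.2 s | continuously fluctuating low band |
| flap  | train of 25 ms broadband clicks every 40 ms | 0.8 s | long, large-amplitude transient train |

Event levels (1.0 / 0.7 / 0.6 / 1.0 relative RMS) preserve the described
loudness ordering while keeping every class detectable. The stationary noise
is either white or "fan hum": a 100 Hz fundamental with three rolled-off
harmonics (amplitudes 1, 0.7, 0.5, 0.35, random phases) over a white floor
whose total power sits 10 dB below the tonal complex. Footsteps are a Poisson
train (default 0.2/s) of 80 ms low-pass thumps at 2-4 times the stationary
RMS. The noise realization is scaled so the realized scene SNR matches the
target exactly.

What the generator deliberately does **not** model: reverberation, multiple
simultaneous birds (field protocols for this kind of recording isolate
single birds precisely to avoid overlapped calls), amplitude clipping, and any spectral fit to measured farm noise — the
noise parameters are stipulated, not estimated, because no quantitative noise
characterization of the recordings exists. Passing tests therefore
demonstrate correct algorithmic behaviour under controlled conditions, not
performance on any particular farm.

### Standard study conditions

All headline numbers are computed on 20 scenes of 3.0 s at 32 kHz, two events
per scene rotating through the four classes (balanced over the set), fan hum
plus footsteps at 0 dB scene SNR, seeds 1-20 (`benchmark_scene_specs()`).
Three-second scenes keep the GA-OMP sparse decomposition tractable on a
single core while still containing a preamble and two full events; longer
excerpts would change nothing structurally, only the arithmetic mean's
variance. Endpoint-detection accuracy is scored on the same
scenes at 10 dB, where events sit comfortably above the detection threshold —
at 0 dB scene SNR the per-event local SNR is only about 2.5 dB, which is
below what any fixed-threshold energy detector can segment with frame-level
precision.

## The five denoisers

All frequency-domain methods share one STFT: 800-sample (25 ms) Hamming
frames with 50% overlap, two-sided spectra, overlap-add resynthesis with
summed-squared-window compensation (floored at 1e-12), and the **noisy phase
reused** throughout — only magnitudes are modified.

**Basic spectral subtraction** estimates the per-bin noise power `D(k)` as
the mean over the first NIS preamble frames and applies the two-branch rule:
subtract `a*D(k)` where the frame power exceeds it, otherwise floor at
`b` times the frame power. Defaults `a = 4`, `b = 0.001` are classical
over-subtraction settings.

**Improved spectral subtraction** replaces the periodogram with a multitaper
estimate: `L = 5` Slepian tapers at time-bandwidth `NW = 3`, averaged
periodograms, which cuts estimator variance roughly by `1/L` and with it the
"musical noise" of the basic method. Amplitudes and PSDs are smoothed over
2M+1 = 3 adjacent frames; the gain `(Py - alpha*Pn)/Py` (floor
`beta*Pn/Py`; `alpha = 4`, `beta = 0.01`) multiplies the smoothed amplitude.
The tapers are applied to unwindowed frames — they are themselves the
analysis windows; double-windowing would square the taper's spectral
concentration for no benefit. Tapers come from the classical symmetric
tridiagonal operator that commutes with the spectral concentration kernel,
so even at N = 800 they cost one well-conditioned eigendecomposition
(cached per (N, NW, L)).

**Decision-directed Wiener filtering** tracks the prior SNR
`xi_hat = alpha_dd * xi_prev + (1 - alpha_dd) * max(gamma - 1, 0)` with the
classical `alpha_dd = 0.98`, gain `H = xi_hat/(xi_hat + 1)`, and
`xi_prev = H^2 * gamma` after filtering. Frames are classified sound/noise by
the energy detector below; on noise frames the noise statistics are updated
by exponential averaging (`lambda_d <- 0.9*lambda_d + 0.1*|Y|^2`). Two
readings of the update rule are possible (update on "segment" or
"non-segment" frames); updating on **noise-only** frames is the standard one
and is what a noise tracker is for, so that is implemented. The
decision-directed estimator needs a few frames to converge, which leaves
warm-up noise at the start of the output; `trim_leading_transient()` removes
the span covered by the NIS preamble frames (`NIS*hop + N - hop` samples)
from both the output and the reference before recomputing metrics. Since the
clean reference is silent there, trimming removes error energy only and can
never lower the SNR.

**Sparse decomposition (GA-OMP)** cuts the waveform into non-overlapping
256-sample frames and approximates each with at most 30 or 50 Gabor atoms;
the approximant is kept as signal, the residual discarded as noise. The
dictionary is the standard dyadic discretization: scale `s = 2^j`
(`1 <= j <= 8`), translation `mu = p*s/2`, frequency `v = k*pi/s`, phase
`omega = i*pi/6` (`0 <= i <= 12`); atoms are Gaussian-windowed cosines,
explicitly renormalized to unit norm because the continuum factor
`1/sqrt(s)` does not normalize a sampled atom. Genes whose sampled atom is
identically zero (`v = 0` with `omega = pi/2` or `3*pi/2`) are flagged
invalid. Atom selection maximizes `|<residual, atom>|`; orthogonal updates
re-solve the least squares on all selected atoms, so the residual norm is
non-increasing and the energy splits exactly between approximant and
residual. The full dictionary for N = 256 (106,496 atoms, ~218 MB as a dense
matrix) is built once per session and cached; inner products run only over
each atom's Gaussian support window.

The genetic atom search uses an integer chromosome `(j, p, k, i)`,
tournament selection (size 2), single-point crossover (0.8), per-gene
uniform mutation (0.1), elitism (2), population 40, 30 generations. Two
additions were necessary in practice: the fitness surface over the gene grid
is highly multimodal, and a plain GA with this budget stalls in a wrong basin
on roughly a third of random residuals. The search therefore (a) reseeds all
non-elite individuals whenever the best fitness stagnates for three
generations, and (b) finishes with a hill climb of the best-ever gene over
its local neighbourhood (translation and frequency within two grid steps, all
13 phases). With these, the GA reaches at least 0.9 times the exhaustive
maximum on over 90% of random residuals at N = 32 while evaluating about 1%
of the N = 256 grid per selection.

## Segmentation, features, classifiers

**Endpoint detection** thresholds per-frame energy at 1.5 times the mean
preamble frame energy. The threshold base is the *mean* over the NIS
preamble frames rather than a single frame — a single-frame base is fragile
under impulsive noise. Runs above threshold separated by gaps of at most 2
frames are merged; runs shorter than 3 frames are dropped. Frame boundary
conventions are inclusive-inclusive on both ends: a call occupying frames
10-55 yields 46 feature rows.

**MFCCs**: pre-emphasis 0.97, one-sided power spectrum, 26 triangular
filters equally spaced in mel (2595*log10(1 + f/700)) between 20 Hz and
16 kHz, log with a 1e-10 floor, orthonormal DCT-II keeping coefficients
1-13. "1st to 13th" is read as excluding the 0th (energy) term, which makes
the static coefficients invariant to overall amplitude scaling. First and
second differences use regression deltas over +/-2 frames with replicated
edge padding, giving 39 dimensions.

**Classifier protocol**: per repeat, a stratified 70/30 split (the split
ratio is this package's choice),
kNN with k = 5 (majority vote, Euclidean) and a 100-tree random forest under
fixed defaults, accuracy = correct/total on the test rows, averaged over 10
seeded repeats.

Note a deliberate quirk of the signal angle inherited from the evaluation
design: RMSE compares the signal before and after filtering, *not* against
the clean reference. A filter that changes the signal least gets the best
RMSE, so RMSE rewards conservatism; SNR against the clean reference is the
fidelity measure.

## Numerical choices and degenerate inputs

* Noise PSDs and posteriors are floored (`lambda_d >= 1e-12`); gains are
  clamped non-negative; `Py = 0` bins get gain 0.
* The prior-SNR innovation `gamma - 1` is floored at 0.
* OLA division is floored at 1e-12 (irrelevant for the default COLA pair).
* Zero frames return empty sparse approximations; zero-energy clean signals
  make a finite target SNR undefined and raise an error; a scene with no
  events keeps its noise at a nominal RMS of 0.05.
* Exhaustive atom selection breaks ties toward the lexicographically first
  gene; the all-zero residual returns the first gene with fitness 0.
* Duplicate GA selections inside OMP are skipped (they consume an iteration;
  the least-squares fit is unchanged).

## Known limitations

* The synthetic classes are constructed to be separable; recognition-angle
  accuracies near 100% say the pipeline is wired correctly, not that field
  recordings would classify this well.
* The fan-hum noise is ~91% tonal by construction. A spectrally sparse noise
  is partially *representable* by Gabor atoms, which caps how much sparse
  decomposition can remove; negative SNR outcomes are an expected failure
  mode of sparse denoising under sparse noise. On these
  fixtures the sparse means land slightly below the 0 dB input, dragged down
  by flap-containing scenes (the broadband click train competes with the
  tones for the atom budget).
* The 3-frame amplitude smoothing of improved spectral subtraction removes
  noise better than the basic method (about half the residual energy on
  noise-only input) but smears frame-scale transients; on the synthetic
  scenes, whose crow chirps and 25 ms flap clicks are exactly frame-scale,
  the distortion dominates and the improved variant scores *below* the basic
  one in mean SNR — the opposite of what longer, smoother real calls under
  broadband noise tend to show. Both methods are implemented
  exactly as their equations are printed; the inversion is a property of the
  fixture, and is reported rather than tuned away.
* The package makes no claim about absolute SNR/RMSE/accuracy values on any
  particular farm recording; those depend on recording conditions and tuning
  constants (a, b, alpha, beta, L, NW, N, hop), and no public reference
  recordings exist for this task. What the package delivers is the
  *structure* of the two-angle evaluation, on fixtures it fully controls.
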