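---
title: "Detecting electrosurgical cautery states from current-sensor packets"
author: "esusense authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting electrosurgical cautery states from current-sensor packets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esusense)
```

## The problem

In computer-assisted and navigated surgery it matters *when* an activated
electrosurgical tool touches the patient — the *energy event*. A navigation
system that knows the exact start and end timestamps of each incision can
attach downstream sensor readings (for example intra-operative mass
spectrometry of the surgical smoke) to spatial positions. The generator
(ESU) itself is a closed commercial device, so the practical observable is
the current induced in the cautery leads, picked up by a non-invasive clamp
sensor and digitized in 50 ms packets of 3900 voltage samples (an effective
78 kHz sampling rate at 20 packets/s).

At any moment the cautery is in one of five states: `off`, `cut_air`,
`coag_air`, `cut_tissue`, `coag_tissue` (codes 0–4; the two `*_tissue`
states are the energy events). An incision starts at a transition from
off/air into a tissue-contact state and ends at the reverse transition. The
package also infers the generator's power setting (30/35/40 W), which is
read off while the blade is in air — surgeons activate the tool before
touching tissue, and rarely change the level mid-operation.

## The pipeline

Each packet is reduced to spectral features:

1. **Magnitude spectrum.** Real-input FFT of the 3900 samples, no window
   function, no detrending — 1951 bins from DC to the 39 kHz Nyquist. No
   window is applied because the discriminating structure is a handful of
   strong, stable carriers, not closely spaced weak lines; the rectangular
   window also keeps the analytic test cases exact.
2. **200-band downsampling.** The `[0, Nyquist]` range is cut into 200
   equal-width intervals; each band is the *mean* of its 9–10 member bins
   (a mean rather than a sum, so bands with 9 and 10 bins are comparable).
   The DC bin stays inside band 1: off-state discrimination rests on the
   noise level, and is unaffected.
3. **Peak features.** The maximal band magnitude and the center frequency
   of the band attaining it (ties broken toward the lowest frequency). This
   2-D pair is the primary feature set (`"peak"`).
4. **Principal components (`"pc5"`).** Alternatively, the first five
   principal components of the banded spectrum — mean-centering only, no
   variance scaling. The PCA is fitted on the *training* rows of each
   cross-validation fold and frozen; validation rows are only projected.
   Fitting per fold costs a little statistical efficiency but removes any
   possibility of information leaking from validation spectra into the
   feature basis. Peak features are likewise taken from the 200-band
   spectrum (not the raw bins) so both feature families see the same
   representation.

Two classifiers are supported with library-default hyperparameters: an
RBF-kernel SVM (`e1071`) and a 100-tree random forest (`randomForest`).
Features are z-scored with training statistics before either model — the
RBF kernel is scale-sensitive and peak frequencies (~10^4 Hz) would
otherwise dominate intensities; forests are scale-invariant, so the shared
standardization is harmless there. The energy-level model is trained per
device, on air-state packets only, with the wattage as the label.

## From predictions to events

Per-packet predictions are smoothed by a *causal* majority vote over the
trailing `window` packets: real-time notification cannot consult future
packets. Ties keep the previously emitted label (suppressing spurious event
edges from oscillating predictions); a tie on the very first packet
resolves to the lowest class code. Events are maximal runs of
tissue-contact states; a direct `cut_tissue`↔`coag_tissue` switch closes
one event and opens another, preserving per-mode bookkeeping; a stream
ending mid-contact yields an event flagged `truncated`.

A trailing vote reacts to a true transition only when the new state reaches
a window majority — a fixed group delay of `floor((window - 1)/2)` packets.
`streamDetect()` compensates this known delay when timestamping events, so
with accurate per-packet predictions the reported boundaries land within
one packet of the truth while detection itself stays causal. The default
window of 20 packets (1 s) matches the rate at which downstream mass
spectrometry consumes labels, but 20 packets is also the length of a
typical 1 s incision, which a vote that long can swallow entirely; event
detection therefore treats the window as a tunable and tests use windows no
longer than half the expected incision.

## The synthetic protocol

No public recordings of the original bench protocol exist, so the package
ships a seeded simulator that emulates the acquisition design: two device
profiles × three powers (30/35/40 W) × three tissues (chicken, porcine,
bovine) = 18 tissue set-ups, incision streams in both modes, and per
device × power two disjoint pools ("train"/"validation") of off/air
packets. Off/air waveforms do not depend on the tissue sample, so those
packets carry no tissue attribute; the two pools, generated under
independent sub-seeds, are what lets tissue-grouped folds keep air packets
disjoint between training and validation. All sub-seeds are derived by
hashing the set-up coordinates with the top-level seed, so any subset of
the protocol regenerates identically.

Waveform shapes follow the qualitative physics of ESU output: cut mode is a
continuous sinusoid at a device-specific carrier; coagulate mode is the
same carrier gated into bursts (duty cycle ~0.35–0.40 at ~100 Hz
repetition); `off` is sensor noise alone. Amplitude scales with
`sqrt(power/30)` — power goes as current squared, and only the monotone
ordering matters. Tissue contact multiplies amplitude by a mode-specific
contact gain and adds a tissue-dependent second harmonic.

All numeric constants are package-defined surrogates (real ESU fundamentals
near 400 kHz lie far above the modeled digitizer's 39 kHz Nyquist), chosen
once to reproduce the *class geometry* the detection problem actually has:

* the two devices occupy disjoint carrier ranges (6/10 kHz vs 15/18 kHz)
  and clearly different amplitudes (1 V vs 2.5 V), so models do not
  transfer across devices — cross-device folds are expected to collapse;
* the cut contact gain (1.35) exceeds the 30→40 W amplitude span
  (`sqrt(40/30)` ≈ 1.155), so leave-one-power-out folds remain separable,
  yet it is by far the smallest contrast in the geometry — per-device
  intensity ranges are disjoint for every class pair *except*
  (`cut_air`, `cut_tissue`), making that the hardest pair, the one that
  dominates residual confusion;
* carriers are multiples of the 20 Hz bin spacing (sinusoids land on exact
  FFT bins, so peak magnitudes are phase-invariant) and second harmonics
  stay below Nyquist.

What the simulator does *not* model: electromagnetic interference,
grounding-pad placement, sensor-to-generator distance, patient tissue
variability, or the ~400 kHz physical fundamentals. Passing tests therefore
demonstrate that the pipeline recovers the documented class geometry from
packetized spectra — not that any particular accuracy would be attained on
new hardware.

## Validation design

`buildFolds()` constructs eight leave-one-group-out folds — one per tissue,
power and device; "8-fold cross-validation" here means eight grouped
leave-out experiments, not eight random partitions. Tissue folds validate
on the held-out tissue's contact packets plus the validation air pool and
train on the rest plus the training air pool; power and device folds
validate on every packet of the held-out group. Axis averages are
unweighted means of their folds' accuracies, and the headline *grand mean*
averages the eight tissue-axis and power-axis cells over
{SVM, RFC} × {peak, pc5} — the device axis is reported separately as a
documented failure mode rather than folded into the headline. Energy-level
evaluation trains on the "train" air pool and reports one accuracy per
device on the disjoint "validation" pool; there is no fold axis. No
significance procedures are applied — the harness reports raw accuracies
and confusion matrices (class order fixed to codes 0–4).

## Problem sizes and numerical choices

The default `ProtocolSpec` runs 12 incisions per mode per set-up with 10
packets (0.5 s) per incision and 120 air packets per state per pool — 8640
packets in all, a desk-scale rendering of the original bench protocol
(which used 120 incisions of ~1 s) that preserves every structural element:
all 18 set-ups, both modes, all five states, disjoint air pools. A full
simulate → featurize → cross-validate → summarize cycle takes on the order
of a minute.

Degenerate inputs are rejected rather than patched: packets of the wrong
length, tissue names on air packets, energy training rows that are not
air-state, single-class training sets, folds whose group is absent. Ties in
the peak search take the lowest frequency; ties in the majority vote hold
the previous label. Features with zero training variance are left unscaled
(standardization divides by 1) so constant columns cannot produce NaNs.

## Known limitations

* The simulator's class geometry is favorable by construction; real
  recordings would add interference and drift the package does not model,
  and reported synthetic accuracies are ceilings, not forecasts.
* Cross-device transfer genuinely fails (by design, mirroring the distinct
  waveforms of different generator models); per-device models are the
  supported configuration.
* The energy-level classifier assumes the power setting is one of the three
  trained wattages; intermediate settings map to the nearest trained class.
* Only the live-electrode channel is simulated and analyzed; a return
  channel would be a mirrored, attenuated copy and is not modeled by
  default.
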