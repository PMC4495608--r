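---
title: "Topographic SSEP analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic SSEP analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic data emulate (and do not), and the places
where the design was genuinely open and a choice had to be committed.

## The analysis problem

A somatosensory evoked potential recorded over the whole scalp is not one
waveform but a spatiotemporal field. Its informative structure is a short
sequence of quasi-stable scalp topographies — component maps — separated
by rapid transitions; each map reflects a distinct configuration of active
intracranial generators. The pipeline characterizes this sequence in four
steps: average the trials into a clean evoked field; cluster the
grand-average maps into K templates; fit the templates back to individual
sessions and quantify each map with eight parameters; and estimate the
underlying current-density distribution with a distributed linear inverse.

All topographic math is reference-independent because every map is
average-referenced first. Three primitives carry the whole chain:

* **GFP** (global field power): the spatial standard deviation across
  electrodes of the average-referenced map, in µV, with the population
  (divide-by-*n*) convention. The divide-by-*n* choice is internal-only:
  every consumer (GEV, clustering weights) uses GFP ratios or GFP² in both
  numerator and denominator, so the convention cancels; it is fixed and
  asserted against a naive implementation in the tests.
* **SC** (spatial correlation): the cosine of the angle between two maps.
  SC is *signed and polarity-sensitive everywhere* in this package. The
  resting-state microstate literature usually ignores polarity; here the
  evoked sequence contains a genuine voltage inversion between the last
  two maps, which must remain two distinct states, so the polarity-ignoring
  convention would be wrong for this problem.
* **GEV** (global explained variance): the GFP²-weighted fraction of map
  variance explained by the assigned templates. Per-map GEVs partition the
  total by construction.

## Preprocessing

Defaults (all in `default_config()`): band-pass 8–300 Hz, optional 50 Hz
notch, epoch window −100..+200 ms (a superset of every analysis window,
including the inverse stage's 100 ms baseline and 0–200 ms post-stimulus
interval), rejection threshold 100 µV, baseline −80..−30 ms. Time is in
milliseconds with stimulus onset at 0; windows are half-open `[t0, t1)`
and frame 1 is the first epoch sample. The pipeline order is fixed:
filter → epoch/reject → average → baseline → average reference.

Filter realization is a committed numerical choice: zero-phase
(forward–backward) filtering so component latencies are preserved, with
the band-pass built as a cascade of a 2nd-order Butterworth high-pass and
a 4th-order low-pass. A single high-order band-pass recursion with an
8 Hz edge at a 5 kHz rate (0.3 % of Nyquist) is numerically fragile; the
cascade is robust and meets the same band spec. The notch is an RBJ biquad
at 50 Hz with Q = 35, also applied forward–backward. Note that zero-phase
filtering guarantees no *delay*, but reshaping an asymmetric peak can
still move its argmax by a fraction of a millisecond; the latency-
preservation guarantee is therefore stated (and tested) for symmetric
peaks.

Rejection is automated and strictly greater-than 100 µV (a trial peaking
at exactly 100.0 µV is kept — an arbitrary but fixed boundary convention).
The original protocol added a visual screening step whose criteria were
never specified; it is deliberately not guessed at, and a user-supplied
trial mask can stand in for it (`kept` mask on the epoch set).

## Segmentation

The modified K-means maximizes GEV with polarity-sensitive assignment:
frames go to the template with the highest signed SC, and each template is
recomputed as the GFP-weighted mean of its frames, renormalized to unit
GFP, until the labeling stops changing. 100 restarts from K random frames
are the default; the best restart by total GEV wins, ties to the lower
index, and everything is seeded and bit-reproducible. Empty clusters are
re-seeded from the worst-explained frame.

Post-processing applies, in a fixed order (the order was unspecified in
the protocol this follows; absorption–merge–reabsorption is committed
here): (1) labeled runs shorter than 2 frames (0.4 ms at 5 kHz) are
reassigned frame-wise to the neighboring run whose template correlates
better; (2) template pairs with signed SC > 0.92 are merged by
GFP-weighted averaging until no pair qualifies. The merge threshold is
interpreted on the *signed* SC, consistent with polarity sensitivity: two
maps that are inverses (SC = −1) are never merged.

Model selection offers two criteria on the within-cluster dispersion
W(K) = Σ_t (‖v_t‖² − (u_{L(t)}ᵀ v_t)²):

* Krzanowski–Lai: KL(K) = |DIFF(K)| / |DIFF(K+1)| with
  DIFF(K) = (K−1)^{2/p} W(K−1) − K^{2/p} W(K), p = number of electrodes;
  maximized over interior K.
* Cross-validation: CV(K) = σ̂²_K ((p−1)/(p−1−K))² with
  σ̂²_K = W(K)/(T(p−1)); minimized.

The cited criteria are named but not restated in the source protocol;
the formulas above are the committed implementation (an open question was
whether the reference software normalizes W by cluster size — both
variants give the same argmax on well-separated synthetic data, and the
unnormalized form is used). W(K) is measured after post-processing, so it
is only non-increasing up to restart/post-processing noise; the tests
allow 5 % slack. The criteria are indexed by the *requested* K; the
effective K after merging is reported alongside.

## Back-fitting and statistics

Back-fitting labels each frame of an individual session with the
highest-SC template, with *no* temporal smoothing, and rejects (to
unlabeled, without reassignment — unlike the segmentation absorption rule,
because the fitting protocol says "rejected") contiguous runs of ≤ 2
frames. Eight parameters are computed per map; duration is *total* labeled
time rather than the longest run (the protocol is silent; total time is
committed and documented). Mean SC uses signed SC, consistent with the
rest of the package.

Successive-map latency comparisons use a Shapiro–Wilk gate at α = 0.05 per
group (no normality test was named in the protocol); both-normal pairs get
an unpaired pooled-variance t-test, otherwise a Mann–Whitney U test.
Because latencies are quantized to the frame grid, ties are ubiquitous and
the normal-approximation Mann–Whitney p-value cannot fall below the
Bonferroni threshold even for perfectly separated small groups; for small
samples the exact permutation distribution of the rank sum is enumerated
instead (≤ 2·10⁵ combinations), which handles ties correctly. The
significance threshold is the protocol's literal "0.01 Bonferroni-corrected
by the number of electrodes" (0.01/33), applied to latency comparisons even
though the electrode count is unrelated to the number of latency tests —
this puzzling but explicit rule is implemented literally, with the divisor
exposed as an argument.

Group comparisons (8 parameters × K maps, and electrode × frame amplitude
maps) are two-tailed unpaired pooled-variance t-tests with the same
corrected threshold; zero-variance cells are flagged and never declared
significant. The classical component comparison (brainstem and cortical
peak amplitude/latency on role electrodes and the GFP) uses p < 0.01
uncorrected, mirroring the 8-test classical analysis. The phrase "two
two-tailed t test" in the source description is read as a typo for a
single two-tailed test per cell.

## Head model, forward solution and inverse

The head is three concentric spheres — scalp 100 %, outer skull 78 %,
inner skull/brain 68 % of a 40 mm scalp radius (a nominal macaque head) —
with relative conductivities 1 / 0.05 / 1. The forward solution is the
analytic series for a dipole in a layered sphere: per spherical-harmonic
order the radial solution in each layer is matched at the interfaces
(potential and radial current) and the scalp surface (zero current),
giving a per-order transfer factor; the series is truncated at order 60,
far past convergence for sources inside the brain shell (verified to
1e−6 against order 200, and to 1e−10 against an independently derived
generating-function closed form in the homogeneous limit). The original
"locally adapted spheres" refinement needs individual anatomy; on a
spherical cap it reduces to radial projection of the electrodes onto the
scalp sphere, which is what is implemented — a stated simplification, not
an equivalent.

The simulator and the inverse module share this one forward routine, so
forward/inverse consistency is structural rather than asserted.

The source space is a cubic grid (node at the head center) intersected
with the open brain sphere, spacing searched to approach 3000 points;
neighbors are 6-connected. The inverse is a LORETA-style smoothness-
penalized minimum norm: T(α) = W⁻¹Kᵀ(KW⁻¹Kᵀ + αH)⁺ with W = (BᵀB) ⊗ I₃,
B = 6I − A the discrete Laplacian-like operator (boundary rows keep the
full diagonal with fewer neighbors — no ghost points — which keeps B
strictly diagonally dominant and W invertible), and H the average-
reference centering operator. Orientations are unconstrained (3
components per source); the reported CD is the per-source Euclidean norm,
in nominal mA/mm³. Thirteen α values are log-spaced over [1e−4, 1e2] ×
the mean eigenvalue of KW⁻¹Kᵀ — the count follows the protocol, the grid
itself is a committed choice since the original values were never listed.
"Regularization according to the noise level" is operationalized as GCV
over the grid, with a fixed-index override.

Source statistics follow the protocol literally: per source and per
post-stimulus frame (0–200 ms), a paired t-test across single epochs
between that frame's CD and the epoch's mean CD over the 100 ms
pre-stimulus baseline, two-tailed, p < 0.05 *uncorrected*; t-values are
then averaged over each component map's frames, and the masked output
keeps significant cells only. Whether the original analysis inverted
single epochs or sub-averages was ambiguous ("across all the epochs");
single epochs are used here. Note the single-trial inverse at full
resolution is memory-hungry (epochs × sources × frames); the analysis
driver therefore runs the epoch-level statistics on a reduced grid
(~800 sources at 1 kHz), while evoked-level CD maps use the full ~3000.

## The synthetic data: what it emulates and what it does not

No recordings of this preparation were ever deposited, so the simulator
defines the study conditions. It emulates: 5 kHz sampling; 0.5 Hz
stimulation for 3 minutes (90 stimuli, with one second of silent pre-roll
so the first epoch fits); a scripted microstate sequence whose boundaries
are the published component-map extents (median: 6 / 12.8 / 15.2 / 25.6 /
50 ms; tibial: 10.8 / 16.4 / 29.2 / 60 ms, the interior tibial boundaries
rounded to the frame grid from the reported onset latencies); templates
generated by stylized dipole placements in the same head model (deep
posterior for the brainstem-like state, contralateral parietal/frontal
for the cortical states, a polarity reversal between the last two) — not
anatomically validated; per-state raised-cosine GFP envelopes peaking near
the classical component latencies (≈6.9 ms brainstem, ≈17.9 ms cortical)
on a 30 % floor, because a real GFP waveform does not drop to zero between
components; trial-level white sensor noise, spatially correlated brain
background (random interior dipoles with AR(1) time courses), latency and
amplitude jitter, optional 50 Hz line interference, and square-pulse
artifact trials on 3 random channels; and per-session cap rotation
(|angle| ≤ 3°, SD 1.5°) with templates re-derived from the planted dipoles
on the rotated cap.

No quantitative single-trial SNR was ever published, so the noise
defaults are the package's own calibration: they are chosen so that the
*session-level* stability surface after ~80-sweep averaging (mean per-map
SC ≈ 0.85–0.96, onset-latency SDs of one or two tenths of a millisecond,
total back-fit GEV ≈ 92–95 %) matches the stability reported for real
repeated sessions of this preparation. They are defaults of the
generator, not measurements of it.

What the synthetic data do *not* contain — and hence what passing tests
cannot show about real data: realistic macaque head geometry or a skull
defect (the craniotomy comparison is exercised as two identically
generated session groups, i.e. as a null); physiological artifact
structure (ocular, muscle, cardiac); non-stationary anaesthesia depth;
electrode impedance drift; or any deviation of real generators from the
three-shell sphere. Recovery results therefore validate the *algorithms*,
not the anatomical accuracy of source localizations.

## Numerical and interface choices

* Configs are YAML (flat keys, human-editable, diff-friendly); file I/O is
  EDF (minimal 16-bit writer/reader with events in a trigger channel and
  the exact sample count in the reserved header field) or delimited text
  with a JSON sidecar. Every writer/reader pair is lossless up to the
  declared precision (0.1 µV for EDF, text precision otherwise).
* Every randomized routine takes a seed and is bit-reproducible; the
  multi-session generator derives per-session seeds below 2³¹.
* Zero-GFP frames are unlabeled everywhere; zero-norm maps make SC error
  out explicitly rather than return NaN.
* Ties in frame assignment go to the first (lowest-index) template;
  restart ties to the lower restart index.
* Problem sizes in the test suite are the package's own validation
  choices: segmentation recovery uses 20 seeded grand averages at GA-level
  SNR 10, stability uses 9 sessions of 90 trials, null calibrations use
  100–1000 seeded replicates, and inverse validation uses 700–800-point
  grids (10 planted dipoles) with a 200-epoch null for the source
  statistics.

## Known limitations

* The builtin 33-electrode layout is a 10-10-inspired approximation; the
  true cap coordinates were never published.
* The spherical head and unconstrained orientations make localization
  low-resolution by design; distributed inverses smear focal sources over
  many grid points (visible in the analysis drivers as large significant
  clusters around the true dipole).
* K-selection criteria are evaluated on the requested K after
  post-processing; on data where merging is common the KL curve can be
  noisy.
* The published headline numbers of the original study (e.g. a 97.33 %
  GA segmentation GEV, Table-level latencies) depend on undeposited animal
  recordings; this package reproduces the *procedures* and validates them
  on ground-truthed synthetic data of matched difficulty, where the
  analysis drivers print closely comparable values (e.g. ~99 % GA GEV,
  ~95 % mean session GEV for the median script).
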