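---
title: "Virtual dense hemispherical arrays: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual dense hemispherical arrays: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

3D photoacoustic tomography needs detectors all around the object; a
hemispherical array maximizes the angular aperture and avoids the
limited-view problem for vessels running in arbitrary directions.  Practical
hemispherical arrays are *sparse* (hundreds rather than tens of thousands of
elements), and sparse-aperture universal back-projection (UBP) produces
curvilinear streak artifacts, exactly as a filtered back-projection CT image
degrades with few projections.  `hemipa` implements a densification strategy
that exploits the regularity of the golden-ratio (Fibonacci) hemispherical
lattice: the array decomposes into three families of *spiral chains*, virtual
sensors are placed between chain-adjacent real sensors, their signals are
estimated by interpolation along each chain (linear baseline, or a trained
convolutional network), and the volume is reconstructed from the combined
real + virtual channel set.

# Array geometry

Sensor $i$ of a Fibonacci hemisphere of radius $R$ sits at

$$x_i = r_i \cos(2\pi i/G), \quad y_i = r_i \sin(2\pi i/G), \quad
  z_i = z_1 + (i-1)\,d_z, \quad r_i = \sqrt{R^2 - z_i^2},$$

with $G = (1+\sqrt5)/2$.  The reference device has $R \approx 60$ mm and 512
channels; nominal indices 7 and 20 are unpopulated (a water-handling hole
next to the illumination hole) and two replacement sensors occupy indices
513 and 514.

`z1` and `dz` are device calibration constants that are not published.  The
package defaults place the 514 nominal indices uniformly between $-0.99R$
(leaving the illumination hole free) and $-0.05R$ (just below the equator).
Both are ordinary configuration fields, so the true values can be
substituted; every integer property used downstream (chain lengths, sensor
counts, pattern sizes) is independent of this choice.

Adjacent points of a Fibonacci lattice at index intervals equal to Fibonacci
numbers are spatial neighbours, which is why the lattice visually decomposes
into spiral families.  For this lattice size the three usable families sit at
intervals 34 (direction 1, tightest spacing), 21 (direction 2) and 13
(direction 3); they play the role of the vertical/horizontal/diagonal
directions of a grid array.  A chain is one residue class modulo the
interval, ordered from the hemisphere bottom outwards.  Because 514 is not a
multiple of any of these intervals (and two indices are missing), chain
lengths differ; each direction is truncated to its minimum chain length —
14, 23 and 38 for the device — so one fixed-size interpolator per direction
suffices.  The truncation means the most peripheral sensors of longer chains
get no virtual neighbours, which is acceptable because the imaging region
sits near the hemisphere centre.

Virtual sensors are placed at the half-ordinal points of a natural cubic
spline through each truncated chain's coordinates (ordinal parameterization
0, 1, 2, …; evaluation at $k + 1/2$).  Two choices here were genuinely open:

* **Radial renormalization.** A spline midpoint falls slightly inside the
  sphere; we renormalize each virtual coordinate onto radius $R$ so that the
  whole dense array is a true spherical aperture (UBP assumes the detection
  surface).  The correction is sub-micrometre for the device geometry.
* **No merging.** Virtual sensors from different directions are kept
  distinct even where they nearly coincide; the dense array therefore has
  exactly $512 + 34{\cdot}13 + 21{\cdot}22 + 13{\cdot}37 = 1897$ channels,
  about four times the real count.

# Forward model

The simulator exists so that training data and ground-truth virtual signals
can be produced for arbitrary phantoms; no measured data are required
anywhere in the package.

* **Spherical absorber.** A uniform sphere of radius $a$ and initial
  pressure $p_0$ radiates the classical N-wave; at distance $r$,
  $p(t) = p_0 (r - ct)/(2r)$ for $|r - ct| \le a$ and zero otherwise.  The
  peak is $p_0 a / (2r)$ and the time integral vanishes.  Support-window
  edges are included with a $10^{-9}$-sample guard so that sensors exactly
  equidistant from an absorber receive bit-identical signals.
* **Cylindrical absorber.** Discretized as a train of spheres along the axis
  (sphere diameter = cylinder diameter, axial step $\le c/(4 f_\mathrm{max})$,
  a quarter of the shortest resolvable wavelength), with amplitudes scaled so
  the total absorbing volume is conserved.  Halving the step changes
  band-limited signals by well under 1% RMS (tested); a closed-form
  cylindrical Green's function is deliberately out of scope.
* **Sound speed.** Never stated by the device description; water coupling is
  implied, so $c = 1500$ m/s, exposed as an argument everywhere.
* **Transducer response.** Only the centre frequency (3.5 MHz) and the −6 dB
  fractional bandwidth (90%) are known.  A plain Gaussian amplitude response
  with those parameters has a DC gain of ≈ 0.033, which a piezoelectric
  receiver does not have.  We therefore use the odd-symmetrized Gaussian
  $H(f) = g(|f|-f_c) - g(|f|+f_c)$: exactly zero at DC, unit gain at $f_c$
  and 0.5 at $f_c(1 \pm 0.45)$ to better than 1%.  Filtering is zero-phase
  in the frequency domain with power-of-two zero padding.
* **Noise calibration.** Noise is i.i.d. Gaussian with standard deviation
  30 dB below "the signal amplitude after bandwidth limitation from an
  absorber with $p_0 = 100$ at the hemisphere centre".  Amplitude is read as
  the *peak* of the band-limited trace, and the reference absorber (whose
  size is unstated) as a 1.0 mm sphere, matching the evaluation phantom's
  vessel diameter.  Both are configuration fields.  This reading makes the
  added noise small relative to sparse-aperture artifacts in the
  reconstructed volume — see "Known limitations" below.

The acquisition window is 1792 samples at 60 MHz starting 1500 samples after
the laser pulse: just enough to cover flight times from the $[-12, 12]^3$ mm
reconstruction region to all sensors.  Wavefronts from absorber parts
outside that region may arrive after the window closes and are truncated,
exactly as in the real device.

# Patterns and the interpolator network

Gathering the traces of one chain into a (members × samples) image yields a
smooth "signal pattern"; interpolating virtual rows is a 1D problem along
the chain, repeated per direction — this is what makes the method tractable
(a 3D network over the whole aperture is not).  The network input is the
linearly interleaved pattern (inserted rows = arithmetic mean of their
neighbours), used only to make input and output sizes equal; the target is
the noise-free ideal pattern with the true virtual rows.

The architecture follows the published constants where they exist: 7 × 77
kernels (sensor × time), 64 filters, shared input/output size per direction
(27/45/75 × 1792), ReLU activations (reading the source's "LeRU" as a
typographical variant), a linear regression output layer, and skip
connections.  Choices the description leaves open, fixed here and exposed in
`cnn_config()`:

* **Depth**: 8 convolutional layers, skip connections every 2.
* **Global input skip**: the output layer is zero-initialized and the input
  is added to the output, so an untrained network is exactly the identity on
  its input (the linear-interpolation baseline).  Training can only improve
  on that baseline on the training distribution, and the identity gives a
  clean degenerate-mode test.
* **Loss**: mean squared error, matching the regression output.
* **Normalization**: one global constant — the noise-calibration reference
  amplitude — divides inputs and targets, so a $p_0 = 100$ absorber maps to
  $O(1)$ values.
* **Solver**: resilient backpropagation with learning rate $10^{-5}$ as the
  initial step size, 50 epochs, mini-batches of 50/100/150 per direction.
  The variant is iRprop⁻ (sign-based step adaptation, update skipped after a
  sign flip) with the standard $\eta^+ = 1.2$, $\eta^- = 0.5$ constants;
  mini-batch Rprop is unconventional but follows the published setup.
* **Validation split**: held-out *phantoms* (10%), not held-out patterns, so
  no chain of a validation phantom leaks into training.

The convolution forward/backward passes and the training loop are
implemented from scratch in C++ (no deep-learning backend is assumed);
gradients are verified against central finite differences in the test suite.

Full-scale training — 1000 random phantoms, 34 000/21 000/13 000 patterns,
roughly a month of GPU time in the original study — is representable in the
configuration but is not run anywhere.  The tested, reduced-scale stand-in
is a 40-channel hemisphere ($R = 20$ mm, one spiral direction at interval 8,
9 × 256 patterns, 4 filters, 5 × 13 kernels, 20 phantoms, 25 epochs, a few
minutes of CPU).  At that scale the trained interpolator must — and does —
strictly beat the linear baseline in held-out virtual-signal correlation and
MSE and in reconstructed volume S/N.  A green reduced-scale test establishes
that the training machinery learns something transferable; it does *not*
reproduce the full-scale correlation of 0.933 or the 23.7 dB table entry,
which are out of desk-scale reach by design.

# Reconstruction

* **Inverse filter**: zero-phase gain $\mathrm{LPF}(f) / \max(H(f),
  1/\text{gain\_cap})$.  The low-pass (5 MHz cutoff) is a zero-phase
  Butterworth-style magnitude $1/\sqrt{1 + (f/f_0)^{2n}}$ with $n = 40$,
  giving > 60 dB attenuation at 1.2× the cutoff; the cap (default 100)
  bounds the amplification where $H \to 0$ (both ends of the band).  The
  spectral region between the cutoff and 1.2× the cutoff is necessarily a
  transition band; stop-band assertions are made at ≥ 1.2× cutoff.
* **UBP**: the Xu–Wang term $b(t) = 2p(t) - 2t\,\mathrm{d}p/\mathrm{d}t$
  (central differences; $t$ includes the acquisition offset) back-projected
  at the voxel–sensor flight time with linear interpolation in sample space.
  Element areas are unpublished, so solid-angle weights are uniform
  ($2\pi/N$), exposed as an argument.  Voxels whose flight time leaves the
  recorded window receive zero from that sensor and are counted once in a
  message.
* **Grid**: 0.1 mm voxels match the device's ~0.2 mm resolution for fidelity
  runs; scaled-down evaluation uses 0.3–0.4 mm over $[-12, 12]^3$ mm (the
  absorber placement region plus margin).  The published work does not state
  its reconstruction extents.
* **Intensity convention**: reconstructed initial pressure is physically
  non-negative; the signed UBP output's negative part is back-projection
  residue.  Image statistics (the S/N table) are computed on the intensity
  volume `volume_intensity()` = positive part, which is what a
  photoacoustic system displays and thresholds.  `snr_db()` itself is
  convention-free (it evaluates whatever volume it is given).

# Evaluation

The S/N of a reconstruction of a known phantom is
$20\log_{10}(\text{mean intensity inside the absorbers} /
\text{SD of the background})$.  The background is the guard-banded
complement: voxels farther than `guard` (default 2 mm) from every absorber
surface, so the blurred absorber rim biases neither mean nor SD.  The
published definition states no guard; the default is a judgement call and
sensitivity to it is mild (the rim is a small voxel fraction).  Correlation
fidelity of estimated virtual signals is the Pearson correlation of all
(virtual sensor, sample) pairs against the noise-free band-limited ideal
signals — the same reference the network trains on.

# What the synthetic world does and does not establish

The generator reproduces the published training conditions: counts 1–4 per
absorber class (spheres, short cylinders, long cylinders), diameters
0.2–1.2 mm, $p_0$ 50–100, centres within 10 mm of the hemisphere centre,
cylinder orientations per class, all uniform.  The evaluation phantom is the
fixed three-cylinder model (⌀ 1 mm, length 50 mm, $p_0 = 100$, y-parallel,
centres $(0,-5,-5)$, $(0,0,0)$, $(0,5,5)$ mm).  Overlapping absorbers are
permitted and superpose, as the linearized acoustics implies.

Real tissue differs in ways the generator does not model: meandering and
branching vessels (the published discussion itself notes trained networks
straighten meanders), optical fluence decay with depth, acoustic
heterogeneity, refraction and frequency-dependent attenuation (UBP assumes
none of these), and element directivity.  Green tests therefore validate the
pipeline's internal consistency and the method's artifact-reduction
mechanism, not clinical performance.

A residual quantitative gap is documented rather than hidden: with the peak
/ 1.0-mm-sphere reading of the noise calibration, added sensor noise barely
changes the reconstructed background (artifacts dominate), so the noisy-512
and linear-1897 S/N values land about 2 dB above the published table while
both ideal-signal values match within 0.7 dB and all orderings and the
+6.1 dB densification gain reproduce.  A full-trace-RMS noise reference
would close that gap but has no textual support; we keep the peak reading
and the discrepancy.

# Numerical and degenerate-input choices

* Support-window edges of the N-wave include boundary samples via a
  $10^{-9}$-sample guard (bit-stable for exactly equidistant sensors).
* Zero-phase filters operate on power-of-two FFTs at ≥ 2× the trace length;
  wrap-around is negligible for decaying responses.
* Chains shorter than 3 cannot support cubic-spline virtual placement and
  raise an error naming the chain; patterns need ≥ 2 rows to interleave.
* Provenance tags on signal containers (`ideal_broadband` →
  `band_limited` → `band_limited_noisy` → `cnn_output` →
  `inverse_filtered`) only move forward; stage functions reject
  out-of-order inputs.
* Constant signal sets make Pearson correlation undefined and raise an
  error, as do empty signal/background masks and zero background SD.
* All randomness (phantoms, noise, weight init, batch shuffling) flows from
  explicit seeds through a per-stage splitter (`stage_seed()`), and RNG use
  is local — library calls never disturb the caller's RNG state.

# Known limitations

* Irregularly placed 2D arrays have no chain structure; the method does not
  apply, and extrapolating virtual sensors outside the real aperture is
  explicitly not attempted.
* Full-scale network training is out of scope; shipped tests train
  reduced-scale models only.
* The palm-measurement evaluation protocol (vessel mask from a threshold of
  40, background slab $-15 \le z < -11$ mm) is documented here for
  completeness but untested: it requires proprietary measured data.
* Volumes are exported as R objects plus plain-text PGM maximum-intensity
  projections; no TIFF writer is available in this stack.
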