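---
title: "Simulating and analyzing Mueller polarimetry of ring tissue phantoms"
author: "muellerpol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing Mueller polarimetry of ring tissue phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellerpol)
```

## The measurement model

A transmission Mueller polarimeter prepares six input polarization states
with a polarization state generator (PSG: a rotating polarizer plus an
insertable quarter-wave plate) and projects the transmitted light onto
eight analyzer configurations (PSA: quarter-wave plate plus polarizer),
recording 6 × 8 = 48 intensity frames per field of view. Collecting the
generator Stokes vectors as the columns of a 4 × 6 matrix $W$ and the
analyzer projection vectors as the rows of an 8 × 4 matrix $A$, the frame
intensities at one pixel form the 8 × 6 matrix

$$B = A\,M\,W,$$

where $M$ is the pixel's 4 × 4 Mueller matrix. With $W$ and $A$ of rank 4,
$M = A^{+} B\, W^{+}$ (Moore–Penrose pseudo-inverses); the 48-frame design
is deliberately redundant relative to the minimal 16 frames, which
stabilizes the inversion against noise.

The six generator states are linear 0°, 45°, 90°, −45° plus right and left
circular, i.e. the Stokes vectors $(1,\pm1,0,0)$, $(1,0,\pm1,0)$,
$(1,0,0,\pm1)$. The eight analyzer configurations analyze those same six
states plus two redundant configurations (the 0° and 45° analyzers with
the quarter-wave plate inserted at the alternate orientation). The
instrument literature does not single out a canonical pair of redundant
states; the schedule returned by `idealSchedule()` is an editable list, so
other choices drop in without code changes. Frames are ordered PSG-major /
PSA-minor and the ordering is recorded in the stack metadata.

Sign conventions, stated once and used everywhere: angles are degrees,
counter-clockwise positive looking into the beam; right-circular light is
$(1,0,0,1)$; retarders follow the Lu–Chipman sign convention (a
quarter-wave plate at 0° maps $(1,0,1,0)$ to $(1,0,0,-1)$); Mueller
elements are indexed 1-based with $m_{11}$ top-left.

## Eigenvalue calibration

Real generators and analyzers are imperfect, so $W$ and $A$ are measured,
not assumed. The eigenvalue calibration method (ECM) uses intensity
matrices of reference samples: air $B_0 = AW$ and references
$B_i = A M_i W$. The package generalizes the classical square-matrix ECM
to the overdetermined 8 × 6 geometry through

$$C_i = B_0^{+} B_i = W^{+} M_i W,$$

whose four non-negligible eigenvalues equal the eigenvalues of $M_i$
(similarity up to the rank-4 projector; the remaining two eigenvalues are
structurally zero). Reference transmittances and retardance are
basis-invariant functions of that spectrum and are fitted without knowing
the reference axis angles: a two-transmittance polarizer contributes
$\{q, \sqrt{qr}, \sqrt{qr}, r\}$ and a retarder of transmittance $\tau$
contributes $\{\tau, \tau, \tau e^{\pm i\delta}\}$.

Two numerical points matter in the fit. First, an ideal polarizer
($r = 0$) makes $B_i$ rank-deficient, and the five-fold (near-)zero
eigenvalue of $C_i$ is extremely ill-conditioned under noise
(perturbations scale like $\varepsilon^{1/k}$ for a defective eigenvalue
of multiplicity $k$). The fit therefore reads $q$ from the well-separated
top eigenvalue and $r$ from the noise-stable trace identity
$\operatorname{tr} C_i = (\sqrt q + \sqrt r)^2$, never from the smallest
eigenvalue. Second, kind-consistency checks only flag *large-modulus*
complex pairs: a noisy polarizer's degenerate pair drifts slightly complex
with small modulus, which is harmless, whereas a retarder mislabelled as a
polarizer shows a complex pair at modulus ≈ τ and errors out.

$W$ is then the (one-dimensional) null space of the stacked linear
operator $W \mapsto M_i(\hat\theta_i)\,W - W\,C_i$ summed over all
references, air included — air pins the row space, and any invertible
reference (the quarter-wave plate) reduces the null space to a scalar, so
the solution is unique up to scale, fixed by $W_{11} = 1$. The reference
axis angles are free parameters of standard ECM practice: the first
non-air reference keeps its nominal angle (that choice *defines* the
laboratory frame), the rest are refined by a Nelder–Mead search on the
smallest-to-next kernel eigenvalue ratio, starting from the nominals, and
skipped entirely when the nominals already solve the system to machine
precision (a simplex would only wobble an exact solution). That ratio is
also reported as the calibration residual: 0 for consistent data, growing
monotonically with measurement noise. Finally $A = B_0 W^{+}$, with a
forward consistency check against $B_0$ (5% by default — tight enough to
catch schedule mix-ups, loose enough for percent-level frame noise). A
degenerate kernel (e.g. a single polarizer as the only reference) raises
an explicit ambiguous-calibration error rather than returning one of many
solutions. Any overall intensity gain common to all frames cancels in
$C_i$ and is absorbed into $A$.

Per-pixel calibration (`calibratePixelwise()`) simply applies the global
algorithm at every pixel, with optional box smoothing of the recovered
fields (off by default, since nothing in the model couples neighbouring
pixels). The bench-side null-intensity pre-alignment is recorded as a
metadata flag (`coarse_aligned`), not simulated: it is a physical
alignment step, not an algorithm.

## Polar decomposition and rotation-invariant parameters

Each reconstructed pixel is factorized by the Lu–Chipman polar
decomposition

$$M = M_\Delta\, M_R\, M_D,$$

a depolarizer, a retarder and a diattenuator in that order. The
diattenuation vector is the first row of the normalized matrix
($D = \lVert (m_{12}, m_{13}, m_{14})\rVert / m_{11}$); $M_D$ is built
from it, $M' = M M_D^{-1}$ (pseudo-inverse branch when $D = 1$ exactly),
and the 3 × 3 depolarizer block comes from the matrix square root of
$m' m'^{\mathsf T}$ with the sign of $\det m'$ (ties at $\det \approx 0$
resolved positive, with a warning counter). $M_R = M_\Delta^{-1} M'$.
Scalar maps, all angles in degrees:

* total retardance $R = \cos^{-1}\!\big(\operatorname{tr}(M_R)/2 - 1\big)$
* linear retardance
  $\delta = \cos^{-1}\!\Big(\sqrt{(m_{R,22}+m_{R,33})^2 +
  (m_{R,32}-m_{R,23})^2} - 1\Big)$
* circular retardance
  $\psi = \tan^{-1}\!\big[(m_{R,32}-m_{R,23})/(m_{R,22}+m_{R,33})\big]$
* fast-axis orientation from the retardance vector,
  $\tfrac12\operatorname{atan2}(m_{R,42}-m_{R,24},\, m_{R,34}-m_{R,43})$
* depolarization $\Delta = 1 - |\operatorname{tr} m_\Delta|/3$, with
  linear and circular components
  $\Delta_L = 1 - (|m_{\Delta,11}| + |m_{\Delta,22}|)/2$ and
  $\Delta_C = 1 - |m_{\Delta,33}|$ read from the diagonal of the
  depolarizer block (an eigenvalue-based variant sits behind
  `depol_from = "eigen"`; the diagonal reading is standard for
  near-diagonal depolarizers like this sample and is exact for the
  phantom's construction).

For a product rotator∘linear-retarder these scalar formulas are exact, and
the test suite holds them to ~1e−12 on thousands of seeded random
products. All arccos/sqrt arguments are clipped into range and the clip
events counted per image as a quality metric — note that arccos is
infinitely steep at its endpoints, so even exact-identity pixels carry
~1e−6 degrees of floating-point dust in the retardance maps; tests and
downstream comparisons use 1e−4 degrees as the "numerically zero"
threshold for angle maps.

The Mueller matrix transformation (MMT) supplies rotation-invariant
scalars from the central block of the normalized matrix:
$b = (m_{22}+m_{33})/2$,
$t = \sqrt{(m_{22}-m_{33})^2 + (m_{23}+m_{32})^2}\,/\,2$, and the degree
of anisotropy $A = 2bt/(b^2+t^2)$, defined as 0 when $b = t = 0$.

Images run through a compiled (RcppArmadillo) per-pixel loop; a readable
single-pixel R implementation (`mmpdDecomposePixel()`) is kept as the
reference and the two are cross-checked in the tests.

### Two notions of "physical"

`isPhysical()` defaults to a cheap sufficient guard: a fixed 26-direction
grid of fully polarized Stokes vectors must map to vectors with
non-negative intensity and degree of polarization ≤ 1. The stricter Cloude
criterion (all coherency-matrix eigenvalues non-negative) is available via
`cloude = TRUE`. The two genuinely differ: a depolarizer
$\mathrm{diag}(1, a, b, c)$ is Stokes-physical for any $a,b,c \in [0,1]$
but Cloude-physical only when the channels are compatible (e.g.
$c \ge a + b - 1$). A sample with large circular depolarization and
near-zero linear depolarization — precisely the regime of this tissue
model — fails the ensemble criterion while remaining a perfectly valid
Stokes map. The pipeline therefore guards with the Stokes test, and uses
the Cloude test with a small slack (`tol = 0.02`) only where its
strictness is the point: scrambled-frame detection, where reconstructed
matrices from permuted stacks are flagrantly non-PSD while correctly
ordered ones are not.

## Tissue masking and ROI statistics

Defective tissue regions are excluded by the scaled-MAD rule: a pixel is
an outlier iff $|x - \mathrm{median}| > k \cdot 1.4826 \cdot
\mathrm{MAD}$ with $k = 3$; the constant 1.4826 makes the scaled MAD a
consistent normal-σ estimate, so the null exclusion rate is the 3σ tail
mass, 0.27%. The mask is computed on the total depolarization map by
default (which depolarization map is a configuration choice: `DeltaL` and
`DeltaC` are accepted alternatives). ROI summaries record masked means and
maxima of every parameter map plus the retained pixel count; radial line
profiles bin an annular sector by distance from the inner ring edge and
report the per-bin means, the profile standard deviation (the spatial-
heterogeneity statistic) and the peak location; empty bins are reported
missing, never interpolated. Ring geometry is supplied explicitly by the
generator, or fitted from a mask by an algebraic least-squares circle fit.

The statistical battery is deliberately non-parametric, with a
Shapiro–Wilk report available per (day, group) cell as the rationale:
Spearman correlations among parameter means and against the design
variables (day as ordinal, group as binary), Kruskal–Wallis across days
within each arm, unadjusted pairwise two-sample Wilcoxon rank-sum tests
between day pairs (original p-values by design, treating the pairwise
questions as independent; Holm adjustment sits behind a flag), and
rank-sum tests between arms within each day. Exact p-values are used for
small tie-free samples, midranks with normal approximation and continuity
correction otherwise — the `stats::wilcox.test` behaviour, asserted in
the suite by its size and power: type-I error 0.05 at 1000 null
Kruskal–Wallis replicates and rank-sum power in [0.80, 0.95] for a 1.5σ
shift at n = 10 per arm.

## Fiber orientation from volumes

Second-harmonic-type volumes are tiled into cubic subvolumes (default 32³
voxels, 50% overlap). Each subvolume is Hann-windowed; its 3D power
spectrum — DC and the two lowest integer-radius frequency shells removed,
which suppresses illumination gradients — feeds a second-moment tensor
over physical frequency coordinates (anisotropic voxel sizes are
honoured). A fiber concentrates spectral energy in the plane normal to
its axis, so the fiber axis is the eigenvector of the *smallest*
eigenvalue. Subvolumes whose passband-to-DC power ratio falls below 0.5
are flagged invalid: for an unstructured intensity field that ratio is the
squared coefficient of variation (≈ 1/λ for Poisson noise at level λ, i.e.
≪ 0.5), while rod content at realistic fill fractions pushes it well
above 1.

Axes are orientation (axial) data: $v$ and $-v$ are the same fiber. Before
averaging, each axis is flipped into the hemisphere around the dominant
eigenvector of the axis scatter matrix (non-negative dot product) — a
rotation-invariant folding convention. The spherical variance of $n$
folded axes is

$$SV = 1 - \frac{\lVert \sum_i v_i \rVert}{n} \in [0, 1],$$

0 for perfect alignment. Reported alongside are the mean and standard
deviation of the in-plane angle θ ∈ [0°, 180°) (averaged on the doubled
angle, as axial data demand) and the out-of-plane angle φ ∈ [−90°, 90°].
`SV` is additionally normalized by `sv_max = 0.4`, the literature's
theoretical maximum under its own (unpublished) folding convention. With
this package's folding the empirical maximum for uniformly random axes is
close to that value but is *not* asserted anywhere; `sv_max` is a plain
configuration constant and can be changed.

## What the generators emulate — and what they do not

`makeRingPhantom()` composes, per pixel inside an annulus,
$M = M_\Delta(1, 1-\Delta_L, 1-\Delta_C)\; M_R(\delta(r), \theta(x,y))\;
M_D(D)$, with radial baseline + Gaussian-bump profiles for δ (default
2° + 9° bump) and $\Delta_C$ (0.01 + 0.03 bump), both bumps centred at
30% of the ring width from the inner edge — emulating the observed
retardance peak near the inner ring — a circumferential fast axis
(the mold guides cell alignment along the ring; the axis zero reference
is the image +x direction, a convention this package defines since ring
geometry has no natural zero), constant low linear depolarization
(0.005), zero circular retardance, and mild diattenuation (0.05).
Outside-ring pixels are exact identity. Optional defect spots carry high
depolarization for the mask to find. The default desk-scale geometry is a
256 × 256 image at 10 µm pitch holding a full 750-µm-wide annulus of
inner radius 400 µm: the real 5-mm mold ring would only ever show a
partial arc in one camera field, but a full annulus exercises the
circumferential axis pattern and the radial profiles far better per
pixel, and nothing downstream depends on the absolute radius.

`makeCohort()` draws per-sample mean δ and $\Delta_C$ from truncated
normal between-sample variation around the published group trajectories
over culture days {2, 4, 7, 14, 21} (control δ rising to ~11° by day 21;
treated δ jumping to ~12.6° at day 7 and plateauing), with the published
per-day standard deviations and group sizes (n = 8, 8, 12, 9, 13 control;
8, 8, 9, 10, 9 treated) as defaults. Each sample's radial profile is
scaled (70% baseline, 30% bump against the closed-form area-weighted bump
mean `ringProfileMean()`) so its analytic ring mean equals the sampled
target exactly; cohort phantoms render at 96² pixels by default with the
pitch scaled to keep the full annulus in frame.

`makeFiberVolume()` rasterizes straight cylinders with axes drawn from a
bipolar Watson distribution (rejection sampling of $\cos\theta \propto
e^{\kappa t^2}$), Gaussian point-spread blur via FFT, and Poisson photon
noise over a small background.

What passing tests on these phantoms establish: the algebra of the
pipeline (round trips to machine precision), its statistical calibration
(mask rates, test sizes and powers), and its qualitative sensitivity
patterns (monotone trends, treatment splits, dispersion orderings). What
they cannot establish: behaviour under real tissue scattering (the model
is a pure per-pixel Mueller map — no spatial mixing, no multiple
scattering, no thickness variation), chromatic effects (single design
wavelength; the 780 ± 5 nm filter bandwidth is ignored), condenser/
objective polarization aberrations, camera nonlinearity, or biology — the
cohort trajectories are inputs pinned to published group means, so
cohort-level agreement is a consistency check of the machinery, never a
biological finding.

## Problem sizes and runtime choices

Defaults are desk-scale by design: 256² phantom pixels (not the camera's
2056 × 1542), 96² for cohort samples, 64 × 64 × 32 fiber volumes with 32³
subvolumes, 100-instrument calibration sweeps, 1000-replicate Monte
Carlos. On one CPU the full test suite runs in a few minutes and the
acceptance script in seconds; every randomized computation takes an
explicit seed.

## Known limitations

* The ECM's reference-angle refinement is a local search started at the
  nominal angles; gross mislabelling of reference orientations (tens of
  degrees) is out of scope.
* The depolarizer-block ΔL/ΔC readings assume a near-diagonal depolarizer
  (true for this sample class); strongly anisotropic depolarizers should
  use the eigenvalue variant.
* `sv_max = 0.4` is a convention-dependent constant, not re-derived here.
* Per-pixel calibration is embarrassingly parallel but currently runs on
  one core.
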