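---
title: "Modality-independent self-similarity descriptors for multimodal registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modality-independent self-similarity descriptors for multimodal registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macmind)
```

## The problem

Aligning two 3D images of the same anatomy acquired with different
modalities (for example abdominal CT and T1 MR) cannot rely on raw
intensities: the same tissue maps to different, sometimes inverted, grey
values, so a sum-of-squared-differences between the images is a poor —
often actively misleading — similarity measure. The classic remedy is to
compare *self-similarity structure* instead of intensity: however a
modality renders a tissue, the pattern of "which nearby patches look
like which" is a property of the underlying anatomy and survives any
monotone intensity remapping.

`macmind` implements that family of descriptors and everything needed to
study them end to end:

* the 6-channel **MIND** descriptor (exponentiated, variance-normalized
  patch distances to the 6-neighbourhood);
* the 18-connection **self-similarity context** (SSC), its multi-scale
  combination (**msSSC**), and the cascaded **macMIND** descriptor that
  aggregates msSSC over 3D log-polar bins into an M×N-channel map;
* the registration losses the descriptor drives (descriptor similarity,
  diffusion smoothness, soft-Dice label consistency);
* a classical multi-resolution demons-style deformable registration
  driver;
* deformation-quality analysis (Jacobian folding counts);
* the full evaluation panel (TRE, DSC, Hd95, MI, SSIM, RVDabs, VOE);
* a synthetic multimodal phantom generator that stands in for paired
  clinical volumes.

## The descriptor cascade

### Patch distances and MIND

All descriptors start from the patch sum-of-squared-differences: for two
patch-centre offsets $o_i, o_j$ and an odd patch edge $R_1$,

$$\mathrm{SSD}(p) = \frac{1}{R_1^3} \sum_{t} \big(I(p+o_i+t) - I(p+o_j+t)\big)^2 ,$$

computed for the whole volume at once by shifting the image by each
offset, squaring the difference and applying a uniform box filter
(`patch_ssd_map()`). MIND compares the central patch with its six axis
neighbours at distance $L$ and normalizes by the local mean of those six
distances:

$$\mathrm{MIND}_n(x) = \exp\!\big(-D_n(x) / V(x)\big), \qquad
V(x) = \tfrac{1}{6}\textstyle\sum_n D_n(x).$$

Because the normalization is a ratio of quadratic forms, every channel
is *exactly* invariant under positive affine intensity maps
$I \mapsto aI+b$ — the formal statement of modality independence for
this family.

### SSC, msSSC and the 18-connection layout

MIND's weakness is that every comparison involves the central patch, so
noise at the centre corrupts all six channels. The self-similarity
context instead connects **every non-collinear pair** among the central
patch and its six neighbours: 18 undirected connections in 9 undirected
orientation classes (the three axis classes plus six diagonal classes);
the three collinear opposite-neighbour pairs are excluded
(`build_connection_layout()`). Each connection becomes one channel,

$$\mathrm{SSC}_{ij}(p) = \exp\!\Big(- \mathrm{SSD}_{ij}(p) \big/
  \overline{\mathrm{SSD}}(p)\Big),$$

with $\overline{\mathrm{SSD}}$ the mean over all 18 connections. The
printed form of this definition sums the exponentials into a scalar; a
scalar per voxel cannot produce the M-channel map the cascade needs, so
the package reads the sum as channel enumeration — one channel per
connection — which is the only reading consistent with the downstream
aggregation. msSSC repeats the construction at $K$ scales (scale $k$
samples its neighbourhood at distance $k \cdot L$) and combines the
per-scale maps channel-wise with weights $\alpha_k$.

### Log-polar aggregation

Each msSSC channel is then average-pooled over a partition of the
surrounding $R_2^3$ patch into 3D log-polar bins: `Na` azimuthal sectors
(starting at +x, counter-clockwise), `Nr` log-spaced radial shells over
$(0, R_2/2]$ (consecutive outer radii in ratio 2; the $r=0$ column joins
the innermost shell), and `Nh` equal height slabs. Offsets outside the
inscribed cylinder stay unassigned. With `Nh = 1` on a flat patch this
reduces to the planar 8×2 = 16-bin illustration familiar from shape
context descriptors; the 3D default `Na = 8, Nr = 2, Nh = 2` gives
N = 32 bins and an 18 × 32 = 576-channel macMIND map. Pooling is average
(not max) so fine matching detail is retained, and each bin's average is
a convolution with a small indicator kernel — the whole cascade is a
fixed two-layer convolutional feature extractor.

Two quirks of this partition are worth knowing. First, at $R_2 = 5$ the
innermost shell's diagonal sectors contain no lattice offsets, so 8 of
the 32 bins are empty; their channels are zero-filled and a warning is
raised when the partition is built. This wastes channels but keeps the
published bin counts intact; larger `R2` fills them. Second, azimuthal
boundaries are assigned to the sector they open (floor convention), and
the z slab boundary at the patch centre belongs to the upper slab; both
conventions are frozen so channel order is reproducible.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `L` | 2 | base patch distance (voxels); scale k samples at k·L |
| `R1` | 5 | patch edge for the patch SSD (odd) |
| `R2` | 5 | aggregation patch edge (odd) |
| `K` | 2 | number of sampling scales |
| `alphas` | (0.7, 0.3) | per-scale weights, normalized to sum 1 |
| `Na, Nr, Nh` | 8, 2, 2 | angular / radial / height bin counts |
| `eps_rel` | 1e-6 | relative floor for the normalizing denominator |

The scale weighting deserves a note: the implementation literature for
this pipeline quotes both (0.3, 0.7) and (0.7, 0.3) for the two-scale
weights, while the ratio study in the same work reports the
small-scale-dominant ratio 7 : 3 as optimal. The two statements cannot
both describe the experiment that was run. This package ships (0.7, 0.3)
— small scale dominant, consistent with the ratio study and the feature
visualisations — and makes `alphas` explicit configuration rather than a
hidden constant, so either ordering is one line of YAML away.

On perfectly flat regions all patch distances vanish and the
normalizations above become 0/0. The denominator is floored at
`eps_rel` times its global mean (absolute floor 1e-12), which makes
constant regions yield channel value 1 — the "everything is similar to
everything" limit — and keeps the affine invariance exact (the floor
scales with the image). Borders use edge-replication padding everywhere;
zero padding would inject artificial edges into the patch distances.

Every fast implementation has a naive per-voxel counterpart
(`*_naive()`) that evaluates the defining sums directly with explicit
index clamping; the test suite holds the two within 1e-5 on random
volumes, and the cascade is deterministic: identical inputs and
configuration give bit-identical feature maps.

## Losses

Three pure-function loss terms drive registration:

* `sim_loss()` — mean over voxels of the squared channel-vector
  difference between two feature maps (the descriptor similarity).
* `smoothness_loss()` — the diffusion regularizer: sum over voxels of
  squared forward-difference gradients of all three displacement
  components, in voxel units (far boundary differences taken as zero).
* `dice_label_loss()` / `seg_consistency_loss()` — soft-Dice label
  terms; the consistency loss has two branches, cross-modality
  prediction consistency through the deformation when no ground truth
  exists, and prediction-versus-ground-truth otherwise.

The combined objective is
$E = \lambda_{sim} E_{sim} + \lambda_{label} E_{label} + \lambda_{smo} E_{smo}$.
The literature states the weights (20, 2, 0.5) but also writes the total
with an unweighted similarity term; the library default is
$\lambda_{sim} = 1$ so both readings are reachable, and the shipped
configuration file carries (20, 2, 0.5).

## The registration driver

The package's optimizer is a deliberately classical stand-in for the
trained registration networks this descriptor was designed for: dense
demons-style gradient descent on a coarse-to-fine pyramid, deterministic
given its configuration.

Design choices that mattered in practice:

* **Feature warping, not re-extraction.** The driver computes the
  descriptor stacks of both images once per pyramid level and resamples
  the moving stack through the current field each iteration.
  Re-extracting descriptors from the warped image — the literal reading
  of the similarity — makes the objective's minimum sit at zero
  displacement whenever the true deformation is subvoxel-to-voxel
  scale, because trilinear interpolation re-smooths the moving image's
  noise and shifts its descriptor statistics more than alignment gains.
  `evaluate_reg_loss()` still evaluates the literal definition for
  reporting; the surrogate is an optimization device.
* **Locally normalized symmetric forces.** Updates are
  $u(p) = \sum_c d_c \nabla W_c \,/\, (\sum_c \|\nabla W_c\|^2 + \kappa)$
  with the ESM-style symmetric gradient (mean of fixed and warped
  stacks' gradients) and $\kappa$ floored at a fraction (`kappa`, default
  0.1) of the global gradient energy, which suppresses updates where the
  descriptor carries no signal. Updates are capped at one voxel,
  Gaussian-smoothed (`smooth_sigma`, default 4 voxels), and applied with
  a fixed step (default 0.3) that halves whenever a trial increases the
  loss — so the accepted loss trace is non-increasing within every
  level. The whole field is additionally smoothed each accepted step
  (`field_sigma`, default 1), the diffusion-like half of the classic
  fluid/diffusion pair.
* **Per-voxel smoothness weight.** The driver weights the smoothness
  sum per voxel ($\lambda_{smo} E_{smo} / |\Omega|$); the raw sum grows
  with resolution and would otherwise freeze coarse levels entirely.
* **Label forces as mask demons.** When labels are supplied, the
  boundary force is the demons force on the soft masks,
  $(a - b)\,\nabla b / (\|\nabla b\|^2 + \kappa_b)$: the raw soft-Dice
  gradient scales as 1/volume and is numerically inert, but step
  acceptance still scores the true Dice loss.
* **`register_cascade()`** is the practical entry point: a (4, 2)
  pyramid driven by the full 576-channel macMIND, then a warm-started
  full-resolution stage driven by macMIND with reduced aggregation
  (`Na = 4, Nr = 1, Nh = 2`, 144 channels), which keeps full-resolution
  feature stacks at a workable memory footprint while preserving the
  multi-sampling structure.

The iteration budgets (10 coarse, 25 mid, 15 fine) are part of the
regularization, not just a runtime bound: with a noisy multimodal
similarity the loss can be driven well below its value at the true
deformation by fitting noise, and early stopping plus update/field
smoothing is what keeps the recovered fields in the smooth regime the
deformation model lives in. On the phantom studies described below,
longer level-2 optimization monotonically *increased* landmark error on
some realizations while the loss kept falling — the textbook signature
of similarity-metric overfitting.

Deformation quality is audited with `jacobian_report()`: the Jacobian of
$T(p) = p + \varphi(p)$ by central differences at interior voxels, with
the folding fraction reported per ten thousand voxels, the scale on
which folding rates are conventionally quoted.

## The synthetic phantom

Real paired CT-MR data with curated labels and landmarks cannot ship
with a package, so `generate_phantom()` builds the structural analogue
of such a pair:

* a shared anatomy: a body ellipsoid, a spine-like rod, two vessel-like
  blobs, a lobulated organ (ellipsoid modulated by low-order angular
  harmonics) with an interior lesion;
* **modality A**: monotone per-class intensity map plus additive
  Gaussian noise (2% of the unit range) — CT-like character;
* **modality B**: a different, nonlinear monotone-per-class map with the
  lesion's contrast *inverted* (dark in A, bright in B) plus
  Rician-like noise (4%) — MR-like character — rendered in the frame
  deformed by the ground-truth field;
* a ground-truth field: i.i.d. Gaussian noise per component, smoothed
  (σ = 6 voxels), cosine-tapered to zero over 4 boundary voxels, and
  rescaled so its maximum magnitude equals the configured amplitude
  (4 voxels by default). The noise is smoothed with a periodic FFT
  Gaussian so its statistics are stationary up to the border (a spatial
  edge-replicated filter inflates boundary variance, which would park
  the global maximum inside the taper ring and under-size the interior
  after rescaling); the taper removes the periodic seam. If a
  configuration folds anyway, the field is rescaled down with a warning
  (error in strict mode).
* landmarks: the lesion centroid plus organ-boundary extremal points
  (axis extremes, then diagonal extremes), mirroring the "tumour centre
  plus anatomical boundary features" style of clinical landmarking.
  Deformed-frame partners are obtained by fixed-point inversion of the
  field, so correspondence is exact by construction. Interior points far
  from any boundary are deliberately not used: they sit outside the
  descriptor's support and no similarity-driven method can localize
  them.

Defaults (64 × 64 × 48 voxels at 1 mm, amplitude 4, σ = 6, 8 landmarks)
keep a full simulate–register–evaluate cycle under a minute. What the
phantom does *not* emulate: imaging physics (beam hardening, bias
fields, partial volume), anisotropic clinical spacing by default, organ
sliding, and intensity inhomogeneity — so green tests here demonstrate
the algorithmic contracts (invariance, oracle equivalence, recovery
under the stated noise model), not clinical performance.

With the default conditions the delivered fields have mean displacement
near one voxel and mean landmark offsets of 0.8–1.8 mm; the cascaded
registration with organ-label guidance reduces mean landmark TRE on
every tested seed, by 6% on the hardest realization and up to ~48% on
the easiest. That spread is honest: individual boundary landmarks can
worsen when their true displacement is tangential to the boundary
(the aperture problem), and the lesion centre is carried by, at most, a
two-voxel-radius structure at the pyramid's working resolution.

## Metrics

The evaluation panel follows the conventions of the multimodal
registration literature: MI from a 32-bin joint histogram in nats
(binning is unstated in most papers; 32 equal-width bins over each
image's range is the convention for 8-bit-equivalent dynamic range, and
`MI(I, I)` then equals the marginal entropy under the same binning);
global SSIM on min-max normalized intensities with c1 = 0.01², c2 =
0.03² (the default is the standard product form, which attains 1 at
identity; a `paper_literal` flag exposes the sum-form numerator that
appears in print but breaks the identity property — kept inspectable,
never default); DSC, VOE and RVDabs from voxel counts (RVDabs is
directional: its second argument is ground truth); Hd95 as the 95th
linear-interpolation percentile of pooled symmetric surface distances
(6-connectivity surfaces, physical mm via the spacing); and landmark TRE
by trilinear interpolation of the field at the source landmark's voxel
position. DSC and VOE are algebraically linked through the Jaccard–Dice
identity, which the tests verify numerically on random masks.

## Degenerate inputs and numerical conventions

* Constant images: MI is defined as 0 with a warning (single-bin
  histogram); SSIM normalization maps a constant image to all-zeros.
* Empty masks: DSC of two empty masks is 100 with a warning (strict
  mode errors); Hd95 and RVDabs error on empty inputs.
* Soft Dice uses ε = 1e-6 in numerator and denominator, so identical
  masks score exactly 0 loss.
* Labels are warped with trilinear interpolation as soft masks inside
  losses, and nearest-neighbour for reported masks.
* All ties in the bin partition (sector boundaries, shell edges, slab
  boundary) resolve by the frozen conventions above; channel order is
  pairs within bins, bins ordered height-radius-angle.

## Problem sizes used by the tests

The unit suite works on 7³–16³ random volumes (where the naive oracles
are affordable) and a 32 × 32 × 24 phantom; the acceptance suite runs
ten full 64 × 64 × 48 phantom registrations and ten undeformed phantom
pairs at the same size. These sizes were chosen so the whole suite
completes in minutes while still exercising every code path at the
default descriptor configuration.

## Known limitations

* The registration driver is a desk-scale classical optimizer; it
  demonstrates that the descriptor and losses behave as specified, not
  state-of-the-art registration accuracy.
* Oblique NIfTI orientations are ignored (axis-aligned grids assumed,
  with a warning); resample obliquely-acquired data upstream.
* The empty-bin waste at `R2 = 5` (8 of 32 bins) is inherent to the
  lattice at that patch size.
* Descriptor memory scales with M × N channels: the full default
  configuration over a 256³ volume would need ~40 GB; use the reduced
  aggregation (as `register_cascade()` does at full resolution) or
  tile.
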