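---
title: "Modality-agnostic cascade segmentation: model, training protocol, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modality-agnostic cascade segmentation: model, training protocol, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiac substructures — the whole heart, the four chambers, the great
vessels, the coronary arteries, the valves and the conduction nodes — are
increasingly delineated individually for radiotherapy planning, because
dose to specific substructures predicts cardiotoxicity better than dose to
the heart as a single organ. Automating this delineation runs into two
structural obstacles at once:

1. **Overlap.** A composite label of 20 substructures assigns more than one
   true label to many voxels (a mitral-valve voxel is also a left-atrium
   voxel and a whole-heart voxel). Plain semantic segmentation assumes one
   label per voxel, so a single softmax head cannot represent the target.
2. **Modality.** Planning and diagnostic images come from different
   scanners — simulation CT, low-field MR-Linac, contrast-enhanced cardiac
   CT angiography — with different intensity scales, contrasts and native
   resolutions. A model trained on one typically fails on the others.

The conventional answer is a matrix of specialised models: one per
(modality, structure-group) pair — twelve models for three modalities and
four groups. `magicseg` implements the alternative this package is built
around: **one** U-shaped network with *modality-specific encoders*, a
*shared bottleneck*, and *group-specific decoders*, so a single parameter
set serves every modality and every structure group.

## Model

### Structure groups

The 20-structure catalog is partitioned into four groups that are
internally disjoint but mutually overlapping:

| group | content | classes (incl. background) |
|---|---|---|
| A | whole heart | 2 |
| B | chambers LA, RA, LV, RV; great vessels AA, SVC, IVC, PA, PVs | 10 |
| C | coronary arteries RCA, LMCA, LADA, LCFX; valves V-AV, V-PV, V-MV, V-TV | 9 |
| D | conduction nodes N-SA, N-AV | 3 |

Each group is an ordinary single-label problem for its own decoder; the
composite segmentation is the union of the four decoded label maps, and
cross-group overlap emerges with no special machinery. Within-group
disjointness is a *validated invariant* of the `composite_segmentation`
container: violating it is an error, never a warning.

### Backbone and cascade

The backbone is a standard 3-D U-Net: encoder stages of two
(3×3×3 convolution → instance norm → leaky ReLU) blocks with stride-2
downsampling between stages, a bottleneck, and a mirrored decoder with skip
connections, deep-supervision heads at every decoder depth, and 1×1×1
projection heads on the encoder stages for self-distillation. Channel
width doubles per stage from `base_width` up to `width_cap`. The default
configuration (5 stages, width 32, cap 320) follows common 3-D U-Net
practice; a `tiny_backbone_spec()` preset (3 stages, width 8) makes CPU
experiments practical.

`build_cascade()` replicates the encoder once per modality (identical
architecture, independent parameters, independent per-component
initialisation seeds) and the decoder once per group (with that group's
class count), around exactly one bottleneck. A forward pass routes through
the *selected* modality's encoder only and emits all four groups' score
maps in one pass; the active encoder's stage-k features feed every
decoder's stage-k skip merge. Two consequences are tested as invariants:

- **Sharing/isolation.** One optimisation step on a batch of modality *m*
  changes the bottleneck and all decoders (shared) but no other modality's
  encoder (isolated).
- **Degeneracy.** A 1-modality/1-group cascade is parameter- and
  output-identical to the plain backbone built from the same seed.

The architecture and autodifferentiation are implemented in this package
directly (R with C++ kernels for convolution, distance transforms and
thinning); every hand-derived backward pass is checked against central
finite differences in the test suite.

### Why this is cheap

Twelve specialised models instantiate 12 encoders, 12 bottlenecks and 12
decoders. The cascade instantiates 3 + 1 + 4 components of the same
backbone. With encoder ≈ decoder ≈ E and bottleneck ≈ 0.2 E the closed
form gives 100·(1 − 7.2E/26.4E) ≈ 72.7% fewer trainable parameters; the
exact count for the default backbone, computed by `count_parameters()` and
`parameter_reduction()`, is recomputed from scratch by
`scripts/acceptance.R`.

## Training protocol

**Preprocessing** (in this order): CT-like modalities are windowed to
[−250, 550] HU (MR intensities are left alone); the volume is cropped to
the whole-heart bounding box plus a margin (from the reference mask when
available, otherwise an intensity-foreground estimate), recorded so
predictions can be mapped back; resampled to the working spacing (default
1.5 mm isotropic; trilinear for images, nearest for labels, aligned by
physical coordinates so image and label grids never drift); and z-score
normalised per volume. A constant image cannot be scaled and is centred
only. The windowing is applied to CT-like modalities only because an HU
window is meaningless on arbitrary MR scales.

**Augmentation:** random flips per axis; 90° rotations per axis; small
rotations uniform in ±10° per axis (trilinear for the image, nearest for
labels); intensity scale in [0.9, 1.1] and shift within ±10% of the range
(image only); random crop to the training patch. Padding — when a cropped
heart is smaller than the patch — uses the minimum (background) intensity,
not zero: after z-scoring, zero sits mid-scale and would fabricate tissue
at the borders.

**Loss.** The primary loss is the equally weighted mean of three terms,
per group and per deep-supervision head:

- *soft Dice* over foreground classes (smoothing ε = 10⁻⁵ in numerator and
  denominator), robust to class imbalance;
- *boundary loss*: mean over voxels and foreground classes of predicted
  probability × signed Euclidean distance (mm) to the reference boundary
  (negative inside, zero on the border voxels, positive outside; empty
  masks get an all-positive field capped at the grid diameter). Over binary
  predictions this is exactly minimised by the reference, which the suite
  verifies by exhaustive enumeration on a small grid;
- *cross-entropy*, the standard per-voxel log-likelihood.

Deep-supervision heads receive the same composite loss against
nearest-neighbour-downsampled references (signed distances recomputed at
the coarser spacing), all with equal weight. Dual self-distillation adds,
with weight 1: on the decoder side, each auxiliary head is a student of
the (detached) full-resolution head via temperature-softened KL divergence
(temperature 3); on the encoder side, shallower stage projections are
students of the deepest stage's projection. Dual self-distillation exists
in several variants in the segmentation literature; the one implemented
here is a deliberate design choice, isolated behind
`distillation_loss()` so it can be swapped — the temperature (3) and the
output-level (rather than feature-level) divergence are package decisions.

**Optimisation:** one AdamW optimiser (lr 10⁻³, weight decay 10⁻⁵) over
the single shared parameter collection, poly learning-rate decay
lr₀·(1 − epoch/epochs)^0.9, 500 epochs by default. Parameters that
received no gradient in a step (inactive encoders) are not updated and
their moment estimates do not advance. Each iteration draws the modality
*uniformly* and then a case uniformly within the modality — "uniform over
modalities, then within" was chosen over "uniform over pooled images"
because only the former removes modality bias when dataset sizes differ.
An epoch defaults to one iteration per labeled training case (the three
pooled datasets give no natural epoch definition); batch size defaults
to 2.

**Model selection:** after every epoch the validation split is segmented
as full volumes (sliding-window) and the mean Dice over all structures and
modalities selects the retained checkpoint. One desk-scale subtlety: a
structure whose *reference* is empty on the working grid (a 1-voxel node
can vanish under coarse resampling) carries no information about model
quality, yet the degenerate both-empty convention would score it 1 for any
model that predicts nothing — enough, at phantom scale, to steer selection
toward all-background checkpoints. The validation mean therefore excludes
structures absent from the case's resampled reference. On clinically
resolved grids where all 20 references are non-empty the two definitions
coincide. The final-epoch weights are also kept on the returned model
(`last_params`) for resuming.

**Pseudo-labeling:** a trained model predicts composites for unlabeled
manifest entries; accepted cases re-enter the training split with
provenance `pseudo` (never validation or test). The human visual check
this emulates is replaced by a pluggable rule — default: mean
winning-class probability over predicted foreground ≥ 0.5 — plus explicit
include/exclude lists as the hook for a human reviewer.

**Inference:** cubic windows tiled at stride max(1, ⌊patch·(1−overlap)⌋)
(default overlap 0.9 → stride 9 for a 96 patch), with a final window
anchored at the volume end so coverage is complete, blended by Gaussian
importance weights (σ = patch/8; uniform blending is available and is used
by the oracle tests). Per-group voxelwise argmax (ties to the lower class
index, deterministically) produces the label maps, and encoding them
yields the composite.

## Evaluation suite

Surfaces are *border voxels* (mask voxels 6-adjacent to background, the
volume edge counting as background) rather than marching-cubes meshes: the
published tolerance is stated in voxels, and the voxel definition keeps an
exhaustive all-pairs oracle feasible, which the suite runs on every
crafted mask up to 16³. Surface-to-surface nearest distances come from an
exact Euclidean distance transform with anisotropic spacing.

- **DSC** 2|A∩B|/(|A|+|B|); both-empty = 1, one-empty = 0.
- **Surface Dice**, tolerance 2 voxels converted to mm as 2·mean(spacing)
  at the working grid (a voxel-denominated tolerance needs a reference
  grid; the working grid is this package's choice, and an explicit mm
  tolerance can be passed instead).
- **HD95**: linear-interpolation (type-7) 95th percentile of the pooled
  symmetric distance multiset.
- **MSD**: mean of the same multiset.
- **Centerline Dice** for the coronary arteries: skeletons from
  topology-preserving sequential thinning (26-connected foreground,
  6-connected background, simple-point test, endpoints preserved), then
  the harmonic mean of topology precision |skel(pred)∩ref|/|skel(pred)|
  and sensitivity |skel(ref)∩pred|/|skel(ref)|.

A structure with an empty prediction (or reference) yields DSC 0 and
*failed* distance records — the infinite-metric discard rule. Method
comparison uses a paired two-tailed Wilcoxon signed-rank test per (metric,
structure) when both methods have finite values on identical cases (exact
small-sample p-values where `stats::wilcox.test` provides them; all-zero
differences report p = 1), and falls back to a two-tailed Mann-Whitney U
test on the finite values once discards break the pairing. Reports
aggregate by substructure class; because "composite" aggregation is
ambiguous (mean of structures vs mean of class means), both are emitted.

## The phantom generator

Clinical cardiac images with full 20-structure composite labels are not
redistributable, so the package ships a seeded generator of
cardiac-like phantoms that
reproduces the *structural* pathologies the pipeline must survive, not the
anatomy: the whole heart is a large ellipsoid; chambers are four disjoint
interior ellipsoids; great vessels are five disjoint tubes entering the
heart surface; coronary arteries are thin curved tubes lying **on** the
heart surface (cross-group overlap with WH at every case, and genuinely
tubular so centerline metrics mean something); valves are thin disks at
chamber and vessel interfaces (cross-group overlap with group B by
construction); nodes are small spheres near the right atrium. Geometry is
parameterised in fractions of the grid so one spec scales across grid
sizes, with seeded jitter of centres and a global scale; a jitter draw
that violates within-group disjointness is re-drawn (bounded retries).

Rendering assigns per-(modality, structure) intensities with
smallest-structure-wins precedence at overlapped voxels (thin
contrast-filled arteries must stay visible), Gaussian smoothing (σ = 0.7
voxels), additive Gaussian noise, and resampling to modality-native
anisotropic spacings — CT-like 1.0×1.0×2.5 mm, MR-like 1.5×1.5×3.0 mm,
CCTA-like 0.6×0.6×0.6 mm, mirroring the acquisition ranges of the
respective clinical protocols — so the preprocessing resampling is
genuinely exercised. CT-like tables span beyond [−250, 550] HU so
windowing clips something real. Each structure gets its *own* intensity
per modality, mimicking differential contrast enhancement (left heart
brighter than right on first-pass CCTA, vessel opacification varying along
the injection path). This is not cosmetic: the phantom geometry is close
to laterally symmetric, and if paired structures also shared one intensity,
random flip augmentation would make LA/RA (and LV/RV) genuinely
indistinguishable — an artifact of the phantom, not a property of the
method, since real anatomy is asymmetric in both shape and appearance.

What the phantoms deliberately lack: anatomical shape realism, cardiac and
respiratory motion, imaging physics (beam hardening, MR bias fields,
artifacts), and inter-patient anatomical variability beyond jitter.
Passing the desk-scale tests therefore demonstrates that the machinery —
architecture, losses, optimisation, inference, metrics — is correct and
can fit a multi-modality overlapping-label task end to end; it does not
certify clinical accuracy on patient images.

## Desk-scale study conditions

All tests run on CPU at deliberately small problem sizes, chosen once:

- unit fixtures: 8³–16³ crafted arrays and ≤16³ oracle grids;
- phantom suite: 32³ reference grids (24³ for the I/O fixtures);
- training surrogate: 32³ phantoms, 3 modalities × (5 train / 2 val /
  3 test), the tiny backbone, 30 epochs × 8 iterations × batch 2 at a
  1.25 mm working spacing with 24³ patches covering the cropped heart.
  The held-out check asks WH DSC ≥ 0.8 — the desk-scale stand-in for the
  clinical performance the original data would support. Eight iterations
  per epoch (rather than the one-per-labeled-case default of 15) keep the
  full 30-epoch run inside a sensible desk-time envelope on one CPU.

With hearts of ~18 working-grid voxels diameter, training patches span
the whole cropped volume; the patch machinery (random crops, sliding
windows with stride floor) is exercised separately at full size by the
closed-form tiling tests.

A second, stricter surrogate bound — group-B (chambers and great vessels)
mean DSC ≥ 0.6 under the same 30-epoch conditions — is encoded as its own
test and does not currently pass: 480 optimisation steps of an 8-channel
backbone are orders of magnitude less compute than the reference protocol
(500 epochs at GPU scale), and the multi-class emergence of the nine
group-B structures has not happened by then, while the binary
high-contrast whole-heart problem has. The bound is kept, unweakened, as
an honest marker of where desk-scale compute stops short.

## Numerical choices and degenerate inputs

- Dice ε 10⁻⁵; log arguments floored at 10⁻³⁰⁰; softmax shifted by the
  per-voxel max.
- Signed distances and surface metrics are exact (Felzenszwalb lower
  envelopes), not chamfer approximations.
- Argmax ties break to the lower class index; background therefore wins
  exact ties, which is the conservative choice for segmentation.
- Empty masks: defined conventions throughout (documented per function)
  rather than NaNs; distance metrics flag failure instead of returning
  infinities.
- HD95 percentile convention: type-7 linear interpolation (R's default),
  documented because percentile conventions differ across toolkits.
- All randomness (initialisation, jitter, augmentation, sampling) flows
  from explicit integer seeds through isolated RNG streams that do not
  disturb the caller's `.Random.seed`.

## Known limitations

- The backbone configuration is fixed by `backbone_spec()`, not derived by
  dataset fingerprinting as self-configuring frameworks do; reproducing
  any particular published parameter count is out of scope (only the
  >70% reduction bound is claimed, and met at 73.5%).
- Distillation internals are a stand-in for an unpublished scheme (above).
- Training is single-process CPU-oriented; there is no GPU path, no
  multi-worker data loading, and no test-time augmentation.
- The phantom generator's realism limits are listed above; conclusions
  about clinical data require clinical data.
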