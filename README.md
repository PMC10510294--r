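# macmind

Modality-independent self-similarity descriptors for 3D multimodal
deformable image registration, in R.

Registering images of the same anatomy from different modalities (CT to
MR, say) cannot rely on raw intensity: the same tissue renders at
different — sometimes inverted — grey values. What survives any
monotone intensity remapping is *self-similarity structure*: which
nearby patches resemble which. `macmind` implements the descriptor
family built on that idea and the machinery to study it end to end:

* **MIND** — the 6-channel modality-independent neighbourhood
  descriptor: `MIND_n(x) = exp(-D_n(x)/V(x))`, with `D_n` the mean
  squared patch difference to the n-th 6-neighbour at distance `L` and
  `V` the mean of the six distances. Exactly invariant under positive
  affine maps `I -> aI + b`.
* **SSC / msSSC** — the self-similarity context: all 18 non-collinear
  patch connections among the centre and its 6-neighbourhood (9
  orientation classes), one channel per connection,
  `exp(-SSD_ij / meanSSD)`, combined over `K` sampling scales with
  weights `alpha_k`.
* **macMIND** — msSSC average-pooled over 3D log-polar bins (`Na`
  azimuthal sectors × `Nr` log-radial shells × `Nh` height slabs; 8×2×2
  = 32 bins by default) in an `R2`-voxel supporting window, giving an
  M×N = 18×32 = 576-channel feature map per voxel. The whole cascade is
  two fixed convolutional layers: shift + box filter for patch SSDs,
  indicator-kernel convolution for the bin averages.
* **Losses** — descriptor similarity (mean squared channel difference),
  diffusion smoothness `sum ||grad phi||^2`, soft-Dice label
  consistency, and their weighted total.
* **Registration** — a deterministic multi-resolution demons-style
  driver (`register()`, `register_cascade()`) exercising those losses,
  with Jacobian folding analysis (`jacobian_report()`).
* **Metrics** — TRE, DSC, Hd95, MI, SSIM, RVDabs, VOE
  (`metric_panel()`).
* **Synthetic phantoms** — paired "CT-like"/"MR-like" volumes of one
  anatomy under different monotone per-tissue intensity maps (lesion
  contrast inverted), with ground-truth smooth deformations, organ and
  lesion labels, and corresponding landmarks (`generate_phantom()`).

## Worked example

Simulate a multimodal phantom pair, extract its descriptor, register
the modalities, and evaluate:

```r
library(macmind)

ph <- generate_phantom(phantom_config(seed = 7))
ph
#> <mac_phantom> 64x64x48 voxels, seed 7, amplitude 4 voxels, 8 landmarks

macmind(ph$vol_a)
#> <mac_featmap> 64x64x48 voxels x 576 channels (macmind)

# landmark error with no registration
zf <- zero_field(dim(ph$vol_a$data))
mean(tre(ph$landmarks_b, ph$landmarks_a, zf)$tre_mm)
#> [1] 1.615

res <- register_cascade(ph$vol_a, ph$vol_b,
                        fixed_label = ph$label_organ_a,
                        moving_label = ph$label_organ_b)
mean(tre(ph$landmarks_b, ph$landmarks_a, res$field)$tre_mm)
#> [1] 0.905

jacobian_report(res$field)
#> <mac_jacobian_report> 0 / 176824 interior voxels fold (0.000 per 10k), min det 0.7641
```

The registration cuts the mean landmark error from 1.62 mm to 0.91 mm
without folding the deformation; the warped organ label's Dice overlap
with the fixed organ rises from 91.0% to 94.9%, and the mutual
information between the modalities rises from 0.68 to 0.79 nats. The
per-landmark table (`tre()`) and the full panel (`metric_panel()`)
break these down further.

A command-line interface wraps the same pipeline
(`inst/cli/macmind`):

```sh
macmind simulate --seed 7 --out-dir case/
macmind extract  --input case/vol_a.nii.gz --output feat.nii.gz
macmind register --fixed case/vol_a.nii.gz --moving case/vol_b.nii.gz \
                 --out-field phi.nii.gz --out-warped warped.nii.gz
macmind evaluate --fixed case/vol_a.nii.gz --warped warped.nii.gz \
                 --field phi.nii.gz --out panel.json
```

Every run writes a JSON manifest (config, input hashes, seed) next to
its output; deterministic commands are bit-reproducible from their
manifests. Configuration is YAML
(`inst/extdata/default-config.yaml` documents every key, including the
descriptor parameters `K = 2, L = 2, R1 = R2 = 5` and loss weights
`20 / 2 / 0.5`).

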