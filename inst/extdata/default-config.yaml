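# Default configuration for the macmind command line.
descriptor:
  L: 2          # base patch distance (voxels); scale k samples at k*L
  R1: 5         # patch edge for the patch SSD (odd)
  R2: 5         # aggregation patch edge (odd)
  K: 2          # number of sampling scales
  # Per-scale weights (normalized to sum 1). The library default weights
  # the small-scale context 0.7 / large-scale 0.3, the ratio found
  # optimal in ratio sweeps; the alternative ordering (0.3, 0.7) is also
  # quoted in the implementation literature for the same pipeline — set
  # it here if you want the large-scale-dominant variant.
  alphas: [0.7, 0.3]
  Na: 8         # angular bins
  Nr: 2         # log-radial bins
  Nh: 2         # height bins (N = Na*Nr*Nh = 32 aggregation bins)
  eps_rel: 1.0e-6
loss:
  lambda_sim: 20
  lambda_label: 2
  lambda_smo: 0.5
registration:
  metric: macmind
  levels: [4, 2]        # coarse-to-fine downsampling factors
  iterations: [10, 25]
  step: 0.3             # per-step update scale (voxels)
  smooth_sigma: 4       # Gaussian width of each update (voxels)
  field_sigma: 1        # Gaussian width applied to the field per step
  kappa: 0.1            # demons force normalization floor (relative)
  tol: 1.0e-5
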