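# mspalm

Illumination-invariant multispectral palmprint image fusion and recognition
in R.

Palmprint identification systems capture each palm at four spectral bands —
Blue, Green, Red and near-infrared (NIR) — because the bands see
complementary structure: surface principal lines and wrinkles dominate the
visible bands, while Red/NIR light penetrates deeper and adds subdermal vein
patterns. In uncontrolled settings the lighting is also uneven, which
cripples recognisers that work on raw intensities. `mspalm` implements a
full image-level fusion pipeline that is robust to multiplicative shading:

1. **FABEMD decomposition + illumination compensation.** Each band image is
   decomposed by the fast and adaptive bidimensional empirical mode
   decomposition into `K` bidimensional intrinsic mode functions (BIMFs)
   plus a residue, `I = Σ Sᵢ + R`, using MAX/MIN order-statistics envelope
   filters whose window size adapts to the spacing of the local extrema.
   The smoothed residue `R_s` estimates the illumination trend, and each
   BIMF is divided by it (`S̃ᵢ = Sᵢ / R_s`, guarded by `eps = 1e-5`),
   cancelling multiplicative shading.
2. **Weighted-Fisher fusion.** The compensated BIMFs of all bands form the
   columns of a per-sample matrix `V` and the fused image is `F = V φ`. The
   coefficient vector solves the generalized eigenproblem `D φ = λ D_w φ`
   built from contribution-weighted between- and within-class scatter
   matrices, where each training sample's weight `μ ∈ [0, 1]` is the
   Gaussian-weighted fraction of other-class samples among its `k` nearest
   neighbours — border samples drive the projection, interior samples do
   not. The classic Fisher criterion (`μ ≡ 1`) and the sum rule
   (`φ ∝ 1`) are included as baselines.
3. **Tensor-based extreme learning machine (TELM).** A single-hidden-layer
   classifier whose input weights are the truncated HOSVD factor matrices
   `U₂, U₃` of the training image tensor (preserving 2D structure) and
   whose output weights come from one pseudoinverse solve `β = H† T`.
   Classic random-weight ELM and a 1-NN matcher are included as baselines.

Because the pipeline's reference databases are licensed, the package ships a
seeded synthetic generator of multispectral palm-like image sets (shared
curvilinear strokes across bands, extra veins in Red/NIR, per-band sensor
noise, co-registered jitter, smooth multiplicative illumination fields) that
reproduces the qualitative regime the method targets.

## Worked example

Generate the standard synthetic fixture — 10 identities, 6 clean training
and 6 illumination-corrupted test samples each, 4 bands at 64×64 — and run
the full pipeline:

```r
library(mspalm)

spec <- synth_spec(n_classes = 10, train_per_class = 6, test_per_class = 6,
                   size = 64, illum_type = "gaussian_bump",
                   illum_strength = 0.4, seed = 1)
ds <- generate_dataset(spec)

# decompose one band of one sample
fabemd(ds$train[[1]]$bands$Blue, K = 4)
#> FABEMD decomposition: 4 BIMFs of a 64 x 64 image
#> window sizes: 3, 3, 3, 5

# full pipeline: decompose -> compensate -> weighted-Fisher fusion -> TELM
res <- run_pipeline(pipeline_config(seed = 1), ds$train, ds$test)
res
#> wfisher fusion + telm classifier: RA = 0.9833 (rank-2 1.0000) on 60 test samples
round(res$cmc[1:5], 4)
#> [1] 0.9833 1.0000 1.0000 1.0000 1.0000
```

`RA = 0.9833` means 59 of the 60 illumination-corrupted test samples were
identified correctly; the cumulative match characteristic reaches 1 at
rank 2, i.e. the true identity is always among the top two scores. The
baselines on the same data show what each stage buys:

```r
run_pipeline(pipeline_config(rule = "sum", seed = 1), ds$train, ds$test)
#> sum fusion + telm classifier: RA = 0.9167 (rank-2 0.9333) on 60 test samples

run_pipeline(pipeline_config(bands = "Blue", seed = 1), ds$train, ds$test)
#> wfisher fusion + telm classifier: RA = 0.9500 (rank-2 0.9500) on 60 test samples
```

The discriminatively fused four-band images (0.9833) beat both the
unweighted sum rule (0.9167) and the best the Blue band can do alone
(0.9500).

A thin command-line wrapper over the same functions is installed as
`exec/mspalm` (`simulate`, `decompose`, `fuse`, `evaluate` subcommands).

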