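# endosr

Endoscopy-style image super-resolution and miniature multi-view 3D
reconstruction, in R.

Endoscopic frames are low-resolution and heavily textured, and everything
downstream — feature matching, camera pose estimation, dense depth, surface
meshing — inherits every pixel the sensor never captured. `endosr` implements
the full chain needed to study that coupling on one machine:

* a **single-image super-resolution network** built from omnidirectional
  self-attention (spatial `A_s = softmax(QKᵀ/√d_k)` and channel
  `A_c = softmax(KᵀQ/√d_k)` attention combined per token block), multi-scale
  aggregation groups (local convolution block → windowed meso attention →
  strided-grid global attention), a dual-stream adaptive focus mechanism that
  predicts softmax-normalised fusion weights for the two attention streams,
  and a dynamic edge-adjustment stage `X' = X + (W_e ∗ X + b_e)`; trained by
  Adam on an L1 loss over a built-in reverse-mode autodiff engine;
* a **structure-from-motion stack**: difference-of-Gaussian keypoints,
  128-component gradient descriptors, ratio-test matching, normalised
  8-point essential matrix in RANSAC, PnP registration, DLT + Gauss–Newton
  triangulation, and Levenberg–Marquardt bundle adjustment minimising
  `Σᵢ ‖xᵢ − π(K, R, t, Xᵢ)‖²`;
* a **multi-view-stereo stage**: NCC plane-sweep depth maps over
  inverse-depth hypotheses, multi-view consistency fusion into an oriented
  point cloud, and a screened-Poisson indicator solve (`∇²χ = ∇·V`) with
  marching-tetrahedra iso-surface extraction and mesh quality metrics
  (vertices, faces, density, texture blocks);
* a **synthetic-data module** that renders endoscopy-like textures (vessels,
  mucosal spots, vignette) and multi-view tube/sphere/plane interiors with
  exact ground-truth cameras and depth, so every stage is validated against
  analytic truth.

An end-to-end pipeline reproduces the A/B design the package exists for:
reconstruct the same scene once from raw low-resolution frames and once from
their ×2 super-resolved versions, and compare mesh quality.

## Worked example: train the tiny SR model

```r
library(endosr)

ds    <- make_sr_dataset(10, texture_spec(size_hr = c(64, 64)), scale = 2, seed = 11)
model <- sr_model(sr_config(scale = 2, channels = 32, n_groups = 2,
                            window = 4, grid = 4), seed = 1)
fit   <- sr_train(model, ds, train_config(epochs = 40, batch_size = 2,
                                          learning_rate = 1e-3, lr_decay = 0.5,
                                          decay_every = 40, seed = 1))
round(fit$loss_trace[c(1, 10, 20, 40)], 4)
#> [1] 0.4928 0.0368 0.0248 0.0230
sr_evaluate(model, ds)
#> SR evaluation on 2 image(s), x2 (border crop 2 px)
#>   model    : PSNR 30.1174 dB  SSIM 0.9209
#>   bicubic  : PSNR 29.5406 dB  SSIM 0.9113
#>   gain     : +0.5768 dB PSNR  +0.0096 SSIM
```

The loss trace falls by ~20× over 40 epochs and the trained network beats
bicubic upscaling by ~0.58 dB PSNR on held-out synthetic pairs — the
network's sub-pixel tail starts as a bicubic interpolator, so training
capacity goes into recovering detail beyond interpolation.

## Worked example: reconstruct a rendered scene

```r
intr  <- camera_intrinsics(fx = 150, fy = 150, cx = 95.5, cy = 71.5,
                           height = 144, width = 192)
tex   <- texture_spec(size_hr = c(768, 768), n_vessels = 60,
                      vessel_width_px = 8, n_spots = 2200,
                      noise_sigma = 0, seed = 3)
views <- render_views(scene_spec("tube_interior", texture = tex,
                                 n_views = 5, seed = 2), intr)
K      <- intrinsics_matrix(intr)
sparse <- reconstruct_sparse(lapply(views, `[[`, "image"), K,
                             seed = 1, contrast_thresh = 0.005)
#> 72 tracks, mean reprojection 0.380 px
align_to_ground_truth(sparse, views)$rot_err_deg
#> [1] 0.91 0.60 0.59 1.02 1.82        # degrees, after similarity alignment
dense <- reconstruct_dense(lapply(views, `[[`, "image"), sparse$poses, K,
                           sparse = sparse)
dense$metrics
#> mesh: 32950 vertices, 64730 faces, area 8.1158,
#>       density 4059.99 vertices/area, 2632 texture blocks
```

All five cameras are recovered to better than 2° and the fused depth maps
mesh into a single watertight tube wall. `write_ply()`, `write_depth()` and
`write_cameras()` export every artifact in open text formats.

The full A/B experiment is one call (or `Rscript inst/cli/endosr.R pipeline`):

```r
man <- run_pipeline(pipeline_config(seed = 1, out_dir = "run"), ab_compare = TRUE)
man$metrics   # mesh metrics for the "sr" and "raw" branches
```

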