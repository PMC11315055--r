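---
title: "Methods: attention-based super-resolution and miniature multi-view reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-based super-resolution and miniature multi-view reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

endosr addresses a concrete problem in endoscopic imaging: frames are
low-resolution and heavily textured, and 3D models reconstructed from them
inherit every lost pixel.  The package implements (i) a single-image
super-resolution (SR) network built around omnidirectional self-attention,
(ii) a miniature incremental structure-from-motion (SfM) and plane-sweep
multi-view-stereo (MVS) stack, and (iii) a synthetic-data module that renders
endoscopy-like scenes with exact ground truth so that every stage can be
validated end to end.  This vignette explains the models, the defaults, the
numerical choices, and what the synthetic experiments do and do not show.

## 1. The super-resolution network

### Omnidirectional self-attention (OSA)

A feature map block of `N` tokens with `C` channels is projected to
`Q = X W_Q`, `K = X W_K`, `V = X W_V`.  Two attention maps are formed:

* spatial: `A_s = softmax(Q K' / sqrt(d_k))`, an `N x N` row-stochastic
  matrix over token pairs;
* channel: `A_c = softmax(K' Q / sqrt(d_k))`, a `C x C` row-stochastic
  matrix over channel pairs.

The output combines both streams additively, `Y = sigma(A_s V + (A_c V')')`,
with `sigma` an activation.  The scaling dimension `d_k` defaults to `C` (the
same quantity scales both maps).  Two open choices are resolved as follows
and kept configurable:

* the activation after the combination is GELU (`act_attn`), the standard
  choice in modern attention blocks; a sequential spatial-then-channel
  variant is available via `attn_mode = "sequential"`;
* "applying `A_c`" to a token matrix means acting on the transposed matrix:
  `(A_c V')'`, i.e. channels attend over channels.

### Multi-scale aggregation (OSAG)

Each aggregation group chains three scales:

1. **LCB** — an inverted-bottleneck convolution block (1x1 expansion,
   depthwise 3x3, squeeze-excitation gating, 1x1 projection, residual);
2. **meso OSA** — the map is cut into non-overlapping `P x P` windows
   (`window_partition()`, shape `(HW/P^2, P^2, C)`) and OSA runs per window;
3. **global OSA** — `grid_partition()` gathers, for each of the `HW/G^2`
   cell offsets, the `G^2` grid positions strided by `(H/G, W/G)`; attention
   over those tokens spans the whole map sparsely.

The grid stage deserves a note: with the alternative reading (dilation-`G`
blocks of `HW/G^2` interacting tokens) the attention matrix grows
quadratically with image area — a single 640x480 frame would need roughly
11 GB for one map — so the strided-token semantics (as in MaxViT-style grid
attention, and matching the stated stride `(H/G, W/G)`) is the only variant
that can process full frames.  Both partitions are exact integer
permutations, inverted bit-for-bit by `window_merge()` / `grid_merge()`.

Group output is `X_i = SE(conv3x3(X_res + X_{i-1}))`.  Inputs whose sides are
not multiples of `lcm(P, G)` are reflect-padded before the groups and cropped
after; all convolutions are zero-padded "same"; pixel indexing is 0-based.

### Adaptive fusion (DAFM) and edge adjustment (DEAF)

DAFM predicts two normalized fusion weights from globally pooled features,
`W = softmax(W_f2 ReLU(W_f1 avgpool(X) + b_f1) + b_f2)`, and gates the
attention output: `X'_t = sigma(X (*) ReLU(ReLU(W_0 A_s X) + ReLU(W_1 A_c X))
+ beta X'_{t-1})`.  The closing `sigma` is a sigmoid by default — the gate
multiplies a feature map, and a bounded gate cannot blow activations up.
The feedback term indexes frames of a sequence; for single images
`prev = NULL` and `beta` (default 0.1) is inert.  The hidden width of the
predictor defaults to `C/4`.  Inside an OSAG the fusion is applied to the
OSA output (OSA then DAFM, composed), so both Eq-style combination and
adaptive re-weighting act.

DEAF computes a channel-wise edge response `E = W_e * X + b_e` with an odd
`k x k` kernel and adds it back, `X' = X + E`.  It is applied once, to the
deep feature map just before the shallow/deep aggregation.  The kernel is
initialised to a 4-neighbour Laplacian scaled by 0.05 so the untrained edge
response is gentle; a zero kernel makes the stage an exact identity, which
the tests exploit.

### Reconstruction tail and initialisation

The full forward pass is: shallow 3x3 convolution producing `X_0`,
`n_groups` OSAG blocks producing the deep features, DEAF, aggregation
`X_0 + X_DF`, then conv -> sub-pixel (pixel-shuffle) upsampler -> conv.  The
output is exactly `scale` times the input in each spatial dimension.

Two initialisation choices matter for small-compute training and are part of
the package design:

* main-path convolutions start as identity passthroughs plus small noise,
  and each group's closing convolution is damped (gain 0.1) so the deep path
  begins as a perturbation;
* the sub-pixel convolution starts as the separable Catmull-Rom interpolator
  reading the luminance channel, so the untrained network is already a
  bicubic upsampler and gradient steps are spent on recovering detail beyond
  interpolation rather than re-learning interpolation.

Training uses Adam on an L1 loss by default (the SR community default; L2 is
available), with step decay, deterministic given the seed.  The engine is a
small reverse-mode autodiff over dense arrays written for this package
(`R/autograd.R`); every operator's gradient is validated against finite
differences in the test suite.  Metrics: PSNR with `MAX = 1` (identical
images report `Inf`), SSIM with an 11x11 Gaussian window (sigma 1.5,
k1 = 0.01, k2 = 0.03, dynamic range 1).  Evaluation crops a `scale`-pixel
border and uses the luminance channel; both conventions change PSNR by
tenths of a dB, are documented, and are switchable.

## 2. Synthetic data: what it emulates, and what it does not

`generate_texture()` emulates the statistics that make endoscopy frames hard:
a bright smooth mucosa background with low-frequency shading, dark
curvilinear vessel-like structures, soft round spots (pit/speck analogues —
these also give blob detectors something to anchor on), radial vignetting,
and sensor noise.  Degradation to LR is anti-aliased Catmull-Rom (`a = -0.5`)
bicubic downsampling, the de-facto SR-literature standard.

`render_views()` ray-traces analytic interiors (finite textured tube, sphere
interior, plane) under a pinhole camera with zero distortion
(`x = K[R|t]X`, depth = camera-frame z, 0-based pixel centres at integers).
Lighting is Lambertian and attached to the surface, so the same surface
point has identical intensity in every view: photo-consistency is exact by
construction, which MVS validation needs.  Pixels are rendered with 2x2
supersampling; the texture would otherwise alias under minification and
break the >= 95% cross-view consistency invariant.  The renderer does not
model specular highlights, deformation, distortion or view-dependent
vignetting — so passing tests here say nothing about robustness to those
effects on clinical data.

The study scene for reconstruction is a textured tube interior traversed by
a forward-moving camera with lateral sway — the lumen geometry a scope
actually sees.  Texture density (60 vessels, 2200 spots on a 768^2 map) was
chosen so that a 144x192 view yields on the order of a hundred keypoints,
comparable to feature counts on real endoscopy frames at that size.

## 3. Sparse reconstruction

Features are scale-space DoG keypoints (3x3x3 extrema, quadratic sub-pixel
refinement, contrast and edge-ratio filtering) with 4x4x8 = 128-component
gradient-histogram descriptors computed in the keypoint's scaled, rotated
frame with trilinear soft binning, L2-normalised, clipped at 0.2 and
renormalised.  For frames under 120 px the pyramid starts one octave below
the input (2x upsampled base), the standard remedy for small images.
Matching is brute-force Euclidean distance with a mutual-nearest-neighbour
ratio test (default 0.8 for generic use; the incremental pipeline uses 0.85).
The printed distance in the source material omits the square root; the
Euclidean distance (root applied) is used — neighbour ordering is identical
either way.

The incremental pipeline estimates an essential matrix for the best
candidate pair by the normalised 8-point algorithm inside RANSAC on the
Sampson error (2000 iterations, 1.5 px, seeded), decomposes it with
cheirality checks, and requires the candidate's median triangulation angle
to fall in [1, 15] degrees — implausibly wide medians signal a wrong pose,
vanishing ones a zero baseline.  Remaining views register by PnP: a DLT
initialiser, a prior-pose initialiser, and RANSAC over minimal DLT subsets
all feed an iterated residual-trimming refinement, and the best-supported
solution wins; the raw consensus pose enters the trimming loop directly
because refining on the full set first would let gross outliers drag the
solution away.  After every registration a short bundle adjustment runs —
without it, pose errors of early views accumulate into low-frequency
distortion that the closing adjustment cannot remove.  Bundle adjustment is
Levenberg-Marquardt on the total squared reprojection error with the first
registered pose fixed as gauge and intrinsics held fixed; steps that would
increase the objective are rejected, so the accepted objective is
non-increasing by construction.  Tracks come from union-find over pairwise
matches (conflicting tracks dropped), are triangulated by DLT plus
Gauss-Newton refinement, filtered by cheirality, minimum triangulation angle
(1.5 degrees) and a depth-sanity band (0.1-8x the median depth — shallow-angle
triangulations otherwise land implausibly far away and, left in place, would
dominate any least-squares alignment).  The reconstruction is finally
rescaled to unit total trajectory length: monocular scale is arbitrary, and
this gauge makes independent runs and branches comparable.

Evaluation against rendered ground truth uses a closed-form similarity
(Umeyama) over track-point correspondences rather than camera centres — a
scope trajectory is nearly collinear, which leaves the rotation about the
trajectory axis unconstrained if only centres are used.  The fit is
trimmed (MAD prefilter, three trimming rounds) for the same outlier reason.

## 4. Dense reconstruction and surfaces

Depth maps come from fronto-parallel plane sweeps with hypotheses uniform in
inverse depth (64 planes by default; near-field resolution matters in a
lumen), scored by windowed NCC (7x7) averaged over the adjacent views, with
parabolic refinement along the inverse-depth axis — without sub-plane
refinement the fused cloud quantises onto depth shells and normal estimates
degrade.  Confidence is the best mean NCC rectified to [0, 1]; pixels under
0.6 are invalidated.  NCC uses the textbook normalised form and is exactly
invariant to positive affine intensity maps; two constant patches return a
flagged sentinel 0.

Fusion back-projects valid pixels and keeps points whose depth, re-observed
in at least one other map, agrees within 1-2% relative tolerance; colours
are sampled from the reference frames and normals come from PCA plane fits
over 12 nearest neighbours, oriented toward the observing camera.

Surfaces are extracted by a regular-grid screened-Poisson solve: normals are
splatted trilinearly and smoothed, and `-L chi + alpha W chi = -div V +
alpha W / 2` is solved matrix-free by Jacobi-preconditioned conjugate
gradients (the screening term pulls the indicator toward 1/2 at the
samples).  The iso-surface at the weighted mean indicator value is extracted
by marching tetrahedra over the translation-consistent 6-tetrahedron (Kuhn)
cube decomposition with linear interpolation along edges.  Relative to a
256-case marching-cubes table this needs only 16 per-tetrahedron sign cases,
is derivable in code, and shares every edge vertex across cells, so a closed
iso-surface yields a watertight, consistently oriented mesh — the property
the sphere acceptance check (closed, Euler characteristic 2) relies on.
Triangles farther than 3 voxels from any input point are trimmed and only
the largest connected component is kept (spurious blobs otherwise grow in
weakly sampled regions).  The grid is capped at 128 cells per axis.

Grid resolution defaults to "auto": standalone, the voxel edge is about
twice the median nearest-neighbour point spacing; inside the pipeline it is
four pixel-footprints at the median scene depth (`4 z / f_x`).  Both rules
make resolution follow what the data support — the behaviour octree-based
screened-Poisson implementations get from their depth parameter — so a
branch reconstructed from sharper images earns a finer mesh honestly rather
than by a fixed-grid artifact.

Mesh metrics report vertex and face counts, total area, density (vertices
per unit area — a declared convention, since "density" alone is ambiguous),
and texture blocks: connected same-colour regions of the vertex graph after
16-level colour quantisation.  The block count is a proxy for texture-chart
richness and is only meaningful in relative comparisons.

## 5. The A/B experiment

`run_pipeline()` renders the study scene at 96x128, optionally trains the
tiny SR model (C = 32, 2 groups) on synthetic pairs and upscales the frames
x2, then runs SfM -> MVS -> metrics on the SR branch and on the raw
low-resolution branch from the same inputs.  Brightness is normalised to the
set mean before reconstruction (the preprocessing convention adopted here).
All randomness derives from one seed through a documented hash, artifacts
are written in open formats (8-bit PNG, float32 TIFF, ASCII PLY, JSON), and
a manifest records config, hashes and timings.  On this scene the SR branch
registers its cameras more accurately, produces more valid and more accurate
depth, and its mesh carries more vertices, higher density and more texture
blocks than the raw branch — the direction of the claim the package is built
to examine.  Problem sizes throughout (10 training pairs of 64x64, five
96x128-or-144x192 views, 2000-point sphere) were chosen so the whole
validation suite runs on a single CPU in minutes; they are stand-ins for
clinical-scale experiments, not reproductions of them.

## 6. Known limitations

* The renderer's Lambertian, rigid world is much kinder than a real scope
  video; nothing here quantifies robustness to specularities, deformation or
  fluid.
* The SR network is trained at toy scale; absolute PSNR/SSIM values on
  synthetic textures say nothing about clinical image quality.
* PnP uses DLT-based initialisation rather than a minimal P3P solver; with
  fewer than ~8 correspondences registration fails rather than degrades.
* The screened-Poisson solver runs on a regular grid; memory limits
  resolution to 128 cells per axis, well below what octree implementations
  reach.
* Texture-block counting is a colour-quantisation proxy, not texture-atlas
  chart counting.
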