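# End-to-end orchestration: simulate -> (optional SR) -> SfM -> MVS ->
# metrics, with per-stage artifacts, structured logging and a reproducibility
# manifest.  The A/B design runs the reconstruction twice from the same
# low-resolution inputs, once through the SR network and once raw.

#' Dense reconstruction from calibrated images
#'
#' Plane-sweep depth maps for every view (neighbours = adjacent views),
#' multi-view consistency fusion, normal estimation, screened-Poisson
#' surface extraction and mesh metrics.  The swept depth range is derived
#' from the sparse tracks when given, otherwise it must be supplied.
#'
#' @param images list of grayscale images
#' @param poses list of `camera_pose` (one per image)
#' @param K 3x3 intrinsics matrix
#' @param sparse optional `sparse_cloud` used to derive the depth range
#' @param depth_range optional `c(min, max)` override
#' @param n_planes,window,conf_floor plane-sweep parameters
#' @param consistency_views,consistency_tol fusion parameters
#' @param stride fusion pixel stride
#' @param max_points fused cloud size cap
#' @param grid_resolution Poisson grid resolution (or `"auto"`)
#' @param verbose print stage progress
#' @return list with `depth_maps`, `cloud`, `mesh`, `metrics`
#' @export
reconstruct_dense <- function(images, poses, K, sparse = NULL,
                              depth_range = NULL, n_planes = 64L,
                              window = 7L, conf_floor = 0.6,
                              consistency_views = 1L, consistency_tol = 0.02,
                              stride = 2L, max_points = 12000L,
                              grid_resolution = "auto", verbose = FALSE) {
  nv <- length(images)
  stopifnot(nv >= 2L, length(poses) == nv)
  if (is.null(depth_range)) {
    if (is.null(sparse))
      stop("either a sparse cloud or an explicit depth_range is required")
    zs <- unlist(lapply(sparse$tracks, function(tr)
      vapply(tr$views, function(v)
        (poses[[v]]$R %*% tr$X + poses[[v]]$t)[3], numeric(1))))
    zs <- zs[zs > 0]
    depth_range <- c(max(1e-6, 0.5 * stats::quantile(zs, 0.05)),
                     1.8 * stats::quantile(zs, 0.95))
  }
  if (verbose)
    message(sprintf("plane sweep over depth [%.3f, %.3f], %d planes",
                    depth_range[1], depth_range[2], n_planes))
  dms <- vector("list", nv)
  for (v in seq_len(nv)) {
    nbs <- setdiff(max(1L, v - 1L):min(nv, v + 1L), v)
    dms[[v]] <- depth_map_plane_sweep(images[[v]], poses[[v]],
                                      images[nbs], poses[nbs], K,
                                      depth_range[1], depth_range[2],
                                      n_planes, window, conf_floor)
    if (verbose)
      message(sprintf("view %d depth map: %d valid px", v, dms[[v]]$n_valid))
  }
  cloud <- fuse_depth_maps(lapply(dms, `[[`, "depth"), poses, K,
                           images = images,
                           consistency_views = consistency_views,
                           tol = consistency_tol, stride = stride,
                           max_points = max_points)
  if (verbose) message(sprintf("fused cloud: %d points", nrow(cloud$points)))
  if (identical(grid_resolution, "auto")) {
    # mesh resolution follows what the images can resolve: voxel size
    # proportional to the pixel footprint at the median scene depth
    zmed <- stats::median(unlist(lapply(dms, function(d)
      d$depth[d$depth > 0])))
    h <- 4 * zmed / K[1, 1]
    ext <- apply(cloud$points, 2, function(x) diff(range(x)))
    grid_resolution <- max(24L, min(128L, as.integer(ceiling(max(ext) / h))))
    if (verbose)
      message(sprintf("Poisson resolution %d (pixel-footprint voxel %.4g)",
                      grid_resolution, h))
  }
  mesh <- poisson_surface(cloud, grid_resolution = grid_resolution,
                          verbose = verbose)
  list(depth_maps = dms, cloud = cloud, mesh = mesh,
       metrics = mesh_metrics(mesh))
}

#' Match every image's mean intensity to the set average
#' @param images list of grayscale images
#' @return list of brightness-normalized images (clipped to \[0, 1\])
#' @export
normalize_brightness <- function(images) {
  means <- vapply(images, mean, numeric(1))
  target <- mean(means)
  lapply(seq_along(images), function(i)
    clip01(images[[i]] * (target / max(means[i], 1e-9))))
}

#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived from it
#' @param out_dir output directory for artifacts
#' @param n_views number of rendered views
#' @param scale SR scale factor
#' @param lr_size rendered low-resolution image size (H, W)
#' @param train_epochs SR training epochs (0 = identity/bicubic tail only)
#' @param sr_channels,sr_groups tiny-model architecture for the SR stage
#' @param stages ordered subset of simulate, sr, sfm, mvs, metrics
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("endosr_run_"),
                            n_views = 5L, scale = 2L,
                            lr_size = c(96L, 128L), train_epochs = 30L,
                            sr_channels = 32L, sr_groups = 2L,
                            stages = c("simulate", "sr", "sfm", "mvs",
                                       "metrics")) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_views = as.integer(n_views), scale = as.integer(scale),
                 lr_size = as.integer(lr_size),
                 train_epochs = as.integer(train_epochs),
                 sr_channels = as.integer(sr_channels),
                 sr_groups = as.integer(sr_groups),
                 stages = stages),
            class = "pipeline_config")
}

#' Write a pipeline configuration as flat YAML
#' @param config a [pipeline_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with [pipeline_config()] fields
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipeline_config, v[intersect(names(v),
                                       names(formals(pipeline_config)))])
}

pipeline_scene <- function(config) {
  # study scene: a textured tube interior viewed by a forward-moving scope
  tex <- texture_spec(size_hr = c(768L, 768L), n_vessels = 60L,
                      vessel_width_px = 8, n_spots = 2200L,
                      noise_sigma = 0, seed = derive_seed(config$seed, "tex"))
  scene_spec("tube_interior", texture = tex, n_views = config$n_views,
             seed = derive_seed(config$seed, "scene"))
}

pipeline_intrinsics <- function(lr_size, scale = 1L) {
  H <- lr_size[1] * scale; W <- lr_size[2] * scale
  f <- 0.78 * W
  camera_intrinsics(fx = f, fy = f, cx = (W - 1) / 2, cy = (H - 1) / 2,
                    height = H, width = W)
}

stage_log <- function(state, stage, msg, verbose = TRUE) {
  line <- sprintf("[%s] %-8s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  if (verbose) message(line)
  c(state, line)
}

#' Run the end-to-end pipeline
#'
#' Renders a synthetic scene at low resolution, optionally trains and applies
#' the SR network, reconstructs sparse and dense geometry from the chosen
#' branch(es), and writes all artifacts (PNG, float TIFF, ASCII PLY, JSON
#' metrics) plus a reproducibility manifest with file hashes.
#'
#' With `ab_compare = TRUE` (the A/B design) the reconstruction runs twice
#' from the same low-resolution renders — once on the SR-upscaled images and
#' once on the raw inputs — and both mesh metric records are written,
#' tagged `sr` and `raw`.
#'
#' @param config a [pipeline_config()]
#' @param ab_compare run both the SR and the raw branch
#' @param verbose print structured progress
#' @return the run manifest (invisibly): per-stage outputs, hashes, timings,
#'   and for each branch the `mesh_metrics`
#' @export
run_pipeline <- function(config = pipeline_config(), ab_compare = TRUE,
                         verbose = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logs <- character(0)
  t_all <- Sys.time()
  manifest <- list(version = "endosr-0.1.0", config = unclass(config),
                   stages = list())
  artifacts <- character(0)
  timing <- function(t0) round(as.numeric(Sys.time() - t0, units = "secs"), 2)

  # ---- simulate ------------------------------------------------------------
  t0 <- Sys.time()
  intr_lr <- pipeline_intrinsics(config$lr_size)
  views <- render_views(pipeline_scene(config), intr_lr)
  sim_dir <- file.path(config$out_dir, "sim")
  dir.create(sim_dir, showWarnings = FALSE)
  for (i in seq_along(views)) {
    write_image(views[[i]]$image,
                file.path(sim_dir, sprintf("view_%03d.png", i)))
    write_depth(views[[i]]$depth_gt,
                file.path(sim_dir, sprintf("depth_%03d.tif", i)))
  }
  write_cameras(lapply(views, `[[`, "pose"), intr_lr,
                file.path(sim_dir, "cameras.txt"))
  artifacts <- c(artifacts, list.files(sim_dir, full.names = TRUE))
  logs <- stage_log(logs, "simulate",
                    sprintf("%d views at %dx%d (%.2fs)", length(views),
                            config$lr_size[1], config$lr_size[2],
                            timing(t0)), verbose)
  manifest$stages$simulate <- list(n_views = length(views), secs = timing(t0))
  if (!any(c("sr", "sfm", "mvs") %in% config$stages))
    return(invisible(finish_manifest(manifest, artifacts, logs, config,
                                     t_all)))

  lr_imgs <- lapply(views, `[[`, "image")

  # ---- sr ------------------------------------------------------------------
  sr_imgs <- NULL
  if ("sr" %in% config$stages) {
    t0 <- Sys.time()
    cfg <- sr_config(scale = config$scale, channels = config$sr_channels,
                     n_groups = config$sr_groups, window = 4L, grid = 4L)
    model <- sr_model(cfg, seed = derive_seed(config$seed, "model"))
    if (config$train_epochs > 0L) {
      ds <- make_sr_dataset(10L, texture_spec(size_hr = c(64L, 64L)),
                            scale = config$scale,
                            seed = derive_seed(config$seed, "srdata"))
      tr <- sr_train(model, ds,
                     train_config(epochs = config$train_epochs,
                                  batch_size = 2L, learning_rate = 1e-3,
                                  lr_decay = 0.5, decay_every = 40L,
                                  seed = derive_seed(config$seed, "train")))
      utils::write.csv(data.frame(epoch = seq_along(tr$loss_trace),
                                  loss = tr$loss_trace),
                       file.path(config$out_dir, "sr_loss.csv"),
                       row.names = FALSE)
      artifacts <- c(artifacts, file.path(config$out_dir, "sr_loss.csv"))
    }
    save_model(model, file.path(config$out_dir, "sr_model.json"))
    sr_dir <- file.path(config$out_dir, "sr")
    dir.create(sr_dir, showWarnings = FALSE)
    sr_imgs <- lapply(lr_imgs, function(im) network_forward(im, model))
    for (i in seq_along(sr_imgs))
      write_image(sr_imgs[[i]],
                  file.path(sr_dir, sprintf("view_%03d.png", i)))
    artifacts <- c(artifacts, file.path(config$out_dir, "sr_model.json"),
                   list.files(sr_dir, full.names = TRUE))
    logs <- stage_log(logs, "sr",
                      sprintf("trained %d epochs, upscaled %d views (%.2fs)",
                              config$train_epochs, length(sr_imgs),
                              timing(t0)), verbose)
    manifest$stages$sr <- list(epochs = config$train_epochs,
                               secs = timing(t0))
  }

  # ---- reconstruction branches --------------------------------------------
  branches <- list()
  if (!is.null(sr_imgs))
    branches$sr <- list(images = sr_imgs,
                        intr = pipeline_intrinsics(config$lr_size,
                                                   config$scale))
  if (ab_compare || is.null(sr_imgs))
    branches$raw <- list(images = lr_imgs, intr = intr_lr)

  results <- list()
  for (tag in names(branches)) {
    br <- branches[[tag]]
    imgs <- normalize_brightness(br$images)
    K <- intrinsics_matrix(br$intr)
    bdir <- file.path(config$out_dir, tag)
    dir.create(bdir, showWarnings = FALSE)
    res <- list()
    if ("sfm" %in% config$stages) {
      t0 <- Sys.time()
      # RANSAC-dependent stages can fail on an unlucky draw; retry with
      # shifted derived seeds before giving up
      sparse <- NULL; last_err <- NULL
      for (attempt in 0:2) {
        sparse <- tryCatch(
          reconstruct_sparse(imgs, K,
                             seed = derive_seed(config$seed,
                                                paste0("sfm", attempt)),
                             contrast_thresh = 0.005),
          error = function(e) { last_err <<- e; NULL })
        if (!is.null(sparse)) break
        logs <- stage_log(logs, "sfm",
                          sprintf("[%s] attempt %d failed: %s", tag,
                                  attempt + 1L, conditionMessage(last_err)),
                          verbose)
      }
      if (is.null(sparse)) stop("sfm stage failed for branch ", tag, ": ",
                                conditionMessage(last_err))
      spc <- structure(list(points = do.call(rbind, lapply(sparse$tracks,
                                                           `[[`, "X")),
                            normals = NULL, colors = NULL),
                       class = "oriented_cloud")
      write_ply(spc, file.path(bdir, "sparse.ply"))
      write_cameras(sparse$poses[sparse$registered], br$intr,
                    file.path(bdir, "cameras_estimated.txt"),
                    names = sprintf("view_%03d", sparse$registered))
      artifacts <- c(artifacts, file.path(bdir, "sparse.ply"),
                     file.path(bdir, "cameras_estimated.txt"))
      logs <- stage_log(logs, "sfm",
                        sprintf("[%s] %d tracks, %.3f px reprojection (%.2fs)",
                                tag, length(sparse$tracks),
                                sparse$mean_reproj_px, timing(t0)), verbose)
      manifest$stages[[paste0("sfm_", tag)]] <-
        list(tracks = length(sparse$tracks),
             mean_reproj_px = sparse$mean_reproj_px, secs = timing(t0))
      res$sparse <- sparse
    }
    if ("mvs" %in% config$stages) {
      t0 <- Sys.time()
      # dense reconstruction uses the registered subset only
      reg <- res$sparse$registered
      sub <- res$sparse
      sub$poses <- res$sparse$poses[reg]
      sub$tracks <- lapply(res$sparse$tracks, function(tr) {
        keep <- tr$views %in% reg
        list(X = tr$X, views = match(tr$views[keep], reg),
             uv = tr$uv[keep, , drop = FALSE])
      })
      dense <- reconstruct_dense(imgs[reg], sub$poses, K,
                                 sparse = sub, verbose = FALSE)
      for (v in seq_along(dense$depth_maps))
        write_depth(dense$depth_maps[[v]]$depth,
                    file.path(bdir, sprintf("depth_%03d.tif", v)))
      write_ply(dense$cloud, file.path(bdir, "dense.ply"))
      write_ply(dense$mesh, file.path(bdir, "mesh.ply"))
      artifacts <- c(artifacts, file.path(bdir, "dense.ply"),
                     file.path(bdir, "mesh.ply"),
                     list.files(bdir, pattern = "depth_.*tif",
                                full.names = TRUE))
      logs <- stage_log(logs, "mvs",
                        sprintf("[%s] %d points, mesh V=%d F=%d (%.2fs)",
                                tag, nrow(dense$cloud$points),
                                dense$metrics$vertices,
                                dense$metrics$faces, timing(t0)), verbose)
      manifest$stages[[paste0("mvs_", tag)]] <-
        list(points = nrow(dense$cloud$points), secs = timing(t0))
      res$dense <- dense
      if ("metrics" %in% config$stages) {
        jsonlite::write_json(unclass(dense$metrics),
                             file.path(bdir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        artifacts <- c(artifacts, file.path(bdir, "metrics.json"))
        manifest$metrics[[tag]] <- unclass(dense$metrics)
      }
    }
    results[[tag]] <- res
  }
  manifest$results <- lapply(results, function(r)
    list(metrics = if (!is.null(r$dense)) unclass(r$dense$metrics)))
  out <- finish_manifest(manifest, artifacts, logs, config, t_all)
  out$branches <- results
  invisible(out)
}

finish_manifest <- function(manifest, artifacts, logs, config, t_all) {
  manifest$wall_clock_secs <- round(as.numeric(Sys.time() - t_all,
                                               units = "secs"), 2)
  manifest$hashes <- as.list(tools::md5sum(sort(unique(artifacts))))
  names(manifest$hashes) <- basename(names(manifest$hashes))
  manifest$log <- logs
  jsonlite::write_json(manifest[setdiff(names(manifest), "branches")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(logs, file.path(config$out_dir, "run.log"))
  manifest
}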