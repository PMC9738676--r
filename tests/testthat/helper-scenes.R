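# On-disk scene-set fixture shared by the pipeline and acceptance tests:
# left/right PGM frames, per-blob instance masks and a calibration YAML,
# with blob depths drawn from a known cosine detection function
# (a1 = 0.5, truncations 3-11 m). With b f = 160 px m every depth in
# [3, 11] m renders to an integer shift in [15, 53] px, so the fused
# distances stay inside the truncation range after quantization.
make_scene_set <- function(root, n_scenes, seed, f_px = 320, width = 96, height = 72) {
  dir.create(file.path(root, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  true <- detection_function("uniform", 1L, coefficients = 0.5)
  depths <- simulate_distances(true, n_scenes, seed = seed)
  for (i in seq_len(n_scenes)) {
    spec <- scene_spec(width = width, height = height,
                       rig = stereo_rig(0.5, f_px), background_depth_m = 20,
                       blobs = list(list(center = c(70, 36), radius = 10,
                                         depth_m = depths[i])),
                       seed = seed + i)
    sc <- render_stereo_pair(spec)
    fid <- sprintf("frame_%04d", i)
    write_pgm(sc$pair$left, file.path(root, "frames", paste0(fid, "_L.pgm")))
    write_pgm(sc$pair$right, file.path(root, "frames", paste0(fid, "_R.pgm")))
    write_pgm(sc$masks[[1]] * 1, file.path(root, "masks", paste0(fid, "_1.pgm")))
  }
  writeLines(c("baseline_m: 0.5", sprintf("focal_px: %g", f_px),
               sprintf("image_width: %d", width), sprintf("image_height: %d", height)),
             file.path(root, "calib.yaml"))
  list(true_a1 = 0.5, depths = depths)
}

write_pipeline_cfg <- function(root, out_dir, max_disparity = 56) {
  cfg <- file.path(root, "pipeline.yaml")
  writeLines(c(
    sprintf("calibration: %s", file.path(root, "calib.yaml")),
    sprintf("left_glob: %s", file.path(root, "frames", "*_L.pgm")),
    sprintf("right_glob: %s", file.path(root, "frames", "*_R.pgm")),
    sprintf("masks_dir: %s", file.path(root, "masks")),
    sprintf("max_disparity: %d", max_disparity),
    "patch_half_height: 1",
    "seed: 7",
    sprintf("out_dir: %s", out_dir)), cfg)
  cfg
}
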