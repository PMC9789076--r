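# Small phantoms used throughout the unit tests. Geometry is scaled to a
# 64 x 56 x 48 grid so one phantom renders in well under a second; the
# acceptance tests use the full protocol grid where the property demands it.

small_grid <- function() acquisition_grid(64, 56, 48)

small_spec <- function(disc_radius_vox = 14, pps_width_vox = 12,
                       lc_thickness_vox = 4, pps_thickness_vox = 5,
                       cup_depth_vox = 4, sclera_curv_vox = 2.5,
                       pore_count = 6L, pore_radius_vox = 1,
                       vessel_count = 2L, lcd_radial_vox = 4, ...) {
  phantom_spec(grid = small_grid(), disc_radius_vox = disc_radius_vox,
               pps_width_vox = pps_width_vox,
               lc_thickness_vox = lc_thickness_vox,
               pps_thickness_vox = pps_thickness_vox,
               cup_depth_vox = cup_depth_vox,
               sclera_curv_vox = sclera_curv_vox, pore_count = pore_count,
               pore_radius_vox = pore_radius_vox,
               vessel_count = vessel_count, lcd_radial_vox = lcd_radial_vox,
               ...)
}

mid_grid <- function() acquisition_grid(128, 112, 96)

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, spec) {
  if (is.null(.phantom_cache[[key]]))
    assign(key, generate_phantom(spec), envir = .phantom_cache)
  .phantom_cache[[key]]
}

small_defect_phantom <- function()
  cached_phantom("defect", small_spec(seed = 7, has_lcd = TRUE))

small_clean_phantom <- function()
  cached_phantom("clean", small_spec(seed = 7))

# detection thresholds matched to the small phantom's defect/pore sizes
small_detect <- function(labels, geom = NULL, ...)
  detect_lcd(labels, geom, min_size = 40, min_enface_diam = 4,
             depth_halfwidth_vox = 1, ...)

# run annotation -> baseline training -> dense prediction -> fusion
fused_baseline_prediction <- function(gt, seed = 11L) {
  preds <- list()
  for (p in c("axial", "sagittal", "coronal")) {
    fr <- extract_slices(gt$intensity, p)
    ann <- simulate_sparse_annotation(gt$labels, p, seed = seed)
    m <- train_plane_segmenter(fr, ann, segmenter_config("baseline"))
    preds[[p]] <- stack_slices(predict_plane(m, fr))
  }
  fuse_planes(preds$axial, preds$sagittal, preds$coronal)
}

random_label_volume <- function(dims, seed = 1) {
  withr::with_seed(seed,
    label_volume(array(sample(0:2, prod(dims), replace = TRUE), dim = dims)))
}

# plain array (no spacing/laterality attributes) for oracle comparisons
as_plain <- function(v) array(as.vector(unclass(v)), dim(v))
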