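#' Estimate optic disc geometry from a label volume
#'
#' Center is the LC centroid, radius the 95th percentile of en-face radial
#' distances of LC voxels from that centroid, and the disc axis the
#' smallest-variance principal direction of the LC voxel coordinates
#' (oriented toward positive depth).
#'
#' @param labels a [label_volume()] containing LC voxels.
#' @param laterality `"OD"` or `"OS"`; defaults to the volume's attribute.
#' @return A `disc_geometry` list with `center`, `radius_vox`, `axis` and
#'   `laterality`.
#' @export
estimate_disc_geometry <- function(labels, laterality = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  laterality <- laterality %||% laterality_of(labels)
  if (laterality == "unknown") laterality <- "OD"
  coords <- which(unclass(labels) == 1L, arr.ind = TRUE)
  if (nrow(coords) == 0)
    stop("cannot estimate disc geometry: no LC voxels in volume",
         call. = FALSE)
  center <- colMeans(coords)
  r_en <- sqrt((coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2)
  radius <- max(unname(quantile(r_en, 0.95)), 0.5)
  axis <- c(0, 0, 1)
  if (nrow(coords) >= 4) {
    ev <- eigen(cov(coords), symmetric = TRUE)
    axis <- ev$vectors[, which.min(ev$values)]
    if (axis[3] < 0) axis <- -axis
  }
  structure(list(center = unname(center), radius_vox = radius,
                 axis = unname(axis), laterality = laterality),
            class = "disc_geometry")
}

# en-face angle of (da, ds) offsets in the laterality-aware frame:
# 0 deg = temporal (+a for OD, -a for OS), 90 deg = superior (+s)
enface_angle <- function(da, ds, laterality) {
  (atan2(ds, temporal_sign(laterality) * da) * 180 / pi) %% 360
}

#' Detect lamina cribrosa defects in a fused label volume
#'
#' Candidates are 26-connected background components inside the rim search
#' band: the annulus around the estimated disc radius, clipped in depth to
#' a window around the smoothed tissue-surface map (the region between the
#' LC and the PPS where a disinsertion can live). A candidate is reported
#' as a defect only if it is (a) full thickness - the en-face columns it
#' occupies contain no LC voxel through the whole plate while flanking
#' columns do; (b) at least `min_size` voxels; (c) not vessel-shadow-like
#' (it does not extend to the anterior volume face); (d) not pore-like
#' (en-face equivalent diameter at least `min_enface_diam`); and (e)
#' radially contained - a defect is a gap bordered by the LC on the inside
#' and the PPS on the outside, so its footprint occupies a narrow radial
#' band near the disc radius, whereas a vessel-shadow tube crossing the
#' rim spans the whole annulus radially. Regions are reported sorted by
#' size, largest first.
#'
#' @param labels fused [label_volume()].
#' @param geom a [estimate_disc_geometry()] result (computed from `labels`
#'   when `NULL`).
#' @param min_size minimum component size in voxels.
#' @param exclusion_rules apply the vessel-shadow and pore exclusions.
#' @param min_enface_diam pore/defect size threshold on the en-face
#'   equivalent diameter, voxels.
#' @param radial_window annulus as fractions of the disc radius.
#' @param max_radial_frac maximum radial spread of a defect footprint as a
#'   fraction of the disc radius (exclusion (e)).
#' @param depth_halfwidth_vox half-width of the depth band around the
#'   tissue surface; `NULL` derives it from the observed plate thickness
#'   (35% of the median per-column tissue count), keeping the band inside
#'   the plate's depth range at any resolution.
#' @param volume_id identifier recorded in the report.
#' @return An `lcd_report`: list with `volume_id`, `regions` (list of
#'   `lcd_region`s), `has_lcd` and `params`. `has_lcd` is `TRUE` iff
#'   `regions` is non-empty; an empty report is a valid outcome.
#' @export
detect_lcd <- function(labels, geom = NULL, min_size = 150L,
                       exclusion_rules = TRUE, min_enface_diam = 8,
                       radial_window = c(0.72, 1.38), max_radial_frac = 0.55,
                       depth_halfwidth_vox = NULL, volume_id = "volume") {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(geom)) geom <- estimate_disc_geometry(labels)
  arr <- unclass(labels)
  dims <- dim(arr)
  na <- dims[1]; ns <- dims[2]; nc <- dims[3]

  da <- seq_len(na) - geom$center[1]
  ds <- seq_len(ns) - geom$center[2]
  r_en <- sqrt(outer(da^2, ds^2, "+"))
  annulus <- r_en >= radial_window[1] * geom$radius_vox &
             r_en <= radial_window[2] * geom$radius_vox

  zs <- tissue_surface_map(arr)
  zmap <- zs$z
  if (is.null(depth_halfwidth_vox))
    depth_halfwidth_vox <- max(1, floor(0.35 * zs$median_thickness))
  kk <- rep(seq_len(nc), each = na * ns)
  in_band <- abs(kk - as.vector(zmap)) <= depth_halfwidth_vox
  mask <- arr == 0L & as.vector(annulus) & in_band
  dim(mask) <- dims

  comp <- label_components_26(as.vector(mask), as.integer(dims))
  ncomp <- attr(comp, "n_components")
  report <- structure(list(volume_id = volume_id, regions = list(),
                           has_lcd = FALSE,
                           params = list(min_size = min_size,
                                         min_enface_diam = min_enface_diam,
                                         radial_window = radial_window,
                                         max_radial_frac = max_radial_frac,
                                         depth_halfwidth_vox =
                                           depth_halfwidth_vox,
                                         exclusion_rules = exclusion_rules)),
                      class = "lcd_report")
  if (ncomp == 0) return(report)

  lc_proj <- apply(arr == 1L, c(1, 2), any)   # en-face LC footprint
  sizes <- tabulate(comp, nbins = ncomp)
  keep <- which(sizes >= min_size)
  regions <- list()
  for (ci in keep) {
    vox <- which(comp == ci)
    coords <- cbind((vox - 1) %% na + 1,
                    ((vox - 1) %/% na) %% ns + 1,
                    (vox - 1) %/% (na * ns) + 1)
    cols <- unique(coords[, 1:2, drop = FALSE])
    col_free <- !lc_proj[cols]
    # flanking LC: LC columns within a 6-voxel ring of the footprint
    near_lc <- FALSE
    for (d in seq_len(nrow(cols))) {
      aa <- cols[d, 1]; ss <- cols[d, 2]
      wa <- max(1, aa - 6):min(na, aa + 6)
      ws <- max(1, ss - 6):min(ns, ss + 6)
      if (any(lc_proj[wa, ws])) { near_lc <- TRUE; break }
    }
    full_thickness <- mean(col_free) >= 0.8 && near_lc
    if (!full_thickness) next
    if (exclusion_rules) {
      if (any(coords[, 3] <= 1)) next               # vessel-shadow-like
      eq_diam <- 2 * sqrt(nrow(cols) / pi)
      if (eq_diam < min_enface_diam) next           # pore-like
      r_cols <- sqrt((cols[, 1] - geom$center[1])^2 +
                     (cols[, 2] - geom$center[2])^2)
      spread <- diff(unname(quantile(r_cols, c(0.02, 0.98))))
      if (spread > max_radial_frac * geom$radius_vox) next  # shadow tube
    }
    ang <- enface_angle(mean(coords[, 1]) - geom$center[1],
                        mean(coords[, 2]) - geom$center[2],
                        geom$laterality)
    vang <- enface_angle(coords[, 1] - geom$center[1],
                         coords[, 2] - geom$center[2], geom$laterality)
    rel <- (vang - ang + 180) %% 360 - 180
    region <- structure(list(
      voxels = coords, size_vox = length(vox),
      centroid_angle_deg = ang,
      arc_extent_deg = max(rel) - min(rel),
      full_thickness = TRUE,
      enface_diameter = 2 * sqrt(nrow(cols) / pi)), class = "lcd_region")
    ori <- classify_orientation(region)
    region$orientation_deg <- ori$orientation_deg
    region$orientation_class <- ori$class
    region$quadrant <- classify_location(region, geom)
    regions[[length(regions) + 1]] <- region
  }
  if (length(regions) > 0) {
    ord <- order(vapply(regions, `[[`, 1, "size_vox"), decreasing = TRUE)
    report$regions <- regions[ord]
    report$has_lcd <- TRUE
  }
  report
}

# per-column mean depth of tissue voxels, gaps filled by iterative
# neighbor averaging (defect columns have no tissue of their own)
tissue_surface_map <- function(arr) {
  dims <- dim(arr)
  m <- matrix(arr != 0L, dims[1] * dims[2], dims[3])
  cnt <- rowSums(m)
  med_th <- if (any(cnt > 0)) stats::median(cnt[cnt > 0]) else 1
  zsum <- as.vector(m %*% seq_len(dims[3]))
  z <- matrix(ifelse(cnt > 0, zsum / pmax(cnt, 1), NA_real_),
              dims[1], dims[2])
  if (anyNA(z)) {
    filled <- z
    filled[is.na(filled)] <- 0
    w <- matrix(as.numeric(!is.na(z)), dims[1], dims[2])
    box <- matrix(1, 5, 5)
    for (it in 1:60) {
      if (!anyNA(z)) break
      sf <- EBImage::filter2(filled, box, boundary = "replicate")
      sw <- EBImage::filter2(w, box, boundary = "replicate")
      upd <- is.na(z) & sw > 1e-9
      z[upd] <- sf[upd] / sw[upd]
      filled[upd] <- z[upd]
      w[upd] <- 1
    }
    z[is.na(z)] <- stats::median(z, na.rm = TRUE)
  }
  list(z = z, median_thickness = med_th)
}

#' @export
print.lcd_report <- function(x, ...) {
  cat(sprintf("<LCD report> %s: %s\n", x$volume_id,
              if (x$has_lcd)
                sprintf("%d defect region(s), largest %d voxels (%s, %s)",
                        length(x$regions), x$regions[[1]]$size_vox,
                        x$regions[[1]]$quadrant,
                        x$regions[[1]]$orientation_class)
              else "no defect"))
  invisible(x)
}

#' Assign a defect to a disc quadrant
#'
#' Quadrants are fixed 90-degree sectors centered on the temporal axis in
#' the laterality-aware en-face frame: temporal `[-45, 45)`, superior
#' `[45, 135)`, nasal `[135, 225)`, inferior `[225, 315)`.
#'
#' @param region an `lcd_region` (or a bare centroid angle in degrees).
#' @param geom a `disc_geometry` (unused for a bare angle; kept for the
#'   calling convention).
#' @return `"temporal"`, `"superior"`, `"nasal"` or `"inferior"`.
#' @export
classify_location <- function(region, geom = NULL) {
  ang <- if (is.numeric(region)) region else region$centroid_angle_deg
  sector <- ((ang + 45) %% 360) %/% 90
  c("temporal", "superior", "nasal", "inferior")[sector + 1]
}

#' Classify defect orientation in the en-face projection
#'
#' The orientation is the major principal-axis angle of the region's
#' en-face voxel footprint, in `[0, 180)` with 90 deg = vertical
#' (superior-inferior). Vertical if within 30 deg of 90, horizontal if
#' within 30 deg of 0/180, oblique otherwise. A single-voxel region has no
#' orientation and is flagged degenerate.
#'
#' @param region an `lcd_region`.
#' @return List with `class`, `orientation_deg` and `degenerate`.
#' @export
classify_orientation <- function(region) {
  coords <- unique(region$voxels[, 1:2, drop = FALSE])
  if (nrow(coords) < 2)
    return(list(class = "oblique", orientation_deg = NA_real_,
                degenerate = TRUE))
  cc <- cov(coords)
  ev <- eigen(cc, symmetric = TRUE)
  major <- ev$vectors[, which.max(ev$values)]
  ang <- (atan2(major[2], major[1]) * 180 / pi) %% 180
  cls <- if (abs(ang - 90) <= 30) "vertical"
         else if (ang <= 30 || ang >= 150) "horizontal"
         else "oblique"
  list(class = cls, orientation_deg = ang, degenerate = FALSE)
}

#' Tidy an LCD report into a one-row-per-region tibble
#'
#' @param x an `lcd_report`.
#' @param ... unused.
#' @return Tibble with columns `volume_id`, `size_vox`, `quadrant`,
#'   `orientation_deg`, `orientation_class`, `centroid_angle_deg`,
#'   `arc_extent_deg`, `full_thickness`.
#' @export
tidy.lcd_report <- function(x, ...) {
  if (length(x$regions) == 0)
    return(tibble::tibble(volume_id = character(0), size_vox = integer(0),
                          quadrant = character(0),
                          orientation_deg = numeric(0),
                          orientation_class = character(0),
                          centroid_angle_deg = numeric(0),
                          arc_extent_deg = numeric(0),
                          full_thickness = logical(0)))
  tibble::tibble(
    volume_id = x$volume_id,
    size_vox = vapply(x$regions, function(r) as.integer(r$size_vox), 1L),
    quadrant = vapply(x$regions, `[[`, "", "quadrant"),
    orientation_deg = vapply(x$regions, `[[`, 1, "orientation_deg"),
    orientation_class = vapply(x$regions, `[[`, "", "orientation_class"),
    centroid_angle_deg = vapply(x$regions, `[[`, 1, "centroid_angle_deg"),
    arc_extent_deg = vapply(x$regions, `[[`, 1, "arc_extent_deg"),
    full_thickness = vapply(x$regions, `[[`, TRUE, "full_thickness"))
}

#' Write an LCD report as JSON and CSV
#'
#' @param report an `lcd_report`.
#' @param path_json,path_csv output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_lcd_report <- function(report, path_json = NULL, path_csv = NULL) {
  tab <- tidy.lcd_report(report)
  if (!is.null(path_json))
    jsonlite::write_json(
      list(volume_id = report$volume_id, has_lcd = report$has_lcd,
           params = report$params, regions = tab),
      path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_csv))
    write.csv(tab, path_csv, row.names = FALSE)
  invisible(report)
}
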