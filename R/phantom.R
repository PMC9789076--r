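#' Acquisition grid of a 3D optic-nerve-head scan
#'
#' Defaults follow a common swept-source scan protocol: a 3 x 3 mm field centered on the
#' optic disc sampled as 256 axial, 222 sagittal and 190 coronal frames
#' (the third axis is depth).
#'
#' @param n_axial,n_sagittal,n_coronal frame counts per plane-normal axis.
#' @param field_mm lateral extent of the (square) scan field in mm.
#' @param depth_mm axial (depth) extent in mm.
#' @return An `acquisition_grid` list.
#' @export
acquisition_grid <- function(n_axial = 256L, n_sagittal = 222L,
                             n_coronal = 190L, field_mm = 3.0,
                             depth_mm = 1.5) {
  stopifnot(n_axial >= 1, n_sagittal >= 1, n_coronal >= 1,
            field_mm > 0, depth_mm > 0)
  structure(list(n_axial = as.integer(n_axial),
                 n_sagittal = as.integer(n_sagittal),
                 n_coronal = as.integer(n_coronal),
                 field_mm = field_mm, depth_mm = depth_mm),
            class = "acquisition_grid")
}

grid_dims <- function(grid) c(grid$n_axial, grid$n_sagittal, grid$n_coronal)

grid_spacing <- function(grid)
  c(grid$field_mm / grid$n_axial, grid$field_mm / grid$n_sagittal,
    grid$depth_mm / grid$n_coronal)

#' Generative parameters of a synthetic optic-nerve-head phantom
#'
#' Describes one simulated eye: a bright, cup-shaped lamina cribrosa (LC)
#' plate inserted into a surrounding peripapillary sclera (PPS) shell, with
#' hyporeflective laminar pores, vessel-shadow columns, signal attenuation
#' over the temporal LC edge, optional disc tilt, multiplicative speckle
#' noise and, optionally, a full-thickness wedge defect (LCD) at the disc
#' rim. Geometric quantities are in voxel units of the lateral axes; angles
#' are measured in the en-face plane with 0 deg pointing temporally
#' (laterality-aware: temporal is +a for OD and -a for OS eyes).
#'
#' At the defaults the LC+PPS anatomy spans 210 consecutive frames along
#' the axial and sagittal axes, and pores (radius 2) are much smaller than
#' the defect's radial width (8), so pores and defects are separable by
#' size.
#'
#' @param grid an [acquisition_grid()].
#' @param seed integer RNG seed; generation is bit-reproducible.
#' @param laterality `"OD"` or `"OS"`.
#' @param disc_center length-3 voxel coordinate of the disc center, or
#'   `NULL` for the lateral grid center at 45% depth.
#' @param disc_radius_vox radius of the LC plate.
#' @param pps_width_vox radial width of the PPS annulus beyond the LC.
#' @param lc_thickness_vox,pps_thickness_vox plate thicknesses (depth).
#' @param cup_depth_vox posterior bowing of the plate at the disc center.
#' @param sclera_curv_vox anterior rise of the shell at its outer edge.
#' @param tilt_deg temporal tilt of the disc plane, degrees.
#' @param pore_count,pore_radius_vox laminar pores: hyporeflective dots in
#'   the intensity image only (their voxels stay LC-labeled).
#' @param vessel_count,vessel_radius_vox vessel shadows: hyporeflective
#'   columns running from the anterior volume face through the whole depth.
#'   All linear defaults (radii, thicknesses, defect width) are
#'   grid-proportional, so structures keep their physical size in mm when
#'   a volume is simulated at reduced resolution.
#' @param has_lcd if `TRUE`, carve a full-thickness wedge gap between LC
#'   and PPS at the rim (ignore the `lcd_*` fields otherwise).
#' @param lcd_angle_deg angular position of the defect centroid, 0 deg =
#'   temporal.
#' @param lcd_arc_deg angular extent of the defect wedge.
#' @param lcd_radial_vox radial width of the gap.
#' @param noise_level standard deviation of the unit-mean multiplicative
#'   (gamma) speckle multiplier; 0 disables noise.
#' @param temporal_attenuation fractional intensity loss over the temporal
#'   LC edge.
#' @param intensity_lc,intensity_pps,intensity_bg tissue reflectivities in
#'   `[0, 1]`; `intensity_lc` must exceed `intensity_bg`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = acquisition_grid(), seed = 1L,
                         laterality = c("OD", "OS"), disc_center = NULL,
                         disc_radius_vox = 0.215 * grid$n_axial,
                         pps_width_vox = 0.195 * grid$n_axial,
                         lc_thickness_vox = 0.037 * grid$n_coronal,
                         pps_thickness_vox = 0.047 * grid$n_coronal,
                         cup_depth_vox = 0.08 * grid$n_coronal,
                         sclera_curv_vox = 0.05 * grid$n_coronal,
                         tilt_deg = 3, pore_count = 30L,
                         pore_radius_vox = 0.0078 * grid$n_axial,
                         vessel_count = 6L,
                         vessel_radius_vox = 0.0117 * grid$n_axial,
                         has_lcd = FALSE, lcd_angle_deg = 0,
                         lcd_arc_deg = 40,
                         lcd_radial_vox = 0.031 * grid$n_axial,
                         noise_level = 0.25, temporal_attenuation = 0.35,
                         intensity_lc = 0.85, intensity_pps = 0.55,
                         intensity_bg = 0.15) {
  laterality <- match.arg(laterality)
  dims <- grid_dims(grid)
  if (is.null(disc_center))
    disc_center <- c((dims[1] + 1) / 2, (dims[2] + 1) / 2, 0.45 * dims[3])
  spec <- list(grid = grid, seed = as.integer(seed), laterality = laterality,
               disc_center = disc_center,
               disc_radius_vox = disc_radius_vox,
               pps_width_vox = pps_width_vox,
               lc_thickness_vox = lc_thickness_vox,
               pps_thickness_vox = pps_thickness_vox,
               cup_depth_vox = cup_depth_vox,
               sclera_curv_vox = sclera_curv_vox,
               tilt_deg = tilt_deg,
               pore_count = as.integer(pore_count),
               pore_radius_vox = pore_radius_vox,
               vessel_count = as.integer(vessel_count),
               vessel_radius_vox = vessel_radius_vox,
               has_lcd = isTRUE(has_lcd),
               lcd_angle_deg = lcd_angle_deg %% 360,
               lcd_arc_deg = lcd_arc_deg, lcd_radial_vox = lcd_radial_vox,
               noise_level = noise_level,
               temporal_attenuation = temporal_attenuation,
               intensity_lc = intensity_lc, intensity_pps = intensity_pps,
               intensity_bg = intensity_bg)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  dims <- grid_dims(spec$grid)
  if (spec$intensity_lc <= spec$intensity_bg)
    stop("intensity_lc must exceed intensity_bg", call. = FALSE)
  if (spec$disc_radius_vox <= 0)
    stop("disc_radius_vox must be positive", call. = FALSE)
  if (spec$noise_level < 0)
    stop("noise_level must be non-negative", call. = FALSE)
  if (spec$has_lcd && spec$pore_radius_vox >= spec$lcd_radial_vox)
    stop("pore_radius_vox must be smaller than lcd_radial_vox ",
         "(pores must be distinguishable from defects by size)",
         call. = FALSE)
  outer <- spec$disc_radius_vox + spec$pps_width_vox
  for (ax in 1:2) {
    if (spec$disc_center[ax] - outer < 2 ||
        spec$disc_center[ax] + outer > dims[ax] - 1)
      stop("disc geometry exceeds grid bounds along axis ", ax,
           ": disc_center/disc_radius_vox/pps_width_vox leave a margin ",
           "< 2 voxels", call. = FALSE)
  }
  if (spec$disc_center[3] < 2 || spec$disc_center[3] > dims[3] - 1)
    stop("disc geometry exceeds grid bounds along axis 3: disc_center",
         call. = FALSE)
  invisible(spec)
}

# temporal-signed en-face x coordinate relative to the disc center:
# +x points temporally (toward +a for OD, -a for OS)
temporal_sign <- function(laterality) if (laterality == "OS") -1 else 1

#' Generate a synthetic optic-nerve-head volume with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: a curved LC plate
#' (bent against the PPS curvature, forming the disc cup) inserted into a
#' PPS shell, plus the confounders seen in real scans - laminar pores
#' (hyporeflective dots, still LC-labeled: a pore is not a defect), vessel
#' shadows (hyporeflective columns connected to the anterior volume face),
#' attenuation over the temporal LC edge, disc tilt and speckle. When
#' `has_lcd` is set, a full-thickness unlabeled wedge separates the LC from
#' the PPS at the requested rim angle.
#'
#' @param spec a [phantom_spec()].
#' @return A `ground_truth` list with elements `intensity`
#'   ([intensity_volume()]), `labels` ([label_volume()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  dims <- grid_dims(spec$grid)
  na <- dims[1]; ns <- dims[2]; nc <- dims[3]
  ctr <- spec$disc_center
  sgn <- temporal_sign(spec$laterality)

  da <- seq_len(na) - ctr[1]
  ds <- seq_len(ns) - ctr[2]
  r_en <- sqrt(outer(da^2, ds^2, "+"))            # en-face radius (na x ns)
  xt <- matrix(sgn * da, na, ns)                  # temporal-signed x
  yv <- matrix(ds, na, ns, byrow = TRUE)          # vertical (superior +)
  outer_r <- spec$disc_radius_vox + spec$pps_width_vox

  # depth of the plate mid-surface: disc cup + scleral curvature + tilt
  zsurf <- ctr[3] +
    spec$cup_depth_vox * exp(-(r_en / (0.9 * spec$disc_radius_vox))^2) -
    spec$sclera_curv_vox * (r_en / outer_r)^2 +
    tanpi(spec$tilt_deg / 180) * xt

  in_lc <- r_en <= spec$disc_radius_vox
  in_pps <- r_en > spec$disc_radius_vox & r_en <= outer_r
  half_lc <- spec$lc_thickness_vox / 2
  half_pps <- spec$pps_thickness_vox / 2

  labels <- array(0L, dim = dims)
  kk <- rep(seq_len(nc), each = na * ns)
  zd <- abs(kk - as.vector(zsurf))                # |k - zsurf| per voxel
  labels[zd <= half_lc & as.vector(in_lc)] <- 1L
  labels[zd <= half_pps & as.vector(in_pps)] <- 2L

  if (spec$has_lcd) {
    theta <- (atan2(yv, xt) * 180 / pi) %% 360
    dth <- abs((theta - spec$lcd_angle_deg + 180) %% 360 - 180)
    wedge <- dth <= spec$lcd_arc_deg / 2 &
      abs(r_en - spec$disc_radius_vox) <= spec$lcd_radial_vox / 2
    # full-thickness carve: remove every tissue voxel in the wedge columns
    carve <- as.vector(wedge) & labels > 0L
    labels[carve] <- 0L
  }

  intensity <- array(spec$intensity_bg, dim = dims)
  intensity[labels == 1L] <- spec$intensity_lc
  intensity[labels == 2L] <- spec$intensity_pps

  # laminar pores: hyporeflective dots inside the LC plate, labels untouched
  if (spec$pore_count > 0) {
    pr <- spec$pore_radius_vox
    pore_r <- sqrt(runif(spec$pore_count)) * 0.85 * spec$disc_radius_vox
    pore_t <- runif(spec$pore_count, 0, 2 * pi)
    for (p in seq_len(spec$pore_count)) {
      pa <- ctr[1] + sgn * pore_r[p] * cos(pore_t[p])
      psv <- ctr[2] + pore_r[p] * sin(pore_t[p])
      ia <- round(pa); is <- round(psv)
      if (ia < 1 || ia > na || is < 1 || is > ns) next
      pk <- zsurf[ia, is]
      box_a <- max(1, floor(pa - pr)):min(na, ceiling(pa + pr))
      box_s <- max(1, floor(psv - pr)):min(ns, ceiling(psv + pr))
      box_c <- max(1, floor(pk - pr)):min(nc, ceiling(pk + pr))
      for (c3 in box_c) for (s2 in box_s) for (a1 in box_a) {
        if ((a1 - pa)^2 + (s2 - psv)^2 + (c3 - pk)^2 <= pr^2 &&
            labels[a1, s2, c3] == 1L)
          intensity[a1, s2, c3] <- spec$intensity_bg + 0.05
      }
    }
  }

  # temporal signal attenuation over the LC edge (intensity only)
  att <- 1 - spec$temporal_attenuation *
    stats::plogis((xt - 0.55 * spec$disc_radius_vox) /
                  (0.15 * spec$disc_radius_vox))
  intensity <- intensity * rep(as.vector(att), times = nc)

  # vessel shadows: columns from the anterior face through the whole depth
  if (spec$vessel_count > 0) {
    vr <- spec$vessel_radius_vox
    v_r <- sqrt(runif(spec$vessel_count)) * 0.9 * outer_r
    v_t <- runif(spec$vessel_count, 0, 2 * pi)
    shadow <- matrix(FALSE, na, ns)
    for (v in seq_len(spec$vessel_count)) {
      va <- ctr[1] + v_r[v] * cos(v_t[v])
      vs <- ctr[2] + v_r[v] * sin(v_t[v])
      box_a <- max(1, floor(va - vr)):min(na, ceiling(va + vr))
      box_s <- max(1, floor(vs - vr)):min(ns, ceiling(vs + vr))
      for (s2 in box_s) for (a1 in box_a)
        if ((a1 - va)^2 + (s2 - vs)^2 <= vr^2) shadow[a1, s2] <- TRUE
    }
    fac <- ifelse(shadow, 0.35, 1)
    intensity <- intensity * rep(as.vector(fac), times = nc)
  }

  # multiplicative unit-mean speckle (gamma family)
  if (spec$noise_level > 0) {
    shape <- 1 / spec$noise_level^2
    mult <- rgamma(length(intensity), shape = shape, rate = shape)
    intensity <- intensity * mult
  }
  intensity <- pmin(pmax(intensity, 0), 1)
  dim(intensity) <- dims

  sp <- grid_spacing(spec$grid)
  structure(list(intensity = intensity_volume(intensity, sp, spec$laterality),
                 labels = label_volume(labels, sp, spec$laterality),
                 spec = spec),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, %s, defect: %s\n",
              paste(dim(x$labels), collapse = " x "), x$spec$laterality,
              if (x$spec$has_lcd)
                sprintf("yes (%.0f deg)", x$spec$lcd_angle_deg) else "no"))
  invisible(x)
}

#' Generate a seeded cohort of phantoms
#'
#' Synthetic stand-in for a case series: exactly `round(n * lcd_fraction)`
#' phantoms carry a defect, per-phantom seeds are derived deterministically
#' from the cohort seed, and nuisance parameters (tilt, pore count, noise
#' level, laterality, defect angle) are jittered per phantom. Defect angles
#' are jittered around the temporal axis, matching the predominantly
#' temporal, vertically running defects seen clinically.
#'
#' @param n cohort size (>= 1).
#' @param lcd_fraction fraction of eyes with a defect, in `[0, 1]`.
#' @param base_spec template [phantom_spec()].
#' @param seed cohort-level RNG seed.
#' @return List of `ground_truth` objects; each phantom's spec gains a
#'   `volume_id` field (`"phantom_001"`, ...).
#' @export
generate_cohort <- function(n, lcd_fraction, base_spec = phantom_spec(),
                            seed = 1L) {
  stopifnot(n >= 1, lcd_fraction >= 0, lcd_fraction <= 1)
  n <- as.integer(n)
  n_pos <- round_half_up(n * lcd_fraction)
  withr::with_seed(seed, {
    pos <- if (n_pos > 0) sample.int(n, n_pos) else integer(0)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    tilts <- runif(n, 0, 6)
    noise <- base_spec$noise_level * runif(n, 0.85, 1.15)
    pores <- sample(20:40, n, replace = TRUE)
    lats <- sample(c("OD", "OS"), n, replace = TRUE)
    angles <- (runif(n, -30, 30)) %% 360
  })
  lapply(seq_len(n), function(i) {
    spec <- base_spec
    spec$seed <- seeds[i]
    spec$tilt_deg <- tilts[i]
    spec$noise_level <- noise[i]
    spec$pore_count <- pores[i]
    spec$laterality <- lats[i]
    spec$has_lcd <- i %in% pos
    if (spec$has_lcd) spec$lcd_angle_deg <- angles[i]
    gt <- generate_phantom(spec)
    gt$spec$volume_id <- sprintf("phantom_%03d", i)
    gt
  })
}
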