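#' Extract a surface mesh of one label class
#'
#' Iso-surface of the binary class mask (marching tetrahedra on the
#' zero-padded mask at iso level 0.5), with vertex coordinates scaled to
#' physical millimetres by the voxel spacing. The surface of a solid mask
#' is closed and watertight; its area converges to the smooth surface area
#' of the underlying shape at sufficient resolution.
#'
#' After extraction the mesh is relaxed by a few Laplacian smoothing
#' iterations, which flattens the voxel staircase (each vertex moves toward
#' the mean of its neighbors, so vertices stay inside the convex hull of
#' the raw surface and hence inside the volume's bounding box).
#'
#' @param labels a [label_volume()].
#' @param class_code label code to mesh (1 = LC, 2 = PPS).
#' @param smooth_iterations,smooth_lambda Laplacian relaxation steps and
#'   step size; `smooth_iterations = 0` returns the raw iso-surface.
#' @return A `surface_mesh`: list with `vertices` (n x 3 mm coordinates),
#'   `faces` (m x 3, 1-based) and `class_code`.
#' @export
labels_to_mesh <- function(labels, class_code, smooth_iterations = 3L,
                           smooth_lambda = 0.6) {
  stopifnot(inherits(labels, "label_volume"))
  arr <- unclass(labels)
  if (!any(arr == class_code))
    stop("class ", class_code, " is absent from the volume", call. = FALSE)
  dims <- dim(arr)
  field <- array(0, dim = dims + 2L)
  field[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <-
    (arr == class_code) * 1
  mt <- march_tetrahedra(as.vector(field), as.integer(dims + 2L), 0.5)
  v <- mt$vertices
  sp <- spacing_mm(labels)
  # 0-based grid coordinate x corresponds to voxel index x of the unpadded
  # mask (one zero layer was prepended), whose center is at (x - 0.5) * sp
  v <- sweep(v, 2, c(0.5, 0.5, 0.5))
  v <- sweep(v, 2, sp, `*`)
  # merge duplicated vertices so edges are shared
  key <- paste(round(v[, 1], 9), round(v[, 2], 9), round(v[, 3], 9))
  uid <- match(key, unique(key))
  verts <- v[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid[mt$faces], ncol = 3)
  if (smooth_iterations > 0) {
    ed <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
    ed <- rbind(ed, ed[, 2:1])
    for (it in seq_len(smooth_iterations)) {
      nb_sum <- rowsum(verts[ed[, 2], , drop = FALSE], ed[, 1])
      nb_cnt <- tabulate(ed[, 1], nbins = nrow(verts))
      verts <- verts + smooth_lambda * (nb_sum / nb_cnt - verts)
    }
  }
  structure(list(vertices = verts, faces = faces, class_code = class_code,
                 spacing_mm = sp),
            class = "surface_mesh")
}

#' Total surface area of a triangle mesh
#'
#' @param mesh a `surface_mesh`.
#' @return Area in mm^2 (or squared voxel units if spacing is 1).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface mesh> class %d: %d vertices, %d triangles, area %.4g\n",
              x$class_code, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Write a mesh as ASCII OBJ or STL
#'
#' STL carries no color, so the LC and PPS are exported as separate
#' per-class meshes.
#'
#' @param mesh a `surface_mesh`.
#' @param path destination `.obj` or `.stl` path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid lamcrib", con)
    for (t in seq_len(nrow(f))) {
      p <- v[f[t, ], , drop = FALSE]
      n <- c(
        (p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
          (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
        (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
          (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
        (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
          (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 con)
      writeLines("  outer loop", con)
      writeLines(sprintf("    vertex %.9g %.9g %.9g",
                         p[, 1], p[, 2], p[, 3]), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid lamcrib", con)
  } else {
    stop("unsupported mesh format for '", path, "' (use .obj or .stl)",
         call. = FALSE)
  }
  invisible(path)
}

#' Read an ASCII OBJ mesh
#'
#' @param path an `.obj` file written by [write_mesh()].
#' @return A `surface_mesh` (class_code `NA`).
#' @export
read_mesh_obj <- function(path) {
  ln <- readLines(path)
  vt <- do.call(rbind, lapply(strsplit(grep("^v ", ln, value = TRUE), " +"),
                              function(p) as.numeric(p[2:4])))
  fc <- do.call(rbind, lapply(strsplit(grep("^f ", ln, value = TRUE), " +"),
                              function(p) as.integer(p[2:4])))
  structure(list(vertices = vt, faces = fc, class_code = NA_integer_,
                 spacing_mm = c(1, 1, 1)),
            class = "surface_mesh")
}

#' En-face projection image with defect overlay
#'
#' Projects the label volume along the depth axis (LC red, PPS blue, as in
#' the usual clinical display convention) and marks each reported defect region: its en-face
#' footprint is filled yellow and an asterisk-like cross is drawn at the
#' projected centroid.
#'
#' @param labels a [label_volume()].
#' @param report an [detect_lcd()] report for the same volume.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
enface_overlay <- function(labels, report, path) {
  arr <- unclass(labels)
  na <- dim(arr)[1]; ns <- dim(arr)[2]
  lc <- apply(arr == 1L, c(1, 2), any)
  pps <- apply(arr == 2L, c(1, 2), any)
  # PNG raster rows run top-to-bottom; put superior (+s) at the top and
  # the a axis left-to-right
  img <- array(0, dim = c(ns, na, 3))
  to_img <- function(a, s) cbind(ns - s + 1, a)
  img[, , 1][to_img(which(lc, arr.ind = TRUE)[, 1],
                    which(lc, arr.ind = TRUE)[, 2])] <- 1
  img[, , 3][to_img(which(pps, arr.ind = TRUE)[, 1],
                    which(pps, arr.ind = TRUE)[, 2])] <- 1
  for (region in report$regions) {
    cols <- unique(region$voxels[, 1:2, drop = FALSE])
    px <- to_img(cols[, 1], cols[, 2])
    img[, , 1][px] <- 1; img[, , 2][px] <- 1; img[, , 3][px] <- 0
    ca <- round(mean(region$voxels[, 1]))
    cs <- round(mean(region$voxels[, 2]))
    for (d in -4:4) {
      for (pt in list(c(ca + d, cs), c(ca, cs + d),
                      c(ca + d, cs + d), c(ca + d, cs - d))) {
        if (pt[1] >= 1 && pt[1] <= na && pt[2] >= 1 && pt[2] <= ns) {
          q <- to_img(pt[1], pt[2])
          img[, , 1][q] <- 1; img[, , 2][q] <- 1; img[, , 3][q] <- 0
        }
      }
    }
  }
  ok <- tryCatch(png::writePNG(img, path),
                 error = function(e) stop("failed to write PNG '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  invisible(path)
}
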