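## Cine stack organisation: read DICOM frames, group them into image stacks
## by view orientation, slice and cardiac phase, and map pixel indices to
## patient coordinates.
##
## Pixel index convention: 0-based continuous (row, col), row = image Y
## (top to bottom), col = image X -- stated explicitly because DICOM mixes
## row/col and x/y. Phases are ordered by TriggerTime when present, else by
## InstanceNumber; phase 1 is end diastole.

#' Load cine DICOM files into image stacks
#'
#' Reads all files, verifies the spatial metadata (PixelSpacing,
#' ImagePositionPatient, ImageOrientationPatient; direction cosines must be
#' unit length and orthogonal to 1e-6), groups frames by view orientation,
#' then by slice position along the view normal, and sorts phases by
#' TriggerTime (falling back to InstanceNumber). Views are classified by
#' their normal's angle to the mean normal of the largest stack (the
#' short-axis stack): more than 45 degrees away = long-axis.
#'
#' @param paths character vector of DICOM files.
#' @return list of `lv_image_stack` objects, one per distinct orientation.
#'   Each has `frames[[slice]][[phase]]` intensity matrices,
#'   `pixel_spacing` (row, col, mm), `slice_positions` (list of
#'   ImagePositionPatient), `slice_orientations` (list of `$row`/`$col`
#'   cosines), `normal`, `n_phases`, `n_slices`, `view`.
#' @export
load_cine_stack <- function(paths) {
  if (!length(paths)) stopf("no DICOM files given")
  metas <- lapply(paths, function(p) {
    m <- read_dicom_frame(p)
    for (fld in c("pixel_spacing", "image_position", "image_orientation"))
      if (is.null(m[[fld]]))
        stopf("%s: missing required metadata (%s)", p, fld)
    rd <- m$image_orientation[1:3]; cd <- m$image_orientation[4:6]
    if (abs(sqrt(sum(rd^2)) - 1) > 1e-6 || abs(sqrt(sum(cd^2)) - 1) > 1e-6 ||
        abs(sum(rd * cd)) > 1e-6)
      stopf("%s: orientation cosines not orthonormal within 1e-6", p)
    m$normal <- c(rd[2] * cd[3] - rd[3] * cd[2],
                  rd[3] * cd[1] - rd[1] * cd[3],
                  rd[1] * cd[2] - rd[2] * cd[1])
    m$path <- p
    m
  })
  ## group by orientation (rounded cosines)
  okey <- vapply(metas, function(m)
    paste(sprintf("%.4f", m$image_orientation), collapse = ","), "")
  groups <- split(metas, okey)
  ## the largest group defines the short-axis reference normal
  sizes <- vapply(groups, length, 1L)
  ref_normal <- groups[[which.max(sizes)]][[1]]$normal
  stacks <- lapply(groups, function(g) {
    nrm <- g[[1]]$normal
    z <- vapply(g, function(m) sum(m$image_position * nrm), 1)
    zkey <- sprintf("%.3f", z)
    slices <- split(seq_along(g), zkey)
    slices <- slices[order(as.numeric(names(slices)))]
    frames <- list(); spos <- list(); sori <- list()
    np <- NULL
    for (si in seq_along(slices)) {
      idx <- slices[[si]]
      ms <- g[idx]
      ps <- vapply(ms, function(m) {
        sp <- m$pixel_spacing
        paste(sprintf("%.6f", sp), collapse = ",")
      }, "")
      if (length(unique(ps)) > 1)
        stopf("mixed pixel spacings within one slice")
      tt <- vapply(ms, function(m) (m$trigger_time %||% NA_real_)[1], 1)
      ord <- if (!anyNA(tt)) order(tt) else
        order(vapply(ms, function(m) m$instance_number %||% NA_integer_, 1L))
      ms <- ms[ord]
      if (is.null(np)) np <- length(ms)
      else if (length(ms) != np)
        stopf("slices disagree on phase count (%d vs %d)", length(ms), np)
      frames[[si]] <- lapply(ms, `[[`, "pixels")
      spos[[si]] <- ms[[1]]$image_position
      sori[[si]] <- list(row = ms[[1]]$image_orientation[1:3],
                         col = ms[[1]]$image_orientation[4:6])
    }
    if (np < 2) stopf("a cine stack needs at least 2 phases, found %d", np)
    ang <- acos(pmin(1, abs(sum(nrm * ref_normal)))) * 180 / pi
    structure(list(frames = frames,
                   pixel_spacing = g[[1]]$pixel_spacing,
                   slice_positions = spos, slice_orientations = sori,
                   normal = nrm, n_phases = np, n_slices = length(frames),
                   view = if (ang > 45) "long_axis" else "short_axis"),
              class = "lv_image_stack")
  })
  names(stacks) <- NULL
  stacks[order(-vapply(stacks, function(s) s$n_slices, 1L))]
}

#' @export
print.lv_image_stack <- function(x, ...) {
  cat(sprintf("<lv_image_stack> %s: %d slices x %d phases, %dx%d px @ %.3g mm\n",
              x$view, x$n_slices, x$n_phases,
              nrow(x$frames[[1]][[1]]), ncol(x$frames[[1]][[1]]),
              x$pixel_spacing[1]))
  invisible(x)
}

#' Map pixel indices to patient coordinates
#'
#' Applies the DICOM patient-coordinate convention:
#' \code{ImagePositionPatient + col * spacing_col * row_dir +
#' row * spacing_row * col_dir}, where `row_dir`/`col_dir` are the first and
#' second direction-cosine triplets of ImageOrientationPatient. Indices are
#' 0-based and continuous; (0,0) maps exactly to ImagePositionPatient. The
#' map is affine, hence invertible on the plane (see
#' [patient_to_pixel()]).
#'
#' @param stack an `lv_image_stack`.
#' @param slice_index slice number (1-based).
#' @param pixel numeric vector (row, col) or an n x 2 matrix of such pairs.
#' @return patient coordinates (mm): length-3 vector or n x 3 matrix.
#' @export
pixel_to_patient <- function(stack, slice_index, pixel) {
  if (slice_index < 1 || slice_index > stack$n_slices)
    stopf("slice index %d out of range [1, %d]", slice_index, stack$n_slices)
  o <- stack$slice_orientations[[slice_index]]
  p0 <- stack$slice_positions[[slice_index]]
  sp <- stack$pixel_spacing
  px <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2)
  out <- rep(p0, each = nrow(px)) +
    outer(px[, 2] * sp[2], o$row) + outer(px[, 1] * sp[1], o$col)
  if (!is.matrix(pixel)) as.numeric(out) else out
}

#' Map patient coordinates back to pixel indices on a slice plane
#'
#' Inverse of [pixel_to_patient()] (orthogonal projection onto the slice
#' plane for points slightly off it).
#'
#' @param stack an `lv_image_stack`.
#' @param slice_index slice number.
#' @param xyz length-3 vector or n x 3 matrix of patient coordinates (mm).
#' @return (row, col) continuous 0-based indices.
#' @export
patient_to_pixel <- function(stack, slice_index, xyz) {
  if (slice_index < 1 || slice_index > stack$n_slices)
    stopf("slice index %d out of range [1, %d]", slice_index, stack$n_slices)
  o <- stack$slice_orientations[[slice_index]]
  p0 <- stack$slice_positions[[slice_index]]
  sp <- stack$pixel_spacing
  pm <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  dp <- sweep(pm, 2, p0)
  out <- cbind(as.numeric(dp %*% o$col) / sp[1],
               as.numeric(dp %*% o$row) / sp[2])
  if (!is.matrix(xyz)) as.numeric(out) else out
}
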