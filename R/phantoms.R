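## Synthetic inputs with known ground truth: analytic moving-domain flow
## benchmarks (piston box, contracting cylinder, half-ellipsoid LV) and
## cine-like DICOM image stacks (see make_image_stack()).

#' Phantom specification
#'
#' Bundles the geometric, motion and imaging parameters of a synthetic test
#' case. Identical spec + seed produces bit-identical output.
#'
#' @param kind one of "image_stack", "piston_box", "contracting_cylinder",
#'   "half_ellipsoid_lv".
#' @param ... parameter overrides; see [make_benchmark_case()] and
#'   [make_image_stack()] for the per-kind defaults.
#' @param seed RNG seed for noisy phantoms.
#' @return list of class `lv_phantom_spec`.
#' @export
phantom_spec <- function(kind = c("image_stack", "piston_box",
                                  "contracting_cylinder", "half_ellipsoid_lv"),
                         ..., seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    image_stack = list(n_slices = 6, n_phases = 20, rows = 128, cols = 128,
                       pixel_spacing = 0.7, slice_spacing = 8,
                       r_base = 18, wall_thickness = 8, taper = 0.55,
                       contraction = 0.25, snr = 10,
                       lumen_intensity = 200, myo_intensity = 80,
                       background_intensity = 20, systole_fraction = 0.4),
    piston_box = list(width = 10, height = 20, speed = 10, duration = 1,
                      nx = 10, ny = 20),
    contracting_cylinder = list(radius_ed = 15, radius_es = 12, length = 60,
                                n_levels = 10, n_theta = 48,
                                systole_fraction = 0.4, heart_rate = 60),
    half_ellipsoid_lv = list(a_ed = 80, a_es = 64, b = 25,
                             n_levels = 16, n_theta = 48,
                             systole_fraction = 0.4, heart_rate = 60,
                             motion_shape = "linear"))
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stopf("unknown %s parameter(s): %s", kind, paste(bad, collapse = ", "))
  p <- utils::modifyList(defaults, ov)
  lens <- p[names(p) %in% c("width", "height", "radius_ed", "radius_es", "length",
                            "a_ed", "a_es", "b", "r_base", "pixel_spacing",
                            "slice_spacing", "wall_thickness")]
  if (any(unlist(lens) <= 0)) stopf("all phantom lengths must be positive")
  if (!is.null(p$snr) && p$snr <= 0) stopf("SNR must be positive")
  structure(c(list(kind = kind, seed = as.integer(seed)), p),
            class = "lv_phantom_spec")
}

#' @export
print.lv_phantom_spec <- function(x, ...) {
  cat(sprintf("<lv_phantom_spec> %s (seed %d)\n", x$kind, x$seed))
  invisible(x)
}

## rings of a cylinder/half-ellipsoid at contraction weight s in [0,1]
.cyl_rings <- function(R, L, n_levels, n_theta) {
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rings <- array(0, c(n_levels, n_theta, 3))
  for (l in seq_len(n_levels)) {
    z <- -L * (l - 1) / (n_levels - 1)            # last ring on the flat cap
    rings[l, , ] <- cbind(R * cos(th), R * sin(th), z)
  }
  rings
}

.ellipsoid_rings <- function(a, b, n_levels, n_theta) {
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rings <- array(0, c(n_levels, n_theta, 3))
  for (l in seq_len(n_levels)) {
    u <- (l - 1) / n_levels                       # depth fraction; apex at u=1
    r <- b * sqrt(1 - u^2)
    rings[l, , ] <- cbind(r * cos(th), r * sin(th), -a * u)
  }
  rings
}

#' Analytic moving-domain benchmark case
#'
#' Builds the boundary-motion geometry for one of the closed-form
#' verification phantoms together with its analytic reference record:
#' \describe{
#'   \item{piston_box}{2D box of width W whose bottom wall moves up at
#'     constant speed s; reference IO flow rate Q' = W s.}
#'   \item{contracting_cylinder}{flat-capped cylinder of length L whose
#'     radius follows R(T) between ED and ES; reference
#'     V(T) = pi R(T)^2 L and Q = -dV/dt.}
#'   \item{half_ellipsoid_lv}{half ellipsoid with semi-axes (b, b, a(T)),
#'     flat IO face; V(T) = (2/3) pi a(T) b^2, SV = (2/3) pi (a_ED-a_ES) b^2.
#'     `motion_shape` "linear" follows the piecewise-linear ED/ES law;
#'     "sinusoidal" uses s(T) = sin^2(pi T) for a smooth volume course.}
#' }
#'
#' @param spec an `lv_phantom_spec` (or a kind name, using defaults).
#' @return list of class `lv_benchmark`: `spec`, `motion` (an
#'   `lv_lumen_motion` ready for [solve_cycle()]) and `reference` (analytic
#'   closures: `volume(T)` mm^3 or `area(T)` mm^2, `flow_rate(T)` in mm^3/s
#'   or mm^2/s, `sv` mm^3 where defined).
#' @export
make_benchmark_case <- function(spec) {
  if (is.character(spec)) spec <- phantom_spec(spec)
  if (spec$kind == "image_stack") stopf("use make_image_stack() for image phantoms")
  if (spec$kind == "piston_box") {
    W <- spec$width; H <- spec$height; s <- spec$speed; dur <- spec$duration
    if (s * dur >= H) stopf("piston stroke exceeds box height: negative dimensions")
    mesh <- mesh_rect2d(0, W, -H, 0, nx = spec$nx, ny = spec$ny, io = "top")
    wn <- boundary_nodes(mesh, "wall")
    x0 <- mesh$nodes[wn, , drop = FALSE]
    cyc <- cycle_phase(0.5, 60 / dur)             # T in [0,1] spans `duration`
    wall_pos <- function(T) {
      fac <- (H - s * dur * (T %% 1)) / H
      cbind(x0[, 1], x0[, 2] * fac)
    }
    motion <- structure(list(mesh = mesh, wall_nodes = wn, wall_pos = wall_pos,
                             cycle = cyc),
                        class = "lv_lumen_motion")
    reference <- list(flow_rate = function(T) rep(W * s, length(T)),
                      area = function(T) W * (H - s * dur * (T %% 1)))
    return(structure(list(spec = spec, motion = motion, reference = reference),
                     class = "lv_benchmark"))
  }
  cyc <- cycle_phase(spec$systole_fraction, spec$heart_rate)
  cyc_s <- 60 / cyc$heart_rate
  if (spec$kind == "contracting_cylinder") {
    red <- .cyl_rings(spec$radius_ed, spec$length, spec$n_levels, spec$n_theta)
    res <- .cyl_rings(spec$radius_es, spec$length, spec$n_levels, spec$n_theta)
    apex <- c(0, 0, -spec$length)                 # flat cap: fan lies in it
    geom <- build_corresponding_surfaces(red, res,
                                         spacing = spec$length / (spec$n_levels - 1),
                                         apex_ed = apex, apex_es = apex, cycle = cyc)
    RT <- function(T) spec$radius_ed + phase_weight(T, cyc) * (spec$radius_es - spec$radius_ed)
    dRdT <- function(T) {
      sf <- cyc$systole_fraction; Tw <- T %% 1
      (spec$radius_es - spec$radius_ed) * ifelse(Tw < sf, 1 / sf, -1 / (1 - sf))
    }
    reference <- list(
      volume = function(T) pi * RT(T)^2 * spec$length,
      flow_rate = function(T) -2 * pi * RT(T) * spec$length * dRdT(T) / cyc_s,
      sv = pi * (spec$radius_ed^2 - spec$radius_es^2) * spec$length)
    ## flat-capped volume mesh: no apex fan, purely radial wall motion
    ts <- theta_subset(spec$n_theta, 2)
    mesh <- mesh_lumen3d(red[, ts, , drop = FALSE], apex = NULL)
    wn <- boundary_nodes(mesh, "wall")
    x0 <- mesh$nodes[wn, , drop = FALSE]
    wall_pos <- function(T) {
      f <- RT(T) / spec$radius_ed
      cbind(x0[, 1] * f, x0[, 2] * f, x0[, 3])
    }
    motion <- structure(list(mesh = mesh, wall_nodes = wn, wall_pos = wall_pos,
                             cycle = cyc, geom = geom),
                        class = "lv_lumen_motion")
    return(structure(list(spec = spec, motion = motion, reference = reference),
                     class = "lv_benchmark"))
  } else {                                        # half_ellipsoid_lv
    sshape <- spec$motion_shape
    sw <- function(T) if (sshape == "sinusoidal") sin(pi * (T %% 1))^2 else phase_weight(T, cyc)
    dswdT <- function(T) {
      if (sshape == "sinusoidal") pi * sin(2 * pi * (T %% 1))
      else {
        sf <- cyc$systole_fraction
        ifelse((T %% 1) < sf, 1 / sf, -1 / (1 - sf))
      }
    }
    aT <- function(T) spec$a_ed + sw(T) * (spec$a_es - spec$a_ed)
    red <- .ellipsoid_rings(spec$a_ed, spec$b, spec$n_levels, spec$n_theta)
    res <- .ellipsoid_rings(spec$a_es, spec$b, spec$n_levels, spec$n_theta)
    geom <- build_corresponding_surfaces(
      red, res, spacing = spec$a_ed / spec$n_levels,
      apex_ed = c(0, 0, -spec$a_ed), apex_es = c(0, 0, -spec$a_es), cycle = cyc,
      weight = if (sshape == "sinusoidal") sw,
      dweight = if (sshape == "sinusoidal") dswdT)
    reference <- list(
      volume = function(T) (2 / 3) * pi * aT(T) * spec$b^2,
      flow_rate = function(T) -(2 / 3) * pi * spec$b^2 *
        (spec$a_es - spec$a_ed) * dswdT(T) / cyc_s,
      sv = (2 / 3) * pi * (spec$a_ed - spec$a_es) * spec$b^2)
  }
  motion <- lumen_motion(geom)
  structure(list(spec = spec, motion = motion, reference = reference),
            class = "lv_benchmark")
}

#' Keyframe traces of a contracting half-disk LV (2D phantom)
#'
#' Generates the closed lumen outlines of a half-disk (optionally
#' half-ellipse) "long-axis" LV whose radius follows the cardiac contraction
#' law, sampled at 8 keyframes as in the tracing workflow: end diastole, two
#' intermediate systolic phases, end systole, and four diastolic phases.
#'
#' @param r_ed,r_es end-diastolic / end-systolic radius, mm.
#' @param depth_ratio apex depth as a multiple of the radius (1 = half disk).
#' @param n_keyframes number of traced phases (default 8).
#' @param n_pts points per generated trace.
#' @param cycle a [cycle_phase()].
#' @return `lv_motion2d` from [build_motion_2d()].
#' @export
phantom_motion_2d <- function(r_ed = 22, r_es = 17, depth_ratio = 1,
                              n_keyframes = 8, n_pts = 128,
                              cycle = cycle_phase()) {
  sf <- cycle$systole_fraction
  times <- c(seq(0, sf, length.out = 4), seq(sf, 1, length.out = 6)[2:5])
  times <- times[seq_len(n_keyframes)]
  traces <- lapply(times, function(T) {
    r <- r_ed + phase_weight(T, cycle) * (r_es - r_ed)
    th <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)] + pi / n_pts
    ## full closed outline crossing y = 0 twice; lumen below y = 0
    cbind(r * cos(th), -depth_ratio * r * sin(th))
  })
  build_motion_2d(traces, times, cycle = cycle)
}

## ---- cine-like DICOM image stack phantom ---------------------------------

#' Generate a cine-like short-axis DICOM stack with ground-truth masks
#'
#' Writes one uncompressed DICOM file per (slice, phase): a bright lumen
#' disk (default intensity 200) inside a darker myocardial ring (80) on a
#' dark background (20), with additive Gaussian noise at the requested SNR
#' (SNR = (lumen - myocardium) / noise sd). The lumen radius contracts over
#' systole and tapers toward the apex; the exact per-frame radii and binary
#' lumen masks are returned as ground truth. Output is bit-reproducible for
#' a fixed spec + seed.
#'
#' @param spec `lv_phantom_spec` of kind "image_stack".
#' @param dir output directory for the DICOM files (created if needed);
#'   NULL to skip writing and return images in memory only.
#' @return list of class `lv_image_phantom`: `files` (paths, slice-major),
#'   `images[[slice]][[phase]]`, `masks[[slice]][[phase]]` (logical),
#'   `radius` (n_slices x n_phases, mm), `center_px` (row, col of the lumen
#'   centre, 0-based), `spec`.
#' @export
make_image_stack <- function(spec, dir = NULL) {
  if (!inherits(spec, "lv_phantom_spec") || spec$kind != "image_stack")
    stopf("spec must be an lv_phantom_spec of kind image_stack")
  ns <- spec$n_slices; np <- spec$n_phases
  rows <- spec$rows; cols <- spec$cols; dx <- spec$pixel_spacing
  ## lumen centre slightly off the image centre so hint logic is exercised
  c_row <- (rows - 1) / 2 + 3; c_col <- (cols - 1) / 2 - 2
  fov <- min(rows, cols) * dx
  cyc <- cycle_phase(spec$systole_fraction, 60)
  taper_of <- function(s) 1 - (1 - spec$taper) * (s - 1) / max(ns - 1, 1)
  radius <- outer(seq_len(ns), seq_len(np), function(s, ph) {
    Tn <- (ph - 1) / np
    spec$r_base * taper_of(s) * (1 - spec$contraction * phase_weight(Tn, cyc))
  })
  if (max(radius) + spec$wall_thickness > fov / 2)
    stopf("lumen+wall (%.1f mm) exceeds the field of view (%.1f mm)",
          max(radius) + spec$wall_thickness, fov / 2)
  rr <- matrix(rep(0:(rows - 1), cols), rows, cols)
  cc <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
  dist_mm <- sqrt(((rr - c_row) * dx)^2 + ((cc - c_col) * dx)^2)
  sigma <- (spec$lumen_intensity - spec$myo_intensity) / spec$snr
  images <- vector("list", ns); masks <- vector("list", ns)
  files <- character(0)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_local_seed(spec$seed, {
    inst <- 0L
    for (s in seq_len(ns)) {
      images[[s]] <- vector("list", np); masks[[s]] <- vector("list", np)
      for (ph in seq_len(np)) {
        r <- radius[s, ph]
        img <- matrix(spec$background_intensity, rows, cols)
        img[dist_mm <= r + spec$wall_thickness] <- spec$myo_intensity
        img[dist_mm <= r] <- spec$lumen_intensity
        img <- img + matrix(rnorm(rows * cols, sd = sigma), rows, cols)
        img <- pmin(pmax(img, 0), 4095)
        masks[[s]][[ph]] <- dist_mm <= r
        images[[s]][[ph]] <- img
        if (!is.null(dir)) {
          inst <- inst + 1L
          f <- file.path(dir, sprintf("sa_s%02d_p%02d.dcm", s, ph))
          write_dicom_frame(
            f, img, pixel_spacing = c(dx, dx),
            image_position = c(-c_col * dx, -c_row * dx,
                               -spec$slice_spacing * (s - 1)),
            image_orientation = c(1, 0, 0, 0, 1, 0),
            instance_number = inst,
            trigger_time = (ph - 1) * 1000 / np,
            series_uid = sprintf("2.25.%d.1", spec$seed),
            sop_uid = sprintf("2.25.%d.1.%d", spec$seed, inst),
            study_uid = sprintf("2.25.%d", spec$seed),
            series_description = "short_axis")
          files <- c(files, f)
        }
      }
    }
  })
  structure(list(files = files, images = images, masks = masks,
                 radius = radius, center_px = c(c_row, c_col), spec = spec),
            class = "lv_image_phantom")
}

#' @export
print.lv_image_phantom <- function(x, ...) {
  cat(sprintf("<lv_image_phantom> %d slices x %d phases, %dx%d px, SNR %g\n",
              x$spec$n_slices, x$spec$n_phases, x$spec$rows, x$spec$cols,
              x$spec$snr))
  invisible(x)
}
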