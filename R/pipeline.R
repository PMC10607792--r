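## End-to-end orchestration: phantom generation or DICOM input, per-frame
## segmentation, 3D reconstruction, cycle simulation and energetics, with
## cached, resumable stages and a JSON summary.

#' Default pipeline configuration
#'
#' All defaults mirror the modelling conditions used throughout the package:
#' heart rate 60 bpm, 40 percent systole, mu = 4 cP, rho = 1060 kg/m^3,
#' C = 10 clusters for short-axis frames.
#'
#' @param ... named overrides of nested fields, e.g.
#'   `phantom = list(kind = "half_ellipsoid_lv")`,
#'   `solver = list(n_steps = 60)`.
#' @return nested configuration list of class `lv_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = list(dicom_dir = NULL),
    phantom = list(kind = "image_stack", seed = 1L, params = list()),
    segmentation = list(C = 10L, m = 2, diffusion_iterations = 10L,
                        snake = TRUE, min_circularity = 0.5),
    geometry = list(n_theta = 24L, n_radial = 4L, n_layers = 10L),
    cycle = list(systole_fraction = 0.4, heart_rate = 60),
    fluid = list(mu = 4e-3, rho = 1060),
    solver = list(n_steps = 60L, n_cycles = 2L, scheme = "auto",
                  backflow = FALSE),
    output = list(dir = "lvflow_run", vtk_phases = c(0, 0.25, 0.5, 0.75),
                  plots = TRUE))
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stopf("unknown config section '%s'", nm)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], ov[[nm]])
  }
  class(cfg) <- "lv_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against its documented range before any stage
#' runs; called by [pipeline_config()] and [run_pipeline()].
#'
#' @param cfg configuration list.
#' @return the validated config, invisibly; errors describe the offending
#'   field.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, fmt, ...) if (!cond) stopf(paste0("config: ", fmt), ...)
  s <- cfg$segmentation
  chk(s$C >= 2, "segmentation C must be >= 2 (got %s)", s$C)
  chk(s$m > 1, "segmentation fuzzy exponent m must be > 1")
  chk(s$min_circularity >= 0 && s$min_circularity <= 1,
      "min_circularity must be in [0,1]")
  g <- cfg$geometry
  chk(g$n_theta >= 8, "n_theta must be >= 8")
  chk(g$n_radial >= 2, "n_radial must be >= 2")
  chk(g$n_layers >= 2, "n_layers must be >= 2")
  cy <- cfg$cycle
  chk(cy$systole_fraction > 0 && cy$systole_fraction < 1,
      "systole_fraction must be in (0,1)")
  chk(cy$heart_rate > 0, "heart_rate must be positive")
  f <- cfg$fluid
  chk(f$mu > 0 && f$rho > 0, "fluid mu and rho must be positive")
  so <- cfg$solver
  chk(so$n_steps >= 20, "solver n_steps must be >= 20")
  chk(so$n_cycles >= 1, "solver n_cycles must be >= 1")
  chk(so$scheme %in% c("auto", "semi_implicit", "coupled"),
      "unknown solver scheme '%s'", so$scheme)
  chk(cfg$phantom$kind %in% c("image_stack", "piston_box",
                              "contracting_cylinder", "half_ellipsoid_lv"),
      "unknown phantom kind '%s'", cfg$phantom$kind)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] sections.
#' @return validated `lv_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

## hash of the scientific configuration; the output section (paths, plot
## switches) does not influence computed results and is excluded, so runs in
## different directories compare equal
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$output <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

## stage cache: recompute unless a cached result exists for the same hash
.stage <- function(dir, name, hash, fn) {
  rds <- file.path(dir, paste0(name, ".rds"))
  tag <- file.path(dir, paste0(name, ".hash"))
  if (file.exists(rds) && file.exists(tag) && readLines(tag)[1] == hash) {
    message(sprintf("[lvflow] %s: cached", name))
    return(readRDS(rds))
  }
  message(sprintf("[lvflow] %s: running", name))
  val <- fn()
  saveRDS(val, rds)
  writeLines(hash, tag)
  val
}

write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(t(mask), 1, 0), path)
}

#' Run the full pipeline
#'
#' Stages, in order: acquire (phantom generation or DICOM reading), segment,
#' reconstruct, mesh + simulate, energetics. Each stage caches its result in
#' the run directory keyed by the config hash, so deleting downstream
#' artifacts and rerunning reproduces them; the summary JSON records the
#' config hash and package version. Benchmark phantom kinds skip the imaging
#' stages and go straight to simulation.
#'
#' @param cfg `lv_config` (see [pipeline_config()]) or a YAML path.
#' @param out_dir run directory (default from the config).
#' @param stop_after optionally halt after one of "acquire", "segment",
#'   "reconstruct", "simulate" (used by the stage subcommands of the CLI
#'   script; later stages reuse the cache).
#' @return list with `summary` (also written as `summary.json`), `series`
#'   (`lv_hemo_series`), and stage artifacts paths.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         stop_after = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  halt <- function(stage) {
    if (!is.null(stop_after) && identical(stop_after, stage)) {
      message(sprintf("[lvflow] stopped after stage '%s'", stage))
      TRUE
    } else FALSE
  }
  out_dir <- out_dir %||% cfg$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  cyc <- cycle_phase(cfg$cycle$systole_fraction, cfg$cycle$heart_rate)
  props <- fluid_props(cfg$fluid$mu, cfg$fluid$rho)
  sopts <- solver_options(scheme = cfg$solver$scheme,
                          backflow = isTRUE(cfg$solver$backflow))
  dice <- NULL
  if (cfg$phantom$kind != "image_stack" && is.null(cfg$input$dicom_dir)) {
    bench <- .stage(out_dir, "phantom", hash, function()
      make_benchmark_case(do.call(phantom_spec,
        c(list(kind = cfg$phantom$kind, seed = cfg$phantom$seed),
          cfg$phantom$params))))
    motion <- bench$motion
    reference <- bench$reference
    if (halt("acquire")) return(invisible(list(out_dir = out_dir)))
  } else {
    seg_in <- .stage(out_dir, "acquire", hash, function() {
      if (!is.null(cfg$input$dicom_dir)) {
        stacks <- load_cine_stack(list.files(cfg$input$dicom_dir,
                                             full.names = TRUE,
                                             pattern = "\\.dcm$"))
        sa <- stacks[[which(vapply(stacks, `[[`, "", "view") == "short_axis")[1]]]
        list(stack = sa, masks = NULL, hint = NULL)
      } else {
        spec <- do.call(phantom_spec,
          c(list(kind = "image_stack", seed = cfg$phantom$seed),
            cfg$phantom$params))
        ddir <- file.path(out_dir, "dicom")
        ph <- make_image_stack(spec, dir = ddir)
        stacks <- load_cine_stack(ph$files)
        sa <- stacks[[1]]
        ## the loader orders slices along the stack normal; realign the
        ## ground-truth masks with the loaded slice order
        z_loaded <- vapply(sa$slice_positions, `[[`, 1, 3)
        z_phantom <- -spec$slice_spacing * (seq_len(spec$n_slices) - 1)
        perm <- match(round(z_loaded, 3), round(z_phantom, 3))
        list(stack = sa, masks = ph$masks[perm], hint = ph$center_px)
      }
    })
    stack <- seg_in$stack
    if (halt("acquire")) return(invisible(list(out_dir = out_dir)))
    seg <- .stage(out_dir, "segment", hash, function() {
      s <- cfg$segmentation
      segment_cine_stack(stack, center_hint = seg_in$hint, C = s$C, m = s$m,
                         diffusion_iterations = s$diffusion_iterations,
                         snake = isTRUE(s$snake),
                         min_circularity = s$min_circularity)
    })
    mdir <- file.path(out_dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    tdir <- file.path(out_dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    if (!is.null(seg_in$masks)) {
      dice <- segmentation_dice(seg, seg_in$masks)
      write.csv(as.data.frame(dice), file.path(out_dir, "dice.csv"),
                row.names = FALSE)
    }
    es_phase <- max(1L, round(cyc$systole_fraction * stack$n_phases) + 1L)
    for (s in seq_len(stack$n_slices)) for (ph in c(1L, es_phase)) {
      tr <- seg$traces[[s]][[ph]]
      if (inherits(tr, "lv_trace")) {
        write.csv(data.frame(row = tr$points[, 1], col = tr$points[, 2]),
                  file.path(tdir, sprintf("trace_s%02d_p%02d.csv", s, ph)),
                  row.names = FALSE)
        write_mask_png(seg$masks[[s]][[ph]],
                       file.path(mdir, sprintf("mask_s%02d_p%02d.png", s, ph)))
      }
    }
    if (halt("segment")) return(invisible(list(out_dir = out_dir, dice = dice)))
    recon <- .stage(out_dir, "reconstruct", hash, function() {
      ok <- vapply(seq_len(stack$n_slices), function(s)
        inherits(seg$traces[[s]][[1L]], "lv_trace") &&
        inherits(seg$traces[[s]][[es_phase]], "lv_trace"), TRUE)
      sl <- which(ok)
      if (length(sl) < 3) stopf("reconstruct: fewer than 3 slices with accepted ED+ES traces")
      r_ed <- reconstruct_3d_contours(lapply(sl, function(s) seg$traces[[s]][[1L]]),
                                      stack, slices = sl,
                                      n_theta = cfg$geometry$n_theta)
      r_es <- reconstruct_3d_contours(lapply(sl, function(s) seg$traces[[s]][[es_phase]]),
                                      stack, slices = sl,
                                      n_theta = cfg$geometry$n_theta,
                                      frame = r_ed$frame)
      build_corresponding_surfaces(r_ed, r_es, cycle = cyc)
    })
    write_vtk_surface(recon$nodes_ed, recon$tris,
                      file.path(out_dir, "surface_ed.vtk"))
    write_vtk_surface(recon$nodes_es, recon$tris,
                      file.path(out_dir, "surface_es.vtk"))
    motion <- lumen_motion(recon, n_radial = cfg$geometry$n_radial,
                           subsample_theta = 1)
    reference <- NULL
    if (halt("reconstruct")) return(invisible(list(out_dir = out_dir)))
  }
  write_vtk_mesh(motion$mesh, file.path(out_dir, "lumen_mesh_ed.vtk"))
  cycres <- .stage(out_dir, "simulate", hash, function()
    solve_cycle(motion, props = props, n_steps = cfg$solver$n_steps,
                n_cycles = cfg$solver$n_cycles, store = "last_cycle",
                opts = sopts))
  if (halt("simulate")) return(invisible(list(out_dir = out_dir)))
  series <- .stage(out_dir, "energetics", hash, function()
    hemo_series(cycres, props))
  write.csv(as.data.frame(series), file.path(out_dir, "hemo_series.csv"),
            row.names = FALSE)
  for (Tp in cfg$output$vtk_phases) {
    i <- which.min(abs(vapply(cycres$states, `[[`, 1, "phase") - Tp))
    write_vtk_state(cycres$states[[i]],
                    file.path(out_dir, sprintf("state_T%03d.vtk", round(100 * Tp))),
                    props)
  }
  sv <- attr(series, "sv")
  d <- attr(series, "space_dim")
  summary <- list(
    package_version = as.character(packageVersion("lvflow")),
    config_hash = hash,
    dim = d,
    sv = sv$sv, sv_flux = sv$sv_flux %||% NA, sv_units = if (d == 3) "mL" else "mm^2",
    peak_Q = max(abs(series$Q)), q_units = if (d == 3) "mL/s" else "mm^2/s",
    peak_ke_avg = max(series$ke_avg),
    peak_abs_hdf = max(abs(series$hdf)),
    peak_abs_P_mW = max(abs(series$P)),
    mass_error_rel = max(cycres$diagnostics$mass_err[-1]) /
      max(abs(cycres$diagnostics$Q)),
    periodicity = cycres$periodicity,
    mean_dice = if (!is.null(dice)) mean(dice) else NA)
  if (!is.null(reference) && !is.null(reference$sv))
    summary$sv_reference <- reference$sv / 1e3
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (isTRUE(cfg$output$plots)) {
    png(file.path(out_dir, "hemo_series.png"), width = 1200, height = 700)
    plot(series, es = cyc$systole_fraction)
    dev.off()
  }
  invisible(list(summary = summary, series = series, out_dir = out_dir,
                 diagnostics = cycres$diagnostics))
}
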