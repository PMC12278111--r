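# Configuration files, stack I/O and reproducible simulation runs.

#' Write a stack as multi-page 32-bit TIFF
#'
#' Planes are stored as 32-bit samples scaled into \[0, 1\] by a single
#' factor (the stack maximum); the factor and voxel sizes are written to a
#' companion JSON sidecar `<path>.json` so the stack can be restored
#' losslessly (to float precision).
#'
#' @param stack An [image_stack].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$intensities)
  scale <- max(stack$intensities, 1e-12)
  pages <- lapply(seq_len(d[1]), function(i) stack$intensities[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(voxel_nm = stack$voxel, scale = scale,
               normalization = stack$normalization,
               z_planes_nm = stack$z_planes)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must exist unless
#'   `voxel` is given.
#' @param voxel Optional c(dz, dy, dx) in nm, overriding the sidecar.
#' @return An [image_stack].
#' @export
read_stack_tiff <- function(path, voxel = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  if (is.null(voxel)) {
    if (is.null(meta)) stop("no voxel metadata: sidecar JSON missing and `voxel` not given")
    voxel <- meta$voxel_nm
  }
  scale <- if (!is.null(meta)) meta$scale else 1
  nz <- length(pages)
  arr <- array(0, c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_len(nz)) arr[i, , ] <- pages[[i]] * scale
  image_stack(arr, voxel,
              normalization = if (!is.null(meta$normalization)) meta$normalization else "raw",
              z_planes = if (!is.null(meta$z_planes_nm)) meta$z_planes_nm else NULL)
}

#' Load a run configuration from YAML or JSON
#'
#' @param path File ending in .yaml/.yml or .json.
#' @return Named list (validated by [validate_run_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json")
  }
  validate_run_config(cfg)
}

#' Validate and complete a run configuration
#'
#' Fills defaults and checks the schema of a simulation run configuration:
#' `model` (one of pcmie, pcmie_tilted, incbl), `sample` (diameter_nm,
#' energy_ev, delta, beta, density_fraction), `microscope` (fields of
#' [microscope_config()]), `grid` (nx, ny, pixel_nm, z_min_nm, z_max_nm,
#' z_step_nm), optional `noise` (photon_scale, flicker_sd, jitter_max), and
#' `seed`.
#'
#' @param cfg Named list.
#' @return The completed configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a named list")
  cfg$model <- cfg$model %||% "pcmie"
  if (!cfg$model %in% c("pcmie", "pcmie_tilted", "incbl")) {
    stop("model must be one of pcmie, pcmie_tilted, incbl")
  }
  s <- cfg$sample %||% list()
  s$diameter_nm <- s$diameter_nm %||% 63.2
  s$energy_ev <- s$energy_ev %||% 510
  s$delta <- s$delta %||% 3.6e-3
  s$beta <- s$beta %||% 2.6e-3
  s$density_fraction <- s$density_fraction %||% 1
  if (s$diameter_nm <= 0 || s$energy_ev <= 0 || s$beta < 0) {
    stop("invalid sample block")
  }
  cfg$sample <- s
  m <- cfg$microscope %||% list()
  g <- cfg$grid %||% list()
  g$nx <- g$nx %||% 256L
  g$ny <- g$ny %||% g$nx
  g$pixel_nm <- g$pixel_nm %||% 5.5
  g$z_min_nm <- g$z_min_nm %||% -6000
  g$z_max_nm <- g$z_max_nm %||% 6000
  g$z_step_nm <- g$z_step_nm %||% 40
  if (g$z_max_nm < g$z_min_nm || g$z_step_nm <= 0 || g$pixel_nm <= 0) {
    stop("invalid grid block")
  }
  cfg$grid <- g
  cfg$microscope <- m
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_objects <- function(cfg) {
  s <- cfg$sample
  optics <- optical_constants(energy = s$energy_ev, delta = s$delta, beta = s$beta)
  sample <- sphere_sample(diameter = s$diameter_nm, optics = optics,
                          density_fraction = s$density_fraction)
  m <- cfg$microscope
  config <- do.call(microscope_config,
                    c(list(wavelength = optics$wavelength), m))
  g <- cfg$grid
  grid <- camera_grid(nx = g$nx, ny = g$ny, pixel_size = g$pixel_nm,
                      z_planes = seq(g$z_min_nm, g$z_max_nm, by = g$z_step_nm))
  list(sample = sample, config = config, grid = grid)
}

log_line <- function(con, stage, t0, ...) {
  msg <- sprintf("[%s] %-10s %7.2fs %s",
                 format(Sys.time(), "%H:%M:%S"), stage,
                 as.numeric(Sys.time()) - t0,
                 paste(..., collapse = " "))
  writeLines(msg, con)
  msg
}

#' Run a simulation to files
#'
#' Runs the configured forward model and writes three files:
#' `<out>.tif` (the stack), `<out>.tif.json` (voxel/scale sidecar) and
#' `<out>_provenance.json` (full configuration echo, package version and
#' seed), plus `<out>.log` with per-stage timings.
#'
#' @param cfg Configuration list or path to a YAML/JSON file.
#' @param out Output path prefix (without extension).
#' @param force Overwrite existing outputs.
#' @param n_fft Pupil FFT size passed to the pc models.
#' @return Invisible character vector of the files written.
#' @export
run_simulate <- function(cfg, out, force = FALSE, n_fft = 1024) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  paths <- c(stack = paste0(out, ".tif"),
             provenance = paste0(out, "_provenance.json"),
             log = paste0(out, ".log"))
  if (!force && any(file.exists(paths))) {
    stop("output exists; use force = TRUE to overwrite")
  }
  t0 <- as.numeric(Sys.time())
  logf <- file(paths["log"], open = "wt")
  on.exit(close(logf))
  ob <- build_objects(cfg)
  log_line(logf, "setup", t0,
           sprintf("model=%s d=%gnm grid=%dx%dx%d", cfg$model,
                   2 * ob$sample$a, length(ob$grid$z_planes),
                   ob$grid$ny, ob$grid$nx))
  stack <- switch(cfg$model,
                  pcmie = pc_image(ob$sample, ob$config, ob$grid, n_fft = n_fft),
                  pcmie_tilted = pc_image_tilted(ob$sample, ob$config, ob$grid, n_fft = n_fft),
                  incbl = incbl_image(ob$sample, ob$config, ob$grid))
  log_line(logf, "model", t0, "stack computed")
  if (!is.null(cfg$noise)) {
    nz <- dim(stack$intensities)[1]
    noise <- acquisition_noise(nz,
                               photon_scale = cfg$noise$photon_scale %||% 1e4,
                               flicker_sd = cfg$noise$flicker_sd %||% 0.05,
                               jitter_max = cfg$noise$jitter_max %||% 3,
                               seed = cfg$seed)
    stack <- corrupt_stack(stack, noise)
    log_line(logf, "noise", t0,
             sprintf("photon_scale=%g seed=%d", noise$photon_scale, cfg$seed))
  }
  write_stack_tiff(stack, paths["stack"])
  prov <- list(package = "txmsim",
               version = as.character(utils::packageVersion("txmsim")),
               config = cfg,
               files = as.list(paths))
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_line(logf, "write", t0, paths["stack"])
  invisible(paths)
}

#' Analyze a stack from files
#'
#' Reads a stack, background-normalizes it, locates the best focus, and
#' writes the radial profile (`<out>_profile.csv`), the absorption table
#' (`<out>_absorption.csv`) and a summary (`<out>_summary.json`) with the
#' best-focus plane, centre, mean absorption and - when a sample block is
#' available from a provenance file or `sample` argument - the ratio to
#' Beer's law.
#'
#' @param stack_path Path to a TIFF written by [write_stack_tiff()].
#' @param out Output path prefix.
#' @param sample Optional [sphere_sample] for the Beer's-law comparison; by
#'   default reconstructed from `<prefix>_provenance.json` if present.
#' @param voxel Optional voxel override c(dz, dy, dx) nm.
#' @param force Overwrite outputs.
#' @return Invisible summary list.
#' @export
run_analyze <- function(stack_path, out, sample = NULL, voxel = NULL,
                        force = FALSE) {
  paths <- c(profile = paste0(out, "_profile.csv"),
             absorption = paste0(out, "_absorption.csv"),
             summary = paste0(out, "_summary.json"))
  if (!force && any(file.exists(paths))) {
    stop("output exists; use force = TRUE to overwrite")
  }
  stack <- read_stack_tiff(stack_path, voxel = voxel)
  stack <- normalize_stack(stack)
  if (is.null(sample)) {
    prov_path <- sub("\\.tif$", "_provenance.json", stack_path)
    prov_path <- sub("\\.tif_provenance", "_provenance", prov_path)
    if (file.exists(prov_path)) {
      pc <- jsonlite::read_json(prov_path, simplifyVector = TRUE)$config
      if (!is.null(pc$sample)) {
        sample <- build_objects(validate_run_config(pc))$sample
      }
    }
  }
  focus <- find_best_focus(stack)
  plane <- stack$intensities[focus$z_index, , ]
  prof <- radial_profile(plane, focus$center, stack$voxel[3], stack$voxel[3])
  utils::write.csv(data.frame(r_nm = prof$r, I = prof$intensity,
                              n_pix = prof$n_pixels),
                   paths["profile"], row.names = FALSE)
  ok <- !is.na(prof$r)
  rmax <- max(prof$r[ok])
  ends <- if (!is.null(sample)) {
    e <- default_endpoints(sample)
    e[e <= rmax]
  } else {
    seq(0.3, 0.8, length.out = 8) * rmax
  }
  A <- absorption_from_profile(prof, ends)
  utils::write.csv(data.frame(r_end_nm = A$endpoints, A_nm2 = A$values),
                   paths["absorption"], row.names = FALSE)
  summary <- list(best_focus_z_index = focus$z_index,
                  best_focus_z_nm = focus$z,
                  center_yx_px = as.numeric(focus$center),
                  min_intensity = focus$value,
                  A_mean_nm2 = A$mean, A_sd_nm2 = A$sd)
  if (!is.null(sample)) {
    abl <- beer_absorption(sample, "closed")
    summary$A_beer_nm2 <- abl
    summary$ratio_model_over_beer <- if (abl > 0) A$mean / abl else NA
  }
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Run the built-in validation suite
#'
#' Re-derives the package's main numerical cross-checks at reduced size:
#' the Mie/ADA/EA agreement for the reference gold sphere, the plane-wave
#' backend equivalence (series vs quadrature), the Airy pattern of the
#' unaberrated pupil, and the Beer's-law closed-form oracle. Intended for
#' the command-line `validate` subcommand.
#'
#' @param verbose Print a line per check.
#' @return Named list of the check values, invisibly.
#' @export
run_validation <- function(verbose = TRUE) {
  sample <- sphere_sample(diameter = 63.2)
  config <- microscope_config(wavelength = sample$optics$wavelength)
  psi <- default_psi_grid(config, n = 512)
  mie <- mie_amplitudes(sample, psi)
  ada <- ada_amplitude(sample, psi)
  ea <- ea_amplitude(sample, psi)
  chk <- list()
  chk$ada_vs_mie <- max(Mod(mie$S1 - ada$S1)) / max(Mod(ada$S1))
  chk$ada_vs_ea <- max(Mod(ada$S1 - ea$S1)) / max(Mod(ada$S1))
  chk$optical_theorem <- abs(mie_qext(sample, "series") - mie_qext(sample, "forward")) /
    mie_qext(sample, "series")
  u <- sample$optics$k * config$r_zp^2 / config$R_f
  v <- seq(1500, 2500, length.out = 64)
  chk$pw_backends <- {
    a1 <- aperture_integral(u, v)
    a2 <- aperture_integral_quad(u, v)
    sqrt(sum(Mod(a1 - a2)^2) / sum(Mod(a2)^2))
  }
  chk$beer_closed_form <- abs(beer_absorption(sample, "quadrature") -
                                beer_absorption(sample, "closed")) /
    beer_absorption(sample, "closed")
  if (verbose) {
    for (nm in names(chk)) cat(sprintf("%-18s %.3g\n", nm, chk[[nm]]))
  }
  invisible(chk)
}
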