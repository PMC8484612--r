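#' Read and validate an experiment configuration
#'
#' A YAML file with sections `scene`, `imaging`, `interface`,
#' `segmentation` and `analysis` (all optional; defaults fill in), plus a
#' global `seed` and `output_dir`. The global seed is fanned out to the
#' scene, noise and SBR-sampling substreams, so one integer reproduces the
#' whole run.
#'
#' @param path YAML path, or a list already in config shape.
#' @return List of class `experiment_config` with fully constructed
#'   component specs.
#' @export
read_experiment_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    yaml::read_yaml(path)
  } else path
  if (!is.list(raw)) stop("config must be a YAML mapping")
  known <- c("seed", "output_dir", "scene", "imaging", "interface",
             "segmentation", "analysis")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seed <- as.integer(raw$seed %||% 1L)
  scene <- do.call(scene_spec, modifyList(list(seed = seed),
                                          raw$scene %||% list()))
  imaging <- do.call(imaging_spec, modifyList(list(seed = seed),
                                              raw$imaging %||% list()))
  iface <- raw$interface %||% list(ri_incident = 1.33, ri_transmitted = 1.333)
  interface <- ri_interface(iface$ri_incident, iface$ri_transmitted)
  seg <- do.call(segmentation_params, raw$segmentation %||% list())
  ana <- raw$analysis %||% list()
  analysis <- list(thresholds_deg = ana$thresholds_deg %||% c(30, 45),
                   tile_um = ana$tile_um %||% 2.4,
                   z_offset_um = ana$z_offset_um %||% 1,
                   n_regions = ana$n_regions %||% 20L,
                   roi = ana$roi)
  structure(list(seed = seed, output_dir = raw$output_dir %||% ".",
                 scene = scene, imaging = imaging, interface = interface,
                 segmentation = seg, analysis = analysis),
            class = "experiment_config")
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(.unclass_rec(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), .unclass_rec) else x
}

.write_manifest <- function(dir, config, stage, artifacts) {
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  manifest$tool <- "crmbiofilm"
  manifest$version <- as.character(packageVersion("crmbiofilm"))
  manifest$config_hash <- .config_hash(config)
  manifest$seed <- config$seed
  manifest$seeds_used <- list(scene = derive_seed(config$seed, "scene"),
                              noise = derive_seed(config$seed, "noise"),
                              sbr = derive_seed(config$seed, "sbr"))
  manifest$stages <- as.list(manifest$stages)
  manifest$stages[[stage]] <- list(status = "ok",
                                   time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  manifest$artifacts <- as.list(manifest$artifacts)
  for (nm in names(artifacts)) manifest$artifacts[[nm]] <- artifacts[[nm]]
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  manifest_path
}

#' Simulate a synthetic experiment to disk
#'
#' Samples, rasterizes and renders the configured scene; writes the
#' rendered stack (TIFF + sidecar), the ground-truth cell table (CSV) and
#' label volume (TIFF), and a run manifest.
#'
#' @param config An `experiment_config` (or a YAML path).
#' @param output_dir Overrides the config's output directory.
#' @return Named character vector of artifact paths, invisibly.
#' @export
run_simulate <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  dir <- output_dir %||% config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_stack(config$scene, config$imaging, config$interface)
  paths <- c(stack = file.path(dir, "stack.tiff"),
             truth_cells = file.path(dir, "truth_cells.csv"),
             truth_labels = file.path(dir, "truth_labels.tiff"))
  write_stack(sim$stack, paths[["stack"]])
  write_truth(sim$truth, paths[["truth_cells"]], paths[["truth_labels"]])
  .write_manifest(dir, config, "simulate", as.list(paths))
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}

#' Analyze a reflection z-stack
#'
#' Runs interface localization, segmentation and the full morphometric
#' battery; writes the per-cell measurement table, occupancy profile and a
#' summary JSON. When ground truth is supplied, recovery errors
#' (|estimate - truth|) are included in the summary.
#'
#' @param config An `experiment_config` (or YAML path).
#' @param stack A [zstack()] or path to one written by [write_stack()].
#' @param truth Optional `ground_truth` (or path to a truth CSV).
#' @param output_dir Overrides the config's output directory.
#' @return The summary list, invisibly; artifacts on disk.
#' @export
run_analyze <- function(config, stack, truth = NULL, output_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  if (is.character(stack)) stack <- read_stack(stack)
  if (is.character(truth)) truth <- read_truth(truth)
  dir <- output_dir %||% config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ana <- config$analysis

  iface <- locate_interface(stack)
  labels <- segment_cells(stack, config$segmentation)
  cells <- measure_cells(labels)
  summ <- angle_summary(cells$pitch_deg, ana$thresholds_deg)
  occ <- occupancy_profile(labels, ana$roi)
  heat <- density_heatmap(labels, ana$tile_um)

  refs <- occ_ref <- NULL
  if (labels$n_labels > 0) {
    refs <- colony_reference_slices(labels, ana$roi)
    occ_ref <- occ$occupancy[refs]
    names(occ_ref) <- names(refs)
  }
  sbr <- tryCatch(
    signal_background_ratio(stack, labels, ana$z_offset_um, ana$n_regions,
                            seed = config$seed),
    error = function(e) NULL)
  background <- estimate_background(stack, ana$z_offset_um, labels = labels)

  summary <- list(
    n_labels = labels$n_labels,
    threshold = labels$threshold,
    interface = list(index = iface$index, z_um = iface$z_um,
                     no_peak = iface$no_peak),
    pitch = list(n = summ$n, mean_deg = summ$mean_deg,
                 fraction_below = as.list(summ$fraction_below)),
    occupancy = if (is.null(occ_ref))
      list(bottom = NA, mid = NA, top = NA)
    else as.list(occ_ref),
    background_au = background,
    sbr = if (!is.null(sbr)) sbr$ratio else NA)

  if (!is.null(truth)) {
    true_pitch <- cell_pitches(truth$cells)
    true_summ <- angle_summary(true_pitch, ana$thresholds_deg)
    recovery <- list(
      mean_pitch_error_deg = abs(summ$mean_deg - true_summ$mean_deg),
      fraction_below_error = as.list(abs(summ$fraction_below -
                                           true_summ$fraction_below)),
      count_error = abs(labels$n_labels - nrow(truth$cells)))
    if (!is.null(truth$labels)) {
      occ_true <- occupancy_profile(truth$labels, ana$roi)
      recovery$max_abs_occupancy_error <-
        max(abs(occ$occupancy - occ_true$occupancy))
    }
    summary$recovery <- recovery
  }

  paths <- c(cells = file.path(dir, "cells.csv"),
             occupancy = file.path(dir, "occupancy.csv"),
             summary = file.path(dir, "summary.json"),
             labels = file.path(dir, "labels.tiff"))
  write.csv(cells, paths[["cells"]], row.names = FALSE)
  write.csv(occ, paths[["occupancy"]], row.names = FALSE)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  write_labels(labels, paths[["labels"]])
  .write_manifest(dir, config, "analyze", as.list(paths))
  invisible(summary)
}

#' Render a human-readable report for an analyzed run
#'
#' Produces PNG figures (occupancy vs z, pitch vs z, axial intensity
#' profile, density-heatmap montage, maximum-intensity projection) and a
#' markdown page referencing them.
#'
#' @param run_dir Directory holding the outputs of [run_simulate()] /
#'   [run_analyze()].
#' @return Path to the markdown report, invisibly.
#' @export
run_report <- function(run_dir) {
  need <- file.path(run_dir, c("cells.csv", "occupancy.csv", "summary.json"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stop("missing analysis output(s): ", paste(miss, collapse = ", "))
  cells <- read.csv(need[1])
  occ <- read.csv(need[2])
  summary <- jsonlite::read_json(need[3], simplifyVector = TRUE)
  figs <- character(0)

  fig <- function(name, expr) {
    p <- file.path(run_dir, name)
    grDevices::png(p, width = 720, height = 540)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr()
    figs <<- c(figs, name)
  }
  fig("occupancy_vs_z.png", function()
    plot(occ$z_um, 100 * occ$occupancy, type = "b", pch = 16,
         xlab = "z from interface (um)", ylab = "area occupation (%)",
         main = "Cell density profile"))
  if (nrow(cells) > 0 && any(!is.na(cells$pitch_deg)))
    fig("pitch_vs_z.png", function()
      plot(cells$pitch_deg, cells$z_um, pch = 1,
           xlab = "pitch angle (deg)", ylab = "centroid z (um)",
           xlim = c(0, 90), main = "Per-cell pitching angles"))
  stack_path <- file.path(run_dir, "stack.tiff")
  if (file.exists(stack_path)) {
    stack <- read_stack(stack_path)
    prof <- axial_intensity_profile(stack)
    fig("axial_profile.png", function()
      plot(prof$z_um, prof$mean_intensity, type = "l",
           xlab = "z from interface (um)", ylab = "mean intensity (a.u.)",
           main = "Axial intensity profile"))
    fig("max_projection.png", function() {
      graphics::image(max_projection(stack), col = grDevices::gray.colors(256),
                      axes = FALSE, main = "Maximum-intensity projection")
    })
  }
  labels_path <- file.path(run_dir, "labels.tiff")
  if (file.exists(labels_path)) {
    labels <- read_labels(labels_path)
    heat <- density_heatmap(labels)
    ks <- unique(round(seq(1, dim(heat$tiles)[3], length.out = 4)))
    fig("density_heatmap.png", function() {
      graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
      for (k in ks)
        graphics::image(t(heat$tiles[, , k]), zlim = c(0, 1), axes = FALSE,
                        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                        main = sprintf("z = %.1f um", heat$z_um[k]))
    })
  }

  md <- file.path(run_dir, "report.md")
  lines <- c("# CRM biofilm analysis report", "",
             sprintf("- Labeled cells: %s", summary$n_labels),
             if (!is.null(summary$pitch) && summary$pitch$n > 0) c(
               sprintf("- Mean pitch: %.1f deg (n = %d)",
                       summary$pitch$mean_deg, summary$pitch$n),
               sprintf("- Fraction below 30 deg: %.2f",
                       summary$pitch$fraction_below$lt_30))
             else "- No cells measured.",
             if (!is.null(summary$recovery)) c("",
               "## Recovery vs ground truth",
               sprintf("- |mean pitch error| = %.2f deg",
                       summary$recovery$mean_pitch_error_deg),
               sprintf("- |count error| = %s", summary$recovery$count_error)),
             "", "## Figures", "",
             sprintf("![%s](%s)", figs, figs))
  writeLines(lines, md)
  invisible(md)
}

#' Run simulate + analyze + report in one call
#'
#' @param config An `experiment_config` or YAML path.
#' @param output_dir Overrides the config's output directory.
#' @return The analysis summary, invisibly.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  dir <- output_dir %||% config$output_dir
  paths <- run_simulate(config, dir)
  summary <- run_analyze(config, paths[["stack"]],
                         truth = read_truth(paths[["truth_cells"]],
                                            paths[["truth_labels"]],
                                            spec = config$scene),
                         output_dir = dir)
  run_report(dir)
  invisible(summary)
}
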