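# Pipeline orchestration: load or generate a volume, mask the fruit, find
# the valley threshold, segment phases, run morphometry, skeleton network
# and region/core analysis, and emit a reproducible run report. Every stage
# can be toggled; a failing stage is recorded with its reason and later
# independent stages still run.

#' Build a run configuration
#'
#' @param input either `list(preset = "<name>", seed = <int>)` to generate a
#'   phantom, or `list(path = "<file>", voxel_size_um = <num or NULL>)` to
#'   load a volume.
#' @param stages named logical toggles: `mask`, `segmentation`,
#'   `morphometry`, `skeleton`, `regions`. Missing entries default to TRUE.
#' @param params stage parameters: `smoothing_window`, `connectivity`,
#'   `min_voxels`, `spur_min_um` (NULL = 2 voxels), `fractions`,
#'   `class_width_um`, `max_um`, `threshold` (NULL = valley),
#'   `window` (optional c(min, max) for 16-bit conversion),
#'   `grid_shape` (optional phantom grid override).
#' @param output_dir where [write_report()] puts files (default: not written).
#' @return A `run_config` list with a versioned schema field.
#' @export
run_config <- function(input, stages = list(), params = list(),
                       output_dir = NULL) {
  defaults <- list(mask = TRUE, segmentation = TRUE, morphometry = TRUE,
                   skeleton = TRUE, regions = TRUE)
  stages <- utils::modifyList(defaults, stages)
  pdef <- list(smoothing_window = 9L, connectivity = 26L, min_voxels = 1L,
               spur_min_um = NULL, fractions = c(1/3, 2/3),
               class_width_um = 100, max_um = 3000, threshold = NULL,
               window = NULL, grid_shape = NULL)
  params <- utils::modifyList(pdef, params)
  if (is.null(input$preset) && is.null(input$path))
    stop("input must name a phantom preset or a volume path", call. = FALSE)
  if (!is.null(input$preset)) {
    if (!input$preset %in% names(preset_table()))
      stop("unknown preset: ", input$preset, call. = FALSE)
    if (is.null(input$seed))
      stop("a seed is mandatory for phantom inputs", call. = FALSE)
  }
  structure(list(schema = "fruitpore-config/1", input = input,
                 stages = stages, params = params, output_dir = output_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return [read_run_config()] returns a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$schema, "fruitpore-config/1"))
    stop("unrecognized config schema: ", y$schema, call. = FALSE)
  run_config(y$input, y$stages %||% list(), y$params %||% list(), y$output_dir)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages in fixed order: load/generate, fruit mask, histogram + valley
#' threshold, phase segmentation, pore labeling and morphometry, skeleton
#' network, region/core analysis. Deterministic for a given config (phantom
#' seeds are part of the config; nothing else draws random numbers). When
#' the input is a phantom, a truth-comparison block quantifies the errors
#' of the measured quantities against the generator's ground truth.
#'
#' @param config a [run_config()].
#' @return A `run_report` list; see the package vignette for the layout.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  report <- list(schema = "fruitpore-report/1",
                 config = unclass(config),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 stages_run = character(0), failures = list())
  note_fail <- function(stage, e) {
    report$failures[[stage]] <<- conditionMessage(e)
  }

  truth <- NULL
  if (!is.null(config$input$preset)) {
    spec <- phantom_preset(config$input$preset, seed = config$input$seed,
                           grid_shape = p$grid_shape)
    gen <- generate_phantom(spec)
    vol <- gen$volume
    truth <- gen$truth
  } else {
    vol <- read_volume(config$input$path,
                       voxel_size_um = config$input$voxel_size_um %||% NULL)
    if (vol$bit_depth == 16L) {
      w <- p$window %||% range(vol$intensities)
      vol <- convert_to_8bit(vol, w[1L], w[2L])
    }
  }
  report$volume <- list(dim = dim(vol$intensities),
                        voxel_size_um = vol$voxel_size_um,
                        bit_depth = vol$bit_depth,
                        axis_convention = vol$axis_convention)
  report$stages_run <- c(report$stages_run, "load")

  mask <- NULL
  if (isTRUE(config$stages$mask)) {
    mask <- tryCatch(compute_fruit_mask(vol), error = function(e) {
      note_fail("mask", e); NULL })
    if (!is.null(mask)) report$stages_run <- c(report$stages_run, "mask")
  }

  phase <- NULL
  if (isTRUE(config$stages$segmentation) && !is.null(mask)) {
    seg <- tryCatch({
      h <- compute_histogram(vol, mask)
      params <- if (is.null(p$threshold))
        find_valley_threshold(h, p$smoothing_window)
      else structure(list(threshold = p$threshold,
                          smoothing_window = p$smoothing_window,
                          source = "manual"), class = "segmentation_params")
      list(params = params, phase = segment_phases(vol, params, mask))
    }, error = function(e) { note_fail("segmentation", e); NULL })
    if (!is.null(seg)) {
      phase <- seg$phase
      report$threshold <- list(value = seg$params$threshold,
                               source = seg$params$source,
                               smoothing_window = seg$params$smoothing_window)
      report$stages_run <- c(report$stages_run, "segmentation")
    }
  }

  if (isTRUE(config$stages$morphometry) && !is.null(phase)) {
    mor <- tryCatch({
      labels <- label_pores(phase, p$connectivity, p$min_voxels)
      tab <- build_pore_table(labels)
      region_mm3 <- sum(mask) * (vol$voxel_size_um / 1000)^3
      list(porosity_percent = porosity(phase, mask),
           profile = porosity_profile(phase),
           n_pores = labels$n,
           pore_density_mm3 = pore_number_density(tab, region_mm3),
           mean_d_eq_um = if (nrow(tab) > 0L) mean(tab$d_eq_um) else NA_real_,
           mean_d_eq_volume_weighted_um = if (nrow(tab) > 0L)
             sum(tab$d_eq_um * tab$volume_um3) / sum(tab$volume_um3) else NA_real_,
           size_histogram = pore_size_histogram(tab, p$class_width_um, p$max_um),
           pore_table = tab)
    }, error = function(e) { note_fail("morphometry", e); NULL })
    if (!is.null(mor)) {
      report$morphometry <- mor[setdiff(names(mor), "pore_table")]
      report$pore_table <- mor$pore_table
      report$stages_run <- c(report$stages_run, "morphometry")
    }
  }

  graph <- NULL
  if (isTRUE(config$stages$skeleton) && !is.null(phase)) {
    net <- tryCatch({
      skel <- skeletonize(phase)
      dmap <- distance_map(phase)
      spur <- p$spur_min_um %||% (2 * vol$voxel_size_um)
      g <- extract_network(skel, dmap, vol$voxel_size_um, spur)
      list(graph = g, stats = network_stats(g))
    }, error = function(e) { note_fail("skeleton", e); NULL })
    if (!is.null(net)) {
      graph <- net$graph
      report$network <- net$stats
      report$stages_run <- c(report$stages_run, "skeleton")
    }
  }

  if (isTRUE(config$stages$regions) && !is.null(phase) && !is.null(mask)) {
    reg <- tryCatch({
      core <- tryCatch(extract_core(vol, mask, p$smoothing_window),
                       fruitpore_core_error = function(e) e)
      core_fallback <- inherits(core, "condition")
      core_msg <- if (core_fallback) conditionMessage(core) else NULL
      if (core_fallback) core <- fallback_core(mask)
      part <- partition_mesocarp(mask, core, p$fractions)
      masks <- region_masks(part)
      zone_por <- lapply(masks, function(m)
        if (any(m)) porosity(phase, m) else NA_real_)
      shape <- core_shape_metrics(core, vol$voxel_size_um)
      list(core_source = if (core_fallback) "fallback_ellipsoid" else "grayscale",
           core_failure = core_msg,
           zone_porosity_percent = zone_por,
           core_shape = shape)
    }, error = function(e) { note_fail("regions", e); NULL })
    if (!is.null(reg)) {
      report$regions <- reg
      report$stages_run <- c(report$stages_run, "regions")
    }
  }

  if (!is.null(truth)) {
    cmp <- list(true_porosity_percent = truth$true_porosity_percent,
                true_n_pores = nrow(truth$pore_table))
    if (!is.null(report$morphometry)) {
      cmp$porosity_error_points <-
        report$morphometry$porosity_percent - truth$true_porosity_percent
      cmp$n_pores_error <- report$morphometry$n_pores - nrow(truth$pore_table)
      if (nrow(truth$pore_table) > 0L)
        cmp$mean_d_eq_error_um <-
          report$morphometry$mean_d_eq_um - mean(truth$pore_table$d_eq_um)
    }
    report$truth_comparison <- cmp
  }

  class(report) <- "run_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a run report
#'
#' JSON report (everything except the bulky pore table), plus the pore table
#' and the axial porosity profile as CSV.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  main <- unclass(report)
  tab <- main$pore_table
  prof <- main$morphometry$profile
  main$pore_table <- NULL
  main$morphometry$profile <- NULL
  jsonlite::write_json(main, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(tab)) write.csv(tab, file.path(dir, "pore_table.csv"),
                               row.names = FALSE)
  if (!is.null(prof)) write.csv(prof, file.path(dir, "porosity_profile.csv"),
                                row.names = FALSE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$timestamp, "\n")
  cat(" stages:", paste(x$stages_run, collapse = ", "), "\n")
  if (!is.null(x$threshold))
    cat(sprintf(" threshold %.2f (%s)\n", x$threshold$value, x$threshold$source))
  if (!is.null(x$morphometry))
    cat(sprintf(" porosity %.2f%%, %d pores, mean d_eq %.0f um\n",
                x$morphometry$porosity_percent, x$morphometry$n_pores,
                x$morphometry$mean_d_eq_um))
  if (!is.null(x$network))
    cat(sprintf(" network: %d nodes, %d edges, avg coordination %.2f (max %d)\n",
                x$network$n_nodes, x$network$n_edges,
                x$network$avg_coordination,
                as.integer(x$network$max_coordination)))
  if (length(x$failures) > 0L)
    cat(" failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
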