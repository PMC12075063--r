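# File formats, configuration and the end-to-end pipeline driver. Images
# travel as multi-page TIFF (one page per z-slice, z outermost); labels as
# 16-bit TIFF, widened to 32-bit float pages (exact for integer ids below
# 2^24) when ids exceed 65,535; tables as CSV; skeletons as SWC; run
# manifests as JSON with md5 checksums of every written file.

#' Read a 3D stack from a multi-page TIFF
#'
#' z comes from page order. Integer containers (8/16 bit) are rescaled back
#' to their integer range; 32-bit float pages are returned as stored.
#' Spacing comes from the `spacing_um` argument; if the file carries
#' resolution tags that disagree, the argument wins and a warning is
#' logged.
#'
#' @param path TIFF file.
#' @param spacing_um voxel spacing (z, y, x) in µm.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, spacing_um) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop_data("stack must be 3D: ", path,
                                   " has a single page")
  info <- attributes(pages[[1]])
  bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 16
  scale <- if (bits <= 16) 2^bits - 1 else 1
  if (!is.null(info$x.resolution) && info$x.resolution > 0) {
    tag_um <- 1 / info$x.resolution
    if (abs(tag_um - spacing_um[3]) / tag_um > 1e-6)
      warning("TIFF resolution tag (", signif(tag_um, 4),
              " um) disagrees with configured spacing (",
              signif(spacing_um[3], 4), " um); using the configuration")
  }
  d2 <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * scale
  image_stack(arr, spacing_um)
}

#' Write a 3D stack to a multi-page TIFF
#'
#' Non-negative integer data are stored losslessly in the smallest
#' sufficient integer container (8 or 16 bit); other data are normalised to
#' `[0, 1]` and stored as 32-bit float (intensity units are arbitrary, so
#' only relative values are preserved in that case).
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  x <- stack$data
  is_int <- all(x >= 0) && all(x == round(x))
  if (is_int && max(x) <= 255) {
    pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else if (is_int && max(x) <= 65535) {
    pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    mx <- max(x)
    mn <- min(x)
    rng <- if (mx > mn) mx - mn else 1
    pages <- lapply(seq_len(dim(x)[1]), function(i) (x[i, , ] - mn) / rng)
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  }
  invisible(path)
}

#' Write an instance label volume to TIFF
#'
#' 16-bit pages when the maximum id fits; otherwise 32-bit float pages
#' (exact for integer labels below 2^24), with the widening logged.
#'
#' @param labels a [label_volume()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  x <- labels$data
  if (any(x < 0)) stop_param("labels must be non-negative")
  m <- max(x)
  if (m > 2^24 - 1) stop_param("labels above 2^24 - 1 are not representable")
  if (m <= 65535) {
    pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    message("label ids exceed 65535: widening to 32-bit float pages")
    pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / 2^24)
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  }
  invisible(path)
}

#' Read an instance label volume from TIFF
#'
#' @param path TIFF written by [write_labels()].
#' @param spacing_um voxel spacing (z, y, x) in µm.
#' @return a [label_volume()].
#' @export
read_labels <- function(path, spacing_um) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop_data("label volume must be 3D")
  info <- attributes(pages[[1]])
  bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 16
  scale <- if (bits <= 16) 2^bits - 1 else 2^24
  d2 <- dim(pages[[1]])
  arr <- array(0L, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) arr[i, , ] <- as.integer(round(pages[[i]] * scale))
  label_volume(arr, spacing_um)
}

default_config <- function() {
  list(
    input = NULL, out_dir = "mnmorph_out", spacing_um = c(1.5, 1.5, 1.5),
    seed = 1L,
    stages = c("simulate", "segment_soma", "quantify_soma", "classify"),
    simulate = list(grid_shape = c(256, 256, 256), n_somata = 50,
                    mixture = list(w = 0.3, mean1 = 4000, sd1 = 1200,
                                   mean2 = 15000, sd2 = 4000),
                    min_gap_um = 25, soma_peak_intensity = 200,
                    background_intensity = 20, noise_sd = 10),
    segment_soma = list(median_radius_vox = 2, low_frac = 0.5,
                        high_frac = 0.75, top_quantile = 0.999,
                        refine_mask = TRUE, refine_dilate_vox = 2,
                        sigma_um = 1,
                        min_seed_distance_um = 8, h_um = 2,
                        min_volume_um3 = 500, max_volume_um3 = 60000),
    quantify_soma = list(expansion_linear_factor = 1.2,
                         slab_thickness_um = 100),
    classify = list(delta_bic_margin = 10),
    trace = list(rod_scales_um = c(1, 1.5, 2, 3), ball_scales_um = c(4, 6, 8),
                 threshold = 0.05, prune_um = 4, axon_min_len_um = 500),
    metrics = list(r_step_um = 25, max_order = 6, exclude_axon = FALSE))
}

check_config_keys <- function(cfg, ref = default_config(), path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0)
    stop_param("unknown configuration key(s): ",
               paste0(path, unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(cfg[[k]]) &&
        k != "mixture")
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Build a validated pipeline configuration
#'
#' Every stage parameter has a default; unknown keys are rejected before
#' any stage runs. Configurations can also be read from YAML with
#' [read_config()].
#'
#' @param ... named overrides of the defaults (nested lists per stage).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  check_config_keys(user)
  cfg <- utils::modifyList(default_config(), user)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] structure.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the pipeline
#'
#' Executes the configured stages in order (simulate, segment_soma,
#' quantify_soma, classify, trace, metrics); each stage writes its outputs
#' before the next starts. A stage failure halts the run after writing a
#' manifest recording partial completion. All randomness derives from
#' `config$seed`, so repeat runs produce identical outputs and checksums.
#'
#' @param config a `pipeline_config`.
#' @return the run manifest (list: config, version, files with md5
#'   checksums, completed stages, timestamps), also written to
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  done <- character(0)
  t0 <- Sys.time()
  note <- function(path) files <<- c(files, path)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    fun()
    done <<- c(done, name)
  }
  finish <- function(status) {
    manifest <- list(
      status = status,
      version = as.character(utils::packageVersion("mnmorph")),
      config = unclass(config),
      completed_stages = done,
      files = data.frame(path = files,
                         md5 = unname(tools::md5sum(files)),
                         row.names = NULL),
      started = format(t0), finished = format(Sys.time()))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest
  }
  res <- tryCatch({
    run_stage("simulate", function() {
      spec <- do.call(soma_field_spec, c(
        config$simulate,
        list(spacing_um = config$spacing_um, seed = config$seed)))
      sim <- generate_soma_field(spec)
      state$stack <- sim$stack
      state$truth <- sim$truth
      note(write_stack(sim$stack, file.path(out_dir, "stack.tif")))
      note(write_labels(sim$truth$label_volume,
                        file.path(out_dir, "truth_labels.tif")))
      p <- file.path(out_dir, "truth.csv")
      write.csv(sim$truth$truth_table, p, row.names = FALSE)
      note(p)
    })
    run_stage("segment_soma", function() {
      if (is.null(state$stack))
        state$stack <- read_stack(config$input, config$spacing_um)
      state$labels <- segment_somata(state$stack, config$segment_soma)
      note(write_labels(state$labels, file.path(out_dir, "labels.tif")))
      rep <- attr(state$labels, "report")
      p <- file.path(out_dir, "seg_report.csv")
      write.csv(rep, p, row.names = FALSE)
      note(p)
    })
    run_stage("quantify_soma", function() {
      ex <- expansion_spec(config$quantify_soma$expansion_linear_factor)
      state$somas <- measure_somas(state$labels, ex)
      p <- file.path(out_dir, "soma.csv")
      write.csv(state$somas, p, row.names = FALSE)
      note(p)
      h <- histogram_volumes(state$somas$volume_um3, state$somas$id)
      ph <- file.path(out_dir, "histogram.csv")
      write.csv(data.frame(bin_left = head(h$bin_edges, -1),
                           bin_right = h$bin_edges[-1],
                           count = h$counts), ph, row.names = FALSE)
      note(ph)
      state$hist <- h
    })
    run_stage("classify", function() {
      k <- assess_modality(state$hist, config$classify$delta_bic_margin)
      fitrep <- list(modality = as.integer(k),
                     delta_bic = attr(k, "delta_bic"))
      if (k == 2L) {
        fit <- attr(k, "fit2")
        cl <- classify_somas(state$somas, fit$threshold_um3)
        pc <- file.path(out_dir, "calls.csv")
        write.csv(cl$calls, pc, row.names = FALSE)
        note(pc)
        fitrep <- c(fitrep, list(
          A = fit$A, mu = fit$mu, sigma = fit$sigma,
          threshold_um3 = fit$threshold_um3,
          small_fraction = cl$small_fraction))
      }
      pf <- file.path(out_dir, "fit.json")
      jsonlite::write_json(fitrep, pf, auto_unbox = TRUE, digits = NA)
      note(pf)
    })
    run_stage("trace", function() {
      if (is.null(state$stack))
        state$stack <- read_stack(config$input, config$spacing_um)
      tr <- config$trace
      skel <- trace_neuron(state$stack, tr$rod_scales_um, tr$ball_scales_um,
                           tr$threshold, tr$prune_um)
      skel <- mark_axon_candidate(skel, tr$axon_min_len_um)
      state$skel <- skel
      note(write_swc(skel, file.path(out_dir, "neuron_1.swc")))
    })
    run_stage("metrics", function() {
      if (is.null(state$skel)) {
        swcs <- list.files(out_dir, pattern = "\\.swc$", full.names = TRUE)
        if (length(swcs) == 0) stop_data("metrics stage: no skeleton available")
        state$skel <- read_swc(swcs[1])
      }
      mm <- config$metrics
      rep <- neuron_report(state$skel, 1L, mm$r_step_um, mm$exclude_axon)
      pb <- file.path(out_dir, "branches.csv")
      write.csv(rep$branches, pb, row.names = FALSE); note(pb)
      ps <- file.path(out_dir, "sholl.csv")
      write.csv(as.data.frame(rep$sholl), ps, row.names = FALSE); note(ps)
      po <- file.path(out_dir, "order_summary.csv")
      write.csv(branch_lengths_by_order(state$skel, mm$max_order,
                                        mm$exclude_axon),
                po, row.names = FALSE); note(po)
    })
    finish("complete")
  }, error = function(e) {
    finish(paste0("failed: ", conditionMessage(e)))
    stop(e)
  })
  res
}
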