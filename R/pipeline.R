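#' Build a pipeline run configuration
#'
#' A fully serializable description of an end-to-end run: phantom
#' generation, segmentation, left/right quantification, and 3D
#' reconstruction. The defaults form the "study replica" scenario: 3 hearts
#' of 5 sections each in the 690 x 970 analysis frame, 89% of stain pixel
#' mass on the left, K initialized at 6, replication factor 7. A run's
#' configuration plus its seed reproduce its outputs bit for bit.
#'
#' @param n_hearts number of hearts to simulate.
#' @param n_slices sections per heart.
#' @param left_fraction true left-side share of stain pixel mass.
#' @param frame_width,frame_height analysis frame (pixels).
#' @param noise_sd phantom pixel noise SD.
#' @param jitter_translation_max,jitter_rotation_max phantom misalignment
#'   bounds (pixels, degrees).
#' @param n_stain_patches stain patches per section.
#' @param seed master seed; per-heart phantom seeds are derived from it.
#' @param k number of color clusters (fixed-K segmentation).
#' @param tune if `TRUE`, tune K per section over `k_range` instead.
#' @param k_range K search range for tuning.
#' @param n_restarts k-means restarts.
#' @param stain_color RGB triple of the chromogen; its L*a*b* coordinates
#'   are the stain reference for cluster selection.
#' @param replication_factor z-layers per section in the volume.
#' @param translation_max,rotation_max registration search bounds.
#' @param register `NA` (default) registers only when the phantom is
#'   jittered; `TRUE`/`FALSE` force it.
#' @param reconstruct_hearts `"first"`, `"all"`, or `"none"`.
#' @param section_thickness micrometers, for voxel z-spacing.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_hearts = 3L, n_slices = 5L, left_fraction = 0.89,
                       frame_width = 690L, frame_height = 970L,
                       noise_sd = 5, jitter_translation_max = 0,
                       jitter_rotation_max = 0, n_stain_patches = 10L,
                       seed = 1L,
                       k = 6L, tune = FALSE, k_range = c(2L, 8L),
                       n_restarts = 10L, stain_color = c(49, 59, 125),
                       replication_factor = 7L,
                       translation_max = 15, rotation_max = 10,
                       register = NA,
                       reconstruct_hearts = c("first", "all", "none"),
                       section_thickness = 14) {
  reconstruct_hearts <- match.arg(reconstruct_hearts)
  cfg <- list(
    phantom = list(n_hearts = as.integer(n_hearts),
                   n_slices = as.integer(n_slices),
                   left_fraction = left_fraction,
                   frame_width = as.integer(frame_width),
                   frame_height = as.integer(frame_height),
                   noise_sd = noise_sd,
                   jitter_translation_max = jitter_translation_max,
                   jitter_rotation_max = jitter_rotation_max,
                   n_stain_patches = as.integer(n_stain_patches),
                   seed = as.integer(seed)),
    segmentation = list(k = as.integer(k), tune = isTRUE(tune),
                        k_range = as.integer(k_range),
                        n_restarts = as.integer(n_restarts),
                        stain_color = stain_color),
    reconstruction = list(replication_factor = as.integer(replication_factor),
                          translation_max = translation_max,
                          rotation_max = rotation_max,
                          register = register,
                          reconstruct_hearts = reconstruct_hearts,
                          section_thickness = section_thickness))
  if (cfg$phantom$n_hearts < 1 || cfg$phantom$n_slices < 1) {
    stop("need at least one heart and one slice", call. = FALSE)
  }
  if (cfg$phantom$left_fraction < 0 || cfg$phantom$left_fraction > 1) {
    stop("left_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

heart_seed <- function(master, h) as.integer(master + (h - 1L) * 1009L)

log_line <- function(level, stage, msg, log_level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, none = 4)
  if (levels[[level]] >= levels[[log_level]]) {
    message(sprintf("[%s] %s: %s", level, stage, msg))
  }
}

#' Run the full phantom-to-volume pipeline
#'
#' Simulates `n_hearts` serial-section phantoms, segments every section by
#' k-means in L*a*b* space, aligns sections (when the phantom is jittered,
#' or when forced), quantifies left/right stain-positive pixels about the
#' phantom's ground-truth separation line, aggregates per heart, compares
#' sides with a t-test, reconstructs stain volumes, and (optionally) writes
#' all artifacts plus a machine-readable report.
#'
#' @param config a [run_config()].
#' @param outdir output directory; `NULL` runs in memory only.
#' @param log_level `"debug"`, `"info"`, `"warn"`, or `"none"`.
#' @return the run report: a list with `per_slice` (data frame),
#'   `per_heart` (data frame), `group` (group-summary row), `comparison`
#'   ([compare_sides()] result), `volumes` (per-heart metadata), `config`,
#'   and `files` (paths written, if any).
#' @export
run_pipeline <- function(config, outdir = NULL, log_level = "info") {
  stopifnot(inherits(config, "run_config"))
  ph <- config$phantom; sg <- config$segmentation; rc <- config$reconstruction
  stain_ref <- stain_reference_lab(sg$stain_color)
  jittered <- ph$jitter_translation_max > 0 || ph$jitter_rotation_max > 0
  do_register <- if (is.na(rc$register)) jittered else isTRUE(rc$register)
  files <- character(0)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  per_slice <- list(); per_heart <- list(); volumes <- list()
  recon_set <- switch(rc$reconstruct_hearts,
                      first = 1L, all = seq_len(ph$n_hearts), none = integer(0))
  for (h in seq_len(ph$n_hearts)) {
    stage <- sprintf("heart %d", h)
    params <- phantom_params(
      n_slices = ph$n_slices, frame_height = ph$frame_height,
      frame_width = ph$frame_width, left_fraction = ph$left_fraction,
      noise_sd = ph$noise_sd,
      jitter_translation_max = ph$jitter_translation_max,
      jitter_rotation_max = ph$jitter_rotation_max,
      n_stain_patches = ph$n_stain_patches,
      seed = heart_seed(ph$seed, h))
    log_line("info", stage, sprintf("simulating %d slices (seed %d)",
                                    ph$n_slices, params$seed), log_level)
    stack <- generate_stack(params)
    if (!is.null(outdir)) {
      files <- c(files, write_phantom(stack, file.path(outdir, sprintf("heart_%d", h))))
    }
    masks <- vector("list", ph$n_slices)
    for (k in seq_len(ph$n_slices)) {
      sm <- segment_slice(stack$slices[[k]], K = sg$k, tune = sg$tune,
                          k_range = sg$k_range, stain_reference = stain_ref,
                          seed = heart_seed(ph$seed, h) + k,
                          n_restarts = sg$n_restarts)
      log_line("debug", stage, sprintf("slice %d: %d positive pixels",
                                       k, sm$positive_count), log_level)
      masks[[k]] <- sm$mask
      if (!is.null(outdir)) {
        f <- file.path(outdir, sprintf("heart_%d/seg_%03d.png", h, k - 1))
        write_mask_png(sm$mask, f); files <- c(files, f)
      }
    }
    pair_tf <- NULL
    if (do_register && ph$n_slices > 1) {
      log_line("info", stage, "registering sections", log_level)
      al <- align_series(masks, translation_max = rc$translation_max,
                         rotation_max = rc$rotation_max)
      masks <- al$aligned
      pair_tf <- al$pair_transforms
    }
    q <- do.call(rbind, lapply(seq_len(ph$n_slices), function(k) {
      quantify_slice(masks[[k]], stack$truth$line, slice_id = k)
    }))
    q$heart <- h
    per_slice[[h]] <- q
    per_heart[[h]] <- summarize_heart(q, heart_id = sprintf("phantom-%d", h))
    if (h %in% recon_set) {
      vol <- stack_volume(masks, replication_factor = rc$replication_factor,
                          section_thickness = rc$section_thickness)
      meta <- list(heart = h, dims = dim(vol$voxels),
                   n_true = sum(vol$voxels),
                   replication_factor = vol$replication_factor,
                   spacing = vol$spacing)
      if (!is.null(outdir)) {
        mhd <- file.path(outdir, sprintf("heart_%d/volume.mhd", h))
        files <- c(files, write_metaimage(vol, mhd))
        vdir <- file.path(outdir, sprintf("heart_%d/views", h))
        export_orthogonal_views(vol, vdir)
        files <- c(files, file.path(vdir, c("axial.png", "coronal.png", "sagittal.png")))
        if (!is.null(pair_tf)) {
          tfj <- file.path(outdir, sprintf("heart_%d/transforms.json", h))
          jsonlite::write_json(lapply(pair_tf, function(t)
            list(tx = t$tx, ty = t$ty, theta = t$theta)),
            tfj, auto_unbox = TRUE, digits = NA)
          files <- c(files, tfj)
        }
        meta$path <- mhd
      }
      volumes[[length(volumes) + 1]] <- meta
    }
  }
  # record outputs relative to outdir so identical configs give identical
  # reports wherever they are written
  relpath <- function(f) {
    if (is.null(outdir)) return(f)
    sub(paste0(outdir, .Platform$file.sep), "", f, fixed = TRUE)
  }
  files <- relpath(files)
  volumes <- lapply(volumes, function(v) {
    if (!is.null(v$path)) v$path <- relpath(v$path)
    v
  })
  per_slice <- do.call(rbind, per_slice)
  per_heart <- do.call(rbind, per_heart)
  comparison <- if (ph$n_hearts >= 2) {
    compare_sides(per_heart$mean_left, per_heart$mean_right)
  } else NULL
  group <- summarize_group(per_heart)
  report <- list(per_slice = per_slice, per_heart = per_heart, group = group,
                 comparison = comparison, volumes = volumes,
                 config = unclass(config),
                 package_version = as.character(utils::packageVersion("stain3d")),
                 files = files)
  if (!is.null(outdir)) {
    f1 <- file.path(outdir, "per_slice.csv")
    utils::write.csv(per_slice, f1, row.names = FALSE)
    f2 <- file.path(outdir, "per_heart.csv")
    utils::write.csv(per_heart, f2, row.names = FALSE)
    f3 <- file.path(outdir, "comparison.json")
    if (!is.null(comparison)) {
      jsonlite::write_json(list(variant = comparison$variant,
                                t = comparison$t_statistic,
                                df = comparison$degrees_of_freedom,
                                p = comparison$p_value,
                                alpha = comparison$alpha,
                                all_variants = comparison$all_variants),
                           f3, auto_unbox = TRUE, digits = NA)
    }
    report$files <- c(report$files, relpath(c(f1, f2, if (!is.null(comparison)) f3)))
    frep <- file.path(outdir, "report.json")
    jsonlite::write_json(
      list(per_heart = per_heart, group = group,
           comparison = if (!is.null(comparison)) list(
             variant = comparison$variant, t = comparison$t_statistic,
             df = comparison$degrees_of_freedom, p = comparison$p_value) ,
           volumes = volumes, config = unclass(config),
           package_version = report$package_version,
           files = report$files),
      frep, auto_unbox = TRUE, digits = NA)
    report$files <- c(report$files, relpath(frep))
  }
  report
}

#' Replicate a simulated study and collect side-comparison p-values
#'
#' Repeats the simulate-segment-quantify-compare path `n_replicates` times
#' (each with a derived seed) and returns the per-replicate p-value and the
#' recovered mean left percentage. Used for power and null-calibration
#' checks; frame size can be reduced to keep simulation cost proportionate.
#'
#' @param n_replicates number of independent study replicates.
#' @param config a [run_config()]; reconstruction is skipped.
#' @param use_truth_masks if `TRUE`, quantify the phantom's ground-truth
#'   masks directly (no segmentation), isolating the statistical pipeline.
#' @return data frame: `replicate`, `p_value`, `pct_left`.
#' @export
simulate_study <- function(n_replicates, config, use_truth_masks = FALSE) {
  out <- vector("list", n_replicates)
  base_cfg <- unclass(config)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$phantom$seed <- as.integer(base_cfg$phantom$seed + (r - 1L) * 131071L)
    cfg$reconstruction$reconstruct_hearts <- "none"
    if (use_truth_masks) {
      ph <- cfg$phantom
      ph_sum <- vector("list", ph$n_hearts)
      for (h in seq_len(ph$n_hearts)) {
        stack <- generate_stack(phantom_params(
          n_slices = ph$n_slices, frame_height = ph$frame_height,
          frame_width = ph$frame_width, left_fraction = ph$left_fraction,
          noise_sd = ph$noise_sd, n_stain_patches = ph$n_stain_patches,
          seed = heart_seed(ph$seed, h)))
        q <- data.frame(slice = seq_len(ph$n_slices),
                        left = stack$truth$left_counts,
                        right = stack$truth$right_counts)
        ph_sum[[h]] <- summarize_heart(q, heart_id = h)
      }
      ph_sum <- do.call(rbind, ph_sum)
      cmp <- compare_sides(ph_sum$mean_left, ph_sum$mean_right)
      out[[r]] <- data.frame(replicate = r, p_value = cmp$p_value,
                             pct_left = mean(ph_sum$pct_left))
    } else {
      rep_out <- run_pipeline(cfg, outdir = NULL, log_level = "none")
      out[[r]] <- data.frame(replicate = r,
                             p_value = rep_out$comparison$p_value,
                             pct_left = mean(rep_out$per_heart$pct_left))
    }
  }
  do.call(rbind, out)
}
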