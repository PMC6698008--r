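#' Run the analysis pipeline from a configuration
#'
#' Orchestrates the package's stages behind a single entry point. The
#' configuration is a list (or path to a YAML file) with a global `seed`,
#' an `out_dir`, and a list of `steps`, each a list with a `command` and
#' its parameters:
#'
#' * `simulate-slide`: `width`, `height`, `target_fraction`,
#'   `vessel_count`, `size_range`, `noise_sd`, `excluded_fraction`,
#'   `name` — generates a synthetic slide and writes image, masks,
#'   annotations and truth.
#' * `simulate-cohort`: `n_stage2`, `n_stage3`, `censor_rate`,
#'   `true_log_hrs` (named list), `name` — generates a cohort CSV plus
#'   truth JSON.
#' * `mvd`: `image`, `annotations` (paths; default: the previous
#'   simulate-slide outputs), `min_pixels`, `connectivity` — runs the
#'   morphometry pipeline, writes the result JSON and appends a row to
#'   `mvd_results.csv`.
#' * `tsp`: `class_map`, `tissue_mask` (paths; default: previous
#'   simulate-slide outputs), `n_points`, `offset_seed` — point-grid
#'   stereology, writes the result JSON.
#' * `stats`: either `table2x2` (4 counts, row-wise) for a chi-square
#'   test, or `cohort` (CSV path), `marker`, `stage` for per-stage ROC
#'   dichotomization + KM/log-rank/Cox; writes the result JSON.
#' * `report`: collates all step results into `report.json`.
#'
#' Each step's RNG seed is derived from the global seed and the step
#' index, so a rerun with an identical configuration reproduces identical
#' outputs. A `manifest.json` with the seed, configuration hash and
#' package version is written alongside the outputs.
#'
#' @param config list or YAML file path.
#' @return named list of step results, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("seed", "out_dir", "steps"))
    if (is.null(config[[f]])) stop("invalid config: missing field '", f, "'")
  seed <- as.integer(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  results <- list()
  last_slide_files <- NULL

  for (i in seq_along(config$steps)) {
    step <- config$steps[[i]]
    cmd <- step$command
    if (is.null(cmd)) stop("invalid config: step ", i, " has no 'command'")
    step_seed <- seed + i
    res <- switch(cmd,
      "simulate-slide" = {
        nm <- step$name %||% sprintf("slide%02d", i)
        spec <- slide_spec(
          width_px = step$width %||% 1000,
          height_px = step$height %||% 1000,
          target_positive_fraction = step$target_fraction %||% 0.05,
          vessel_count = step$vessel_count %||% 50,
          vessel_size_range_px = unlist(step$size_range %||% c(100, 2000)),
          noise_sd = step$noise_sd %||% 8,
          excluded_fraction = step$excluded_fraction %||% 0,
          seed = step_seed)
        slide <- generate_slide(spec)
        last_slide_files <- write_slide(slide, out, nm)
        list(files = as.list(last_slide_files),
             truth_positive_fraction = slide$truth$positive_fraction)
      },
      "simulate-cohort" = {
        nm <- step$name %||% sprintf("cohort%02d", i)
        spec <- cohort_spec(
          n_stage2 = step$n_stage2 %||% 53,
          n_stage3 = step$n_stage3 %||% 54,
          true_log_hrs = unlist(step$true_log_hrs %||% list()),
          censor_rate = step$censor_rate %||% 0.3,
          seed = step_seed)
        gen <- generate_cohort(spec)
        csv <- file.path(out, paste0(nm, ".csv"))
        write_cohort(gen$cohort, csv)
        jsonlite::write_json(gen$truth, file.path(out, paste0(nm, "_truth.json")),
                             auto_unbox = TRUE, digits = NA)
        list(files = list(cohort = csv), n = nrow(gen$cohort))
      },
      "mvd" = {
        img <- step$image %||% last_slide_files[["image"]]
        ann <- step$annotations %||% last_slide_files[["annotations"]]
        if (is.null(img) || is.null(ann))
          stop("mvd step: no image/annotations given and no prior simulate-slide step")
        slide <- read_annotated_slide(img, ann)
        r <- quantify_slide(slide,
                            min_pixels = step$min_pixels %||% 100,
                            connectivity = step$connectivity %||% 8)
        jp <- file.path(out, sprintf("mvd_step%02d.json", i))
        jsonlite::write_json(unclass(r), jp, auto_unbox = TRUE, digits = NA)
        row <- data.frame(image = img, mvd_percent = r$mvd_percent,
                          n_components = r$n_components,
                          positive_pixels = r$positive_pixels,
                          analysed_pixels = r$analysed_pixels)
        csv <- file.path(out, "mvd_results.csv")
        write.table(row, csv, sep = ",", row.names = FALSE,
                    col.names = !file.exists(csv), append = file.exists(csv))
        unclass(r)
      },
      "tsp" = {
        cmp <- step$class_map %||% last_slide_files[["class_map"]]
        msk <- step$tissue_mask %||% last_slide_files[["tissue_mask"]]
        if (is.null(cmp) || is.null(msk))
          stop("tsp step: no class_map/tissue_mask given and no prior simulate-slide step")
        class_map <- read_class_map(cmp)
        mask <- read_class_map(msk) > 0
        grid <- generate_grid(mask, n_points = step$n_points %||% 400,
                              offset_seed = step$offset_seed %||% step_seed)
        r <- compute_tsp(classify_points(grid, class_map = class_map))
        jsonlite::write_json(unclass(r),
                             file.path(out, sprintf("tsp_step%02d.json", i)),
                             auto_unbox = TRUE, digits = NA)
        unclass(r)
      },
      "stats" = {
        r <- if (!is.null(step$table2x2)) {
          counts <- as.integer(unlist(step$table2x2))
          if (length(counts) != 4) stop("stats step: table2x2 needs 4 counts")
          unclass(pearson_chi2(matrix(counts, 2, byrow = TRUE)))
        } else if (!is.null(step$cohort)) {
          cohort <- read_cohort(step$cohort)
          if (!is.null(step$stage))
            cohort <- cohort[cohort$stage == step$stage, , drop = FALSE]
          marker <- step$marker %||% "mvd_percent"
          cut <- dichotomize_roc(cohort[[marker]], cohort$dfs_event)
          grp <- factor(ifelse(cohort[[marker]] > cut$cutoff, "high", "low"),
                        levels = c("low", "high"))
          sfit <- km_logrank(cohort$dfs_months, cohort$dfs_event, grp)
          list(marker = marker, stage = step$stage %||% "all",
               cutoff = cut$cutoff, youden_j = cut$youden_j,
               hr = sfit$hr, ci_low = sfit$ci_low, ci_high = sfit$ci_high,
               logrank_p = sfit$logrank_p)
        } else stop("stats step: give either table2x2 or cohort")
        jsonlite::write_json(r, file.path(out, sprintf("stats_step%02d.json", i)),
                             auto_unbox = TRUE, digits = NA)
        r
      },
      "report" = {
        jsonlite::write_json(results, file.path(out, "report.json"),
                             auto_unbox = TRUE, digits = NA)
        list(file = file.path(out, "report.json"))
      },
      stop("invalid config: unknown command '", cmd, "' in step ", i))
    results[[sprintf("step%02d_%s", i, cmd)]] <- res
  }

  manifest <- list(seed = seed,
                   config_file = cfg_path,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package = "mvdmorph",
                   package_version = as.character(utils::packageVersion("mvdmorph")),
                   r_version = R.version.string,
                   steps = names(results))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
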