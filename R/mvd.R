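#' Stain classifier configuration
#'
#' Parameters of the rule that decides whether a pixel carries DAB chromogen
#' (brown, CD31-positive endothelium) rather than haematoxylin/eosin
#' counterstain. Two modes are available:
#'
#' * `"rgb_rule"`: a pixel is positive when `R >= min_red`, `B <= max_blue`,
#'   `R - B >= min_red_minus_blue` and `R - G >= min_red_minus_green`.
#'   Brown has a strong red excess over blue; counterstains (blue-purple
#'   haematoxylin, pink eosin) fail the blue ceiling or the red-excess tests.
#' * `"stain_deconvolution"`: channel optical densities are projected onto a
#'   unit DAB stain vector (Ruifrok-Johnston colour deconvolution); a pixel
#'   is positive when the DAB density reaches `od_threshold`. The projection
#'   does not remove haematoxylin cross-talk, so the default threshold sits
#'   well above the counterstain's projected density.
#'
#' The defaults are calibrated on the synthetic slides produced by
#' [generate_slide()]; when the constants of a particular scanner/stain
#' combination are known they can be dropped in directly.
#'
#' @param mode `"rgb_rule"` or `"stain_deconvolution"`.
#' @param min_red,max_blue,min_red_minus_blue,min_red_minus_green integer
#'   thresholds in 0..255 for the RGB rule.
#' @param dab_vector length-3 optical-density stain vector for DAB.
#' @param od_threshold positive optical-density threshold.
#' @return an object of class `stain_config`.
#' @export
stain_config <- function(mode = c("rgb_rule", "stain_deconvolution"),
                         min_red = 60, max_blue = 120,
                         min_red_minus_blue = 30, min_red_minus_green = 10,
                         dab_vector = c(0.268, 0.570, 0.776),
                         od_threshold = 0.6) {
  mode <- match.arg(mode)
  thr <- c(min_red, max_blue, min_red_minus_blue, min_red_minus_green)
  if (any(thr < -255 | thr > 255)) stop("RGB thresholds must lie in [-255, 255]")
  if (od_threshold <= 0) stop("od_threshold must be positive")
  structure(list(mode = mode, min_red = min_red, max_blue = max_blue,
                 min_red_minus_blue = min_red_minus_blue,
                 min_red_minus_green = min_red_minus_green,
                 dab_vector = dab_vector / sqrt(sum(dab_vector^2)),
                 od_threshold = od_threshold),
            class = "stain_config")
}

#' Classify chromogen-positive pixels
#'
#' Applies the stain rule to every pixel inside the analysis mask. Pixels
#' outside the mask are never positive. A pure function of the pixel values
#' and the configuration; an all-negative result is valid.
#'
#' @param slide an [annotated_slide()].
#' @param mask logical analysis mask from [rasterize_annotation()].
#' @param config a [stain_config()].
#' @return logical matrix, `TRUE` for positive pixels (subset of `mask`).
#' @export
classify_positive_pixels <- function(slide, mask, config = stain_config()) {
  stopifnot(inherits(slide, "annotated_slide"), inherits(config, "stain_config"))
  d <- dim(slide$image)
  if (!identical(dim(mask), d[1:2])) stop("mask shape does not match image")
  R <- slide$image[, , 1]; G <- slide$image[, , 2]; B <- slide$image[, , 3]
  if (config$mode == "rgb_rule") {
    pos <- (R >= config$min_red) & (B <= config$max_blue) &
      ((R - B) >= config$min_red_minus_blue) &
      ((R - G) >= config$min_red_minus_green)
  } else {
    od <- function(ch) -log10((ch + 1) / 256)
    dab <- od(R) * config$dab_vector[1] + od(G) * config$dab_vector[2] +
      od(B) * config$dab_vector[3]
    pos <- dab >= config$od_threshold
  }
  pos & mask
}

#' Label connected positive-pixel clusters
#'
#' Groups positive pixels into maximal connected components ("clustered"
#' pixels, the candidate microvessels) under 4- or 8-connectivity.
#'
#' @param mask logical matrix of positive pixels.
#' @param connectivity 4 or 8 (default 8, the usual particle-analysis rule).
#' @return an object of class `component_set`: `label_map` (integer matrix,
#'   0 = background, k = component k), `sizes` (pixel count per label),
#'   `connectivity`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- label_components_cpp(mask, connectivity)
  n <- max(lab)
  sizes <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  structure(list(label_map = lab, sizes = sizes, connectivity = connectivity),
            class = "component_set")
}

#' Apply the minimum microvessel size filter
#'
#' Removes components smaller than `min_pixels` from the label map entirely:
#' they contribute neither to the positive-pixel numerator nor to the
#' component count. Components with exactly `min_pixels` pixels are retained
#' (a minimum size of one hundred positive pixels keeps 100-pixel clusters).
#' Remaining labels are renumbered contiguously from 1.
#'
#' @param components a `component_set` from [label_components()].
#' @param min_pixels minimum retained component size in pixels (default 100).
#' @return a filtered `component_set`.
#' @export
filter_components <- function(components, min_pixels = 100) {
  stopifnot(inherits(components, "component_set"), min_pixels >= 1)
  keep <- which(components$sizes >= min_pixels)
  if (length(keep) == length(components$sizes)) return(components)
  remap <- integer(length(components$sizes) + 1L) # index 1 = background
  remap[keep + 1L] <- seq_along(keep)
  lab <- matrix(remap[components$label_map + 1L],
                nrow = nrow(components$label_map))
  structure(list(label_map = lab,
                 sizes = components$sizes[keep],
                 connectivity = components$connectivity),
            class = "component_set")
}

#' Compute microvessel density from retained components
#'
#' MVD is the total percentage of CD31-positive clustered pixels over the
#' tissue area analysed:
#' `mvd_percent = 100 * sum(component sizes) / analysed_pixels`.
#'
#' @param filtered a size-filtered `component_set`.
#' @param analysed_pixels number of analysable tissue pixels (mask size).
#' @param min_component_px the size threshold that was applied (recorded in
#'   the result for provenance).
#' @return an object of class `mvd_result` with fields `mvd_percent`,
#'   `n_components`, `positive_pixels`, `analysed_pixels`,
#'   `min_component_px`.
#' @export
compute_mvd <- function(filtered, analysed_pixels, min_component_px = 100) {
  stopifnot(inherits(filtered, "component_set"))
  if (analysed_pixels < 1) stop("analysed_pixels must be >= 1")
  pos <- sum(filtered$sizes)
  if (pos > analysed_pixels)
    stop("positive pixels exceed analysed pixels; inconsistent inputs")
  structure(list(mvd_percent = 100 * pos / analysed_pixels,
                 n_components = length(filtered$sizes),
                 positive_pixels = as.integer(pos),
                 analysed_pixels = as.integer(analysed_pixels),
                 min_component_px = as.integer(min_component_px)),
            class = "mvd_result")
}

#' @export
print.mvd_result <- function(x, ...) {
  cat(sprintf("MVD: %.3f%% (%d positive px in %d components / %d analysed px; min size %d px)\n",
              x$mvd_percent, x$positive_pixels, x$n_components,
              x$analysed_pixels, x$min_component_px))
  invisible(x)
}

#' Quantify microvessel density on an annotated slide
#'
#' Full morphometric pipeline: rasterize the delineation (include minus
#' exclude), classify chromogen-positive pixels, label connected clusters,
#' drop clusters below the minimum microvessel size, and report the percent
#' positive area. Deterministic.
#'
#' @inheritParams classify_positive_pixels
#' @inheritParams filter_components
#' @inheritParams label_components
#' @return an `mvd_result`.
#' @export
quantify_slide <- function(slide, config = stain_config(), min_pixels = 100,
                           connectivity = 8) {
  mask <- rasterize_annotation(slide)
  pos <- classify_positive_pixels(slide, mask, config)
  comp <- label_components(pos, connectivity)
  comp <- filter_components(comp, min_pixels)
  compute_mvd(comp, sum(mask), min_component_px = min_pixels)
}
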