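#' Synthetic slide specification
#'
#' Describes a synthetic CD31-stained section: a tissue region, a target
#' chromogen-positive area fraction realized by vessel-like objects
#' (ellipses and lumen-bearing annuli with jittered boundaries), an
#' epithelium/stroma background with haematoxylin/eosin-like colours, and
#' additive Gaussian channel noise. Every generated slide carries exact
#' pixel-level ground truth, so the morphometry pipeline can be validated
#' against known answers.
#'
#' The first `vessel_count - 1` vessel areas are drawn adaptively from
#' `vessel_size_range_px`; the last vessel's area is set to whatever remains
#' of the positive-pixel budget (and is not constrained to the range), so
#' the realized positive fraction lands within 0.5 percentage points of
#' `target_positive_fraction`.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel size (default 0.23, a 20x scan).
#' @param tissue_polygon polygon (n x 2, 0-based pixel coordinates)
#'   delineating tissue; default is the full frame.
#' @param target_positive_fraction target fraction of analysed tissue pixels
#'   covered by vessel objects, in `[0, 1]`.
#' @param vessel_count number of vessels to place.
#' @param vessel_size_range_px `c(min, max)` vessel areas in pixels.
#' @param positive_color RGB triple for the DAB-brown chromogen.
#' @param background_colors named list with RGB triples `epithelium`,
#'   `stroma`, `lumen`.
#' @param noise_sd Gaussian noise standard deviation per channel (0..255
#'   scale).
#' @param excluded_fraction fraction of tissue to mark as damaged/excluded,
#'   in `[0, 1)`.
#' @param stroma_target approximate stroma share of informative tissue,
#'   realized as a blocky random epithelium/stroma mosaic.
#' @param shapes vessel shape set to sample from.
#' @param seed integer RNG seed; the whole slide is a deterministic function
#'   of the spec.
#' @return an object of class `slide_spec`.
#' @export
slide_spec <- function(width_px, height_px, pixel_size_um = 0.23,
                       tissue_polygon = NULL,
                       target_positive_fraction = 0.05,
                       vessel_count = 50,
                       vessel_size_range_px = c(100, 2000),
                       positive_color = c(120, 80, 50),
                       background_colors = list(epithelium = c(160, 130, 185),
                                                stroma = c(235, 185, 195),
                                                lumen = c(245, 245, 245)),
                       noise_sd = 8, excluded_fraction = 0,
                       stroma_target = 0.5,
                       shapes = c("ellipse", "annulus"),
                       seed = 1) {
  stopifnot(width_px >= 8, height_px >= 8, pixel_size_um > 0,
            target_positive_fraction >= 0, target_positive_fraction <= 1,
            vessel_count >= 0, noise_sd >= 0,
            excluded_fraction >= 0, excluded_fraction < 1,
            stroma_target > 0, stroma_target < 1)
  if (is.null(tissue_polygon))
    tissue_polygon <- poly_rect(0, 0, width_px, height_px)
  if (length(vessel_size_range_px) != 2 || any(vessel_size_range_px < 1) ||
      vessel_size_range_px[1] > vessel_size_range_px[2])
    stop("vessel_size_range_px must be c(min, max) with 1 <= min <= max")
  cols <- c(positive_color, unlist(background_colors))
  if (any(cols < 0 | cols > 255)) stop("RGB components must lie in [0, 255]")
  shapes <- match.arg(shapes, c("ellipse", "annulus"), several.ok = TRUE)

  # achievability of the target given vessel count and size range
  tissue_px <- abs(polygon_area(tissue_polygon))
  target_px <- target_positive_fraction * tissue_px
  if (target_positive_fraction == 0 && vessel_count > 0)
    stop("unachievable target: vessel_count > 0 requires target_positive_fraction > 0")
  if (target_positive_fraction > 0 && vessel_count == 0)
    stop("unachievable target: target_positive_fraction > 0 requires vessel_count > 0")
  if (vessel_count > 1 && (vessel_count - 1) * vessel_size_range_px[1] > target_px)
    stop(sprintf(paste0("unachievable target: (vessel_count - 1) * min size = %d px ",
                        "exceeds the target positive area of %.0f px"),
                 (vessel_count - 1L) * as.integer(vessel_size_range_px[1]), target_px))
  if (target_px > 0.85 * tissue_px)
    stop("unachievable target: target positive area exceeds 85% of the tissue area")

  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 tissue_polygon = tissue_polygon,
                 target_positive_fraction = target_positive_fraction,
                 vessel_count = as.integer(vessel_count),
                 vessel_size_range_px = as.integer(vessel_size_range_px),
                 positive_color = positive_color,
                 background_colors = background_colors,
                 noise_sd = noise_sd,
                 excluded_fraction = excluded_fraction,
                 stroma_target = stroma_target,
                 shapes = shapes,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

# shoelace area of a polygon (pixel^2 units)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# pixel linear indices of a (possibly annular) jittered ellipse
ellipse_pixels <- function(cx, cy, a, b, theta, h, w,
                           inner_ratio = 0, jitter = 0.1,
                           jfreq = 5, jphase = 0) {
  rmax <- max(a, b) * (1 + jitter) + 1
  r0 <- max(1L, floor(cy - rmax) + 1L); r1 <- min(h, ceiling(cy + rmax) + 1L)
  c0 <- max(1L, floor(cx - rmax) + 1L); c1 <- min(w, ceiling(cx + rmax) + 1L)
  if (r0 > r1 || c0 > c1) return(list(ring = integer(0), lumen = integer(0)))
  rows <- r0:r1; cols <- c0:c1
  dy <- (rows - 0.5) - cy
  dx <- (cols - 0.5) - cx
  DX <- matrix(dx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  DY <- matrix(dy, nrow = length(rows), ncol = length(cols))
  u <- (DX * cos(theta) + DY * sin(theta)) / a
  v <- (-DX * sin(theta) + DY * cos(theta)) / b
  rr <- u * u + v * v
  thr <- (1 + jitter * sin(jfreq * atan2(v, u) + jphase))^2
  outer_in <- rr <= thr
  lumen_in <- if (inner_ratio > 0) rr <= (inner_ratio^2) else
    matrix(FALSE, nrow(rr), ncol(rr))
  ring <- outer_in & !lumen_in
  ridx <- which(ring); lidx <- which(lumen_in)
  # translate to full-image linear indices (column-major)
  to_full <- function(idx) {
    if (!length(idx)) return(integer(0))
    rr_ <- ((idx - 1L) %% length(rows)) + 1L
    cc_ <- ((idx - 1L) %/% length(rows)) + 1L
    (cols[cc_] - 1L) * h + rows[rr_]
  }
  list(ring = to_full(ridx), lumen = to_full(lidx))
}

# blocky epithelium/stroma/lumen mosaic; 1 = epithelium, 2 = stroma, 3 = other
make_class_map <- function(h, w, stroma_target, block = 64L) {
  nbr <- ceiling(h / block); nbc <- ceiling(w / block)
  u <- runif(nbr * nbc)
  blk <- matrix(1L, nbr, nbc)
  blk[u < stroma_target] <- 2L
  blk[u > 1 - 0.04] <- 3L # occasional lumen/mucus blocks
  ridx <- pmin(nbr, ((seq_len(h) - 1L) %/% block) + 1L)
  cidx <- pmin(nbc, ((seq_len(w) - 1L) %/% block) + 1L)
  blk[ridx, cidx, drop = FALSE]
}

#' Generate a synthetic CD31-stained slide
#'
#' Renders the slide described by a [slide_spec()]: an epithelium/stroma
#' mosaic background, vessel objects painted in chromogen brown, per-channel
#' Gaussian noise, and exact ground-truth masks. Deterministic given the
#' spec's seed. The realized positive fraction is within 0.5 percentage
#' points of the target.
#'
#' @param spec a [slide_spec()].
#' @return an object of class `synthetic_slide` with fields `image`
#'   (integer `h x w x 3`, 0..255), `tissue_mask`, `excluded_mask`,
#'   `vessel_label_map`, `class_map` (1 = epithelium, 2 = stroma,
#'   3 = other), `truth` (see [recount_truth()]), `tissue_polygon`,
#'   `exclude_polygons`, `pixel_size_um`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px
  tissue <- rasterize_polygon(spec$tissue_polygon, w, h)
  if (!any(tissue)) stop("tissue polygon rasterizes to an empty mask")
  tissue_idx <- which(tissue)
  n_tissue <- length(tissue_idx)

  class_map <- make_class_map(h, w, spec$stroma_target)
  class_map[!tissue] <- 3L

  label <- matrix(0L, h, w)
  lumen_extra <- integer(0)
  target_px <- round(spec$target_positive_fraction * n_tissue)
  painted <- 0L
  counts <- integer(0)
  k <- 0L
  fails <- 0L
  smin <- spec$vessel_size_range_px[1]; smax <- spec$vessel_size_range_px[2]
  while (painted < target_px) {
    k <- k + 1L
    remaining <- target_px - painted
    n_left <- spec$vessel_count - k + 1L
    s <- if (k < spec$vessel_count) {
      min(max(smin, min(smax, round(runif(1, 0.6, 1.4) * remaining / n_left))),
          remaining)
    } else remaining # last (or topping-up) vessel: unconstrained size
    if (s < 4) s <- 4
    shape <- sample(spec$shapes, 1)
    inner <- if (shape == "annulus") runif(1, 0.45, 0.65) else 0
    q <- runif(1, 0.5, 1)
    area_scale <- pi * q * (1 - inner^2)
    a <- sqrt(s / area_scale); b <- q * a
    theta <- runif(1, 0, pi)
    jphase <- runif(1, 0, 2 * pi)
    placed <- NULL
    for (try in 1:40) {
      ctr <- tissue_idx[sample.int(n_tissue, 1)]
      cy <- ((ctr - 1L) %% h) + 0.5
      cx <- ((ctr - 1L) %/% h) + 0.5
      px <- ellipse_pixels(cx, cy, a, b, theta, h, w,
                           inner_ratio = inner, jphase = jphase)
      if (!length(px$ring)) next
      if (all(tissue[px$ring]) && all(label[px$ring] == 0L)) { placed <- px; break }
      if (try == 40) placed <- px # accept clipped/overlapping placement
    }
    ring <- placed$ring[tissue[placed$ring] & label[placed$ring] == 0L]
    # a vessel must realize at least the spec's minimum size; clipped or
    # overlapped placements below it are rejected and redrawn elsewhere
    if (length(ring) < min(s, smin) && fails < 400L) {
      fails <- fails + 1L
      k <- k - 1L
      next
    }
    if (length(ring)) {
      label[ring] <- k
      counts <- c(counts, length(ring))
      painted <- painted + length(ring)
    } else {
      k <- k - 1L # nothing painted; retry with a fresh draw
    }
    lum <- placed$lumen[tissue[placed$lumen] & label[placed$lumen] == 0L]
    lumen_extra <- c(lumen_extra, lum)
    if (k >= spec$vessel_count && (target_px - painted) <= max(4, 0.001 * n_tissue))
      break
    if (k > spec$vessel_count + 50L) break # safety: budget nearly met anyway
  }
  if (length(lumen_extra)) class_map[lumen_extra] <- 3L
  class_map[label > 0L] <- 3L

  # render: background mosaic colours, vessels in chromogen brown, noise
  image <- array(0L, dim = c(h, w, 3))
  bg <- list(spec$background_colors$epithelium,
             spec$background_colors$stroma,
             spec$background_colors$lumen)
  npx <- h * w
  for (ch in 1:3) {
    plane <- matrix(bg[[3]][ch], h, w)
    plane[class_map == 1L] <- bg[[1]][ch]
    plane[class_map == 2L] <- bg[[2]][ch]
    plane[label > 0L] <- spec$positive_color[ch]
    if (spec$noise_sd > 0)
      plane <- plane + rnorm(npx, 0, spec$noise_sd)
    image[, , ch] <- pmin(pmax(round(plane), 0), 255)
  }
  storage.mode(image) <- "integer"

  slide <- structure(list(image = image,
                          tissue_mask = tissue,
                          excluded_mask = matrix(FALSE, h, w),
                          vessel_label_map = label,
                          class_map = class_map,
                          truth = NULL,
                          tissue_polygon = spec$tissue_polygon,
                          exclude_polygons = list(),
                          pixel_size_um = spec$pixel_size_um,
                          spec = spec),
                     class = "synthetic_slide")
  slide$truth <- recount_truth(slide)
  if (spec$excluded_fraction > 0)
    slide <- inject_excluded_regions(slide, spec$excluded_fraction,
                                     seed = spec$seed + 1L)
  slide
}

#' Recompute ground truth by brute-force pixel count
#'
#' Recounts the ground-truth quantities of a synthetic slide directly on its
#' arrays, over the analysed region (tissue minus exclusions):
#' `positive_fraction` (vessel pixels / analysed pixels),
#' `vessel_pixel_counts` (per-vessel analysed pixel counts, empty vessels
#' dropped) and `stroma_fraction` (stroma / (stroma + epithelium)).
#'
#' @param slide a `synthetic_slide`.
#' @return a list with the fields above.
#' @export
recount_truth <- function(slide) {
  stopifnot(inherits(slide, "synthetic_slide"))
  analysed <- slide$tissue_mask & !slide$excluded_mask
  n_an <- sum(analysed)
  lab <- slide$vessel_label_map[analysed]
  cm <- slide$class_map[analysed]
  counts <- if (any(lab > 0L)) tabulate(lab[lab > 0L]) else integer(0)
  counts <- counts[counts > 0L]
  ns <- sum(cm == 2L); ne <- sum(cm == 1L)
  list(positive_fraction = if (n_an > 0) sum(lab > 0L) / n_an else 0,
       vessel_pixel_counts = counts,
       stroma_fraction = if (ns + ne > 0) ns / (ns + ne) else NA_real_,
       analysed_pixels = n_an)
}

#' Inject excluded (damaged) regions into a synthetic slide
#'
#' Marks approximately `fraction` of the tissue as damaged/absent by placing
#' random axis-aligned rectangles, mimicking the digital exclusion of
#' damaged parts from delineated tumours. Exclusion rectangles are also
#' recorded as polygons so the slide can round-trip through annotation
#' files. Ground truth is recomputed over the reduced denominator.
#'
#' @param slide a `synthetic_slide`.
#' @param fraction fraction of tissue pixels to exclude, in `[0, 1)`.
#' @param seed RNG seed for rectangle placement.
#' @return the modified `synthetic_slide`.
#' @export
inject_excluded_regions <- function(slide, fraction, seed = 1) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  if (fraction == 0) return(slide)
  set.seed(as.integer(seed))
  h <- nrow(slide$tissue_mask); w <- ncol(slide$tissue_mask)
  n_tissue <- sum(slide$tissue_mask)
  target <- fraction * n_tissue
  side <- max(4, round(sqrt(0.01 * n_tissue))) # ~1% of tissue per rectangle
  excl <- slide$excluded_mask
  polys <- slide$exclude_polygons
  guard <- 0L
  while (sum(excl & slide$tissue_mask) < target && guard < 10000L) {
    guard <- guard + 1L
    x0 <- runif(1, 0, w - side); y0 <- runif(1, 0, h - side)
    p <- poly_rect(x0, y0, x0 + side, y0 + side)
    m <- rasterize_polygon(p, w, h)
    if (!any(m & slide$tissue_mask & !excl)) next
    excl <- excl | m
    polys <- c(polys, list(p))
  }
  slide$excluded_mask <- excl & slide$tissue_mask
  slide$exclude_polygons <- polys
  slide$truth <- recount_truth(slide)
  slide
}

#' Convert a synthetic slide to an annotated slide
#'
#' Packages a generated slide's image together with its tissue polygon and
#' exclusion polygons, in the form consumed by the morphometry pipeline.
#'
#' @param slide a `synthetic_slide`.
#' @return an [annotated_slide()].
#' @export
as_annotated_slide <- function(slide) {
  stopifnot(inherits(slide, "synthetic_slide"))
  annotated_slide(slide$image, list(slide$tissue_polygon),
                  slide$exclude_polygons, slide$pixel_size_um)
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("Synthetic slide %d x %d px: %d vessels, positive fraction %.4f, stroma fraction %.3f, %.1f%% excluded\n",
              ncol(x$tissue_mask), nrow(x$tissue_mask),
              length(x$truth$vessel_pixel_counts), x$truth$positive_fraction,
              x$truth$stroma_fraction,
              100 * sum(x$excluded_mask) / max(1, sum(x$tissue_mask))))
  invisible(x)
}
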