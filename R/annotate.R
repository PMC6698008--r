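#' Annotated slide
#'
#' Bundle an RGB image with the tumour-delineation polygons and the polygons
#' marking damaged or tissue-free regions that must be excluded from analysis.
#'
#' Coordinates are 0-based pixel coordinates: the pixel in row `r`, column `c`
#' of the image (1-based R indices) spans `[c-1, c] x [r-1, r]` and has its
#' center at `(c - 0.5, r - 0.5)`. Polygons may extend beyond the image; they
#' are clipped during rasterization.
#'
#' @param image integer array `h x w x 3`, channel values in 0..255.
#' @param include_polygons list of `n x 2` matrices (x, y) delineating
#'   representative tumour tissue. A single matrix is accepted.
#' @param exclude_polygons list of polygons marking damaged/absent tissue,
#'   digitally excluded from analysis. May be empty.
#' @param pixel_size_um physical pixel edge length in micrometres. The
#'   default 0.23 corresponds to a 20x whole-slide scan.
#' @return an object of class `annotated_slide`.
#' @export
annotated_slide <- function(image, include_polygons, exclude_polygons = list(),
                            pixel_size_um = 0.23) {
  if (is.matrix(include_polygons)) include_polygons <- list(include_polygons)
  if (is.matrix(exclude_polygons)) exclude_polygons <- list(exclude_polygons)
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            length(include_polygons) >= 1, pixel_size_um > 0)
  for (p in c(include_polygons, exclude_polygons)) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      stop("polygons must be n x 2 matrices with at least 3 vertices")
  }
  structure(list(image = image,
                 include_polygons = include_polygons,
                 exclude_polygons = exclude_polygons,
                 pixel_size_um = pixel_size_um),
            class = "annotated_slide")
}

#' @export
print.annotated_slide <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Annotated slide: %d x %d px (%.3g um/px), %d include / %d exclude polygon(s)\n",
              d[2], d[1], x$pixel_size_um,
              length(x$include_polygons), length(x$exclude_polygons)))
  invisible(x)
}

# Scanline rasterization of one polygon under the even-odd rule.
# A pixel belongs to the polygon iff its center lies inside.
rasterize_polygon <- function(poly, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  nonhoriz <- y1 != y2
  if (!any(nonhoriz)) return(mask)
  x1 <- x1[nonhoriz]; y1 <- y1[nonhoriz]
  x2 <- x2[nonhoriz]; y2 <- y2[nonhoriz]
  rlo <- max(1L, floor(min(y1, y2) + 0.5) + 1L)
  rhi <- min(height, ceiling(max(y1, y2) + 0.5))
  if (rlo > rhi) return(mask)
  for (r in rlo:rhi) {
    yc <- r - 0.5
    # half-open span convention so shared vertices are counted once
    hit <- (y1 <= yc & yc < y2) | (y2 <= yc & yc < y1)
    if (!any(hit)) next
    xi <- sort(x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      # pixel centers strictly between successive crossings are interior
      clo <- max(1L, floor(xi[k] + 0.5) + 1L)
      chi <- min(width, ceiling(xi[k + 1L] - 0.5) + 1L - 1L)
      if (clo <= chi) mask[r, clo:chi] <- TRUE
    }
  }
  mask
}

#' Rasterize slide annotations into an analysis mask
#'
#' Builds the boolean mask of analysable tissue: the union of the include
#' polygons minus the union of the exclude polygons. Each polygon is filled
#' under the even-odd rule; a pixel counts as inside when its center lies
#' inside the polygon.
#'
#' @param slide an [annotated_slide()].
#' @return logical matrix with the image's height x width.
#' @export
rasterize_annotation <- function(slide) {
  stopifnot(inherits(slide, "annotated_slide"))
  h <- dim(slide$image)[1]; w <- dim(slide$image)[2]
  mask <- matrix(FALSE, h, w)
  for (p in slide$include_polygons) mask <- mask | rasterize_polygon(p, w, h)
  for (p in slide$exclude_polygons) mask <- mask & !rasterize_polygon(p, w, h)
  if (!any(mask)) stop("no analysable tissue: analysis mask is empty")
  mask
}

#' Axis-aligned rectangle polygon
#'
#' Convenience constructor for a rectangular annotation polygon in 0-based
#' pixel coordinates, covering `[x0, x1] x [y0, y1]`.
#'
#' @param x0,y0,x1,y1 rectangle corners.
#' @return a 4 x 2 polygon matrix.
#' @export
poly_rect <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
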