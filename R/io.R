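#' Read an RGB slide image
#'
#' Reads a TIFF or PNG raster into the integer `h x w x 3` (0..255)
#' representation used throughout the package. Grayscale images are
#' expanded to three channels; an alpha channel is dropped.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @return integer array `h x w x 3`.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  storage.mode(img) <- "double"
  array(as.integer(round(img * 255)), dim = dim(img))
}

#' Write slide annotations as GeoJSON
#'
#' Polygons are written as a GeoJSON FeatureCollection in pixel
#' coordinates, with a `role` property of `"include"` or `"exclude"`.
#'
#' @param include_polygons,exclude_polygons lists of `n x 2` polygon
#'   matrices.
#' @param path output path.
#' @export
write_annotations_geojson <- function(include_polygons, exclude_polygons,
                                      path) {
  feat <- function(poly, role) {
    ring <- rbind(poly, poly[1, , drop = FALSE]) # closed ring
    list(type = "Feature",
         properties = list(role = role),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))))
  }
  fc <- list(type = "FeatureCollection",
             features = c(lapply(include_polygons, feat, role = "include"),
                          lapply(exclude_polygons, feat, role = "exclude")))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read slide annotations from GeoJSON
#'
#' @param path GeoJSON file written by [write_annotations_geojson()] (or
#'   any FeatureCollection of Polygon features with a `role` property;
#'   features without a role are treated as include).
#' @return list with `include_polygons` and `exclude_polygons`.
#' @export
read_annotations_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  inc <- list(); exc <- list()
  for (f in fc$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p)[1:2])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    role <- f$properties$role
    if (!is.null(role) && identical(role, "exclude")) exc <- c(exc, list(m))
    else inc <- c(inc, list(m))
  }
  list(include_polygons = inc, exclude_polygons = exc)
}

#' Write a synthetic slide and its ground truth to disk
#'
#' Writes the RGB image as deflate-compressed TIFF, the tissue/excluded
#' masks and class map as single-channel PNGs, the annotations as GeoJSON
#' polygons, and the ground truth as JSON.
#'
#' @param slide a `synthetic_slide`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return named character vector of written paths, invisibly.
#' @export
write_slide <- function(slide, dir, name = "slide") {
  stopifnot(inherits(slide, "synthetic_slide"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(dir, paste0(name, suffix))
  tiff::writeTIFF(slide$image / 255, p(".tiff"), compression = "deflate")
  png::writePNG(slide$tissue_mask * 1, p("_tissue_mask.png"))
  png::writePNG(slide$excluded_mask * 1, p("_excluded_mask.png"))
  png::writePNG(slide$class_map / 255, p("_class_map.png"))
  write_annotations_geojson(list(slide$tissue_polygon),
                            slide$exclude_polygons, p("_annotations.geojson"))
  jsonlite::write_json(slide$truth, p("_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(image = p(".tiff"), tissue_mask = p("_tissue_mask.png"),
              excluded_mask = p("_excluded_mask.png"),
              class_map = p("_class_map.png"),
              annotations = p("_annotations.geojson"),
              truth = p("_truth.json")))
}

#' Read an annotated slide from image + GeoJSON annotation files
#'
#' @param image_path TIFF/PNG image.
#' @param annotations_path GeoJSON annotation file.
#' @param pixel_size_um physical pixel size.
#' @return an [annotated_slide()].
#' @export
read_annotated_slide <- function(image_path, annotations_path,
                                 pixel_size_um = 0.23) {
  img <- read_slide_image(image_path)
  ann <- read_annotations_geojson(annotations_path)
  annotated_slide(img, ann$include_polygons, ann$exclude_polygons,
                  pixel_size_um)
}

#' Read a class map written by [write_slide()]
#'
#' @param path single-channel PNG whose gray levels encode the classes
#'   1 = epithelium, 2 = stroma, 3 = other.
#' @return integer matrix.
#' @export
read_class_map <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow = nrow(m))
}

#' Write / read a cohort table as CSV
#'
#' @param cohort cohort data frame.
#' @param path CSV path.
#' @name cohort_io
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
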