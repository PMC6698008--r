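#' Generate a systematic point grid within an analysis mask
#'
#' Places a square lattice with a uniformly random sub-cell offset
#' (systematic uniform random sampling) over the mask. The lattice spacing
#' is chosen so that the expected number of in-mask points equals
#' `n_points`; only points whose pixel lies inside the mask are returned.
#' With a full-frame mask whose sides are multiples of the spacing the grid
#' has exactly `n_points` points. Deterministic given `offset_seed`.
#'
#' @param mask logical analysis mask.
#' @param n_points requested grid size (default 400, the 20x-objective
#'   grid).
#' @param offset_seed RNG seed for the random offset.
#' @param fixed_origin if `TRUE`, anchor the lattice at half a spacing from
#'   the origin instead of a random offset (reproduces a specific count).
#' @return an object of class `point_grid`: `points` (n x 2 matrix of
#'   continuous 0-based x, y), `px` (n x 2 integer matrix of 1-based
#'   column, row), `spacing`, `n_requested`, `offset_seed`.
#' @export
generate_grid <- function(mask, n_points = 400, offset_seed = 1,
                          fixed_origin = FALSE) {
  stopifnot(is.matrix(mask), is.logical(mask), n_points >= 1)
  m <- sum(mask)
  if (m == 0) stop("analysis mask is empty")
  if (m < n_points)
    stop(sprintf("mask has %d pixels, fewer than the %d grid points requested",
                 m, n_points))
  h <- nrow(mask); w <- ncol(mask)
  s <- sqrt(m / n_points)
  if (fixed_origin) {
    off <- c(s / 2, s / 2)
  } else {
    set.seed(as.integer(offset_seed))
    off <- runif(2, 0, s)
  }
  xs <- seq(off[1], w, by = s); xs <- xs[xs < w]
  ys <- seq(off[2], h, by = s); ys <- ys[ys < h]
  pts <- cbind(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
  col <- floor(pts[, 1]) + 1L; row <- floor(pts[, 2]) + 1L
  keep <- mask[cbind(row, col)]
  structure(list(points = pts[keep, , drop = FALSE],
                 px = cbind(col = col[keep], row = row[keep]),
                 spacing = s,
                 n_requested = as.integer(n_points),
                 offset_seed = as.integer(offset_seed)),
            class = "point_grid")
}

#' Classify grid points as epithelium, stroma or other
#'
#' Scores each grid point either automatically from a class map raster
#' (1 = epithelium, 2 = stroma, 3 = other; e.g. the ground-truth map of a
#' synthetic slide or any supplied segmentation) or from a manually scored
#' table with one row per point, preserving the operator-scored workflow.
#'
#' @param grid a [generate_grid()] result.
#' @param class_map integer matrix covering the image, or `NULL`.
#' @param manual data frame with a `label` column
#'   (`epithelium`/`stroma`/`other`), one row per grid point, or `NULL`.
#' @return an object of class `point_classification`: factor `labels`
#'   aligned with the grid, and `source`.
#' @export
classify_points <- function(grid, class_map = NULL, manual = NULL) {
  stopifnot(inherits(grid, "point_grid"))
  lv <- c("epithelium", "stroma", "other")
  n <- nrow(grid$px)
  if (!is.null(class_map)) {
    stopifnot(is.matrix(class_map))
    vals <- class_map[cbind(grid$px[, "row"], grid$px[, "col"])]
    bad <- which(is.na(vals) | !(vals %in% 1:3))
    if (length(bad))
      stop("class map gives no valid label for point(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    labels <- factor(lv[vals], levels = lv)
    src <- "auto_from_class_map"
  } else if (!is.null(manual)) {
    if (!("label" %in% names(manual)))
      stop("manual table must have a 'label' column")
    if (nrow(manual) != n)
      stop(sprintf("manual table has %d rows for %d grid points",
                   nrow(manual), n))
    bad <- which(!(as.character(manual$label) %in% lv))
    if (length(bad))
      stop("invalid manual label for point(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    labels <- factor(as.character(manual$label), levels = lv)
    src <- "manual_table"
  } else {
    stop("provide either class_map or manual")
  }
  structure(list(labels = labels, source = src), class = "point_classification")
}

#' Compute tumour-stroma percentage from classified points
#'
#' TSP is the number of stromal hits divided by the total number of
#' epithelial and stromal hits, as a percent. Points scored `other`
#' (lumen, mucus, necrosis, background) enter neither numerator nor
#' denominator.
#'
#' @param classification a [classify_points()] result.
#' @return an object of class `tsp_result` with `tsp_percent`, `n_stroma`,
#'   `n_epithelium`, `n_other`.
#' @export
compute_tsp <- function(classification) {
  stopifnot(inherits(classification, "point_classification"))
  tab <- table(classification$labels)
  ns <- as.integer(tab[["stroma"]]); ne <- as.integer(tab[["epithelium"]])
  no <- as.integer(tab[["other"]])
  if (ns + ne == 0)
    stop("no informative (epithelium or stroma) hits; TSP undefined")
  structure(list(tsp_percent = 100 * ns / (ns + ne),
                 n_stroma = ns, n_epithelium = ne, n_other = no),
            class = "tsp_result")
}

#' @export
print.tsp_result <- function(x, ...) {
  cat(sprintf("TSP: %.2f%% (%d stroma / %d epithelium hits, %d other excluded)\n",
              x$tsp_percent, x$n_stroma, x$n_epithelium, x$n_other))
  invisible(x)
}
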