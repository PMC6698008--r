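test_that("stain rule: pure white is negative, reference brown saturates", {
  white <- annotated_slide(array(255L, dim = c(20, 20, 3)),
                           poly_rect(0, 0, 20, 20))
  mask <- rasterize_annotation(white)
  expect_false(any(classify_positive_pixels(white, mask)))

  brown <- array(0L, dim = c(20, 20, 3))
  brown[, , 1] <- 120L; brown[, , 2] <- 80L; brown[, , 3] <- 50L
  sl <- annotated_slide(brown, poly_rect(0, 0, 20, 20))
  expect_identical(classify_positive_pixels(sl, mask), mask)
})

test_that("positive mask is always a subset of the analysis mask", {
  sl <- small_slide(seed = 2)
  ann <- as_annotated_slide(sl)
  mask <- rasterize_annotation(ann)
  mask[1:100, ] <- FALSE
  pos <- classify_positive_pixels(ann, mask)
  expect_true(all(mask[pos]))
})

test_that("default classifier recovers the generator vessel map on >= 99% of pixels", {
  sl <- small_slide(seed = 13)
  ann <- as_annotated_slide(sl)
  mask <- rasterize_annotation(ann)
  pos <- classify_positive_pixels(ann, mask)
  agree <- mean((pos == (sl$vessel_label_map > 0))[mask])
  expect_gte(agree, 0.99)
})

test_that("stain-deconvolution mode also separates chromogen from counterstain", {
  sl <- small_slide(seed = 13)
  ann <- as_annotated_slide(sl)
  mask <- rasterize_annotation(ann)
  pos <- classify_positive_pixels(ann, mask,
                                  stain_config(mode = "stain_deconvolution"))
  agree <- mean((pos == (sl$vessel_label_map > 0))[mask])
  expect_gte(agree, 0.95)
})

test_that("diagonal pixels merge under 8-connectivity and split under 4", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE
  c8 <- label_components(m, 8)
  expect_equal(length(c8$sizes), 1)
  expect_equal(unname(c8$sizes), 2)
  c4 <- label_components(m, 4)
  expect_equal(length(c4$sizes), 2)
  expect_equal(unname(c4$sizes), c(1, 1))
})

test_that("labeling matches a flood-fill oracle on random masks", {
  set.seed(99)
  for (i in 1:10) {
    m <- matrix(runif(64 * 64) < 0.4, 64, 64)
    for (conn in c(4, 8)) {
      cs <- label_components(m, conn)
      oracle <- flood_fill_labels(m, conn)
      expect_true(same_partition(cs$label_map, oracle))
      expect_equal(sum(cs$sizes), sum(m))
      expect_equal(unname(cs$sizes),
                   as.integer(tabulate(cs$label_map[cs$label_map > 0])))
    }
  }
})

test_that("size filter keeps >= min_pixels, is idempotent and a no-op at 1", {
  m <- matrix(FALSE, 30, 40)
  m[2:10, 2:12] <- TRUE   # 99 px
  m[2:11, 15:24] <- TRUE  # 100 px
  m[15:21, 2:16] <- c(rep(TRUE, 101), rep(FALSE, 4))[1:105]
  cs <- label_components(m, 8)
  f <- filter_components(cs, 100)
  expect_setequal(unname(f$sizes), c(100, 101))
  expect_true(all(sort(unique(as.vector(f$label_map))) %in% 0:2))
  expect_identical(filter_components(f, 100), f)
  expect_identical(filter_components(cs, 1), cs)

  empty <- label_components(matrix(FALSE, 5, 5), 8)
  expect_length(filter_components(empty, 100)$sizes, 0)
})

test_that("MVD arithmetic follows the percent-positive formula", {
  m <- matrix(FALSE, 100, 100)
  m[1:10, 1:15] <- TRUE                   # 150 px
  m[50:59, 50:61] <- TRUE                 # 120 px
  m[80:88, 1:11] <- TRUE                  # 99 px, removed by the filter
  cs <- filter_components(label_components(m, 8), 100)
  r <- compute_mvd(cs, 10000)
  expect_equal(r$mvd_percent, 2.70)
  expect_equal(r$n_components, 2)
  expect_equal(r$positive_pixels, 270L)

  none <- filter_components(label_components(matrix(FALSE, 10, 10), 8), 100)
  expect_equal(compute_mvd(none, 10000)$mvd_percent, 0)

  all_on <- label_components(matrix(TRUE, 20, 20), 8)
  expect_equal(compute_mvd(all_on, 400)$mvd_percent, 100)
  expect_error(compute_mvd(all_on, 0), "analysed_pixels")
})

test_that("full pipeline recovers generator ground truth within 0.5 pp", {
  sl <- small_slide(seed = 41, target = 0.06, n_vessels = 12,
                    size = c(150, 700))
  r <- quantify_slide(as_annotated_slide(sl))
  expect_lt(abs(r$mvd_percent - 100 * sl$truth$positive_fraction), 0.5)
  expect_gte(r$mvd_percent, 0); expect_lte(r$mvd_percent, 100)
})

test_that("shrinking some vessels below threshold removes exactly their pixels", {
  sl <- small_slide(seed = 55, target = 0.05, n_vessels = 10,
                    size = c(150, 600))
  # artificially shrink a third of the vessels below 100 px on the arrays
  shrink <- seq(1, length(sl$truth$vessel_pixel_counts), by = 3)
  for (k in shrink) {
    idx <- which(sl$vessel_label_map == k)
    drop <- idx[-seq_len(min(60, length(idx)))]
    sl$vessel_label_map[drop] <- 0L
    for (ch in 1:3) {
      plane <- sl$image[, , ch]
      plane[drop] <- 250L
      sl$image[, , ch] <- plane
    }
  }
  big_truth <- sum(sl$vessel_label_map > 0 & sl$tissue_mask) -
    sum(tabulate(sl$vessel_label_map[sl$vessel_label_map > 0])[
      tabulate(sl$vessel_label_map[sl$vessel_label_map > 0]) < 100])
  r <- quantify_slide(as_annotated_slide(sl))
  expect_lt(abs(r$mvd_percent - 100 * big_truth / sum(sl$tissue_mask)), 0.5)
})

test_that("adding a disjoint component strictly increases MVD", {
  sl <- small_slide(seed = 61)
  r0 <- quantify_slide(as_annotated_slide(sl))
  # paint a fresh 12x12 brown block in a vessel-free corner region
  free <- which(sl$vessel_label_map[1:40, 1:40] == 0)
  sl2 <- sl
  sl2$image[1:12, 1:12, 1] <- 120L
  sl2$image[1:12, 1:12, 2] <- 80L
  sl2$image[1:12, 1:12, 3] <- 50L
  r1 <- quantify_slide(as_annotated_slide(sl2))
  expect_gt(r1$mvd_percent, r0$mvd_percent)
})

test_that("all-background slide quantifies to exactly zero", {
  img <- array(245L, dim = c(64, 64, 3))
  r <- quantify_slide(annotated_slide(img, poly_rect(0, 0, 64, 64)))
  expect_equal(r$mvd_percent, 0)
  expect_equal(r$n_components, 0)
})
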