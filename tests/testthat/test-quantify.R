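test_that("well-separated blobs are counted as distinct cells", {
  m <- matrix(0L, 64L, 64L)
  m[10:14, 10:14] <- 1L          # 5x5 blob
  m[10:14, 40:44] <- 1L          # 26 px away: distinct
  comps <- label_cells(m, 1L)
  expect_length(comps, 2L)
  expect_identical(canon_components(comps),
                   canon_components(oracle_label_cells(m, 1L)))
})

test_that("blobs within the merge radius fuse into one cell", {
  m <- matrix(0L, 32L, 32L)
  m[10:14, 10:12] <- 1L
  m[10:14, 16:18] <- 1L          # 3-px gap: merged under radius 4
  expect_length(label_cells(m, 1L, merge_radius_px = 4L), 1L)
  expect_length(oracle_label_cells(m, 1L, 4L), 1L)
  # without merging they stay apart
  expect_length(label_cells(m, 1L, merge_radius_px = 0L), 2L)
})

test_that("label_cells matches the flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    m <- random_mask()
    for (cls in c(1L, 2L)) {
      expect_identical(canon_components(label_cells(m, cls)),
                       canon_components(oracle_label_cells(m, cls)))
    }
  }
})

test_that("label_cells validates its inputs", {
  m <- matrix(0L, 8L, 8L)
  expect_error(label_cells(m, 3L), "class_label")
  expect_identical(label_cells(m, 1L), list())
  bad <- matrix(5L, 4L, 4L)
  expect_error(label_cells(bad, 1L), "out-of-range")
})

test_that("count_cells tallies both classes", {
  expect_identical(count_cells(matrix(0L, 16L, 16L))$total, 0L)
  m <- matrix(0L, 64L, 64L)
  m[5:8, 5:8] <- 1L; m[5:8, 30:33] <- 1L; m[40:43, 40:43] <- 1L
  m[55:58, 5:8] <- 2L
  ct <- count_cells(m)
  expect_identical(ct$n_positive, 3L)
  expect_identical(ct$n_negative, 1L)
})

test_that("the minimum-area gate drops sub-cellular specks only", {
  m <- matrix(0L, 32L, 32L)
  m[5:10, 5:10] <- 1L            # 36 px cell
  m[20, 20] <- 1L                # 1 px speck
  expect_identical(count_cells(m)$n_positive, 2L)
  expect_identical(count_cells(m, min_area_px = 8L)$n_positive, 1L)
})

test_that("TPS follows its defining ratio and rejects empty tallies", {
  expect_equal(compute_tps(cell_tally(3L, 1L)), 75.0)
  expect_equal(compute_tps(cell_tally(0L, 5L)), 0.0)
  expect_error(compute_tps(cell_tally(0L, 0L)), class = "pdl1_no_tumour_error")
})

test_that("TPS is scale-invariant and bounded", {
  set.seed(7)
  for (i in 1:20) {
    np <- sample(0:30, 1); nn <- sample(0:30, 1)
    if (np + nn == 0) nn <- 1
    tps <- compute_tps(cell_tally(np, nn))
    expect_gte(tps, 0); expect_lte(tps, 100)
    k <- sample(2:9, 1)
    expect_equal(compute_tps(cell_tally(k * np, k * nn)), tps)
  }
})

test_that("ROI tiling lays a row-major grid with the stated offsets", {
  img <- array(0.5, c(512L, 512L, 3L))
  tiles <- tile_roi(img, NULL, tile_px = 256L)
  expect_length(tiles, 4L)
  expect_identical(lapply(tiles, `[[`, "offset"),
                   list(c(0L, 0L), c(0L, 256L), c(256L, 0L), c(256L, 256L)))
  expect_true(all(vapply(tiles, function(t) all(t$valid), TRUE)))
})

test_that("partial edge tiles are padded and the padding marked invalid", {
  img <- array(0.5, c(256L, 300L, 3L))
  tiles <- tile_roi(img, NULL, tile_px = 256L)
  expect_length(tiles, 2L)
  expect_identical(dim(tiles[[2]]$image), c(256L, 256L, 3L))
  expect_identical(sum(!tiles[[2]]$valid), 256L * 212L)
})

test_that("an ROI that misses the image is rejected", {
  img <- array(0.5, c(64L, 64L, 3L))
  far <- roi_polygon(cbind(c(200, 300, 300, 200), c(200, 200, 300, 300)))
  expect_error(tile_roi(img, far), "does not intersect")
})

test_that("polygon ROIs exclude outside pixels from counting", {
  mask <- matrix(0L, 64L, 64L)
  mask[10:13, 10:13] <- 1L       # inside the ROI
  mask[40:43, 40:43] <- 1L       # outside
  roi <- roi_polygon(cbind(c(0, 32, 32, 0), c(0, 0, 32, 32)))
  res <- score_mask(mask, roi, tile_px = 32L)
  expect_identical(res$tally$n_positive, 1L)
})

test_that("per-tile tallies sum exactly to the whole-mask tally", {
  spec <- synthetic_patch_spec(128L, 128L, n_positive = 4L, n_negative = 6L,
                               cell_radius_range = c(3L, 4L),
                               min_cell_gap_px = 10L,
                               forbid_tile_straddle = TRUE,
                               tile_size_px = 64L)
  for (seed in c(3L, 17L)) {
    p <- generate_patch(spec, seed)
    whole <- count_cells(p$mask)
    tiled <- score_mask(p$mask, NULL, tile_px = 64L)
    expect_identical(tiled$tally$n_positive, whole$n_positive)
    expect_identical(tiled$tally$n_negative, whole$n_negative)
    expect_equal(tiled$tps_percent, compute_tps(whole))
    expect_equal(tiled$tps_percent, p$tally$n_positive /
                   p$tally$total * 100)
    expect_length(tiled$per_patch_tallies, 4L)
  }
})

test_that("score_roi sums predicted per-tile tallies into one score", {
  # a stub segmenter stands in for the model: tiles are masks already
  mask <- matrix(0L, 64L, 128L)
  mask[10:13, 10:13] <- 1L; mask[10:13, 30:33] <- 2L   # tile 1: (1,1)
  mask[10:13, 70:73] <- 2L; mask[40:43, 70:73] <- 2L   # tile 2: (0,2)
  img <- array(0, c(64L, 128L, 3L))
  img[, , 1] <- mask                                    # encode labels in R
  seg <- function(tile) matrix(as.integer(round(tile[, , 1])),
                               nrow(tile), ncol(tile))
  res <- score_roi(img, seg, tile_px = 64L)
  expect_identical(res$n_patches, 2L)
  expect_identical(res$tally$n_positive, 1L)
  expect_identical(res$tally$n_negative, 3L)
  expect_equal(res$tps_percent, 25.0)
})

test_that("a tumour-free prediction is reported, not scored", {
  img <- array(0.9, c(64L, 64L, 3L))
  seg <- function(tile) matrix(0L, nrow(tile), ncol(tile))
  res <- score_roi(img, seg, tile_px = 64L)
  expect_identical(res$status, "no_tumour_detected")
  expect_true(is.na(res$tps_percent))
})

test_that("GeoJSON ROIs round-trip in pixel coordinates", {
  roi <- roi_polygon(cbind(c(0, 40, 40, 0), c(0, 0, 48, 48)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_roi_geojson(roi, path)
  back <- read_roi_geojson(path)
  expect_equal(back[[1]], roi[[1]])
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(gj$type, "FeatureCollection")
  expect_identical(gj$features[[1]]$geometry$type, "Polygon")
})
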