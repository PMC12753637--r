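#' Cell tallies
#'
#' A cell tally holds the counts that enter the tumour proportion score:
#' the number of PD-L1-positive and PD-L1-negative intact tumour cells.
#'
#' @param n_positive,n_negative non-negative integer counts.
#' @return an object of class `cell_tally` with fields `n_positive`,
#'   `n_negative` and `total`.
#' @export
cell_tally <- function(n_positive = 0L, n_negative = 0L) {
  n_positive <- as.integer(n_positive)
  n_negative <- as.integer(n_negative)
  if (is.na(n_positive) || is.na(n_negative) ||
      n_positive < 0L || n_negative < 0L) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(n_positive = n_positive, n_negative = n_negative,
         total = n_positive + n_negative),
    class = "cell_tally"
  )
}

#' @export
print.cell_tally <- function(x, ...) {
  cat(sprintf("cell tally: %d positive, %d negative (total %d)\n",
              x$n_positive, x$n_negative, x$total))
  invisible(x)
}

#' @rdname cell_tally
#' @param x,y `cell_tally` objects.
#' @export
add_tallies <- function(x, y) {
  cell_tally(x$n_positive + y$n_positive, x$n_negative + y$n_negative)
}

#' Group labelled pixels into cells by connected components
#'
#' Pixels carrying `class_label` are grouped into cell objects. Nearby
#' fragments belonging to one cell are merged by first dilating the binary
#' class mask with a box structuring element of radius `merge_radius_px`
#' (the radius-4 neighbourhood used for the connected-components search),
#' labelling the dilated mask with 4-connectivity, and assigning each
#' original pixel the label of its dilated component.
#'
#' Components smaller than `min_area_px` can be discarded: an intact
#' tumour cell has a minimum plausible footprint, and sub-cellular
#' specks (typically prediction noise) should not enter the TPS
#' denominator. The default 0 keeps every component.
#'
#' @param mask a label mask (see [validate_mask()]).
#' @param class_label 1 (positive tumour cells) or 2 (negative).
#' @param merge_radius_px non-negative integer merge radius in pixels
#'   (default 4). 0 disables merging (plain 4-connected labelling).
#' @param min_area_px discard merged components with fewer pixels than
#'   this (default 0: keep all).
#' @return list of integer vectors; each element holds the linear (column
#'   major) pixel indices of one cell, ordered by first-labelled component.
#' @export
label_cells <- function(mask, class_label, merge_radius_px = 4L,
                        min_area_px = 0L) {
  mask <- validate_mask(mask)
  if (!class_label %in% c(1L, 2L)) {
    stop("class_label must be 1 (positive) or 2 (negative)", call. = FALSE)
  }
  merge_radius_px <- as.integer(merge_radius_px)
  stopifnot(merge_radius_px >= 0L)
  bin <- mask == class_label
  if (!any(bin)) return(list())
  grown <- bin
  if (merge_radius_px > 0L) {
    brush <- EBImage::makeBrush(2L * merge_radius_px + 1L, shape = "box")
    grown <- EBImage::dilate(bin * 1, brush) > 0
  }
  lab <- EBImage::bwlabel(grown * 1)  # 4-connected labelling
  px <- which(bin)
  comp <- split(px, as.integer(lab[px]))
  comp <- unname(comp[order(as.integer(names(comp)))])
  if (min_area_px > 0L) {
    comp <- comp[vapply(comp, length, 0L) >= min_area_px]
  }
  comp
}

#' Count positive and negative tumour cells in a mask
#'
#' Applies [label_cells()] to each foreground class and returns the tally.
#'
#' @inheritParams label_cells
#' @return a [cell_tally()].
#' @export
count_cells <- function(mask, merge_radius_px = 4L, min_area_px = 0L) {
  cell_tally(
    length(label_cells(mask, 1L, merge_radius_px, min_area_px)),
    length(label_cells(mask, 2L, merge_radius_px, min_area_px))
  )
}

#' Tumour proportion score
#'
#' TPS\% = 100 x (number of PD-L1-positive intact tumour cells) /
#' (total number of intact tumour cells). A tally with no tumour cells has
#' no defined score and raises a `pdl1_no_tumour_error` so that callers
#' report "no viable tumour" rather than a number.
#'
#' @param tally a [cell_tally()].
#' @return the score as a percentage in \[0, 100\].
#' @export
compute_tps <- function(tally) {
  stopifnot(inherits(tally, "cell_tally"))
  if (tally$total == 0L) {
    stop(structure(
      class = c("pdl1_no_tumour_error", "error", "condition"),
      list(message = "no intact tumour cells detected; TPS is undefined",
           call = sys.call(-1))
    ))
  }
  100 * tally$n_positive / tally$total
}

#' Regions of interest
#'
#' An ROI is one or more closed polygons in 0-based pixel coordinates
#' (x = column, y = row, y increasing downward), the convention of QuPath
#' GeoJSON exports. `read_roi_geojson()` parses a FeatureCollection of
#' Polygon features; `roi_polygon()` builds an ROI from coordinate
#' matrices directly.
#'
#' @param polygons a two-column (x, y) matrix or list of such matrices,
#'   one per polygon ring.
#' @return an object of class `pdl1_roi`: a list of closed coordinate
#'   matrices.
#' @export
roi_polygon <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  polys <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L) {
      stop("each ROI polygon needs a two-column (x, y) matrix with >= 3 vertices",
           call. = FALSE)
    }
    # close the ring
    if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
    p
  })
  structure(polys, class = "pdl1_roi")
}

#' @rdname roi_polygon
#' @param path GeoJSON file path.
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  polys <- list()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (!identical(geom$type, "Polygon")) {
      stop("ROI GeoJSON must contain Polygon geometries, found: ",
           geom$type, call. = FALSE)
    }
    ring <- geom$coordinates[[1]]  # exterior ring only
    polys[[length(polys) + 1L]] <-
      do.call(rbind, lapply(ring, function(xy) as.numeric(xy[1:2])))
  }
  if (length(polys) == 0L) stop("no Polygon features in ", path, call. = FALSE)
  roi_polygon(polys)
}

#' @rdname roi_polygon
#' @param roi a `pdl1_roi`.
#' @export
write_roi_geojson <- function(roi, path) {
  stopifnot(inherits(roi, "pdl1_roi"))
  feats <- lapply(roi, function(p) {
    list(type = "Feature", properties = list(),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(p)),
                                     function(i) as.numeric(p[i, ])))
         ))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# logical matrix: TRUE where the pixel centre falls inside any ROI polygon
roi_inside_matrix <- function(roi, nrow_px, ncol_px, row0 = 0L, col0 = 0L) {
  centers <- cbind(
    x = rep(col0 + seq_len(ncol_px) - 0.5, each = nrow_px),
    y = rep(row0 + seq_len(nrow_px) - 0.5, times = ncol_px)
  )
  inside <- rep(FALSE, nrow(centers))
  for (p in roi) {
    inside <- inside | mgcv::in.out(p, centers)
  }
  matrix(inside, nrow_px, ncol_px)
}

#' Tile a region of interest into fixed-size patches
#'
#' Lays an axis-aligned grid of `tile_px` x `tile_px` tiles over the
#' bounding box of the ROI (clipped to the image), in row-major order.
#' Pixels outside the ROI polygon, and padding added to partial edge
#' tiles, are marked invalid in each tile's validity mask and set to a
#' neutral background value in the tile image.
#'
#' @param image `H x W x 3` array (or an `H x W` label matrix).
#' @param roi a `pdl1_roi`, or NULL to tile the whole image.
#' @param tile_px tile side length in pixels (default 256).
#' @param background fill value for invalid pixels (default 1, white).
#' @return list of tiles; each tile is a list with `image` (tile-sized),
#'   `valid` (logical matrix) and `offset` (0-based `c(row, col)` of the
#'   tile's top-left corner in the source image).
#' @export
tile_roi <- function(image, roi = NULL, tile_px = 256L, background = 1) {
  dims <- dim(image)
  H <- dims[1]; W <- dims[2]
  is_raster <- length(dims) == 3L
  tile_px <- as.integer(tile_px)
  stopifnot(tile_px >= 1L)

  if (is.null(roi)) {
    r0 <- 0L; c0 <- 0L; r1 <- H; c1 <- W
    inside <- NULL
  } else {
    stopifnot(inherits(roi, "pdl1_roi"))
    allv <- do.call(rbind, lapply(roi, identity))
    r0 <- max(0L, floor(min(allv[, 2])))
    c0 <- max(0L, floor(min(allv[, 1])))
    r1 <- min(H, ceiling(max(allv[, 2])))
    c1 <- min(W, ceiling(max(allv[, 1])))
    if (r1 <= r0 || c1 <= c0) {
      stop("ROI does not intersect the image", call. = FALSE)
    }
    inside <- roi_inside_matrix(roi, r1 - r0, c1 - c0, r0, c0)
    if (!any(inside)) stop("ROI does not intersect the image", call. = FALSE)
  }

  tiles <- list()
  for (tr in seq(r0, r1 - 1L, by = tile_px)) {
    for (tc in seq(c0, c1 - 1L, by = tile_px)) {
      rows <- (tr + 1L):min(tr + tile_px, H)
      cols <- (tc + 1L):min(tc + tile_px, W)
      valid <- matrix(FALSE, tile_px, tile_px)
      sub_valid <- if (is.null(inside)) {
        matrix(TRUE, length(rows), length(cols))
      } else {
        inside[rows - r0, cols - c0, drop = FALSE]
      }
      valid[seq_along(rows), seq_along(cols)] <- sub_valid
      if (is_raster) {
        timg <- array(background, c(tile_px, tile_px, dims[3]))
        sub <- image[rows, cols, , drop = FALSE]
        for (ch in seq_len(dims[3])) {
          page <- sub[, , ch]
          page[!sub_valid] <- background
          timg[seq_along(rows), seq_along(cols), ch] <- page
        }
      } else {
        timg <- matrix(if (is.integer(image)) 0L else 0, tile_px, tile_px)
        sub <- image[rows, cols, drop = FALSE]
        sub[!sub_valid] <- 0L
        timg[seq_along(rows), seq_along(cols)] <- sub
      }
      tiles[[length(tiles) + 1L]] <-
        list(image = timg, valid = valid, offset = c(tr, tc))
    }
  }
  tiles
}

#' TPS over a tiled region of interest
#'
#' Each tile is segmented, cells are counted per tile, the per-tile tallies
#' are summed, and the TPS is computed from the summed tally. The per-tile
#' tallies are retained for audit. When the summed tally contains no tumour
#' cells the result carries status `"no_tumour_detected"` and an `NA` score
#' instead of raising.
#'
#' @param image `H x W x 3` array in \[0, 1\].
#' @param segmenter either a model built by [build_model()] (possibly
#'   trained) or a function `function(image) -> mask` producing a label
#'   mask; ground-truth masks can be scored with [score_mask()].
#' @param roi optional [roi_polygon()]; NULL scores the whole image.
#' @param tile_px tile size (default 256).
#' @param merge_radius_px connected-components merge radius (default 4).
#' @param min_area_px minimum component area passed to [count_cells()].
#' @param mask_threshold foreground acceptance threshold passed to
#'   [predict_mask()] when `segmenter` is a model (default 0.5).
#' @return an object of class `tps_result`: `tps_percent`, `tally`,
#'   `per_patch_tallies`, `offsets`, `n_patches`, `status`.
#' @export
score_roi <- function(image, segmenter, roi = NULL, tile_px = 256L,
                      merge_radius_px = 4L, min_area_px = 0L,
                      mask_threshold = 0.5) {
  seg_fn <- if (is.function(segmenter)) {
    segmenter
  } else {
    function(img) predict_mask(segmenter, img, mask_threshold)
  }
  tiles <- tile_roi(image, roi, tile_px)
  tallies <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    m <- validate_mask(seg_fn(tiles[[i]]$image))
    m[!tiles[[i]]$valid] <- 0L
    tallies[[i]] <- count_cells(m, merge_radius_px, min_area_px)
  }
  finish_tps_result(tallies, lapply(tiles, `[[`, "offset"))
}

#' Score a ground-truth mask by ROI tiling
#'
#' Applies the same tile-count-sum procedure as [score_roi()] directly to a
#' label mask, bypassing segmentation. Used to verify tiling additivity and
#' to score annotated (rather than predicted) masks.
#'
#' @param mask a label mask.
#' @inheritParams score_roi
#' @return a `tps_result`.
#' @export
score_mask <- function(mask, roi = NULL, tile_px = 256L,
                       merge_radius_px = 4L, min_area_px = 0L) {
  mask <- validate_mask(mask)
  tiles <- tile_roi(mask, roi, tile_px)
  tallies <- lapply(tiles, function(t) {
    m <- t$image
    m[!t$valid] <- 0L
    count_cells(m, merge_radius_px, min_area_px)
  })
  finish_tps_result(tallies, lapply(tiles, `[[`, "offset"))
}

finish_tps_result <- function(tallies, offsets) {
  total <- Reduce(add_tallies, tallies, cell_tally(0L, 0L))
  res <- list(
    tps_percent = NA_real_,
    tally = total,
    per_patch_tallies = tallies,
    offsets = offsets,
    n_patches = length(tallies),
    status = "scored"
  )
  if (total$total == 0L) {
    res$status <- "no_tumour_detected"
  } else {
    res$tps_percent <- compute_tps(total)
  }
  structure(res, class = "tps_result")
}

#' @export
print.tps_result <- function(x, ...) {
  if (x$status == "no_tumour_detected") {
    cat("TPS: no intact tumour cells detected (", x$n_patches,
        " patches)\n", sep = "")
  } else {
    cat(sprintf("TPS %.2f%% (%d positive / %d tumour cells over %d patches)\n",
                x$tps_percent, x$tally$n_positive, x$tally$total, x$n_patches))
  }
  invisible(x)
}
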