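#' Synthetic IHC patch specification
#'
#' Describes one synthetic PD-L1 IHC-like patch: stained (DAB-brown)
#' PD-L1-positive tumour cells, unstained (haematoxylin-blue) negative
#' tumour cells and optional macrophage-like stained distractors that are
#' rendered with a positive-like stain but labelled background — the
#' "hugging" objects that must not be counted as tumour.
#'
#' @param height_px,width_px patch size in pixels (default 256 x 256, the
#'   patch convention used throughout the pipeline).
#' @param n_positive,n_negative,n_distractor non-negative object counts.
#' @param cell_radius_range length-2 integer vector, min/max major radius
#'   of tumour cells in pixels.
#' @param min_cell_gap_px minimum boundary gap between any two rendered
#'   objects, guaranteed in Chebyshev (chessboard) distance — the metric
#'   of the box dilation used when counting. Values above twice the
#'   downstream merge radius (> 8 px for the default radius-4 merge)
#'   guarantee that generated cells never merge during counting.
#' @param stain_intensity chromogen intensity in \[0, 1\].
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param forbid_tile_straddle if TRUE, every object is placed fully
#'   inside the interior of one `tile_size_px` tile, so per-tile counting
#'   is exactly additive.
#' @param tile_size_px tile size used by `forbid_tile_straddle`.
#' @return an object of class `synthetic_patch_spec`.
#' @export
synthetic_patch_spec <- function(height_px = 256L, width_px = 256L,
                                 n_positive = 0L, n_negative = 0L,
                                 n_distractor = 0L,
                                 cell_radius_range = c(4L, 7L),
                                 min_cell_gap_px = 10L,
                                 stain_intensity = 0.9,
                                 noise_sd = 0.02,
                                 forbid_tile_straddle = FALSE,
                                 tile_size_px = 256L) {
  spec <- list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
    n_distractor = as.integer(n_distractor),
    cell_radius_range = as.integer(cell_radius_range),
    min_cell_gap_px = as.integer(min_cell_gap_px),
    stain_intensity = as.numeric(stain_intensity),
    noise_sd = as.numeric(noise_sd),
    forbid_tile_straddle = isTRUE(forbid_tile_straddle),
    tile_size_px = as.integer(tile_size_px)
  )
  with(spec, {
    stopifnot(height_px > 0L, width_px > 0L, tile_size_px > 0L)
    if (n_positive < 0L || n_negative < 0L || n_distractor < 0L) {
      stop("object counts must be non-negative", call. = FALSE)
    }
    if (length(cell_radius_range) != 2L ||
        cell_radius_range[1] > cell_radius_range[2] ||
        cell_radius_range[1] < 1L) {
      stop("cell_radius_range must be positive with min <= max", call. = FALSE)
    }
    if (min_cell_gap_px < 0L) stop("min_cell_gap_px must be >= 0", call. = FALSE)
    if (stain_intensity < 0 || stain_intensity > 1) {
      stop("stain_intensity must lie in [0, 1]", call. = FALSE)
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  })
  structure(spec, class = "synthetic_patch_spec")
}

# parametric stain palette (RGB in [0, 1])
.stain_colors <- list(
  background = c(0.94, 0.90, 0.92),  # pale eosin-pink tissue
  positive   = c(0.45, 0.29, 0.13),  # DAB brown chromogen
  negative   = c(0.26, 0.33, 0.62),  # haematoxylin blue
  distractor = c(0.70, 0.52, 0.32)   # paler granular DAB (macrophage-like)
)

# raise the explicit placement-failure condition
packing_error <- function(msg) {
  stop(structure(
    class = c("pdl1_packing_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Generate one synthetic IHC patch
#'
#' Places non-overlapping elliptical cells by seeded rejection sampling
#' (at most 1000 attempts per object), renders them over a noisy pale
#' background and returns the image, the ground-truth label mask and the
#' tally fixed by construction. Identical `(spec, seed)` pairs give
#' bit-identical output.
#'
#' @param spec a [synthetic_patch_spec()].
#' @param seed integer seed for this patch.
#' @return list with `image` (`H x W x 3` in \[0, 1\]), `mask` (label
#'   matrix) and `tally` (a [cell_tally()]).
#' @export
generate_patch <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_patch_spec"))
  with_seed(seed, generate_patch_impl(spec))
}

generate_patch_impl <- function(spec) {
  H <- spec$height_px; W <- spec$width_px
  rmin <- spec$cell_radius_range[1]; rmax <- spec$cell_radius_range[2]
  gap <- spec$min_cell_gap_px
  n_obj <- spec$n_positive + spec$n_negative + spec$n_distractor

  # feasibility: requested footprint (incl. half-gap collars) must fit
  if (n_obj > 0) {
    foot <- (spec$n_positive + spec$n_negative) * pi * (rmax + gap / 2)^2 +
      spec$n_distractor * pi * (3 + gap / 2)^2
    if (foot > 0.55 * H * W) {
      packing_error(sprintf(
        "requested %d objects cannot fit a %dx%d patch at min gap %d px",
        n_obj, H, W, gap))
    }
  }

  types <- c(rep("positive", spec$n_positive),
             rep("negative", spec$n_negative),
             rep("distractor", spec$n_distractor))
  placed <- list()
  for (ty in types) {
    a <- if (ty == "distractor") stats::runif(1, 2, 3)
         else stats::runif(1, rmin, rmax)
    ecc <- stats::runif(1, 1, 2)
    b <- max(a / ecc, 1.5)
    theta <- stats::runif(1, 0, pi)
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      if (spec$forbid_tile_straddle) {
        ts <- spec$tile_size_px
        n_tr <- max(1L, H %/% ts); n_tc <- max(1L, W %/% ts)
        ti <- sample.int(n_tr, 1L) - 1L; tj <- sample.int(n_tc, 1L) - 1L
        lo_r <- ti * ts + a + 2; hi_r <- min((ti + 1L) * ts, H) - a - 2
        lo_c <- tj * ts + a + 2; hi_c <- min((tj + 1L) * ts, W) - a - 2
      } else {
        lo_r <- a + 2; hi_r <- H - a - 2
        lo_c <- a + 2; hi_c <- W - a - 2
      }
      if (hi_r <= lo_r || hi_c <= lo_c) {
        packing_error(sprintf(
          "object radius %.1f px cannot be placed inside a %d px tile",
          a, spec$tile_size_px))
      }
      cy <- stats::runif(1, lo_r, hi_r)
      cx <- stats::runif(1, lo_c, hi_c)
      # gap is guaranteed in Chebyshev distance (the metric of the box
      # dilation used when counting), hence the sqrt(2) safety factor on
      # the Euclidean centre separation
      clear <- TRUE
      for (p in placed) {
        if (sqrt((cy - p$cy)^2 + (cx - p$cx)^2) <
            a + p$a + gap * sqrt(2)) {
          clear <- FALSE; break
        }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) {
      packing_error(sprintf(
        "failed to place object %d of %d after 1000 attempts (min gap %d px)",
        length(placed) + 1L, n_obj, gap))
    }
    placed[[length(placed) + 1L]] <-
      list(type = ty, cy = cy, cx = cx, a = a, b = b, theta = theta,
           jitter = stats::runif(1, 0.9, 1.1))
  }

  # render: background, then objects, then additive noise
  img <- array(rep(.stain_colors$background, each = H * W), c(H, W, 3))
  mask <- matrix(0L, H, W)
  for (p in placed) {
    rr <- max(1L, floor(p$cy - p$a)):min(H, ceiling(p$cy + p$a))
    cc <- max(1L, floor(p$cx - p$a)):min(W, ceiling(p$cx + p$a))
    dy <- outer(rr - p$cy, rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - p$cx)
    u <- (dx * cos(p$theta) + dy * sin(p$theta)) / p$a
    v <- (-dx * sin(p$theta) + dy * cos(p$theta)) / p$b
    d2 <- u^2 + v^2
    inside <- d2 <= 1
    if (!any(inside)) next
    rim <- inside & d2 > 0.55    # darker rim: membranous staining hint
    col <- .stain_colors[[p$type]]
    intensity <- min(1, spec$stain_intensity * p$jitter)
    for (ch in 1:3) {
      page <- img[rr, cc, ch]
      val <- (1 - intensity) * .stain_colors$background[ch] +
        intensity * col[ch]
      page[inside] <- val
      page[rim] <- val * 0.8
      img[rr, cc, ch] <- page
    }
    if (p$type != "distractor") {
      sub <- mask[rr, cc]
      sub[inside] <- if (p$type == "positive") 1L else 2L
      mask[rr, cc] <- sub
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask,
       tally = cell_tally(spec$n_positive, spec$n_negative))
}

#' Generate a multi-patch synthetic case
#'
#' A case bundles several patches (four by default in the study design)
#' with a known case-level tally and TPS. The master seed is expanded into
#' deterministic per-patch substream seeds.
#'
#' @param spec a single [synthetic_patch_spec()] applied to every patch,
#'   or a list of one spec per patch (used by [generate_cohort()] to vary
#'   counts across patches).
#' @param n_patches number of patches (>= 1); inferred from `spec` when a
#'   list is given.
#' @param seed master seed for the case.
#' @param case_id optional identifier.
#' @return an object of class `synthetic_case`: `patches` (list of
#'   `image`/`mask`/`tally`), `true_tally`, `true_tps` (NA when the case
#'   holds no tumour cells), `case_id`, `seed`.
#' @export
generate_case <- function(spec, n_patches = 4L, seed = 1L, case_id = NULL) {
  specs <- if (inherits(spec, "synthetic_patch_spec")) {
    stopifnot(n_patches >= 1L)
    rep(list(spec), n_patches)
  } else {
    stopifnot(is.list(spec), length(spec) >= 1L,
              all(vapply(spec, inherits, TRUE, "synthetic_patch_spec")))
    spec
  }
  sub <- expand_seed(seed, length(specs))
  patches <- Map(generate_patch, specs, sub)
  tally <- Reduce(add_tallies, lapply(patches, `[[`, "tally"),
                  cell_tally(0L, 0L))
  tps <- if (tally$total > 0L) compute_tps(tally) else NA_real_
  structure(
    list(patches = patches, true_tally = tally, true_tps = tps,
         case_id = if (is.null(case_id)) sprintf("case_%010d", seed)
                   else as.character(case_id),
         seed = as.integer(seed)),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("synthetic case %s: %d patches, true tally (%d, %d), true TPS %s\n",
              x$case_id, length(x$patches), x$true_tally$n_positive,
              x$true_tally$n_negative,
              if (is.na(x$true_tps)) "undefined" else sprintf("%.2f%%", x$true_tps)))
  invisible(x)
}

#' Synthetic cohort specification
#'
#' Describes a cohort of synthetic cases whose ground-truth TPS values are
#' spread over the three clinical categories in chosen proportions. The
#' exact score distribution of the study cohort is not published, so the
#' proportions are user parameters; the default leans slightly towards the
#' expressing categories, as typical for NSCLC PD-L1 cohorts.
#'
#' @param n_cases number of cases (>= 1).
#' @param category_proportions three non-negative numbers summing to 1:
#'   target fractions of cases with TPS <1\%, 1-49\% and >=50\%.
#' @param per_case_patch_count patches per case (default 4).
#' @param cells_per_patch intact tumour cells rendered per patch.
#' @param patch_spec template [synthetic_patch_spec()]; its per-class
#'   counts are overridden per patch.
#' @param seed master cohort seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases,
                        category_proportions = c(0.30, 0.35, 0.35),
                        per_case_patch_count = 4L,
                        cells_per_patch = 40L,
                        patch_spec = synthetic_patch_spec(),
                        seed = 1L) {
  stopifnot(n_cases >= 1L, per_case_patch_count >= 1L, cells_per_patch >= 1L,
            inherits(patch_spec, "synthetic_patch_spec"))
  p <- as.numeric(category_proportions)
  if (length(p) != 3L || any(p < 0)) {
    stop("category_proportions must be three non-negative numbers",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("category_proportions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), category_proportions = p,
         per_case_patch_count = as.integer(per_case_patch_count),
         cells_per_patch = as.integer(cells_per_patch),
         patch_spec = patch_spec, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Case counts per clinical category are fixed by rounding the cumulative
#' proportions (so they always sum to `n_cases`). Within a category, each
#' case draws a positive-cell count compatible with the category from its
#' seeded substream; positives are distributed as evenly as possible over
#' the case's patches.
#'
#' @param cohort a [cohort_spec()].
#' @return list of [generate_case()] results, one per case.
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  counts <- diff(c(0L, round(cumsum(cohort$category_proportions) *
                               cohort$n_cases)))
  categories <- rep(c("<1%", "1-49%", ">=50%"), counts)
  seeds <- expand_seed(cohort$seed, 2L * cohort$n_cases)
  n_pp <- cohort$per_case_patch_count
  total <- cohort$cells_per_patch * n_pp

  lapply(seq_len(cohort$n_cases), function(i) {
    cat_i <- categories[i]
    pick1 <- function(v) v[sample.int(length(v), 1L)]
    P <- with_seed(seeds[i], {
      switch(cat_i,
        "<1%" = 0L,
        # TPS in [1, 50): ceil(total/100) <= P < total/2
        "1-49%" = pick1(seq(ceiling(total / 100), ceiling(total / 2) - 1L)),
        ">=50%" = pick1(seq(ceiling(total / 2), total - 1L))
      )
    })
    base <- P %/% n_pp
    pos_per_patch <- rep(base, n_pp) +
      c(rep(1L, P - base * n_pp), rep(0L, n_pp - (P - base * n_pp)))
    specs <- lapply(pos_per_patch, function(np) {
      s <- cohort$patch_spec
      s$n_positive <- as.integer(np)
      s$n_negative <- cohort$cells_per_patch - as.integer(np)
      s
    })
    cs <- generate_case(specs, seed = seeds[cohort$n_cases + i],
                        case_id = sprintf("case_%03d", i))
    stopifnot(identical(clinical_category(cs$true_tps), cat_i))
    cs
  })
}

#' Write a synthetic case to disk
#'
#' Writes each patch image as 8-bit RGB PNG, each mask as single-channel
#' PNG with literal values 0/1/2, and a JSON manifest (case id, files,
#' true tally, true TPS, seed).
#'
#' @param case a [generate_case()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  image_files <- character(); mask_files <- character()
  for (i in seq_along(case$patches)) {
    imf <- sprintf("%s_patch%02d.png", case$case_id, i)
    mkf <- sprintf("%s_patch%02d_mask.png", case$case_id, i)
    write_image(case$patches[[i]]$image, file.path(dir, imf))
    write_mask(case$patches[[i]]$mask, file.path(dir, mkf))
    image_files <- c(image_files, imf); mask_files <- c(mask_files, mkf)
  }
  manifest <- list(
    case_id = case$case_id, seed = case$seed,
    images = image_files, masks = mask_files,
    true_tally = list(n_positive = case$true_tally$n_positive,
                      n_negative = case$true_tally$n_negative),
    true_tps = case$true_tps
  )
  path <- file.path(dir, paste0(case$case_id, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
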