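# Independent oracles used to cross-check the implementation. These are
# deliberately naive (per-pixel loops, BFS flood fill) and share no code
# with the package internals.

# brute-force connected components: mark a (2r+1) box around every pixel
# of the class, flood-fill the marked area with 4-connectivity, then
# assign the original pixels to their flooded component
oracle_label_cells <- function(mask, class_label, r = 4L) {
  H <- nrow(mask); W <- ncol(mask)
  bin <- mask == class_label
  if (!any(bin)) return(list())
  dil <- matrix(FALSE, H, W)
  for (idx in which(bin)) {
    i <- (idx - 1L) %% H + 1L; j <- (idx - 1L) %/% H + 1L
    dil[max(1L, i - r):min(H, i + r), max(1L, j - r):min(W, j + r)] <- TRUE
  }
  labm <- matrix(0L, H, W); cur <- 0L
  for (start in which(dil)) {
    if (labm[start] != 0L) next
    cur <- cur + 1L
    queue <- start; labm[start] <- cur
    while (length(queue) > 0) {
      q <- queue[1]; queue <- queue[-1]
      i <- (q - 1L) %% H + 1L; j <- (q - 1L) %/% H + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= H && nb[2] >= 1L && nb[2] <= W) {
          k <- (nb[2] - 1L) * H + nb[1]
          if (dil[k] && labm[k] == 0L) {
            labm[k] <- cur
            queue <- c(queue, k)
          }
        }
      }
    }
  }
  px <- which(bin)
  comp <- split(px, labm[px])
  unname(comp[order(vapply(comp, min, 0))])
}

# canonical form for comparing component lists regardless of label order
canon_components <- function(comps) {
  comps <- lapply(comps, function(v) sort(as.integer(v)))
  comps[order(vapply(comps, min, 0L))]
}

# naive per-pixel confusion tally
oracle_confusion <- function(gt, pred) {
  cm <- matrix(0, 3, 3)
  for (i in seq_along(gt)) {
    cm[gt[i] + 1L, pred[i] + 1L] <- cm[gt[i] + 1L, pred[i] + 1L] + 1
  }
  cm
}

# random sparse label mask: scattered pixels plus a few discs
random_mask <- function(H = 64L, W = 64L, n_px = 40L, n_disc = 3L) {
  m <- matrix(0L, H, W)
  idx <- sample.int(H * W, n_px)
  m[idx] <- sample(c(1L, 2L), n_px, replace = TRUE)
  for (k in seq_len(n_disc)) {
    ci <- sample.int(H, 1); cj <- sample.int(W, 1)
    r <- sample(2:4, 1)
    lab <- sample(c(1L, 2L), 1)
    rows <- max(1, ci - r):min(H, ci + r)
    cols <- max(1, cj - r):min(W, cj + r)
    for (i in rows) for (j in cols) {
      if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- lab
    }
  }
  m
}

# quick patch spec for small test patches
small_spec <- function(..., cell_radius_range = c(3L, 4L),
                       min_cell_gap_px = 10L) {
  synthetic_patch_spec(height_px = 64L, width_px = 64L,
                       cell_radius_range = cell_radius_range,
                       min_cell_gap_px = min_cell_gap_px, ...)
}
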