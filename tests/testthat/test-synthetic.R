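test_that("generated patches carry exactly the requested cells", {
  p <- generate_patch(synthetic_patch_spec(
    256L, 256L, n_positive = 10L, n_negative = 40L,
    cell_radius_range = c(4L, 7L), min_cell_gap_px = 10L), seed = 1L)
  expect_identical(p$tally$n_positive, 10L)
  expect_identical(p$tally$n_negative, 40L)
  expect_equal(compute_tps(p$tally), 20.0)
  # mask agrees with the tally by construction (ground-truth closure)
  ct <- count_cells(p$mask)
  expect_identical(ct$n_positive, 10L)
  expect_identical(ct$n_negative, 40L)
})

test_that("an empty spec yields an all-zero mask", {
  p <- generate_patch(small_spec(), seed = 3L)
  expect_true(all(p$mask == 0L))
  expect_identical(p$tally$total, 0L)
})

test_that("identical spec and seed give bit-identical output", {
  spec <- small_spec(n_positive = 2L, n_negative = 2L, n_distractor = 1L)
  a <- generate_patch(spec, seed = 11L)
  b <- generate_patch(spec, seed = 11L)
  expect_identical(a, b)
  c <- generate_patch(spec, seed = 12L)
  expect_false(identical(a$image, c$image))
})

test_that("distractors are rendered but never labelled as tumour", {
  spec <- small_spec(n_positive = 0L, n_negative = 0L, n_distractor = 4L)
  p <- generate_patch(spec, seed = 5L)
  expect_true(all(p$mask == 0L))
  # they are visible: the image departs from plain background
  bg_only <- generate_patch(small_spec(), seed = 5L)
  expect_gt(sum(abs(p$image - bg_only$image)), 1)
})

test_that("infeasible packings raise a placement error, never truncate", {
  spec <- synthetic_patch_spec(64L, 64L, n_positive = 200L,
                               cell_radius_range = c(4L, 7L),
                               min_cell_gap_px = 10L)
  expect_error(generate_patch(spec, seed = 1L), class = "pdl1_packing_error")
})

test_that("ground-truth closure holds across random small patches", {
  for (seed in 1:8) {
    spec <- small_spec(n_positive = (seed %% 3L),
                       n_negative = ((seed + 1L) %% 3L),
                       n_distractor = 1L)
    p <- generate_patch(spec, seed = seed)
    ct <- count_cells(p$mask)
    expect_identical(ct$n_positive, spec$n_positive)
    expect_identical(ct$n_negative, spec$n_negative)
  }
})

test_that("cases sum patch tallies and recompute the TPS", {
  spec <- small_spec(n_positive = 1L, n_negative = 3L)
  cs <- generate_case(spec, n_patches = 4L, seed = 2L)
  expect_identical(cs$true_tally$n_positive, 4L)
  expect_identical(cs$true_tally$n_negative, 12L)
  expect_equal(cs$true_tps, 25.0)
  # single patch, no positives
  cs0 <- generate_case(small_spec(n_negative = 5L), n_patches = 1L, seed = 2L)
  expect_equal(cs0$true_tps, 0.0)
  # per-patch specs: (1,0) and (0,1) -> 50%
  cs2 <- generate_case(list(small_spec(n_positive = 1L),
                            small_spec(n_negative = 1L)), seed = 9L)
  expect_equal(cs2$true_tps, 50.0)
  # determinism
  expect_identical(generate_case(spec, 4L, seed = 2L), cs)
})

test_that("cohorts honour rounded category proportions and seeds", {
  base <- small_spec(cell_radius_range = c(3L, 4L), min_cell_gap_px = 9L)
  ch <- cohort_spec(n_cases = 10L, category_proportions = c(0.2, 0.4, 0.4),
                    per_case_patch_count = 2L, cells_per_patch = 4L,
                    patch_spec = base, seed = 4L)
  cases <- generate_cohort(ch)
  cats <- vapply(cases, function(cs) clinical_category(cs$true_tps), "")
  expect_identical(as.vector(table(factor(cats, c("<1%", "1-49%", ">=50%")))),
                   c(2L, 4L, 4L))
  expect_identical(generate_cohort(ch), cases)

  ch1 <- cohort_spec(n_cases = 1L, category_proportions = c(1, 0, 0),
                     per_case_patch_count = 2L, cells_per_patch = 4L,
                     patch_spec = base, seed = 4L)
  expect_lt(generate_cohort(ch1)[[1]]$true_tps, 1)
})

test_that("cohort proportions must sum to one", {
  expect_error(cohort_spec(5L, category_proportions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("written cases round-trip through PNG masks and JSON manifests", {
  dir <- withr::local_tempdir()
  cs <- generate_case(small_spec(n_positive = 2L, n_negative = 1L),
                      n_patches = 2L, seed = 6L, case_id = "t1")
  mf <- write_case(cs, dir)
  m <- jsonlite::fromJSON(mf)
  expect_identical(m$case_id, "t1")
  expect_identical(m$true_tally$n_positive, 2L * 2L)
  expect_equal(m$true_tps, cs$true_tps)
  mask_back <- read_mask(file.path(dir, m$masks[1]))
  expect_identical(mask_back, cs$patches[[1]]$mask)
  img_back <- read_image(file.path(dir, m$images[1]))
  expect_equal(img_back, cs$patches[[1]]$image, tolerance = 1 / 255)
})
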