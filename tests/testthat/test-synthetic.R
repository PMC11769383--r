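# Determinism, geometry and on-disk layout of the synthetic nucleus
# generator.

test_that("empty count range yields an empty sample", {
  spec <- synthetic_spec(n_range = c(0, 0), seed = 5)
  s <- generate_sample(spec, 1)
  expect_equal(max(s$mask), 0)
  expect_length(s$nuclei, 0)
  expect_length(s$nucleus_masks, 0)
})

test_that("samples are bit-identical for the same (seed, index)", {
  spec <- synthetic_spec(seed = 17)
  a <- generate_sample(spec, 3)
  b <- generate_sample(spec, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)

  # counter-based: generation order must not matter
  s5_first <- generate_sample(spec, 5)
  generate_sample(spec, 2)
  s5_again <- generate_sample(spec, 5)
  expect_identical(s5_first$image, s5_again$image)

  # different seeds diverge
  expect_false(identical(
    generate_sample(synthetic_spec(seed = 18), 3)$image, a$image))
})

test_that("counts, ranges and invariants hold across many samples", {
  spec <- synthetic_spec(size = 48, n_range = c(5, 10), radius = c(2, 5),
                         overlap = FALSE, seed = 23)
  counts <- integer(0)
  for (i in 1:200) {
    s <- generate_sample(spec, i)
    counts <- c(counts, length(s$nuclei))
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(s$mask %in% c(0, 1)))
    # union of per-nucleus masks equals the sample mask exactly
    u <- Reduce(`+`, s$nucleus_masks)
    expect_identical((u > 0) * 1, matrix(s$mask[1, , ], 48))
    # non-overlap: per-nucleus masks pairwise disjoint
    expect_true(all(u <= 1))
  }
  expect_true(all(counts >= 5 & counts <= 10))
  expect_gt(length(unique(counts)), 1)
})

test_that("foreground fraction responds monotonically to count and radius", {
  frac <- function(spec) {
    mean(vapply(1:100, function(i) mean(generate_sample(spec, i)$mask),
                numeric(1)))
  }
  base <- synthetic_spec(n_range = c(1, 3), radius = c(2, 5), seed = 31)
  more <- synthetic_spec(n_range = c(6, 10), radius = c(2, 5), seed = 31)
  bigger <- synthetic_spec(n_range = c(1, 3), radius = c(6, 10), seed = 31)
  f0 <- frac(base)
  expect_gt(f0, 0.005)           # small objects present, not empty
  expect_gt(frac(more), f0)
  expect_gt(frac(bigger), f0)
})

test_that("generator covers small and touching-object regimes", {
  small <- synthetic_spec(n_range = c(3, 3), radius = c(2, 2.5), seed = 41)
  areas <- unlist(lapply(1:50, function(i)
    vapply(generate_sample(small, i)$nucleus_masks, sum, numeric(1))))
  expect_lt(min(areas), 25)      # objects of a few pixels exist

  dense <- synthetic_spec(size = 48, n_range = c(12, 12), radius = c(4, 8),
                          overlap = TRUE, seed = 43)
  touched <- vapply(1:30, function(i) {
    s <- generate_sample(dense, i)
    sum(Reduce(`+`, s$nucleus_masks) > 1)
  }, numeric(1))
  expect_gt(mean(touched > 0), 0.5)   # overlapping pairs are common
})

test_that("dataset writer emits the Bowl layout and round-trips", {
  spec <- synthetic_spec(size = 32, n_range = c(1, 4), radius = c(2, 6),
                         seed = 53)
  out <- file.path(tempfile("synth_"), "ds")
  man <- generate_dataset(spec, 4, out)
  dirs <- list.dirs(out, recursive = FALSE)
  expect_length(dirs, 4L)
  for (d in dirs) {
    expect_length(dir(file.path(d, "images"), pattern = "\\.png$"), 1L)
    expect_true(dir.exists(file.path(d, "masks")))
  }
  expect_true(file.exists(file.path(out, "manifest.json")))

  handle <- load_bowl2018(out)
  expect_equal(handle$ids, sort(vapply(man$samples, `[[`, "", "id")))
  for (i in 1:4) {
    s <- dataset_get(handle, i)
    idx <- which(vapply(man$samples, `[[`, "", "id") == s$id)
    ref <- generate_sample(spec, idx)
    expect_identical(s$mask, ref$mask)   # masks round-trip exactly
    # 8-bit quantisation: images agree to 1/255
    expect_lt(max(abs(s$image - ref$image)), 1 / 255)
  }

  # refusal to overwrite a non-empty directory
  expect_error(generate_dataset(spec, 4, out), "not empty")
})

test_that("regenerating a dataset yields byte-identical PNGs", {
  spec <- synthetic_spec(size = 32, seed = 59)
  d1 <- file.path(tempfile("synth_"), "a")
  d2 <- file.path(tempfile("synth_"), "b")
  generate_dataset(spec, 3, d1)
  generate_dataset(spec, 3, d2)
  f1 <- sort(list.files(d1, recursive = TRUE, pattern = "\\.png$"))
  f2 <- sort(list.files(d2, recursive = TRUE, pattern = "\\.png$"))
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
})
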