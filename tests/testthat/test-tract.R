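test_that("density thresholding keeps exactly the fixels at/above threshold", {
  t <- fixel_template(array(c(4L, rep(0L, 7)), c(2, 2, 2)),
                      array(0L, c(2, 2, 2)),
                      matrix(rep(c(1, 0, 0), 4), ncol = 3, byrow = TRUE))
  d <- fixel_scalar(c(0, 0.2, 5, 1), t)
  m <- mask_from_density(d, t, threshold = 0.5, name = "X")
  expect_identical(m$fixel_indices, c(2L, 3L))

  # threshold at the smallest positive density keeps all positive fixels
  m2 <- mask_from_density(d, t, threshold = 0.2, name = "X")
  expect_identical(m2$fixel_indices, c(1L, 2L, 3L))

  expect_error(mask_from_density(d, t, threshold = 10, name = "X"),
               class = "fixelnorm_degenerate_mask_error")
  expect_error(mask_from_density(d, t, threshold = 0, name = "X"),
               class = "fixelnorm_parameter_error")
})

test_that("tract_mean is the arithmetic mean over the mask", {
  t <- tiny_template()
  m <- tract_mask("X", "L", 0:2, t)

  const <- fixel_scalar(rep(1, t$n_fixels), t)
  expect_identical(tract_mean(const, m), 1)

  vals <- numeric(t$n_fixels)
  vals[1:3] <- c(0.2, 0.4, 0.6)
  expect_equal(tract_mean(fixel_scalar(vals, t), m), 0.4)

  m01 <- tract_mask("Y", "L", 0:1, t)
  expect_equal(tract_mean(fixel_scalar(vals, t), m01), 0.3)

  empty <- tract_mask("Z", "L", integer(0), t)
  expect_error(tract_mean(const, empty),
               class = "fixelnorm_degenerate_mask_error")

  holey <- fixel_scalar(replace(vals, 2, NA), t, allow_missing = TRUE)
  expect_error(tract_mean(holey, m),
               class = "fixelnorm_missing_data_error")
})

test_that("tract_mean equals the brute-force oracle on random masks", {
  t <- tiny_template()
  set.seed(21)
  for (i in 1:25) {
    vals <- runif(t$n_fixels)
    fdc <- fixel_scalar(vals, t)
    idx <- sort(sample(0:(t$n_fixels - 1), sample(1:20, 1)))
    m <- tract_mask("X", "L", idx, t)
    expect_equal(tract_mean(fdc, m), sum(vals[idx + 1]) / length(idx))
  }
})

test_that("build_tract_matrix matches hand-computed means and orderings", {
  t <- tiny_template()
  v1 <- numeric(t$n_fixels); v1[1:4] <- c(1, 2, 3, 4)
  v2 <- numeric(t$n_fixels); v2[1:4] <- c(5, 6, 7, 8)
  fdc <- list(a = fixel_scalar(v1, t), b = fixel_scalar(v2, t))
  masks <- list(t1 = tract_mask("t1", "L", 0:1, t),
                t2 = tract_mask("t2", "R", 2:3, t))
  meta <- tibble::tibble(id = c("a", "b"), group = "control",
                         batch = "s1")
  tm <- build_tract_matrix(fdc, masks, meta)
  expect_equal(unname(tm$values),
               matrix(c(1.5, 3.5, 5.5, 7.5), 2, 2))
  expect_identical(tm$stage, "raw")

  # permuting the input list leaves values keyed by id unchanged
  tm2 <- build_tract_matrix(rev(fdc), masks, meta)
  expect_identical(tm$values, tm2$values)

  meta_dup <- tibble::tibble(id = c("a", "a"), group = "control",
                             batch = "s1")
  expect_error(build_tract_matrix(fdc, masks, meta_dup),
               class = "fixelnorm_assembly_error")
  meta_extra <- tibble::tibble(id = c("a", "b", "c"), group = "control",
                               batch = "s1")
  expect_error(build_tract_matrix(fdc, masks, meta_extra),
               class = "fixelnorm_assembly_error")
  expect_error(build_tract_matrix(fdc, masks, meta_extra), "c")
})

test_that("a noise-free cohort yields the baseline mean everywhere", {
  t <- tiny_template()
  masks <- make_tract_masks(t, seed = 6)
  spec <- cohort_spec(n_controls = 4, mu0 = 0.5, mu0_spread = 0, cv = 0,
                      fixel_noise = 0, seed = 2)
  sim <- simulate_cohort(t, spec)
  tm <- build_tract_matrix(sim$fdc, masks, sim$metadata)
  expect_equal(unname(tm$values),
               matrix(0.5, nrow(tm$values), ncol(tm$values)))
})

test_that("tract matrices round trip through CSV", {
  dir <- withr::local_tempdir()
  tm <- small_cohort_matrix(n_per_batch = 5, n_tracts = 4, seed = 3)
  path <- file.path(dir, "tm.csv")
  write_tract_matrix(tm, path)
  back <- read_tract_matrix(path)
  expect_equal(back$values, tm$values)
  expect_identical(back$tracts$hemisphere, tm$tracts$hemisphere)
  expect_identical(back$metadata$id, tm$metadata$id)
})

test_that("long tidy form carries metadata and stage", {
  tm <- small_cohort_matrix(n_per_batch = 3, n_tracts = 2, seed = 4)
  long <- tidy(tm)
  expect_identical(nrow(long), 2L * 6L)
  expect_true(all(c("tract", "hemisphere", "id", "value", "stage",
                    "group", "batch") %in% names(long)))
  expect_equal(long$value[long$tract == rownames(tm$values)[1] &
                            long$id == tm$metadata$id[2]],
               tm$values[1, 2])
})
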