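test_that("template generation is deterministic and validated", {
  t1 <- make_template(c(1, 1, 1), max_fixels_per_voxel = 1, fill = 1,
                      seed = 1)
  expect_identical(t1$n_fixels, 1L)

  a <- make_template(c(10, 10, 10), max_fixels_per_voxel = 3, fill = 0.5,
                     seed = 7)
  b <- make_template(c(10, 10, 10), max_fixels_per_voxel = 3, fill = 0.5,
                     seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$directions, b$directions)
  expect_identical(nrow(validate_template(a)), 0L)

  expect_error(make_template(c(5, 5, 5), fill = 0),
               class = "fixelnorm_parameter_error")
})

test_that("the standard tract set is 11 bilateral pairs plus the CC", {
  tr <- standard_tracts()
  expect_identical(nrow(tr), 23L)
  expect_identical(sum(tr$hemisphere == "midline"), 1L)
  expect_identical(tr$name[tr$hemisphere == "midline"], "CC")
  expect_identical(sum(tr$hemisphere == "L"), 11L)
  expect_identical(sum(tr$hemisphere == "R"), 11L)
})

test_that("tract masks are disjoint, hemisphere-paired and deterministic", {
  t <- make_template(c(12, 12, 12), max_fixels_per_voxel = 3, fill = 0.5,
                     seed = 3)
  masks <- make_tract_masks(t, seed = 5)
  expect_identical(length(masks), 23L)

  all_idx <- unlist(lapply(masks, `[[`, "fixel_indices"))
  expect_identical(anyDuplicated(all_idx), 0L)        # pairwise disjoint
  expect_true(all(all_idx >= 0 & all_idx < t$n_fixels))

  sizes <- vapply(masks, function(m) length(m$fixel_indices), 1L)
  bundles <- sub("_(left|right)$", "", names(masks))
  for (b in setdiff(unique(bundles), "CC")) {
    pair <- sizes[bundles == b]
    expect_identical(pair[[1]], pair[[2]])            # L/R equal size
  }

  masks2 <- make_tract_masks(t, seed = 5)
  expect_identical(lapply(masks, `[[`, "fixel_indices"),
                   lapply(masks2, `[[`, "fixel_indices"))

  tiny <- make_template(c(2, 2, 2), max_fixels_per_voxel = 1, fill = 0.5,
                        seed = 1)
  expect_error(make_tract_masks(tiny), class = "fixelnorm_capacity_error")
})

test_that("null site effects leave per-fixel batch differences at noise level", {
  t <- make_template(c(8, 8, 8), max_fixels_per_voxel = 2, fill = 0.5,
                     seed = 2)
  spec <- cohort_spec(n_controls = 90, batch_shift = c(0, 0),
                      batch_scale = c(1, 1), seed = 1)
  sim <- simulate_cohort(t, spec)
  stack <- fixel_stack(sim$fdc)
  in_a <- sim$metadata$batch == "siteA"
  p <- apply(stack, 1, function(v) t.test(v[in_a], v[!in_a])$p.value)
  expect_gte(mean(p >= 0.05), 0.95)   # n.s. for >= 95% of fixels
})

test_that("an additive site shift appears at the injected magnitude", {
  t <- make_template(c(8, 8, 8), max_fixels_per_voxel = 2, fill = 0.5,
                     seed = 2)
  spec <- cohort_spec(n_controls = 90, seed = 1)
  sigma <- spec$cv * spec$mu0
  spec_shift <- cohort_spec(n_controls = 90,
                            batch_shift = c(0, 0.3 * sigma), seed = 1)
  masks <- make_tract_masks(t, seed = 9)
  batch_diff <- function(spec) {
    sim <- simulate_cohort(t, spec)
    tmx <- build_tract_matrix(sim$fdc, masks, sim$metadata)
    in_a <- tmx$metadata$batch == "siteA"
    rowMeans(tmx$values[, !in_a]) - rowMeans(tmx$values[, in_a])
  }
  # identical seeds share every random draw, so the difference between the
  # shifted and unshifted cohorts isolates the injected site effect exactly
  excess <- batch_diff(spec_shift) - batch_diff(spec)
  expect_equal(unname(excess), rep(0.3 * sigma, length(excess)),
               tolerance = 1e-10)
  # and the shift is visible in the shifted cohort itself at roughly 0.3 sigma
  expect_equal(mean(batch_diff(spec_shift)), 0.3 * sigma, tolerance = 1)
})

test_that("cohort simulation is bit-identical under the same seed", {
  t <- tiny_template()
  s1 <- simulate_cohort(t, cohort_spec(n_controls = 10, seed = 99))
  s2 <- simulate_cohort(t, cohort_spec(n_controls = 10, seed = 99))
  expect_identical(s1$fdc$C001$values, s2$fdc$C001$values)
  expect_identical(s1$metadata, s2$metadata)
})

test_that("realized between-subject CV tracks the requested cv", {
  t <- make_template(c(8, 8, 8), max_fixels_per_voxel = 2, fill = 0.5,
                     seed = 4)
  masks <- make_tract_masks(t, seed = 4)
  cvs <- vapply(1:20, function(seed) {
    sim <- simulate_cohort(t, cohort_spec(n_controls = 45, cv = 0.1,
                                          seed = seed))
    tmx <- build_tract_matrix(sim$fdc, masks, sim$metadata)
    mean(apply(tmx$values, 1, sd) / rowMeans(tmx$values))
  }, numeric(1))
  expect_equal(mean(cvs), 0.1, tolerance = 0.15)
})

test_that("lesions are local, scaled and deterministic", {
  t <- tiny_template()
  masks <- make_tract_masks(t, seed = 2)
  m <- masks$AF_left
  ones <- fixel_scalar(rep(1, t$n_fixels), t)

  # null lesion is the identity
  l0 <- implant_lesion(ones, m, lesion_spec("AF_left", reduction = 0))
  expect_identical(l0$values, ones$values)

  # full lesion zeroes exactly the masked fixels
  l1 <- implant_lesion(ones, m, lesion_spec("AF_left", reduction = 1,
                                            extent = 1))
  expect_true(all(l1$values[m$fixel_indices + 1L] == 0))
  expect_true(all(l1$values[-(m$fixel_indices + 1L)] == 1))

  # 25% reduction over the whole mask moves the tract mean to 0.75
  l2 <- implant_lesion(ones, m, lesion_spec("AF_left", reduction = 0.25,
                                            extent = 1))
  expect_equal(tract_mean(l2, m), 0.75)

  # partial extent touches only the chosen fraction
  l3 <- implant_lesion(ones, m, lesion_spec("AF_left", reduction = 0.5,
                                            extent = 0.5, seed = 8))
  touched <- which(l3$values != 1) - 1L
  expect_true(all(touched %in% m$fixel_indices))
  expect_identical(length(touched),
                   as.integer(round(0.5 * length(m$fixel_indices))))

  expect_error(lesion_spec("AF_left", reduction = 0.5, extent = 0),
               class = "fixelnorm_parameter_error")
})
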