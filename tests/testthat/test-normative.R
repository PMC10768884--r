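test_that("control mean and SD use the n-1 divisor", {
  m <- matrix(c(0.4, 0.5, 0.6), 1, 3,
              dimnames = list("tr", c("c1", "c2", "c3")))
  model <- fit_normative(m)
  expect_equal(model$features$mu, 0.5)
  expect_equal(model$features$sigma, 0.1)
  expect_identical(model$n_controls, 3L)
})

test_that("constant features are excluded, not fatal", {
  m <- matrix(c(1, 1, 1, 0.2, 0.5, 0.8), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "ok"), c("a", "b", "c")))
  model <- fit_normative(m)
  expect_true(model$features$excluded[1])
  expect_identical(model$features$reason[1], "zero control variance")
  expect_false(model$features$excluded[2])

  rep <- z_report(model, c(flat = 1, ok = 0.5))
  expect_true(is.na(rep$scores$z[1]))
  expect_identical(rep$most_affected, "ok")
})

test_that("the normative fit is invariant to subject order", {
  tm <- small_cohort_matrix(n_per_batch = 10, n_tracts = 5, seed = 3)
  perm <- sample(ncol(tm$values))
  tm_perm <- tract_matrix(tm$values[, perm], tm$tracts,
                          tm$metadata[perm, ], stage = "raw")
  expect_equal(tidy(fit_normative(tm)), tidy(fit_normative(tm_perm)))
})

test_that("patient ids cannot enter the control list", {
  tm <- small_cohort_matrix(n_per_batch = 5, n_tracts = 3, seed = 4,
                            n_patients = 2)
  pat_id <- tm$metadata$id[tm$metadata$group == "patient"][1]
  expect_error(fit_normative(tm, control_ids = c(pat_id,
                                                 tm$metadata$id[1:5])),
               class = "fixelnorm_identity_error")
})

test_that("z-scores centre, scale and flag at the threshold", {
  tm <- small_cohort_matrix(n_per_batch = 10, n_tracts = 4, seed = 5)
  model <- fit_normative(tm)
  mu <- tidy(model)$mu

  rep0 <- z_report(model, setNames(mu, tidy(model)$feature))
  expect_equal(rep0$scores$z, rep(0, 4))
  expect_false(any(rep0$scores$abnormal))

  m1 <- fit_normative(matrix(c(0.4, 0.5, 0.6), 1, 3,
                             dimnames = list("tr", NULL)))
  r1 <- z_report(m1, c(tr = 0.304))
  expect_equal(r1$scores$z, -1.96, tolerance = 1e-12)
  expect_true(r1$scores$abnormal)
  r2 <- z_report(m1, c(tr = 0.305))
  expect_false(r2$scores$abnormal)

  expect_error(z_report(model, c(bogus = 1)),
               class = "fixelnorm_lookup_error")
})

test_that("laterality index follows its sign and symmetry conventions", {
  z <- c(A_left = -1, A_right = -1, B_left = -2, B_right = -2, CC = -3)
  h <- c(A_left = "L", A_right = "R", B_left = "L", B_right = "R",
         CC = "midline")
  expect_identical(laterality_index(z, h), 0)

  # L_sum -3, R_sum -1 -> (-2)/(-4) = 0.5; positive = left more abnormal
  z2 <- c(A_left = -3, A_right = -1)
  h2 <- c(A_left = "L", A_right = "R")
  expect_equal(laterality_index(z2, h2), 0.5)

  # swapping hemispheres negates the index
  h2_swap <- c(A_left = "R", A_right = "L")
  expect_equal(laterality_index(z2, h2_swap), -0.5)

  expect_error(laterality_index(c(a = 1, b = -1),
                                c(a = "L", b = "R")),
               class = "fixelnorm_undefined_index_error")
  expect_error(laterality_index(c(a = 1), c(a = "L")),
               class = "fixelnorm_parameter_error")

  # the CC never enters the sums when excluded (default)
  z3 <- c(A_left = -2, A_right = -1, CC = -100)
  h3 <- c(A_left = "L", A_right = "R", CC = "midline")
  expect_equal(laterality_index(z3, h3), (-2 + 1) / (-3))
})

test_that("LI antisymmetry under hemisphere swap holds for random z-maps", {
  set.seed(31)
  tr <- standard_tracts()
  for (i in 1:50) {
    z <- setNames(rnorm(23), tr$name)
    h <- setNames(tr$hemisphere, tr$name)
    h_swap <- setNames(dplyr::recode(h, L = "R", R = "L"), tr$name)
    li <- tryCatch(laterality_index(z, h), error = function(e) NA)
    li_swap <- tryCatch(laterality_index(z, h_swap),
                        error = function(e) NA)
    if (!is.na(li)) expect_equal(li_swap, -li)
  }
})

test_that("fixel z-maps equal the scalar z-score applied fixelwise", {
  set.seed(13)
  t <- make_template(c(10, 10, 10), max_fixels_per_voxel = 2, fill = 0.9,
                     seed = 40)
  stack2 <- matrix(rnorm(t$n_fixels * 20, 0.5, 0.05), t$n_fixels, 20)
  model2 <- fit_normative(stack2, stage_provenance = "raw")
  patient <- fixel_scalar(rnorm(t$n_fixels, 0.45, 0.05), t)
  zm <- fixel_zmap(model2, patient, t)
  oracle <- (patient$values - tidy(model2)$mu) / tidy(model2)$sigma
  expect_equal(zm$z$values, oracle)
  expect_identical(zm$mask$values, as.numeric(oracle <= -1.96))
})

test_that("fixel z-map boundary behaviour: null patient, lesion, threshold", {
  t <- make_template(c(6, 6, 6), max_fixels_per_voxel = 2, fill = 0.8,
                     seed = 41)
  set.seed(41)
  stack <- matrix(rnorm(t$n_fixels * 30, 0.5, 0.05), t$n_fixels, 30)
  model <- fit_normative(stack, stage_provenance = "raw")
  mu <- tidy(model)$mu
  sigma <- tidy(model)$sigma

  # patient at the control mean -> empty mask
  null_zm <- fixel_zmap(model, fixel_scalar(mu, t), t)
  expect_identical(sum(null_zm$mask$values), 0)

  # lesioned fixels at mu - 3 sigma land in the mask at z ~ -3
  lesion_idx <- 1:20
  vals <- mu
  vals[lesion_idx] <- mu[lesion_idx] - 3 * sigma[lesion_idx]
  zm <- fixel_zmap(model, fixel_scalar(vals, t), t)
  expect_true(all(zm$mask$values[lesion_idx] == 1))
  expect_equal(zm$z$values[lesion_idx], rep(-3, 20))

  # an unreachable threshold empties the mask
  zm_inf <- fixel_zmap(model, fixel_scalar(vals, t), t, threshold = -Inf)
  expect_identical(sum(zm_inf$mask$values), 0)

  other <- make_template(c(3, 3, 3), max_fixels_per_voxel = 1, fill = 1,
                         seed = 42)
  expect_error(fixel_zmap(model, fixel_scalar(rep(0.5, other$n_fixels),
                                              other), t),
               class = "fixelnorm_binding_error")
})

test_that("a lesioned tract is ranked most affected and usually flagged", {
  # 25% reduction against 10% between-subject CV through the full
  # harmonize -> INT(controls) -> z pipeline. The lesioned tract should
  # dominate the ranking almost always; the hard -1.96 flag has limited
  # power because the patient's own between-subject variability (still
  # 0.75 * CV after the lesion) propagates into the Z-score.
  hits <- flags <- logical(40)
  for (i in seq_len(40)) {
    tm <- small_cohort_matrix(n_per_batch = 45, shift = 0.02, seed = 100 + i,
                              n_patients = 1, cv = 0.1)
    pat <- which(tm$metadata$group == "patient")
    tm$values["AF_left", pat] <- tm$values["AF_left", pat] * 0.75
    harm <- apply_combat(tm, fit_combat(tm, fit_on = "controls"))
    ti <- int_transform(harm, scope = "controls_only")
    model <- fit_normative(ti)
    rep <- zscore_patients(ti, model)[[1]]
    flags[i] <- rep$scores$abnormal[rep$scores$feature == "AF_left"]
    hits[i] <- rep$most_affected == "AF_left"
  }
  expect_gte(mean(hits), 0.95)
  expect_gte(mean(flags), 0.6)
})
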