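#' Fit the normative control model
#'
#' Per-feature control mean and sample SD (divisor n - 1), computed across
#' the healthy control cohort, for tract features or fixel features alike.
#' Features with zero control variance are marked excluded (with a reason)
#' rather than crashing downstream Z-scoring.
#'
#' @param x A [tract_matrix()] or a features-by-subjects numeric matrix
#'   (rows may be fixels; `NA` rows are excluded).
#' @param control_ids Subject ids (or column names) defining the control
#'   set; defaults to `group == "control"` for a tract matrix, or all
#'   columns for a bare matrix.
#' @param ... Passed between methods.
#' @return An object of class `normative_model`: tibble-backed per-feature
#'   `mu`, `sigma`, exclusion flags, plus `n_controls` and
#'   `stage_provenance`.
#' @export
fit_normative <- function(x, control_ids = NULL, ...) {
  UseMethod("fit_normative")
}

#' @rdname fit_normative
#' @export
fit_normative.tract_matrix <- function(x, control_ids = NULL, ...) {
  if (is.null(control_ids)) {
    control_ids <- x$metadata$id[x$metadata$group == "control"]
  }
  patients <- x$metadata$id[x$metadata$group == "patient"]
  bad <- intersect(control_ids, patients)
  if (length(bad) > 0) {
    abort_fixelnorm(
      paste("patient ids in the control list:", paste(bad, collapse = ", ")),
      "fixelnorm_identity_error")
  }
  model <- fit_normative(x$values, control_ids = control_ids,
                         stage_provenance = x$stage)
  model$features <- dplyr::left_join(model$features,
                                     dplyr::rename(x$tracts,
                                                   feature = "name"),
                                     by = "feature")
  model
}

#' @rdname fit_normative
#' @param stage_provenance Processing stage of the values the model was
#'   fitted on (`"raw"`, `"harmonized"`, `"int"`).
#' @export
fit_normative.default <- function(x, control_ids = NULL,
                                  stage_provenance = "raw", ...) {
  x <- as.matrix(x)
  if (is.null(control_ids)) control_ids <- colnames(x)
  if (is.null(control_ids)) control_ids <- seq_len(ncol(x))
  ctrl <- x[, control_ids, drop = FALSE]
  n <- ncol(ctrl)
  if (n < 3) {
    abort_fixelnorm("normative model needs at least 3 controls",
                    "fixelnorm_data_error")
  }
  mu <- unname(rowMeans(ctrl))
  sigma <- unname(apply(ctrl, 1, sd))
  feature_ids <- rownames(x)
  if (is.null(feature_ids)) feature_ids <- as.character(seq_len(nrow(x)))
  excluded <- !is.finite(sigma) | sigma == 0 | !is.finite(mu)
  reason <- dplyr::case_when(
    !is.finite(mu) | !is.finite(sigma) ~ "missing control values",
    sigma == 0 ~ "zero control variance",
    TRUE ~ NA_character_)
  structure(list(
    features = tibble(feature = feature_ids, mu = mu, sigma = sigma,
                      excluded = excluded, reason = reason),
    n_controls = n,
    stage_provenance = stage_provenance
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model> ", nrow(x$features), " features, ",
      x$n_controls, " controls, stage: ", x$stage_provenance, "\n",
      sep = "")
  invisible(x)
}

#' @method tidy normative_model
#' @export
tidy.normative_model <- function(x, ...) x$features

#' @method glance normative_model
#' @export
glance.normative_model <- function(x, ...) {
  tibble(n_features = nrow(x$features),
         n_excluded = sum(x$features$excluded),
         n_controls = x$n_controls,
         stage_provenance = x$stage_provenance)
}

#' Score one patient against the normative model
#'
#' Computes `z = (x - mu) / sigma` per feature, flags abnormality where
#' `z <= z_threshold` (default -1.96; abnormality means reduced FDC, so
#' positive deviations are reported but never flagged), identifies the
#' most affected tract (minimum z; ties broken by feature order), and --
#' when hemisphere tags are available -- the hemispheric laterality index.
#'
#' @param model A `normative_model` with hemisphere-tagged features.
#' @param patient_values Named per-feature vector (names must match the
#'   model's features) for one subject.
#' @param subject_id Subject identifier recorded on the report.
#' @param z_threshold Abnormality threshold (default -1.96).
#' @param li_exclude_midline Exclude midline tracts (the corpus callosum)
#'   from the laterality sums (default TRUE).
#' @return An object of class `z_report`.
#' @export
z_report <- function(model, patient_values, subject_id = "patient",
                     z_threshold = -1.96, li_exclude_midline = TRUE) {
  stopifnot(inherits(model, "normative_model"))
  feats <- model$features
  if (!is.null(names(patient_values))) {
    missing <- setdiff(feats$feature, names(patient_values))
    if (length(missing) > 0) {
      abort_fixelnorm(
        paste("patient values missing features:",
              paste(missing, collapse = ", ")),
        "fixelnorm_lookup_error")
    }
    patient_values <- patient_values[feats$feature]
  } else if (length(patient_values) != nrow(feats)) {
    abort_fixelnorm("unnamed patient vector must align with the model",
                    "fixelnorm_lookup_error")
  }
  z <- ifelse(feats$excluded, NA_real_,
              (patient_values - feats$mu) / feats$sigma)
  scores <- tibble(
    feature = feats$feature,
    hemisphere = if ("hemisphere" %in% names(feats)) feats$hemisphere
                 else NA_character_,
    value = as.numeric(patient_values),
    z = as.numeric(z),
    abnormal = !is.na(z) & z <= z_threshold
  )
  ok <- which(!is.na(scores$z))
  most_affected <- if (length(ok)) scores$feature[ok[which.min(scores$z[ok])]]
                   else NA_character_
  li <- if (all(c("L", "R") %in% scores$hemisphere)) {
    tryCatch(
      laterality_index(setNames(scores$z, scores$feature),
                       setNames(scores$hemisphere, scores$feature),
                       exclude_midline = li_exclude_midline),
      fixelnorm_undefined_index_error = function(e) NA_real_)
  } else NA_real_
  structure(list(
    subject_id = subject_id, scores = scores, z_threshold = z_threshold,
    most_affected = most_affected, smallest_z = if (length(ok))
      min(scores$z[ok]) else NA_real_,
    li = li, stage_provenance = model$stage_provenance
  ), class = "z_report")
}

#' @export
print.z_report <- function(x, ...) {
  cat("<z_report> ", x$subject_id, ": most affected ", x$most_affected,
      " (z = ", format(x$smallest_z, digits = 3), "), LI = ",
      format(x$li, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy z_report
#' @export
tidy.z_report <- function(x, ...) {
  dplyr::mutate(x$scores, subject_id = x$subject_id, .before = 1)
}

#' @method glance z_report
#' @export
glance.z_report <- function(x, ...) {
  tibble(subject_id = x$subject_id, li = x$li,
         most_affected = x$most_affected, smallest_z = x$smallest_z,
         n_abnormal = sum(x$scores$abnormal, na.rm = TRUE),
         z_threshold = x$z_threshold,
         stage_provenance = x$stage_provenance)
}

#' Score every patient in a tract matrix
#'
#' Fits nothing: applies an existing normative model to each subject whose
#' metadata `group` is `"patient"`.
#'
#' @param tm A [tract_matrix()] at the same stage the model was fitted on.
#' @param model A `normative_model`.
#' @inheritParams z_report
#' @return Named list of `z_report` objects, one per patient.
#' @export
zscore_patients <- function(tm, model, z_threshold = -1.96,
                            li_exclude_midline = TRUE) {
  if (!identical(tm$stage, model$stage_provenance)) {
    warn(sprintf("matrix stage '%s' differs from model provenance '%s'",
                 tm$stage, model$stage_provenance))
  }
  patients <- tm$metadata$id[tm$metadata$group == "patient"]
  reports <- lapply(patients, function(p) {
    z_report(model, setNames(tm$values[, p], rownames(tm$values)),
             subject_id = p, z_threshold = z_threshold,
             li_exclude_midline = li_exclude_midline)
  })
  setNames(reports, patients)
}

#' Hemispheric laterality index of tract Z-scores
#'
#' `LI = (L_sum - R_sum) / (L_sum + R_sum)` over the per-hemisphere sums
#' of tract Z-scores. Because abnormality is a negative Z, positive LI
#' indicates greater left-hemisphere abnormality. Midline tracts (the
#' corpus callosum) belong to neither hemisphere and are excluded by
#' default. `|LI|` may exceed 1 when the two sums have opposite signs.
#'
#' @param z Named numeric vector of per-tract Z-scores.
#' @param hemispheres Named character vector (`"L"`, `"R"`, `"midline"`)
#'   aligned with `z` by name.
#' @param exclude_midline Drop midline tracts from the sums (default
#'   TRUE).
#' @return A single numeric laterality index.
#' @export
laterality_index <- function(z, hemispheres, exclude_midline = TRUE) {
  if (!is.null(names(z)) && !is.null(names(hemispheres))) {
    hemispheres <- hemispheres[names(z)]
  }
  keep <- !is.na(z)
  if (exclude_midline) keep <- keep & hemispheres != "midline"
  z <- z[keep]
  hemispheres <- hemispheres[keep]
  if (!any(hemispheres == "L") || !any(hemispheres == "R")) {
    abort_fixelnorm("need at least one left and one right tract",
                    "fixelnorm_parameter_error")
  }
  l_sum <- sum(z[hemispheres == "L"])
  r_sum <- sum(z[hemispheres == "R"])
  if (l_sum + r_sum == 0) {
    abort_fixelnorm("laterality index undefined: L_sum + R_sum = 0",
                    "fixelnorm_undefined_index_error")
  }
  (l_sum - r_sum) / (l_sum + r_sum)
}

#' Stack per-subject fixel fields into a fixels-by-subjects matrix
#'
#' @param fdc Named list of [fixel_scalar()] on a shared template.
#' @return Numeric matrix with one row per fixel, one column per subject.
#' @export
fixel_stack <- function(fdc) {
  ids <- names(fdc)
  tid <- unique(vapply(fdc, `[[`, "", "template_id"))
  if (length(tid) != 1) {
    abort_fixelnorm("fixel fields are bound to different templates",
                    "fixelnorm_binding_error")
  }
  m <- vapply(fdc, `[[`, numeric(length(fdc[[1]]$values)), "values")
  colnames(m) <- ids
  rownames(m) <- as.character(seq_len(nrow(m)) - 1L)  # 0-based fixel index
  attr(m, "template_id") <- tid
  m
}

#' Per-fixel Z-map for one patient
#'
#' Applies a fixel-level normative model (control mean and SD at each
#' template fixel) to one patient's FDC field: a Z-score per fixel, plus a
#' binary mask of fixels whose Z is at or below the threshold (FDC
#' reductions beyond -1.96 SD by default). Excluded fixels (zero control
#' variance) carry the missing sentinel `NA` in both outputs.
#'
#' @param model A `normative_model` fitted on a [fixel_stack()].
#' @param patient A [fixel_scalar()] bound to the same template.
#' @param template The [fixel_template()], for constructing the outputs.
#' @param threshold Mask threshold on z (default -1.96).
#' @return List with `z` and `mask`, both [fixel_scalar()] with
#'   missingness allowed.
#' @export
fixel_zmap <- function(model, patient, template, threshold = -1.96) {
  stopifnot(inherits(model, "normative_model"),
            inherits(patient, "fixel_scalar"))
  .check_bound(patient, template)
  if (nrow(model$features) != template$n_fixels) {
    abort_fixelnorm("model features do not match template fixel count",
                    "fixelnorm_binding_error")
  }
  mu <- model$features$mu
  sigma <- model$features$sigma
  z <- (patient$values - mu) / sigma
  z[model$features$excluded] <- NA_real_
  mask <- as.numeric(!is.na(z) & z <= threshold)
  mask[model$features$excluded] <- NA_real_
  list(z = fixel_scalar(z, template, allow_missing = TRUE),
       mask = fixel_scalar(mask, template, allow_missing = TRUE))
}

#' Leave-one-out control Z-scores for one feature
#'
#' For each control in turn: fit the INT mapping and the normative mean/SD
#' on the remaining controls, pass the held-out value through the mapping,
#' and Z-score it. Used to check the calibration of the single-subject
#' pipeline (the false-positive rate at a given threshold).
#'
#' @param values Control values for one feature.
#' @param offset_c Blom offset.
#' @return Numeric vector of leave-one-out Z-scores, one per control.
#' @export
loo_zscores <- function(values, offset_c = 3 / 8) {
  n <- length(values)
  vapply(seq_len(n), function(i) {
    fit <- fit_int(values[-i], offset_c = offset_c,
                   scope = "controls_only")
    t_ctrl <- fit$transformed
    t_pat <- transform_patient(fit$mapping, values[i])
    (t_pat - mean(t_ctrl)) / sd(t_ctrl)
  }, numeric(1))
}
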