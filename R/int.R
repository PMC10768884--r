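#' Shapiro-Wilk normality screen
#'
#' Tests normality of each tract's control distribution. The result is
#' advisory: the pipeline applies the rank-based inverse normal transform
#' regardless, and the report documents how far from Gaussian the raw
#' control distributions were.
#'
#' @param x A [tract_matrix()] (controls are selected from the `group`
#'   metadata column) or a numeric vector.
#' @param alpha Significance level for the `passed` flag (default 0.05).
#' @param ... Passed between methods.
#' @return Tibble with columns `feature`, `statistic`, `p_value`,
#'   `passed`.
#' @export
normality_check <- function(x, alpha = 0.05, ...) {
  UseMethod("normality_check")
}

#' @rdname normality_check
#' @param feature Feature label for the vector method.
#' @export
normality_check.numeric <- function(x, alpha = 0.05, feature = "feature",
                                    ...) {
  x <- as.numeric(x)
  if (length(x) < 3) {
    abort_fixelnorm("normality check needs at least 3 values",
                    "fixelnorm_data_error")
  }
  if (stats::sd(x) == 0) {
    abort_fixelnorm(
      sprintf("'%s' is constant; normality is undefined", feature),
      "fixelnorm_degenerate_distribution_error")
  }
  sw <- shapiro.test(x)
  tibble(feature = feature, statistic = unname(sw$statistic),
         p_value = sw$p.value, passed = sw$p.value >= alpha)
}

#' @rdname normality_check
#' @export
normality_check.tract_matrix <- function(x, alpha = 0.05, ...) {
  ctrl <- which(x$metadata$group == "control")
  purrr::map_dfr(rownames(x$values), function(tr) {
    normality_check(x$values[tr, ctrl], alpha = alpha, feature = tr)
  })
}

#' Rank-based inverse normal transform (Blom)
#'
#' Maps each value to the normal quantile of its offset-adjusted midrank:
#' `qnorm((r - c) / (n - 2c + 1))` with `r` the midrank and `c` the Blom
#' offset (default 3/8). Ties receive midranks. The output preserves input
#' order; the fitted mapping retains the sorted reference values so that
#' out-of-sample values (patients) can be passed through the same mapping
#' with [transform_patient()].
#'
#' @param values Numeric vector, `n >= 3`, all finite.
#' @param offset_c Blom-type offset in `[0, 0.5)`.
#' @param scope `"joint"` if the fit included patients, `"controls_only"`
#'   if fitted on controls alone (recorded on the mapping).
#' @param feature Feature label.
#' @return List with `mapping` (class `int_mapping`) and `transformed`
#'   (numeric vector in input order).
#' @export
fit_int <- function(values, offset_c = 3 / 8, scope = "controls_only",
                    feature = "feature") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    abort_fixelnorm("INT input contains non-finite values",
                    "fixelnorm_data_error")
  }
  if (length(values) < 3) {
    abort_fixelnorm("INT needs at least 3 values", "fixelnorm_data_error")
  }
  if (!(offset_c >= 0 && offset_c < 0.5)) {
    abort_fixelnorm("offset_c must be in [0, 0.5)",
                    "fixelnorm_parameter_error")
  }
  scope <- match.arg(scope, c("controls_only", "joint"))
  n <- length(values)
  r <- rank(values, ties.method = "average")
  transformed <- qnorm((r - offset_c) / (n - 2 * offset_c + 1))
  mapping <- structure(
    list(feature = feature, control_values = sort(values),
         n = n, offset_c = offset_c, scope = scope),
    class = "int_mapping")
  list(mapping = mapping, transformed = transformed)
}

#' @export
print.int_mapping <- function(x, ...) {
  cat("<int_mapping> ", x$feature, ", n = ", x$n, ", c = ", x$offset_c,
      ", scope = ", x$scope, "\n", sep = "")
  invisible(x)
}

#' Pass an out-of-sample value through a fitted INT mapping
#'
#' The patient value receives the pseudo-midrank
#' `r* = #(reference < value) + 0.5 * #(reference == value) + 0.5` among
#' the `n` reference (control) values, and is mapped to
#' `qnorm((r* - c) / (n - 2c + 1))`. The result is non-decreasing in the
#' value and bounded by the mapping's extreme quantiles plus/minus one
#' rank step.
#'
#' @param mapping An `int_mapping` fitted with `scope = "controls_only"`.
#' @param value Numeric value(s) to transform.
#' @return Transformed value(s), standard-normal scale.
#' @export
transform_patient <- function(mapping, value) {
  stopifnot(inherits(mapping, "int_mapping"))
  if (mapping$scope != "controls_only") {
    abort_fixelnorm(
      "transform_patient requires a mapping fitted on controls only",
      "fixelnorm_parameter_error")
  }
  if (any(!is.finite(value))) {
    abort_fixelnorm("cannot transform non-finite values",
                    "fixelnorm_data_error")
  }
  cv <- mapping$control_values
  n <- mapping$n
  c0 <- mapping$offset_c
  vapply(value, function(v) {
    r_star <- sum(cv < v) + 0.5 * sum(cv == v) + 0.5
    qnorm((r_star - c0) / (n - 2 * c0 + 1))
  }, numeric(1))
}

#' Apply the INT stage to a tract matrix
#'
#' With `scope = "joint"` (default) each tract's transform is fitted on
#' the full available column, controls and patients together, mirroring a
#' column-wise transform of the combined table. With
#' `scope = "controls_only"` the mapping is fitted on controls and patient
#' values are passed through it with [transform_patient()] -- the
#' statistically safer choice when patients carry large pathology.
#'
#' @param tm A [tract_matrix()] (stage `"raw"` or `"harmonized"`).
#' @param scope `"joint"` or `"controls_only"`.
#' @param offset_c Blom offset (default 3/8).
#' @return A [tract_matrix()] at stage `"int"`, with the fitted mappings
#'   attached as `$int_mappings` and the mode recorded as `$int_scope`.
#' @export
int_transform <- function(tm, scope = c("joint", "controls_only"),
                          offset_c = 3 / 8) {
  stopifnot(inherits(tm, "tract_matrix"))
  scope <- match.arg(scope)
  ctrl <- which(tm$metadata$group == "control")
  pat <- setdiff(seq_len(ncol(tm$values)), ctrl)
  values <- tm$values
  mappings <- list()
  for (tr in rownames(values)) {
    if (scope == "joint") {
      fit <- fit_int(values[tr, ], offset_c = offset_c, scope = "joint",
                     feature = tr)
      values[tr, ] <- fit$transformed
    } else {
      fit <- fit_int(values[tr, ctrl], offset_c = offset_c,
                     scope = "controls_only", feature = tr)
      values[tr, ctrl] <- fit$transformed
      if (length(pat) > 0) {
        values[tr, pat] <- transform_patient(fit$mapping, values[tr, pat])
      }
    }
    mappings[[tr]] <- fit$mapping
  }
  out <- tract_matrix(values, tm$tracts, tm$metadata, stage = "int")
  out$int_mappings <- mappings
  out$int_scope <- scope
  out
}
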