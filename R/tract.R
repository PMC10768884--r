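#' Tract fixel mask
#'
#' A named subset of template fixels belonging to one white-matter bundle,
#' tagged with its hemisphere (`"L"`, `"R"`, or `"midline"` for the corpus
#' callosum).
#'
#' @param name Tract label, e.g. `"AF_left"`.
#' @param hemisphere One of `"L"`, `"R"`, `"midline"`.
#' @param fixel_indices 0-based indices into the template fixel list.
#' @param template The [fixel_template()] the mask lives on.
#' @return An object of class `tract_mask`.
#' @export
tract_mask <- function(name, hemisphere, fixel_indices, template) {
  hemisphere <- match.arg(hemisphere, c("L", "R", "midline"))
  fixel_indices <- sort(unique(as.integer(fixel_indices)))
  if (length(fixel_indices) > 0 &&
      (min(fixel_indices) < 0 || max(fixel_indices) >= template$n_fixels)) {
    abort_fixelnorm(
      sprintf("mask '%s' has fixel indices outside [0, %d)",
              name, template$n_fixels),
      "fixelnorm_binding_error")
  }
  structure(list(name = name, hemisphere = hemisphere,
                 fixel_indices = fixel_indices,
                 template_id = template$id),
            class = "tract_mask")
}

#' @export
print.tract_mask <- function(x, ...) {
  cat("<tract_mask> ", x$name, " (", x$hemisphere, "), ",
      length(x$fixel_indices), " fixels\n", sep = "")
  invisible(x)
}

#' Binarize a streamline-density fixel image into a tract mask
#'
#' Tract delineations arrive as per-fixel streamline densities (the output
#' of mapping a bundle's streamlines onto the fixel template); the binary
#' tract mask contains every fixel whose density is at or above the
#' threshold. The default threshold of 1 requires at least one streamline.
#'
#' @param density A [fixel_scalar()] of non-negative streamline densities.
#' @param template The [fixel_template()] the density is bound to.
#' @param threshold Inclusion threshold (fixels with `density >= threshold`
#'   are kept); must be > 0.
#' @param name Tract label for the resulting mask.
#' @param hemisphere Hemisphere tag.
#' @return A [tract_mask()].
#' @export
mask_from_density <- function(density, template, threshold = 1,
                              name = "tract", hemisphere = "midline") {
  stopifnot(inherits(density, "fixel_scalar"))
  .check_bound(density, template)
  if (threshold <= 0) {
    abort_fixelnorm("threshold must be > 0", "fixelnorm_parameter_error")
  }
  idx <- which(density$values >= threshold) - 1L
  if (length(idx) == 0L) {
    abort_fixelnorm(
      sprintf("tract '%s': no fixel reaches density threshold %g",
              name, threshold),
      "fixelnorm_degenerate_mask_error")
  }
  tract_mask(name, hemisphere, idx, template)
}

#' Mean FDC within a tract mask
#'
#' The arithmetic mean of the per-fixel values over the mask's fixels.
#' Missing values inside the mask are an error, never silently skipped:
#' dropping fixels would change the estimand.
#'
#' @param fdc A [fixel_scalar()].
#' @param mask A [tract_mask()] on the same template.
#' @return A single numeric value.
#' @export
tract_mean <- function(fdc, mask) {
  stopifnot(inherits(fdc, "fixel_scalar"), inherits(mask, "tract_mask"))
  if (length(mask$fixel_indices) == 0L) {
    abort_fixelnorm(sprintf("mask '%s' is empty", mask$name),
                    "fixelnorm_degenerate_mask_error")
  }
  if (!identical(fdc$template_id, mask$template_id)) {
    abort_fixelnorm("mask and FDC field are bound to different templates",
                    "fixelnorm_binding_error")
  }
  vals <- fdc$values[mask$fixel_indices + 1L]
  if (anyNA(vals)) {
    abort_fixelnorm(
      sprintf("mask '%s' contains %d missing FDC values",
              mask$name, sum(is.na(vals))),
      "fixelnorm_missing_data_error")
  }
  mean(vals)
}

#' Tracts-by-subjects feature matrix
#'
#' Container for the central tabular object of the pipeline: mean FDC per
#' tract and subject, together with per-subject metadata and a `stage`
#' marker that tracks the processing provenance (`raw` -> `harmonized` ->
#' `int`).
#'
#' @param values Numeric matrix, tracts x subjects, with dimnames.
#' @param tracts Tibble with columns `name`, `hemisphere` in row order.
#' @param metadata Tibble with an `id` column matching the matrix columns,
#'   plus `group`, `batch` and any covariates.
#' @param stage One of `"raw"`, `"harmonized"`, `"int"`.
#' @return An object of class `tract_matrix`.
#' @export
tract_matrix <- function(values, tracts, metadata, stage = "raw") {
  stage <- match.arg(stage, c("raw", "harmonized", "int"))
  stopifnot(is.matrix(values),
            nrow(values) == nrow(tracts),
            ncol(values) == nrow(metadata))
  if (anyDuplicated(metadata$id)) {
    abort_fixelnorm("duplicate subject ids", "fixelnorm_assembly_error")
  }
  if (anyDuplicated(tracts$name)) {
    abort_fixelnorm("duplicate tract names", "fixelnorm_assembly_error")
  }
  if (!all(is.finite(values))) {
    abort_fixelnorm("tract matrix values must be finite",
                    "fixelnorm_data_error")
  }
  dimnames(values) <- list(tracts$name, metadata$id)
  structure(list(values = values, tracts = tibble::as_tibble(tracts),
                 metadata = tibble::as_tibble(metadata), stage = stage),
            class = "tract_matrix")
}

#' @export
print.tract_matrix <- function(x, ...) {
  cat("<tract_matrix> ", nrow(x$values), " tracts x ", ncol(x$values),
      " subjects, stage: ", x$stage, "\n", sep = "")
  invisible(x)
}

#' @method as_tibble tract_matrix
#' @export
as_tibble.tract_matrix <- function(x, ...) {
  long <- tibble(
    tract = rep(rownames(x$values), times = ncol(x$values)),
    hemisphere = rep(x$tracts$hemisphere, times = ncol(x$values)),
    id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    stage = x$stage
  )
  dplyr::left_join(long, x$metadata, by = "id")
}

#' Tidy a tract matrix into a long tibble
#'
#' @param x A [tract_matrix()].
#' @param ... Unused.
#' @return Long tibble with one row per tract x subject, metadata joined.
#' @method tidy tract_matrix
#' @export
tidy.tract_matrix <- function(x, ...) as_tibble.tract_matrix(x)

#' Assemble the tracts-by-subjects mean-FDC matrix
#'
#' Entry `(t, s)` is [tract_mean()] of subject `s`'s FDC field over mask
#' `t`. Ordering is deterministic: tracts as given, subjects as in the
#' metadata table.
#'
#' @param subject_fdc Named list of [fixel_scalar()], names are subject
#'   ids.
#' @param masks Named list of [tract_mask()].
#' @param metadata Tibble with columns `id`, `group`, `batch`, plus
#'   optional covariates; every id must have an FDC field.
#' @return A [tract_matrix()] at stage `"raw"`.
#' @export
build_tract_matrix <- function(subject_fdc, masks, metadata) {
  metadata <- tibble::as_tibble(metadata)
  if (anyDuplicated(metadata$id)) {
    abort_fixelnorm(
      paste("duplicate subject ids:",
            paste(unique(metadata$id[duplicated(metadata$id)]),
                  collapse = ", ")),
      "fixelnorm_assembly_error")
  }
  missing_ids <- setdiff(metadata$id, names(subject_fdc))
  if (length(missing_ids) > 0) {
    abort_fixelnorm(
      paste("subjects missing an FDC field:",
            paste(missing_ids, collapse = ", ")),
      "fixelnorm_assembly_error")
  }
  tracts <- tibble(
    name = vapply(masks, `[[`, "", "name"),
    hemisphere = vapply(masks, `[[`, "", "hemisphere")
  )
  values <- matrix(NA_real_, nrow = length(masks), ncol = nrow(metadata))
  for (ti in seq_along(masks)) {
    for (si in seq_len(nrow(metadata))) {
      values[ti, si] <- tract_mean(subject_fdc[[metadata$id[si]]],
                                   masks[[ti]])
    }
  }
  tract_matrix(values, tracts, metadata, stage = "raw")
}

#' Write a tract matrix as delimited text
#'
#' Wide form: tracts as rows, subjects as columns, with a sidecar metadata
#' CSV next to it.
#'
#' @param tm A [tract_matrix()].
#' @param path Output CSV path; metadata goes to `*_metadata.csv`.
#' @return `path`, invisibly.
#' @export
write_tract_matrix <- function(tm, path) {
  df <- data.frame(tract = rownames(tm$values),
                   hemisphere = tm$tracts$hemisphere,
                   tm$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  write.csv(tm$metadata,
            sub("\\.csv$", "_metadata.csv", path), row.names = FALSE)
  invisible(path)
}

#' Read a tract matrix written by [write_tract_matrix()]
#'
#' @param path CSV path (wide form, `tract` + `hemisphere` columns first).
#' @param metadata_path Sidecar metadata CSV; defaults to
#'   `*_metadata.csv`.
#' @param stage Stage tag to attach.
#' @return A [tract_matrix()].
#' @export
read_tract_matrix <- function(path,
                              metadata_path = sub("\\.csv$",
                                                  "_metadata.csv", path),
                              stage = "raw") {
  df <- read.csv(path, check.names = FALSE)
  meta <- tibble::as_tibble(read.csv(metadata_path))
  values <- as.matrix(df[, setdiff(names(df), c("tract", "hemisphere")),
                         drop = FALSE])
  meta <- meta[match(colnames(values), meta$id), ]
  tract_matrix(values,
               tibble(name = df$tract, hemisphere = df$hemisphere),
               meta, stage = stage)
}
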