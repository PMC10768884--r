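#' Fixel template
#'
#' The shared geometry all per-fixel data in an analysis is defined on: a
#' 3-D voxel grid where each voxel holds zero or more fixels (distinct
#' fibre populations with their own orientations). The template stores the
#' per-voxel fixel count, the offset of each voxel's first fixel in the
#' global fixel list, and one unit direction per fixel. All per-subject
#' data files (FDC, Z-maps, masks) are flat vectors indexed by this list.
#'
#' @param counts 3-D integer array of per-voxel fixel counts.
#' @param offsets 3-D integer array of 0-based start indices into the fixel
#'   list (ignored for voxels with count 0).
#' @param directions `n_fixels` x 3 matrix of unit direction vectors.
#' @param vox Voxel size in mm (length 3).
#' @param transform 3x4 voxel-to-scanner affine, carried opaquely.
#' @return An object of class `fixel_template`.
#' @export
fixel_template <- function(counts, offsets, directions, vox = c(1, 1, 1),
                           transform = NULL) {
  counts <- as.array(counts)
  offsets <- as.array(offsets)
  stopifnot(length(dim(counts)) == 3L, identical(dim(counts), dim(offsets)))
  directions <- matrix(as.numeric(directions), ncol = 3)
  if (is.null(transform)) transform <- cbind(diag(3), c(0, 0, 0))
  t <- structure(
    list(
      grid_dims = dim(counts),
      counts = counts,
      offsets = offsets,
      n_fixels = nrow(directions),
      directions = directions,
      vox = rep_len(as.numeric(vox), 3L),
      transform = transform
    ),
    class = "fixel_template"
  )
  t$id <- .template_id(t)
  t
}

# cheap structural fingerprint used to bind scalars to their template
.template_id <- function(t) {
  sig <- sum(as.numeric(t$counts) * seq_along(t$counts)) %% 1e9 +
    if (t$n_fixels > 0) sum(abs(t$directions)) else 0
  sprintf("fx%d-%s", t$n_fixels, format(sig, digits = 12))
}

#' @export
print.fixel_template <- function(x, ...) {
  cat("<fixel_template> grid ", paste(x$grid_dims, collapse = "x"),
      ", ", x$n_fixels, " fixels\n", sep = "")
  invisible(x)
}

#' Per-fixel scalar field
#'
#' One value per template fixel for one subject: FDC (unitless), a Z-score
#' (SD units), a binary mask, or a streamline density. Values must be
#' finite unless `allow_missing` is set (missingness encoded as NA).
#'
#' @param values Numeric vector of length `template$n_fixels`.
#' @param template The [fixel_template()] the values are defined on.
#' @param allow_missing Permit NA values (used for excluded fixels in
#'   Z-maps).
#' @return An object of class `fixel_scalar`.
#' @export
fixel_scalar <- function(values, template, allow_missing = FALSE) {
  stopifnot(inherits(template, "fixel_template"))
  values <- as.numeric(values)
  if (length(values) != template$n_fixels) {
    abort_fixelnorm(
      sprintf("scalar has %d values but template has %d fixels",
              length(values), template$n_fixels),
      "fixelnorm_binding_error")
  }
  bad <- if (allow_missing) sum(is.infinite(values) | is.nan(values))
         else sum(!is.finite(values))
  if (bad > 0) {
    abort_fixelnorm(
      sprintf("%d non-finite fixel values (missing values %s)", bad,
              if (allow_missing) "must be NA" else "not allowed"),
      "fixelnorm_data_error")
  }
  structure(list(values = values, template_id = template$id),
            class = "fixel_scalar")
}

#' @export
print.fixel_scalar <- function(x, ...) {
  cat("<fixel_scalar> ", length(x$values), " fixels on ", x$template_id,
      "\n", sep = "")
  invisible(x)
}

.check_bound <- function(scalar, template) {
  if (!identical(scalar$template_id, template$id)) {
    abort_fixelnorm("scalar is not bound to this template",
                    "fixelnorm_binding_error")
  }
}

#' Validate a fixel template
#'
#' Structural validation: the fixel count total must match the direction
#' list, per-voxel `[offset, offset + count)` ranges must be disjoint and
#' in range, and directions must have unit norm (tolerance 1e-4).
#' Validation never raises; it reports.
#'
#' @param template A [fixel_template()].
#' @return A tibble with columns `check` and `message`, one row per
#'   violation; zero rows iff the template satisfies every invariant.
#' @export
validate_template <- function(template) {
  out <- list()
  add <- function(check, message) {
    out[[length(out) + 1L]] <<- tibble(check = check, message = message)
  }
  counts <- as.vector(template$counts)
  offsets <- as.vector(template$offsets)
  n <- template$n_fixels

  if (any(counts < 0)) add("counts", "negative fixel count")
  if (sum(counts) != n) {
    add("counts",
        sprintf("sum of counts (%d) != n_fixels (%d)", sum(counts), n))
  }
  occ <- which(counts > 0)
  starts <- offsets[occ]
  ends <- starts + counts[occ]   # exclusive
  if (length(occ) > 0) {
    if (any(starts < 0) || any(ends > n)) {
      add("offsets", "fixel range outside [0, n_fixels)")
    }
    ord <- order(starts)
    if (length(occ) > 1 &&
        any(starts[ord][-1] < ends[ord][-length(ord)])) {
      add("offsets", "overlapping per-voxel fixel ranges")
    }
  }
  if (n > 0) {
    norms <- sqrt(rowSums(template$directions^2))
    n_bad <- sum(abs(norms - 1) > 1e-4)
    if (n_bad > 0) {
      add("directions", sprintf("%d non-unit direction vectors", n_bad))
    }
  }
  if (length(out) == 0) {
    tibble(check = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read a fixel directory
#'
#' A fixel directory holds an `index` image (4-D, last axis length 2: the
#' per-voxel count volume then the offset volume), a `directions` file
#' (`n_fixels` x 3) and zero or more per-fixel data files (`n_fixels` x 1),
#' whose file names (minus extension) become scalar names.
#'
#' @param dir Directory path.
#' @param ext Image file extension (default `"mif"`).
#' @return A list with elements `template` (a validated [fixel_template()])
#'   and `scalars` (named list of [fixel_scalar()]).
#' @export
read_fixel_directory <- function(dir, ext = "mif") {
  index_path <- file.path(dir, paste0("index.", ext))
  dirs_path <- file.path(dir, paste0("directions.", ext))
  if (!file.exists(index_path) || !file.exists(dirs_path)) {
    abort_fixelnorm(
      sprintf("fixel directory %s lacks index.%s or directions.%s",
              dir, ext, ext),
      "fixelnorm_format_error")
  }
  index <- read_raster(index_path)
  if (length(index$dims) != 4L || index$dims[4] != 2L) {
    abort_fixelnorm("index image must be 4-D with last axis length 2",
                    "fixelnorm_format_error")
  }
  counts <- array(index$values[, , , 1], dim = index$dims[1:3])
  offsets <- array(index$values[, , , 2], dim = index$dims[1:3])
  dirs_img <- read_raster(dirs_path)
  n_fixels <- if (length(dirs_img$dims) >= 1) dirs_img$dims[1] else 0L
  directions <- matrix(as.vector(dirs_img$values), nrow = n_fixels)
  if (ncol(directions) != 3L && n_fixels > 0) {
    abort_fixelnorm("directions file must be n_fixels x 3",
                    "fixelnorm_format_error")
  }
  template <- fixel_template(counts, offsets, directions,
                             vox = index$vox[1:3],
                             transform = index$transform)
  report <- validate_template(template)
  if (nrow(report) > 0) {
    abort_fixelnorm(
      paste0("invalid fixel template in ", dir, ": ",
             paste(report$message, collapse = "; ")),
      "fixelnorm_format_error")
  }

  files <- setdiff(list.files(dir, pattern = paste0("\\.", ext, "$")),
                   c(paste0("index.", ext), paste0("directions.", ext)))
  scalars <- list()
  for (f in files) {
    img <- read_raster(file.path(dir, f))
    vals <- as.vector(img$values)
    vals[is.nan(vals)] <- NA_real_   # NaN is the on-disk missing sentinel
    if (length(vals) != template$n_fixels) {
      abort_fixelnorm(
        sprintf("data file %s has %d values but template has %d fixels",
                f, length(vals), template$n_fixels),
        "fixelnorm_binding_error")
    }
    name <- sub(paste0("\\.", ext, "$"), "", f)
    scalars[[name]] <- fixel_scalar(vals, template, allow_missing = TRUE)
  }
  list(template = template, scalars = scalars[order(names(scalars))])
}

#' Write a fixel directory
#'
#' Inverse of [read_fixel_directory()]: writes the index and directions
#' images plus one data file per named scalar. The index image is written
#' as 32-bit unsigned integers, data files as 32-bit little-endian floats.
#'
#' @param template A [fixel_template()].
#' @param scalars Named list of [fixel_scalar()] bound to `template`.
#' @param dir Output directory (created if absent).
#' @param ext Image file extension.
#' @param datatype Element type for the per-fixel data files; 32-bit floats
#'   are the interchange default, `"Float64LE"` preserves doubles exactly.
#' @return `dir`, invisibly.
#' @export
write_fixel_directory <- function(template, scalars = list(), dir,
                                  ext = "mif", datatype = "Float32LE") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- array(c(as.vector(template$counts), as.vector(template$offsets)),
               dim = c(template$grid_dims, 2L))
  write_raster(
    raster_image(idx, vox = c(template$vox, 1), datatype = "UInt32LE",
                 transform = template$transform),
    file.path(dir, paste0("index.", ext)))
  write_raster(
    raster_image(array(template$directions,
                       dim = c(template$n_fixels, 3L)),
                 datatype = "Float64LE",
                 transform = template$transform),
    file.path(dir, paste0("directions.", ext)))
  for (name in names(scalars)) {
    s <- scalars[[name]]
    .check_bound(s, template)
    write_raster(
      raster_image(array(s$values, dim = c(template$n_fixels, 1L)),
                   datatype = datatype,
                   transform = template$transform),
      file.path(dir, paste0(name, ".", ext)))
  }
  invisible(dir)
}

#' Export a per-fixel scalar as delimited text
#'
#' @param scalar A [fixel_scalar()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixel_csv <- function(scalar, path) {
  write.csv(data.frame(fixel = seq_along(scalar$values) - 1L,
                       value = scalar$values),
            path, row.names = FALSE)
  invisible(path)
}
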