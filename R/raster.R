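#' Raster image carrier
#'
#' An in-memory representation of the ASCII-header raster format used by
#' fixel-based analysis pipelines: a text header of `key: value` lines
#' (magic line, `dim`, `vox`, `layout`, `datatype`, three `transform` rows,
#' a `file: . <offset>` directive and an `END` sentinel) followed by a raw
#' binary payload. Unrecognized header keys are carried verbatim, in order,
#' so that files written by other tools round-trip untouched.
#'
#' @param values Numeric array (1--4 axes) of voxel values in image axis
#'   order.
#' @param vox Voxel size in mm per axis (recycled to the number of axes).
#' @param datatype Element type tag; one of [raster_datatypes()].
#' @param transform 3x4 voxel-to-scanner affine, carried opaquely.
#' @param extras Data frame with columns `key`, `value` of extra header
#'   lines to preserve (may contain repeated keys).
#'
#' @return An object of class `raster_image` with fields `dims`, `vox`,
#'   `layout` (signed 0-based axis permutation), `datatype`, `transform`,
#'   `extras` and `values`.
#' @seealso [read_raster()], [write_raster()]
#' @export
raster_image <- function(values, vox = 1, datatype = "Float32LE",
                         transform = NULL,
                         extras = data.frame(key = character(),
                                             value = character())) {
  values <- as.array(values)
  dims <- dim(values)
  if (length(dims) < 1L || length(dims) > 4L) {
    abort_fixelnorm("raster images must have 1-4 axes",
                    "fixelnorm_format_error")
  }
  if (!datatype %in% raster_datatypes()) {
    abort_fixelnorm(
      sprintf("unsupported datatype '%s'", datatype),
      "fixelnorm_capability_error")
  }
  if (is.null(transform)) {
    transform <- cbind(diag(3), c(0, 0, 0))
  }
  stopifnot(is.matrix(transform), nrow(transform) == 3, ncol(transform) == 4)
  structure(
    list(
      dims = as.integer(dims),
      vox = rep_len(as.numeric(vox), length(dims)),
      layout = seq_along(dims) - 1L,
      datatype = datatype,
      transform = transform,
      extras = extras,
      values = values
    ),
    class = "raster_image"
  )
}

#' Supported raster element types
#'
#' @return Character vector of datatype tags understood by the reader and
#'   writer (8-bit unsigned plus 32/64-bit signed integer and float in both
#'   endiannesses).
#' @export
raster_datatypes <- function() {
  c("UInt8", "Int32LE", "Int32BE", "UInt32LE", "UInt32BE",
    "Float32LE", "Float32BE", "Float64LE", "Float64BE")
}

.dtype_info <- function(datatype) {
  switch(datatype,
    UInt8     = list(what = "integer", size = 1L, endian = "little", signed = FALSE),
    Int32LE   = list(what = "integer", size = 4L, endian = "little", signed = TRUE),
    Int32BE   = list(what = "integer", size = 4L, endian = "big",    signed = TRUE),
    UInt32LE  = list(what = "integer", size = 4L, endian = "little", signed = TRUE),
    UInt32BE  = list(what = "integer", size = 4L, endian = "big",    signed = TRUE),
    Float32LE = list(what = "double",  size = 4L, endian = "little", signed = TRUE),
    Float32BE = list(what = "double",  size = 4L, endian = "big",    signed = TRUE),
    Float64LE = list(what = "double",  size = 8L, endian = "little", signed = TRUE),
    Float64BE = list(what = "double",  size = 8L, endian = "big",    signed = TRUE),
    abort_fixelnorm(sprintf("unsupported datatype '%s'", datatype),
                    "fixelnorm_capability_error")
  )
}

.raster_magic <- "mrtrix image"
.recognized_keys <- c("dim", "vox", "layout", "datatype", "transform", "file")

#' Read a raster image
#'
#' Decodes a file in the ASCII-header raster format. The header must carry
#' the magic line, `dim`, `layout`, `datatype` and a `file: . <offset>`
#' data-offset directive; `vox` and `transform` default to unit voxels and
#' an identity affine when absent. Header keys the format does not define
#' are preserved verbatim and in order in `$extras`.
#'
#' @param path Path to the image file.
#' @return A [raster_image()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    abort_fixelnorm(sprintf("file does not exist: %s", path),
                    "fixelnorm_format_error")
  }
  n_bytes <- file.size(path)
  raw <- readBin(path, "raw", n = n_bytes)
  header <- .parse_raster_header(raw, path)

  info <- .dtype_info(header$datatype)
  n_vals <- prod(header$dims)
  need <- header$offset + n_vals * info$size
  if (need > n_bytes) {
    abort_fixelnorm(
      sprintf("truncated data section in %s: need %d bytes, file has %d",
              path, need, n_bytes),
      "fixelnorm_size_error")
  }
  con <- rawConnection(raw[seq.int(header$offset + 1L, need)])
  on.exit(close(con), add = TRUE)
  buf <- readBin(con, info$what, n = n_vals, size = info$size,
                 endian = info$endian, signed = info$signed)
  values <- .delayout(buf, header$dims, header$layout)

  img <- raster_image(values, vox = header$vox, datatype = header$datatype,
                      transform = header$transform, extras = header$extras)
  img
}

.parse_raster_header <- function(raw, path) {
  end_pat <- charToRaw("\nEND\n")
  limit <- min(length(raw), 65536L)
  end_at <- NA_integer_
  nl <- which(raw[seq_len(limit)] == as.raw(10L))
  for (i in nl) {
    if (i + 4L <= length(raw) && identical(raw[i:(i + 4L)], end_pat)) {
      end_at <- i
      break
    }
  }
  if (is.na(end_at)) {
    abort_fixelnorm(sprintf("no END sentinel found in header of %s", path),
                    "fixelnorm_format_error")
  }
  txt <- rawToChar(raw[seq_len(end_at - 1L)])
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L || trimws(lines[1]) != .raster_magic) {
    abort_fixelnorm(sprintf("missing magic line in %s", path),
                    "fixelnorm_format_error")
  }
  kv <- lapply(lines[-1], function(ln) {
    m <- regmatches(ln, regexec("^([^:]+):\\s?(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      abort_fixelnorm(sprintf("garbled header line '%s' in %s", ln, path),
                      "fixelnorm_format_error")
    }
    c(key = trimws(m[2]), value = m[3])
  })
  keys <- vapply(kv, `[[`, "", "key")
  vals <- vapply(kv, `[[`, "", "value")

  get1 <- function(key, required = TRUE) {
    hit <- which(keys == key)
    if (length(hit) == 0L) {
      if (required) {
        abort_fixelnorm(
          sprintf("header of %s lacks required key '%s'", path, key),
          "fixelnorm_format_error")
      }
      return(NULL)
    }
    vals[hit[1]]
  }
  num_list <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])

  dims <- as.integer(num_list(get1("dim")))
  layout_raw <- strsplit(get1("layout"), ",", fixed = TRUE)[[1]]
  layout <- vapply(layout_raw, function(tok) {
    tok <- trimws(tok)
    sign <- if (startsWith(tok, "-")) -1L else 1L
    sign * (abs(as.integer(gsub("[+-]", "", tok))))
  }, integer(1), USE.NAMES = FALSE)
  # signed permutation check: |layout| must be 0..k-1 exactly once each
  if (!setequal(abs(layout), seq_along(dims) - 1L) ||
      anyDuplicated(abs(layout))) {
    abort_fixelnorm(sprintf("layout of %s is not a signed axis permutation",
                            path), "fixelnorm_format_error")
  }
  datatype <- get1("datatype")
  if (!datatype %in% raster_datatypes()) {
    abort_fixelnorm(sprintf("unsupported datatype '%s' in %s", datatype, path),
                    "fixelnorm_capability_error")
  }
  file_dir <- get1("file")
  fm <- regmatches(file_dir, regexec("^\\.\\s+(\\d+)$", trimws(file_dir)))[[1]]
  if (length(fm) != 2L) {
    abort_fixelnorm(
      sprintf("malformed data-offset directive 'file: %s' in %s",
              file_dir, path),
      "fixelnorm_format_error")
  }
  offset <- as.integer(fm[2])

  vox_raw <- get1("vox", required = FALSE)
  vox <- if (is.null(vox_raw)) rep(1, length(dims)) else num_list(vox_raw)
  trows <- which(keys == "transform")
  transform <- if (length(trows) == 3L) {
    do.call(rbind, lapply(vals[trows], num_list))
  } else {
    cbind(diag(3), c(0, 0, 0))
  }

  extra_idx <- which(!(keys %in% .recognized_keys))
  extras <- data.frame(key = keys[extra_idx], value = vals[extra_idx],
                       stringsAsFactors = FALSE)

  list(dims = dims, vox = rep_len(vox, length(dims)), layout = layout,
       datatype = datatype, transform = transform, extras = extras,
       offset = offset)
}

# map a flat buffer in stored (layout) order onto an array in image order
.delayout <- function(buf, dims, layout) {
  k <- length(dims)
  ap <- abs(layout) + 1L
  s <- array(buf, dim = dims[ap])
  for (p in seq_len(k)) {
    if (layout[p] < 0L) {
      idx <- rep(list(quote(expr = )), k)
      idx[[p]] <- rev(seq_len(dim(s)[p]))
      s <- do.call(`[`, c(list(s), idx, list(drop = FALSE)))
    }
  }
  if (k > 1L) s <- aperm(s, order(ap))
  array(s, dim = dims)
}

#' Write a raster image
#'
#' Serializes a [raster_image()] in the ASCII-header raster format with the
#' default ascending axis layout. Reading the file back reproduces values
#' bit-exactly and preserves all header keys, including extras. NaN values
#' are representable and written as-is; semantic validation of the payload
#' is the caller's responsibility.
#'
#' @param img A [raster_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  info <- .dtype_info(img$datatype)

  fmt_num <- function(x) {
    vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                                 trim = TRUE), "")
  }
  lines <- c(
    .raster_magic,
    paste0("dim: ", paste(img$dims, collapse = ",")),
    paste0("vox: ", paste(fmt_num(img$vox), collapse = ",")),
    paste0("layout: ", paste(sprintf("%+d", img$layout), collapse = ",")),
    paste0("datatype: ", img$datatype),
    vapply(1:3, function(r) {
      paste0("transform: ", paste(fmt_num(img$transform[r, ]), collapse = ","))
    }, "")
  )
  if (nrow(img$extras) > 0L) {
    lines <- c(lines,
               paste0(img$extras$key, ": ", img$extras$value))
  }
  # data offset depends on its own printed width; iterate to a fixed point
  offset <- 0L
  for (i in 1:4) {
    trailer <- sprintf("file: . %d\nEND\n", offset)
    new_offset <- nchar(paste0(paste(lines, collapse = "\n"), "\n", trailer),
                        type = "bytes")
    if (new_offset == offset) break
    offset <- new_offset
  }
  header <- paste0(paste(lines, collapse = "\n"), "\n",
                   sprintf("file: . %d\nEND\n", offset))

  vals <- as.vector(img$values)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(header), con)
  if (info$what == "integer") {
    writeBin(as.integer(vals), con, size = info$size, endian = info$endian)
  } else {
    writeBin(as.double(vals), con, size = info$size, endian = info$endian)
  }
  invisible(path)
}

#' @export
print.raster_image <- function(x, ...) {
  cat("<raster_image> ", paste(x$dims, collapse = "x"),
      " ", x$datatype, "\n", sep = "")
  invisible(x)
}
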