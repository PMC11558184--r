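#' Write a voxel volume to disk
#'
#' Two formats are supported. `"tiff_stack"` writes a multi-page TIFF
#' with one page per flow-axis slice (inlet slice first) plus a JSON
#' sidecar (`<path>.json`) carrying the voxel size, origin and binary
#' flag, since TIFF tags do not round-trip physical metadata through the
#' reader used here. `"nrrd"` writes a single NRRD0004 file with raw
#' little-endian encoding (`uint8` for masks, `double` for grayscale);
#' spacing and origin travel in the header.
#'
#' @param vol A [voxel_volume()].
#' @param path Output file path.
#' @param format `"nrrd"` (default) or `"tiff_stack"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("nrrd", "tiff_stack")) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "voxel_volume"))
  binary <- is.logical(vol$grid)
  d <- dim(vol$grid)
  if (format == "tiff_stack") {
    pages <- lapply(seq_len(d[3]), function(k) {
      m <- vol$grid[, , k]
      storage.mode(m) <- "double"
      t(m) # tiff convention: rows = image rows (y), columns = x
    })
    tiff::writeTIFF(pages, path, bits.per.sample = if (binary) 8L else 32L)
    meta <- list(
      voxel_um = vol$voxel_um, origin_mm = vol$origin_mm,
      dims = d, binary = binary, axis_order = "x,y,z (inlet slice first)"
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  } else {
    sp_mm <- vol$voxel_um / 1000
    header <- c(
      "NRRD0004",
      "# fiberclot voxel volume",
      sprintf("type: %s", if (binary) "uint8" else "double"),
      "dimension: 3",
      sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
      sprintf("spacings: %.9g %.9g %.9g", sp_mm, sp_mm, sp_mm),
      sprintf(
        "axis mins: %.9g %.9g %.9g",
        vol$origin_mm[1], vol$origin_mm[2], vol$origin_mm[3]
      ),
      "encoding: raw",
      "endian: little",
      ""
    )
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    if (binary) {
      writeBin(as.integer(vol$grid), con, size = 1L, endian = "little")
    } else {
      writeBin(as.double(vol$grid), con, size = 8L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a voxel volume from disk
#'
#' Counterpart of [write_volume()]; see there for the on-disk layout.
#' Anisotropic voxel spacings are rejected.
#'
#' @param path File path.
#' @param format `"nrrd"` or `"tiff_stack"`; guessed from the extension
#'   when missing.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
      "nrrd"
    } else {
      "tiff_stack"
    }
  }
  format <- match.arg(format, c("nrrd", "tiff_stack"))
  if (format == "tiff_stack") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("missing voxel-size sidecar: ", sidecar, call. = FALSE)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- as.integer(meta$dims)
    grid <- array(0, d)
    for (k in seq_len(d[3])) grid[, , k] <- t(pages[[k]])
    if (isTRUE(meta$binary)) grid <- array(grid > 0.5, d)
    voxel_volume(grid, meta$voxel_um, as.numeric(meta$origin_mm))
  } else {
    read_nrrd(path)
  }
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-5]$", magic)) {
    stop("not an NRRD file (bad magic line): ", path, call. = FALSE)
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- strsplit(line, ": ", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed NRRD header line: ", line, call. = FALSE)
    fields[[kv[1]]] <- kv[2]
  }
  need <- c("type", "dimension", "sizes", "spacings", "encoding")
  missing <- setdiff(need, names(fields))
  if (length(missing)) {
    stop("NRRD header missing field(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (fields$dimension != "3") stop("only 3D NRRD supported", call. = FALSE)
  if (fields$encoding != "raw") stop("only raw encoding supported", call. = FALSE)
  d <- as.integer(strsplit(fields$sizes, " ")[[1]])
  sp <- as.numeric(strsplit(fields$spacings, " ")[[1]])
  if (max(sp) - min(sp) > 1e-12 * max(sp)) {
    stop("anisotropic voxels are not supported", call. = FALSE)
  }
  origin <- if (!is.null(fields[["axis mins"]])) {
    as.numeric(strsplit(fields[["axis mins"]], " ")[[1]])
  } else {
    c(0, 0, 0)
  }
  n <- prod(d)
  grid <- switch(fields$type,
    uint8 = array(readBin(con, "integer", n, size = 1L, signed = FALSE,
      endian = "little") > 0, d),
    double = array(readBin(con, "double", n, size = 8L, endian = "little"), d),
    stop("unsupported NRRD type: ", fields$type, call. = FALSE)
  )
  voxel_volume(grid, sp[1] * 1000, origin)
}

#' Write or read a resistance series as CSV
#'
#' The CSV dialect has columns `time_min`, `dp_mmhg`, `q_ml_min`,
#' `resistance`, `ln_resistance` (plus any extra columns present).
#'
#' @param series A `resistance_series` tibble.
#' @param path CSV file path.
#' @return `write_resistance_csv()` returns `path` invisibly;
#'   `read_resistance_csv()` returns the series tibble.
#' @export
write_resistance_csv <- function(series, path) {
  stopifnot(is.data.frame(series))
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_resistance_csv
#' @export
read_resistance_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("resistance_series", class(out))
  out
}

#' Write a chamber spec to a JSON description file
#'
#' Round-trips losslessly through [read_chamber_spec()].
#'
#' @param spec A [chamber_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chamber_spec <- function(spec, path) {
  stopifnot(inherits(spec, "chamber_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chamber_spec
#' @export
read_chamber_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  chamber_spec(
    pd = as.numeric(x$pd), path_length_mm = as.numeric(x$path_length_mm),
    width_mm = as.numeric(x$width_mm), height_mm = as.numeric(x$height_mm),
    fiber_um = as.numeric(x$fiber_um), lattice = x$lattice
  )
}
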