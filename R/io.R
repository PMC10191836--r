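# File I/O: MRC (mode 2, 32-bit float) for micrographs and volumes,
# 16-bit TIFF for micrographs, CSV for traces/profiles, STAR for
# particle tables.  The MRC and STAR readers are deliberately minimal:
# they cover the subset of each format this package writes and the
# common output of single-particle pipelines.

#' Write an image or volume as MRC (mode 2)
#'
#' @param x a \code{\link{micrograph}} or \code{\link{density_volume}}.
#' @param path output file path.
#' @export
write_mrc <- function(x, path) {
  if (inherits(x, "micrograph")) {
    dat <- as.numeric(t(x$values))            # x fastest
    dims <- c(ncol(x$values), nrow(x$values), 1L)
    apix <- x$pixel_size_nm * 10
  } else if (inherits(x, "density_volume")) {
    dat <- as.numeric(x$values)
    dims <- dim(x$values)
    apix <- x$voxel_size_A
  } else stopf("write_mrc needs a micrograph or density_volume")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(dims); wi(2L); wi(c(0L, 0L, 0L)); wi(dims)
  wf(dims * apix); wf(c(90, 90, 90)); wi(c(1L, 2L, 3L))
  wf(c(min(dat), max(dat), mean(dat)))
  wi(c(0L, 0L))                                # ispg, nsymbt
  wi(rep(0L, 25L))                             # extra
  wf(c(0, 0, 0))                               # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(stats::sd(dat))
  wi(0L)                                       # nlabl
  writeBin(raw(800L), con)                     # labels
  wf(dat)
  invisible(path)
}

#' Read an MRC image or volume
#'
#' Reads 32-bit float (mode 2), 16-bit signed (mode 1) or 8-bit (mode 0)
#' MRC files.  Single-section files are returned as micrographs, stacks
#' and maps as density volumes.
#'
#' @param path MRC file path.
#' @return a \code{\link{micrograph}} (nz = 1) or
#'   \code{\link{density_volume}}.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  dims <- ri(3L); mode <- ri(1L); ri(3L); mxyz <- ri(3L)
  cella <- rf(3L); rf(3L); ri(3L); rf(3L); ri(2L)
  seek(con, 1024L)
  n <- prod(dims)
  dat <- switch(as.character(mode),
                "0" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
                "1" = as.numeric(readBin(con, "integer", n, size = 2L,
                                         signed = TRUE, endian = "little")),
                "2" = rf(n),
                stopf("unsupported MRC mode %d", mode))
  apix <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  if (dims[3] == 1L) {
    micrograph(t(matrix(dat, nrow = dims[1], ncol = dims[2])),
               pixel_size_nm = apix / 10)
  } else {
    density_volume(array(dat, dim = dims), voxel_size_A = apix)
  }
}

#' Write a micrograph as 16-bit TIFF
#'
#' Intensities are min-max scaled onto the 16-bit range; the physical
#' pixel size is not stored, so prefer MRC when calibration matters.
#'
#' @param x a \code{\link{micrograph}}.
#' @param path output path.
#' @export
write_tiff16 <- function(x, path) {
  stopifnot(inherits(x, "micrograph"))
  v <- x$values
  rng <- range(v)
  v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a micrograph image file
#'
#' Dispatches on extension: \code{.mrc} via \code{\link{read_mrc}},
#' \code{.tif}/\code{.tiff} via the tiff package (pixel size must then
#' be supplied).
#'
#' @param path input path.
#' @param pixel_size_nm pixel size for formats that do not store one.
#' @return a \code{\link{micrograph}}.
#' @export
read_micrograph <- function(path, pixel_size_nm = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mrc") {
    m <- read_mrc(path)
    if (!inherits(m, "micrograph")) stopf("%s is a volume, not an image", path)
    if (!is.null(pixel_size_nm)) m$pixel_size_nm <- pixel_size_nm
    m
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(pixel_size_nm)) stopf("pixel_size_nm required for TIFF input")
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    micrograph(v, pixel_size_nm)
  } else stopf("unsupported image format: .%s", ext)
}

#' Read and write particle tables as STAR
#'
#' Minimal STAR support for flat particle tables: one data block with a
#' \code{loop_} of \code{_rln...}-style column labels.  All columns are
#' read; numeric-looking columns are converted.
#'
#' @param df data frame of particle records.
#' @param path file path.
#' @param block data block name (written as \code{data_<block>}).
#' @return \code{read_star} returns a data frame.
#' @export
write_star <- function(df, path, block = "particles") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 6, format = "f") else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  writeLines(apply(fmt, 1L, paste, collapse = "  "), con)
  invisible(path)
}

#' @rdname write_star
#' @export
read_star <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) stopf("no loop_ block in %s", path)
  i <- loop_at[1] + 1L
  labels <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    labels <- c(labels, sub("^_", "", strsplit(lines[i], "[[:space:]]+")[[1]][1]))
    i <- i + 1L
  }
  rows <- lines[seq.int(i, length(lines))]
  rows <- rows[!startsWith(rows, "data_") & rows != "loop_"]
  parts <- strsplit(rows, "[[:space:]]+")
  ok <- lengths(parts) == length(labels)
  parts <- parts[ok]
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- labels
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}

#' Read and write filament traces as CSV
#'
#' Traces are two-column tables of 0-based pixel coordinates (x, y).
#'
#' @param trace a \code{\link{filament_trace}} or plain data frame.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(x = trace$x, y = trace$y), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  filament_trace(df$x, df$y)
}

#' Read and write axial profiles as CSV
#'
#' @param profile an \code{\link{axial_profile}}.
#' @param path file path.
#' @param unit unit tag applied on read.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path, unit = "intensity") {
  df <- utils::read.csv(path)
  axial_profile(df[[1]], df[[2]], unit = unit)
}
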