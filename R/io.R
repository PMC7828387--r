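#' Read a time-lapse stack from TIFF
#'
#' Reads a single-channel multi-page TIFF, or a directory of ordered
#' single-page TIFFs, into an [image_stack()].  Frame order follows page
#' order (or lexicographic file order for a directory).  Acquisition
#' metadata (`frame_interval`, `pixel_size`) is taken from the arguments,
#' never guessed from TIFF tags.
#'
#' @param path a TIFF file or a directory containing `.tif`/`.tiff` files.
#' @param dtype_policy `"float"` converts integer payloads to double
#'   (the default); `"preserve"` keeps the values exactly as stored (both
#'   are held in R doubles; the policy matters only for integer-valued
#'   payloads, which `"preserve"` leaves un-rescaled too).
#' @param frame_interval,pixel_size metadata forwarded to [image_stack()].
#' @return An [image_stack()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, dtype_policy = c("float", "preserve"),
                       frame_interval = 1.0, pixel_size = NA_real_) {
  dtype_policy <- match.arg(dtype_policy)
  if (!file.exists(path))
    stop(sprintf("input not found: '%s'", path), call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0)
      stop(sprintf("no TIFF files in directory '%s'", path), call. = FALSE)
    pages <- unlist(lapply(files, function(f)
      tiff::readTIFF(f, all = TRUE, as.is = (dtype_policy == "preserve"))),
      recursive = FALSE)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE,
                            as.is = (dtype_policy == "preserve"))
    if (!is.list(pages)) pages <- list(pages)
  }
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) {
      if (dim(pg)[3] == 1L) {
        pages[[k]] <- pg[, , 1]
      } else {
        stop(sprintf("page %d is multi-channel (%d channels); only grayscale stacks are supported",
                     k, dim(pg)[3]), call. = FALSE)
      }
    }
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop(sprintf("inconsistent frame shapes: page %d is %s, page 1 is %s",
                 which(shapes != shapes[1])[1],
                 shapes[which(shapes != shapes[1])[1]], shapes[1]),
         call. = FALSE)
  if (length(pages) < 2L)
    stop("a stack needs at least 2 frames", call. = FALSE)
  image_stack(pages, frame_interval = frame_interval, pixel_size = pixel_size)
}

#' Write a stack as a multi-page 32-bit float TIFF
#'
#' One TIFF page per frame, stored as uncompressed IEEE 32-bit float
#' samples so that arbitrary non-negative intensities round-trip through
#' [read_stack()] without rescaling (bit-exact for values representable in
#' single precision).
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  check_stack(stack, min_frames = 1L)
  if (any(stack$frames < 0))
    stop("intensities must be >= 0", call. = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("directory does not exist: '%s'", dir), call. = FALSE)
  frames <- lapply(seq_len(n_frames(stack)), function(k) stack$frames[k, , ])
  write_tiff_float32(frames, path)
  invisible(path)
}

# Minimal multi-page uncompressed 32-bit IEEE-float grayscale TIFF writer
# (little-endian).  Needed because no installed writer stores float samples
# of arbitrary range losslessly; readers (including tiff::readTIFF) handle
# SampleFormat = IEEEFP.
write_tiff_float32 <- function(frames, path) {
  m <- nrow(frames[[1]]); n <- ncol(frames[[1]])
  npages <- length(frames)
  bytes_per_page <- 4L * m * n
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  # layout: 8-byte header | page data blocks | IFD chain
  data_off <- 8L + (seq_len(npages) - 1L) * bytes_per_page
  ifd_base <- 8L + npages * bytes_per_page
  ifd_off <- ifd_base + (seq_len(npages) - 1L) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off[1], con, size = 4, endian = "little")
  for (k in seq_len(npages)) {
    # TIFF stores rows contiguously: write row-major (transpose of R's
    # column-major matrix)
    writeBin(as.numeric(t(frames[[k]])), con, size = 4, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT: value left-justified in 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {          # LONG
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_len(npages)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, n)                 # ImageWidth
    entry(257L, 4L, 1L, m)                 # ImageLength
    entry(258L, 3L, 1L, 32L)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression = none
    entry(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
    entry(273L, 4L, 1L, data_off[k])       # StripOffsets
    entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
    entry(278L, 4L, 1L, m)                 # RowsPerStrip (one strip)
    entry(279L, 4L, 1L, bytes_per_page)    # StripByteCounts
    entry(339L, 3L, 1L, 3L)                # SampleFormat = IEEE float
    next_off <- if (k < npages) ifd_off[k + 1L] else 0L
    writeBin(next_off, con, size = 4, endian = "little")
  }
  invisible(path)
}
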