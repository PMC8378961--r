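#' Canonical 2-D grayscale image
#'
#' The package-wide image container: a numeric matrix of intensities in the
#' canonical range \[0,1\] plus the bit depth of the source the pixels came
#' from (8 or 16).  Quantization back to integer gray levels happens only at
#' I/O and metric boundaries.
#'
#' @param pixels numeric matrix of intensities
#' @param source_depth bits per sample of the originating format (8 or 16)
#' @param clip if `TRUE`, clip values into \[0,1\] instead of erroring
#' @return an object of class `image_gray`
#' @export
image_gray <- function(pixels, source_depth = 8L, clip = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_shape("pixels must be a numeric matrix")
  if (!all(is.finite(pixels)))
    abort_param("image contains non-finite values")
  if (clip) {
    pixels[pixels < 0] <- 0
    pixels[pixels > 1] <- 1
  } else if (min(pixels) < 0 || max(pixels) > 1) {
    abort_param("image values must lie in [0,1] (use clip = TRUE to clip)")
  }
  if (!source_depth %in% c(8L, 16L))
    abort_param("source_depth must be 8 or 16")
  structure(list(pixels = pixels, source_depth = as.integer(source_depth)),
            class = "image_gray")
}

#' @export
print.image_gray <- function(x, ...) {
  cat(sprintf("<image_gray %d x %d, %d-bit source, range [%.4f, %.4f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$source_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_gray <- function(x) dim(x$pixels)

as_pixels <- function(img) {
  if (inherits(img, "image_gray")) img$pixels
  else if (is.matrix(img)) img
  else abort_shape("expected an image_gray or a numeric matrix")
}

#' BT.601 luma from a (H, W, 3+) array
#' @noRd
luma_601 <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

#' Load an image from disk
#'
#' PNG files (8/16-bit; grayscale, gray+alpha, RGB or RGBA, where color is
#' converted to luma with BT.601 weights 0.299/0.587/0.114) yield a single
#' [image_gray].  NIfTI-1 volumes (`.nii` / `.nii.gz`) are treated as stacks
#' of axial slices and yield a list of [image_gray], one per slice, jointly
#' rescaled to \[0,1\] over the whole volume.
#'
#' @param path path to a `.png`, `.nii` or `.nii.gz` file
#' @return an [image_gray] (PNG) or a list of them (NIfTI)
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    abort_io(sprintf("cannot read '%s': no such file", path))
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    r <- cpp_read_png(path.expand(path))
    px <- r$pixels
    m <- if (r$channels >= 3) luma_601(px) else px[, , 1]
    depth <- if (r$depth == 16) 16L else 8L
    image_gray(m, source_depth = depth, clip = TRUE)
  } else if (grepl("\\.nii$", lower) || grepl("\\.nii\\.gz$", lower)) {
    v <- read_nifti(path)
    lapply(seq_len(dim(v)[3]), function(k)
      image_gray(v[, , k], source_depth = 16L, clip = TRUE))
  } else {
    abort_format(sprintf("unsupported image extension for '%s' (need .png, .nii or .nii.gz)", path))
  }
}

#' Save an image to disk as PNG
#'
#' @param img an [image_gray] or numeric matrix in \[0,1\]
#' @param path output path ending in `.png`
#' @param depth output bit depth, 8 or 16 (defaults to the image's source depth)
#' @return `path`, invisibly
#' @export
save_image <- function(img, path, depth = NULL) {
  if (!grepl("\\.png$", tolower(path)))
    abort_format(sprintf("unsupported output extension for '%s' (need .png)", path))
  m <- as_pixels(img)
  if (is.null(depth))
    depth <- if (inherits(img, "image_gray")) img$source_depth else 8L
  if (!depth %in% c(8L, 16L)) abort_param("depth must be 8 or 16")
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(sprintf("output directory '%s' does not exist", dir))
  cpp_write_png_gray(path.expand(path), m, as.integer(depth))
  invisible(path)
}

# ---- minimal NIfTI-1 support (single-file .nii, optionally gzipped) --------

nifti_dtypes <- list(`2` = "uint8", `4` = "int16", `8` = "int32",
                     `16` = "float32", `64` = "float64", `512` = "uint16")

#' Read a NIfTI-1 volume
#'
#' Minimal reader for single-file NIfTI-1 (`.nii`, `.nii.gz`): handles
#' uint8/int16/int32/uint16/float32/float64 data, applies the scl slope and
#' intercept, and linearly rescales the volume to \[0,1\] when its values
#' fall outside that range.  4-D files are truncated to their first volume.
#'
#' @param path path to the file
#' @return a 3-D numeric array (x, y, slice) with values in \[0,1\]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s': no such file", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) abort_format(sprintf("'%s': truncated NIfTI header", path))
  rd <- function(what, n, size, off, endian) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size, endian = endian,
            signed = !(what == "integer" && size == 1))
  }
  endian <- "little"
  if (rd("integer", 1, 4, 0, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 4, 0, endian) != 348L)
      abort_format(sprintf("'%s' is not a NIfTI-1 file", path))
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    abort_format(sprintf("'%s' is not a NIfTI-1 file (bad magic)", path))
  dims <- rd("integer", 8, 2, 40, endian)
  ndim <- dims[1]
  if (ndim < 2) abort_format(sprintf("'%s': NIfTI rank %d unsupported", path, ndim))
  nx <- dims[2]; ny <- dims[3]; nz <- if (ndim >= 3) max(1L, dims[4]) else 1L
  datatype <- rd("integer", 1, 2, 70, endian)
  vox_offset <- rd("double", 1, 4, 108, endian)
  scl_slope <- rd("double", 1, 4, 112, endian)
  scl_inter <- rd("double", 1, 4, 116, endian)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt))
    abort_format(sprintf("'%s': NIfTI datatype %d unsupported", path, datatype))
  skip <- max(0, round(vox_offset) - 348)
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- as.integer(nx) * as.integer(ny) * as.integer(nz)
  vals <- switch(dt,
    uint8   = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian)),
    int16   = as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
    uint16  = {
      v <- readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian)
      as.numeric(v)
    },
    int32   = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    float32 = readBin(con, "double", n, size = 4, endian = endian),
    float64 = readBin(con, "double", n, size = 8, endian = endian))
  if (length(vals) < n) abort_format(sprintf("'%s': truncated NIfTI data", path))
  if (is.finite(scl_slope) && scl_slope != 0)
    vals <- vals * scl_slope + scl_inter
  lo <- min(vals); hi <- max(vals)
  if (lo < 0 || hi > 1) {
    vals <- if (hi > lo) (vals - lo) / (hi - lo) else vals * 0
  }
  array(vals, dim = c(nx, ny, nz))
}

#' Write a 3-D array as a minimal NIfTI-1 volume (float32)
#'
#' @param vol 3-D numeric array
#' @param path output path (`.nii`, or `.nii.gz` for gzip)
#' @return `path`, invisibly
#' @export
write_nifti <- function(vol, path) {
  if (length(dim(vol)) != 3) abort_shape("vol must be a 3-D array")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol)
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused
  writeBin(as.integer(c(3, d, 1, 1, 1, 1)), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                              # intent params etc.
  writeBin(c(16L, 32L), con, size = 2)                # datatype float32, bitpix
  writeBin(raw(2), con)                               # slice_start
  writeBin(numeric(8), con, size = 4)                 # pixdim
  writeBin(352, con, size = 4)                        # vox_offset
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  # fill remaining header bytes 120..343, then magic
  writeBin(raw(224), con)
  writeBin(charToRaw("n+1"), con)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                               # extension flag
  writeBin(as.numeric(vol), con, size = 4)
  invisible(path)
}
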