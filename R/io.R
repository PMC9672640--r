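# File formats: minimal NIfTI-1 volumes, CSV manifests, and a documented
# raw-float bag container with a JSON sidecar.
#
# No NIfTI package is available in this stack, so the subset of NIfTI-1
# needed here is implemented directly: single-file .nii / .nii.gz, 3D
# grids, datatypes uint8/int16/int32/float32/float64, scl_slope/scl_inter
# rescaling, and both endiannesses on read. Written files are always
# little-endian float32 with vox_offset 352.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii`, or `.nii.gz` — compression is
#' detected from the magic bytes, not the extension) into a [ct_volume()].
#' Voxel spacing is taken from `pixdim[2:4]`; `scl_slope`/`scl_inter`
#' rescaling is applied when set. 4D files with a singleton fourth
#' dimension are accepted.
#'
#' @param path file path.
#' @param id volume id; defaults to the file name.
#' @return A [ct_volume()].
#' @seealso [write_nifti()]
#' @export
read_nifti <- function(path, id = NULL) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (rev_int32(sizeof_hdr) != 348L)
      stop_invalid(path, " is not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  readBin(con, "raw", 36L)                                   # unused header
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                  # intent params/codes
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 348L - 120L)                           # rest of header
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop_invalid("unsupported NIfTI datatype code ", datatype)
  nd <- dims[1]
  if (nd < 3L || nd > 4L || (nd == 4L && dims[5] != 1L))
    stop_invalid("only 3D volumes are supported (dim[0] = ", nd, ")")
  d <- dims[2:4]
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop_invalid("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  sp <- pixdim[2:4]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- rep(1, 3)
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(array(as.double(vals), dim = d), spacing = sp, id = id)
}

rev_int32 <- function(x) {
  r <- packBits(rev(packBits(intToBits(x), "raw")), "integer")
  r[1]
}

#' Write a CT volume as NIfTI-1
#'
#' Writes `volume` as a little-endian float32 single-file NIfTI-1 image;
#' `.gz` paths are written compressed. Round-trips through [read_nifti()]
#' up to float32 precision.
#'
#' @param volume a [ct_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  if (!inherits(volume, "ct_volume")) stop_invalid("not a ct_volume")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(volume$voxels)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                               # sizeof_hdr
  w_raw(36L)
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))           # dim[8]
  w_raw(14L)
  w_i16(16L)                                # datatype float32
  w_i16(32L)                                # bitpix
  w_i16(0L)                                 # slice_start
  w_f32(c(1, volume$spacing, 0, 0, 0, 0))   # pixdim[8]
  w_f32(352)                                # vox_offset
  w_f32(1); w_f32(0)                        # scl_slope, scl_inter
  w_raw(344L - 120L)                        # through intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1L)    # magic at offset 344
  w_raw(4L)                                 # pad to vox_offset 352
  w_f32(as.vector(volume$voxels))
  invisible(path)
}

#' Read a bag manifest
#'
#' The manifest is a CSV with columns `bag_id, path, center_x, center_y,
#' center_z, label`. Centers are 0-based voxel coordinates in the 1 mm
#' resampled grid (the on-disk convention); the returned data frame keeps
#' them 0-based, and [preprocess_manifest()] converts to R's 1-based
#' indexing when cropping. `path` entries are resolved relative to the
#' manifest's directory unless absolute.
#'
#' @param path CSV file path.
#' @return A data.frame with the manifest columns plus `path_abs`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bag_id", "path", "center_x", "center_y", "center_z", "label")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_invalid("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$bag_id)) stop_invalid("duplicated bag_id in manifest")
  root <- dirname(normalizePath(path))
  abs <- grepl("^(/|[A-Za-z]:)", m$path)
  m$path_abs <- ifelse(abs, m$path, file.path(root, m$path))
  m
}

#' Persist a preprocessed bag
#'
#' Writes the instance tensor as raw little-endian float32 (`<prefix>.bin`,
#' values in instance-major order matching `as.vector` of the
#' `K x S x S x 3` array) plus a JSON sidecar (`<prefix>.json`) recording
#' dimensions, label, HU window, instance size and normalization constants,
#' so the binary is self-describing.
#'
#' @param bag a [build_bag()] object.
#' @param prefix output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
save_bag <- function(bag, prefix) {
  if (!inherits(bag, "tumor_bag")) stop_invalid("not a tumor_bag")
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.double(bag$instances), con, size = 4L, endian = "little")
  close(con)
  meta <- list(format = "dmilct-bag-v1", dim = dim(bag$instances),
               label = bag$label, bag_id = bag$bag_id, window = bag$window,
               size = bag$size, normalized = bag$normalized, norm = bag$norm)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Load a persisted bag
#'
#' @param prefix path prefix used in [save_bag()].
#' @return A `"tumor_bag"` object.
#' @export
load_bag <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "dmilct-bag-v1"))
    stop_invalid("not a dmilct bag container: ", prefix)
  d <- as.integer(meta$dim)
  con <- file(paste0(prefix, ".bin"), "rb")
  vals <- readBin(con, "double", prod(d), size = 4L, endian = "little")
  close(con)
  if (length(vals) != prod(d)) stop_invalid("truncated bag data: ", prefix)
  structure(list(instances = array(vals, dim = d),
                 label = if (is.null(meta$label)) NA else meta$label,
                 bag_id = meta$bag_id, window = meta$window, size = meta$size,
                 normalized = meta$normalized,
                 norm = lapply(meta$norm, as.numeric)),
            class = "tumor_bag")
}
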