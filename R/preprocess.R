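# CT preprocessing: isotropic resampling, tumor-cuboid cropping, and
# conversion of a cuboid into a model-ready bag of slice instances.

#' ImageNet channel-normalization constants
#'
#' The conventional per-channel mean and standard deviation of the natural
#' images the standard backbones are trained on, applied to each replicated
#' channel after the slice has been windowed into `[0, 1]`.
#'
#' @format A list with numeric vectors `mean` and `sd`, each length 3.
#' @export
imagenet_norm <- list(mean = c(0.485, 0.456, 0.406),
                      sd = c(0.229, 0.224, 0.225))

#' Construct a CT volume
#'
#' A `ct_volume` is a 3D scalar field in Hounsfield units (air about -1000,
#' water 0) with a physical voxel size per axis. Axis order is (x, y, z)
#' with z the slice (axial) direction; voxel `(1,1,1)` sits at physical
#' coordinate `(0,0,0)` mm and voxel `i` at `(i-1) * spacing` mm.
#'
#' @param voxels 3D numeric array of HU values, all finite.
#' @param spacing numeric length-3, voxel size in mm per axis, all positive.
#'   A scalar is recycled.
#' @param id character label carried through preprocessing provenance.
#' @return An object of class `"ct_volume"`.
#' @examples
#' v <- ct_volume(array(-1000, dim = c(4, 4, 4)), spacing = c(0.8, 0.8, 3))
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), id = "volume") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop_invalid("'voxels' must be a non-empty 3D array")
  if (!all(is.finite(voxels)))
    stop_invalid("'voxels' contains non-finite values")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop_invalid("'spacing' must be 3 positive voxel sizes in mm")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 id = as.character(id)[1]),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("CT volume '", x$id, "': ", d[1], " x ", d[2], " x ", d[3],
      " voxels at (", paste(fmt_num(x$spacing, 2), collapse = ", "),
      ") mm\n", sep = "")
  cat("  HU range [", fmt_num(min(x$voxels), 1), ", ",
      fmt_num(max(x$voxels), 1), "]\n", sep = "")
  invisible(x)
}

is_isotropic <- function(vol, target = 1, tol = 1e-6) {
  all(abs(vol$spacing - target) < tol)
}

# 1D linear-interpolation design: for output grid positions g (in source
# voxel units, 0-based), return lower index (1-based), and fraction, with
# samples beyond the grid clamped to the border voxel.
interp_axis_design <- function(g, n_in) {
  g <- pmin(pmax(g, 0), n_in - 1)
  i0 <- floor(g)
  f <- g - i0
  i0 <- pmin(i0, n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  list(i0 = as.integer(i0) + 1L, i1 = as.integer(i1) + 1L, f = f)
}

#' Resample a CT volume to isotropic voxels
#'
#' CT cohorts mix slice thicknesses (2-5 mm) and in-plane pixel sizes;
#' resampling to an isotropic grid (default 1 x 1 x 1 mm) removes that
#' acquisition variability before cropping. The output grid has
#' `round(dim * spacing / target)` voxels per axis (minimum 1), output voxel
#' `j` sits at physical position `(j-1) * target` mm, and values are
#' obtained by trilinear interpolation in physical coordinates; positions
#' beyond the source grid clamp to the border voxel.
#'
#' Interpolation is convex, so output values never exceed the input range,
#' and the physical extent is preserved to within one target spacing per
#' axis.
#'
#' @param volume a [ct_volume()].
#' @param target_spacing positive scalar, target voxel size in mm.
#' @return A [ct_volume()] with spacing `rep(target_spacing, 3)`.
#' @examples
#' v <- ct_volume(array(rnorm(1000), dim = c(10, 10, 10)), spacing = 2)
#' dim(resample_isotropic(v, 1)$voxels)  # 20 20 20
#' @export
resample_isotropic <- function(volume, target_spacing = 1) {
  if (!inherits(volume, "ct_volume")) stop_invalid("not a ct_volume")
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop_invalid("'target_spacing' must be a positive number")
  d <- dim(volume$voxels)
  sp <- volume$spacing
  if (all(abs(sp - target_spacing) < 1e-12)) {
    volume$spacing <- rep(target_spacing, 3)
    return(volume)
  }
  n_out <- pmax(1L, as.integer(round_half_up(d * sp / target_spacing)))
  v <- volume$voxels
  # separable trilinear interpolation, one axis at a time
  ax <- interp_axis_design((seq_len(n_out[1]) - 1) * target_spacing / sp[1], d[1])
  v <- v[ax$i0, , , drop = FALSE] * (1 - ax$f) +
       v[ax$i1, , , drop = FALSE] * ax$f
  ay <- interp_axis_design((seq_len(n_out[2]) - 1) * target_spacing / sp[2], d[2])
  fy <- rep(ay$f, each = n_out[1])
  v <- v[, ay$i0, , drop = FALSE] * (1 - fy) +
       v[, ay$i1, , drop = FALSE] * fy
  az <- interp_axis_design((seq_len(n_out[3]) - 1) * target_spacing / sp[3], d[3])
  fz <- rep(az$f, each = n_out[1] * n_out[2])
  v <- v[, , az$i0, drop = FALSE] * (1 - fz) +
       v[, , az$i1, drop = FALSE] * fz
  ct_volume(v, spacing = rep(target_spacing, 3), id = volume$id)
}

#' Crop a standardized tumor cuboid from an isotropic volume
#'
#' Extracts the fixed-size cuboid (default `64 x 64 x 32` voxels, i.e. a
#' 64 x 64 x 32 mm box at 1 mm spacing, large enough to contain a whole
#' tumor) centered on a tumor center supplied in voxel coordinates.
#'
#' Centering convention for the even extents: the center voxel occupies
#' 1-based cuboid index `extent/2 + 1` on each axis (e.g. `(33, 33, 17)`
#' for 64 x 64 x 32; equivalently 0-based index `extent/2`), so the low
#' side receives `extent/2` voxels and the high side `extent/2 - 1`.
#' In-bounds voxels are copied verbatim; positions falling outside the
#' volume are filled with `pad_value` (default -1000 HU, air).
#'
#' @param volume a [ct_volume()] already resampled to isotropic 1 mm.
#' @param center integer length-3 tumor center, 1-based voxel coordinates.
#' @param shape cuboid extent per axis; the standard model uses
#'   `c(64, 64, 32)`.
#' @param pad_value HU value for out-of-bounds positions.
#' @return An object of class `"tumor_cuboid"`: list with `voxels`
#'   (array of dim `shape`), `center`, `source_id`.
#' @export
crop_tumor_cuboid <- function(volume, center, shape = c(64L, 64L, 32L),
                              pad_value = -1000) {
  if (!inherits(volume, "ct_volume")) stop_invalid("not a ct_volume")
  if (!is_isotropic(volume, 1))
    stop_invalid("volume must be isotropic at 1 mm; run resample_isotropic()")
  d <- dim(volume$voxels)
  center <- as.integer(round(center))
  if (length(center) != 3L || any(center < 1L) || any(center > d))
    stop_invalid("'center' must be a voxel coordinate inside the volume")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_invalid("'shape' must be 3 positive extents")
  lo <- center - shape %/% 2L            # 1-based start of the cuboid window
  hi <- lo + shape - 1L
  out <- array(pad_value, dim = shape)
  src_lo <- pmax(lo, 1L)
  src_hi <- pmin(hi, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - lo + 1L
    dst_hi <- src_hi - lo + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      volume$voxels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2],
                    src_lo[3]:src_hi[3]]
  }
  structure(list(voxels = out, center = center, source_id = volume$id),
            class = "tumor_cuboid")
}

#' @export
print.tumor_cuboid <- function(x, ...) {
  d <- dim(x$voxels)
  cat("Tumor cuboid ", d[1], " x ", d[2], " x ", d[3], " from '",
      x$source_id, "' centered at (",
      paste(x$center, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Bilinear image resize
#'
#' Resizes a 2D matrix with the half-pixel-center convention: output pixel
#' `j` (1-based) samples source coordinate
#' `(j - 0.5) * n_in / n_out - 0.5` (0-based), clamped to the image.
#' Exposed because the resize convention is part of the preprocessing
#' contract.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions in pixels.
#' @return An `out_h x out_w` matrix.
#' @export
bilinear_resize <- function(img, out_h, out_w = out_h) {
  if (!is.matrix(img)) stop_invalid("'img' must be a matrix")
  ax <- interp_axis_design((seq_len(out_h) - 0.5) * nrow(img) / out_h - 0.5,
                           nrow(img))
  v <- img[ax$i0, , drop = FALSE] * (1 - ax$f) +
       img[ax$i1, , drop = FALSE] * ax$f
  ay <- interp_axis_design((seq_len(out_w) - 0.5) * ncol(img) / out_w - 0.5,
                           ncol(img))
  fy <- rep(ay$f, each = out_h)
  v[, ay$i0, drop = FALSE] * (1 - fy) + v[, ay$i1, drop = FALSE] * fy
}

#' Convert a tumor cuboid into a bag of slice instances
#'
#' Each of the 32 axial (z) slices of the cuboid becomes one instance of
#' the bag, in z order: the slice is clipped to the HU `window`, linearly
#' mapped to `[0, 1]`, bilinearly resized to `target_size x target_size`,
#' replicated into 3 identical channels (grayscale-to-RGB for backbones
#' trained on color images), and, when `normalize = TRUE`, standardized per
#' channel with the natural-image constants in `norm` (see
#' [imagenet_norm]). The construction is fully deterministic.
#'
#' @param cuboid a [crop_tumor_cuboid()] result (or a 3D array).
#' @param window HU interval `c(lower, upper)`, `lower < upper`. The default
#'   `c(-1000, 400)` spans air background through soft-tissue tumor.
#' @param target_size output instance size in pixels (backbone input size);
#'   at least 8.
#' @param label bag label: 1 = response, 0 = nonresponse, `NA` = unknown.
#' @param bag_id character identifier.
#' @param normalize apply the per-channel standardization. With
#'   `normalize = FALSE` all values stay in `[0, 1]`.
#' @param norm list with `mean` and `sd`, length-3 each.
#' @return An object of class `"tumor_bag"`: list with `instances`
#'   (array `K x S x S x 3`), `label`, `bag_id`, and the window/size/
#'   normalization provenance.
#' @export
build_bag <- function(cuboid, window = c(-1000, 400), target_size = 224L,
                      label = NA, bag_id = NULL, normalize = TRUE,
                      norm = imagenet_norm) {
  vox <- if (inherits(cuboid, "tumor_cuboid")) cuboid$voxels else cuboid
  if (!is.array(vox) || length(dim(vox)) != 3L)
    stop_invalid("'cuboid' must be a 3D array or tumor_cuboid")
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop_invalid("'window' must be a finite HU interval with lower < upper")
  target_size <- as.integer(target_size)
  if (is.na(target_size) || target_size < 8L)
    stop_invalid("'target_size' must be at least 8 pixels")
  if (is.null(bag_id))
    bag_id <- if (inherits(cuboid, "tumor_cuboid")) cuboid$source_id else "bag"
  K <- dim(vox)[3]
  S <- target_size
  instances <- array(NA_real_, dim = c(K, S, S, 3L))
  width <- window[2] - window[1]
  for (k in seq_len(K)) {
    sl <- (pmin(pmax(vox[, , k], window[1]), window[2]) - window[1]) / width
    sl <- bilinear_resize(sl, S, S)
    for (ch in 1:3) {
      instances[k, , , ch] <- if (normalize)
        (sl - norm$mean[ch]) / norm$sd[ch] else sl
    }
  }
  structure(list(instances = instances, label = label, bag_id = bag_id,
                 window = window, size = S, normalized = normalize,
                 norm = norm),
            class = "tumor_bag")
}

#' @export
print.tumor_bag <- function(x, ...) {
  d <- dim(x$instances)
  cat("Tumor bag '", x$bag_id, "': ", d[1], " instances of ", d[2], "x",
      d[3], "x3, label = ", x$label, "\n", sep = "")
  cat("  window [", x$window[1], ", ", x$window[2], "] HU, standardized: ",
      x$normalized, "\n", sep = "")
  invisible(x)
}
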