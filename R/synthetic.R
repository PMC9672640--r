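# Seeded synthetic cohorts with the MIL structure the method assumes:
# a bag is positive iff at least one of its instances carries signal, and
# negative bags contain none. Two levels are provided — full CT-like
# volumes for end-to-end tests of the imaging pipeline, and Gaussian
# embedding bags that bypass imaging for fast pooling/training tests.

#' Configuration for synthetic cohorts
#'
#' The defaults describe the emulated world: lung-like Gaussian background
#' at -700 HU, an ellipsoidal tumor at +30 HU (both inside the default
#' lung-mass window), acquisition noise of 40 HU, and a class-dependent
#' textured signal of 200 HU (5 standard deviations of the noise) added to
#' a subset of the 32 cuboid slices of positive bags only. For embedding
#' cohorts the same `signal_effect` is expressed in noise-sd units, i.e.
#' `signal_effect / noise_sd` (5 by default).
#'
#' @param n_bags number of bags (>= 2).
#' @param prevalence fraction of positive (response) bags, in (0, 1).
#' @param volume_shape integer length-3 voxel grid of each generated volume.
#' @param spacing voxel spacing in mm. The default is already isotropic
#'   1 mm so that slice-level signal ground truth survives resampling
#'   exactly; anisotropic inputs are exercised separately by the
#'   preprocessing tests.
#' @param tumor_radius range (mm) the three ellipsoid semi-axes are drawn
#'   from, uniformly.
#' @param background_hu,tumor_hu mean HU of lung background and tumor.
#' @param noise_sd voxelwise Gaussian noise, HU.
#' @param signal_effect additive signal magnitude, HU (image level) or
#'   `signal_effect / noise_sd` sd units (embedding level).
#' @param signal_fraction fraction of the `n_instances` slices of a
#'   positive bag that carry signal, in (0, 1]; at least one slice always
#'   does.
#' @param n_instances instances per bag (the standard cuboid gives 32).
#' @param embed_dim embedding dimension for [generate_embedding_cohort()].
#' @param seed top-level seed; every draw is derived from it.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_bags = 200L, prevalence = 0.5,
                             volume_shape = c(80L, 80L, 48L),
                             spacing = c(1, 1, 1),
                             tumor_radius = c(8, 20),
                             background_hu = -700, tumor_hu = 30,
                             noise_sd = 40, signal_effect = 200,
                             signal_fraction = 1, n_instances = 32L,
                             embed_dim = 8L, seed = 1L) {
  n_bags <- as.integer(n_bags)
  if (is.na(n_bags) || n_bags < 2L) stop_invalid("'n_bags' must be >= 2")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop_invalid("'prevalence' must lie strictly between 0 and 1")
  if (signal_fraction <= 0 || signal_fraction > 1)
    stop_invalid("'signal_fraction' must lie in (0, 1]")
  if (noise_sd < 0) stop_invalid("'noise_sd' must be non-negative")
  if (length(tumor_radius) != 2L || tumor_radius[1] > tumor_radius[2] ||
      tumor_radius[1] <= 0)
    stop_invalid("'tumor_radius' must be a positive range c(lo, hi) in mm")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L))
    stop_invalid("'volume_shape' must be 3 extents of at least 8 voxels")
  structure(list(n_bags = n_bags, prevalence = prevalence,
                 volume_shape = volume_shape, spacing = as.numeric(spacing),
                 tumor_radius = as.numeric(tumor_radius),
                 background_hu = background_hu, tumor_hu = tumor_hu,
                 noise_sd = noise_sd, signal_effect = signal_effect,
                 signal_fraction = signal_fraction,
                 n_instances = as.integer(n_instances),
                 embed_dim = as.integer(embed_dim), seed = as.integer(seed)),
            class = "synthetic_config")
}

# class labels honoring prevalence to within rounding, in seeded random order
synthetic_labels <- function(config) {
  n_pos <- max(1L, min(config$n_bags - 1L,
                       as.integer(round_half_up(config$prevalence *
                                                config$n_bags))))
  set.seed(derive_seed(config$seed, "labels"))
  sample(c(rep(1L, n_pos), rep(0L, config$n_bags - n_pos)))
}

# number of signal instances per positive bag
n_signal_instances <- function(config) {
  max(1L, as.integer(round_half_up(config$signal_fraction *
                                   config$n_instances)))
}

#' Generate a synthetic image-level cohort
#'
#' Each bag is a CT-like volume: Gaussian lung background (`background_hu`,
#' sd `noise_sd`) containing one ellipsoidal tumor (`tumor_hu`, same noise)
#' whose center is recorded. In positive bags only, a randomly chosen
#' subset of `max(1, round(signal_fraction * n_instances))` of the cuboid's
#' axial slices receives an additive textured signal of mean magnitude
#' `signal_effect` HU over the tumor cross-section (or a 10 mm disc where
#' the slice misses the tumor), giving attention a slice-level ground
#' truth. Negative bags receive no signal anywhere — the standard MIL
#' assumption. Everything is determined by `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return List of class `"synthetic_image_cohort"` with `volumes` (list of
#'   [ct_volume()]), `centers` (n x 3 integer matrix, 1-based voxel
#'   coordinates), `labels` (0/1), `signal_slices` (list of cuboid
#'   z-indices carrying signal, `integer(0)` for negative bags), and
#'   `config`.
#' @export
generate_image_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) stop_invalid("not a config")
  labels <- synthetic_labels(config)
  m_sig <- n_signal_instances(config)
  d <- config$volume_shape
  K <- config$n_instances
  half_low <- K %/% 2L
  volumes <- vector("list", config$n_bags)
  centers <- matrix(0L, config$n_bags, 3L)
  signal_slices <- vector("list", config$n_bags)
  for (b in seq_len(config$n_bags)) {
    set.seed(derive_seed(config$seed, paste0("vol", b)))
    vox <- array(stats::rnorm(prod(d), config$background_hu, config$noise_sd),
                 dim = d)
    center <- as.integer(d %/% 2L +
                           c(sample(-4:4, 2L, replace = TRUE), sample(-2:2, 1L)))
    radii_mm <- stats::runif(3L, config$tumor_radius[1], config$tumor_radius[2])
    radii <- radii_mm / config$spacing          # semi-axes in voxels
    gx <- (seq_len(d[1]) - center[1]) / radii[1]
    gy <- (seq_len(d[2]) - center[2]) / radii[2]
    gz <- (seq_len(d[3]) - center[3]) / radii[3]
    R2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
    mask <- R2 <= 1
    vox[mask] <- stats::rnorm(sum(mask), config$tumor_hu, config$noise_sd)
    if (labels[b] == 1L) {
      # cuboid slice j covers volume z = center_z - K/2 + j - 1 (1 mm voxels);
      # the whole chosen slice receives the textured signal, making the
      # slice, not a sub-region, the positive instance
      sl <- sort(sample.int(K, m_sig))
      signal_slices[[b]] <- sl
      for (j in sl) {
        z <- center[3] - half_low + j - 1L
        if (z < 1L || z > d[3]) next
        vox[, , z] <- vox[, , z] +
          config$signal_effect * stats::runif(d[1] * d[2], 0.5, 1.5)
      }
    } else signal_slices[[b]] <- integer(0)
    volumes[[b]] <- ct_volume(vox, spacing = config$spacing,
                              id = sprintf("synth%03d", b))
    centers[b, ] <- center
  }
  structure(list(volumes = volumes, centers = centers, labels = labels,
                 signal_slices = signal_slices, config = config),
            class = "synthetic_image_cohort")
}

#' Generate a synthetic embedding-level cohort
#'
#' Fast stand-in for the imaging path: negative-bag instances are standard
#' normal draws in `embed_dim` dimensions; in positive bags,
#' `max(1, round(signal_fraction * n_instances))` instances are shifted by
#' `signal_effect / noise_sd` standard deviations along a fixed random unit
#' direction. Bags are `K x D` matrices ready for the pooling operators or
#' for [dmil()] with `backbone = NULL`.
#'
#' @param config a [synthetic_config()].
#' @return List of class `"synthetic_embedding_cohort"` with `bags` (list
#'   of `K x D` matrices), `labels`, `signal_instances` (list of indices),
#'   `direction`, and `config`.
#' @export
generate_embedding_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) stop_invalid("not a config")
  labels <- synthetic_labels(config)
  m_sig <- n_signal_instances(config)
  K <- config$n_instances
  D <- config$embed_dim
  effect <- if (config$noise_sd > 0)
    config$signal_effect / config$noise_sd else config$signal_effect
  set.seed(derive_seed(config$seed, "direction"))
  dir <- stats::rnorm(D)
  dir <- dir / sqrt(sum(dir^2))
  bags <- vector("list", config$n_bags)
  signal_instances <- vector("list", config$n_bags)
  for (b in seq_len(config$n_bags)) {
    set.seed(derive_seed(config$seed, paste0("bag", b)))
    E <- matrix(stats::rnorm(K * D), nrow = K)
    if (labels[b] == 1L) {
      idx <- sort(sample.int(K, m_sig))
      E[idx, ] <- E[idx, , drop = FALSE] +
        matrix(effect * dir, nrow = m_sig, ncol = D, byrow = TRUE)
      signal_instances[[b]] <- idx
    } else signal_instances[[b]] <- integer(0)
    bags[[b]] <- E
  }
  names(bags) <- sprintf("ebag%03d", seq_len(config$n_bags))
  structure(list(bags = bags, labels = labels,
                 signal_instances = signal_instances, direction = dir,
                 config = config),
            class = "synthetic_embedding_cohort")
}
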