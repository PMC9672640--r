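# Independent brute-force oracles and small fixture builders. Everything
# here is written as plain loops over definitions, deliberately not sharing
# code with the package internals it checks.

# trilinear interpolation of volume `v` (spacing sp, voxel i at (i-1)*sp mm)
# at one physical point, clamping out-of-grid coordinates to the border
oracle_trilinear <- function(v, sp, point) {
  d <- dim(v)
  g <- point / sp                      # 0-based voxel coordinate
  g <- pmin(pmax(g, 0), d - 1)
  i0 <- pmin(floor(g), d - 1)
  i1 <- pmin(i0 + 1, d - 1)
  f <- g - i0
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
         (if (cy) f[2] else 1 - f[2]) *
         (if (cz) f[3] else 1 - f[3])
    ix <- if (cx) i1[1] else i0[1]
    iy <- if (cy) i1[2] else i0[2]
    iz <- if (cz) i1[3] else i0[3]
    acc <- acc + w * v[ix + 1, iy + 1, iz + 1]
  }
  acc
}

# bilinear sample of matrix `img` at output pixel (oh, ow) of an
# out_h x out_w resize under the half-pixel-center convention
oracle_bilinear_pixel <- function(img, oh, ow, out_h, out_w) {
  gh <- (oh - 0.5) * nrow(img) / out_h - 0.5
  gw <- (ow - 0.5) * ncol(img) / out_w - 0.5
  gh <- min(max(gh, 0), nrow(img) - 1)
  gw <- min(max(gw, 0), ncol(img) - 1)
  h0 <- min(floor(gh), nrow(img) - 1); h1 <- min(h0 + 1, nrow(img) - 1)
  w0 <- min(floor(gw), ncol(img) - 1); w1 <- min(w0 + 1, ncol(img) - 1)
  fh <- gh - h0; fw <- gw - w0
  (1 - fh) * (1 - fw) * img[h0 + 1, w0 + 1] +
    (1 - fh) * fw * img[h0 + 1, w1 + 1] +
    fh * (1 - fw) * img[h1 + 1, w0 + 1] +
    fh * fw * img[h1 + 1, w1 + 1]
}

# attention pooling evaluated directly from the printed formulas:
# a_k = exp(w' tanh(V h_k')) / sum_j exp(w' tanh(V h_j')); z = sum a_k h_k
oracle_attention <- function(E, V, w) {
  K <- nrow(E)
  s <- numeric(K)
  for (k in seq_len(K)) s[k] <- sum(w * tanh(V %*% E[k, ]))
  e <- exp(s)
  a <- e / sum(e)
  z <- numeric(ncol(E))
  for (k in seq_len(K)) z <- z + a[k] * E[k, ]
  list(a = a, z = z)
}

# Mann-Whitney AUC by exhaustive pair enumeration with half-credit ties
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# net benefit recomputed from scratch at one threshold
oracle_net_benefit <- function(scores, labels, p) {
  pred <- scores >= p
  TP <- sum(pred & labels == 1)
  FP <- sum(pred & labels == 0)
  N <- length(scores)
  TP / N - (FP / N) * p / (1 - p)
}

# a scored cohort realizing exact confusion counts at cutoff 0.5
cohort_from_counts <- function(TP, FN, TN, FP) {
  list(scores = c(rep(0.9, TP), rep(0.1, FN), rep(0.1, TN), rep(0.9, FP)),
       labels = c(rep(1, TP + FN), rep(0, TN + FP)))
}

# small random embedding bag
random_bag <- function(K = 32, D = 8, scale = 1) {
  matrix(rnorm(K * D, sd = scale), nrow = K)
}

# quick synthetic image bag list for training tests
make_image_bags <- function(cohort, size = 32) {
  ids <- vapply(cohort$volumes, `[[`, character(1), "id")
  bags <- lapply(seq_along(cohort$volumes), function(i) {
    vol <- resample_isotropic(cohort$volumes[[i]], 1)
    cub <- crop_tumor_cuboid(vol, cohort$centers[i, ])
    build_bag(cub, target_size = size, label = cohort$labels[i],
              bag_id = ids[i])
  })
  names(bags) <- ids
  bags
}
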