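# Shared-weight feature-extraction backbones.
#
# A backbone maps every instance (slice) of a bag through the same
# convolutional stack ("the weights in backbone networks are shared") and
# ends at a spatial feature map; global average pooling then reduces each
# map to one value per channel, giving the K x D instance-embedding matrix.

# Registry of known architectures. `cfg` is a function returning a layer
# stack for the sequential ones; NULL means the architecture needs building
# blocks (residual/dense/inverted-residual) this package does not bundle.
.backbones <- list(
  tiny_test = list(
    input_size = 32L, feature_dim = 8L, map_size = 8L,
    cfg = function() list(
      nn_conv(3L, 8L, 3L, stride = 2L, pad = 1L), nn_relu(),
      nn_conv(8L, 8L, 3L, stride = 2L, pad = 1L), nn_relu())
  ),
  vgg16 = list(
    input_size = 224L, feature_dim = 512L, map_size = 7L,
    cfg = function() {
      plan <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, NA,
                512, 512, 512, NA, 512, 512, 512, NA)
      layers <- list()
      in_ch <- 3L
      for (p in plan) {
        if (is.na(p)) {
          layers <- c(layers, list(nn_maxpool(2L)))
        } else {
          layers <- c(layers, list(nn_conv(in_ch, as.integer(p), 3L,
                                           stride = 1L, pad = 1L), nn_relu()))
          in_ch <- as.integer(p)
        }
      }
      layers
    }
  ),
  alexnet = list(
    input_size = 224L, feature_dim = 256L, map_size = 6L,
    cfg = function() list(
      nn_conv(3L, 64L, 11L, stride = 4L, pad = 2L), nn_relu(),
      nn_maxpool(3L, 2L),
      nn_conv(64L, 192L, 5L, stride = 1L, pad = 2L), nn_relu(),
      nn_maxpool(3L, 2L),
      nn_conv(192L, 384L, 3L, stride = 1L, pad = 1L), nn_relu(),
      nn_conv(384L, 256L, 3L, stride = 1L, pad = 1L), nn_relu(),
      nn_conv(256L, 256L, 3L, stride = 1L, pad = 1L), nn_relu(),
      nn_maxpool(3L, 2L))
  ),
  resnet34 = list(input_size = 224L, feature_dim = 512L, map_size = 7L,
                  cfg = NULL),
  densenet = list(input_size = 224L, feature_dim = 1024L, map_size = 7L,
                  cfg = NULL),
  mobilenet_v2 = list(input_size = 224L, feature_dim = 1280L, map_size = 7L,
                      cfg = NULL)
)

#' List the backbone registry
#'
#' @return A data.frame with one row per registered backbone: its name,
#'   expected input size in pixels, embedding dimension `D`, final spatial
#'   map size, and whether this package can construct it offline.
#' @examples
#' list_backbones()
#' @export
list_backbones <- function() {
  data.frame(
    name = names(.backbones),
    input_size = vapply(.backbones, `[[`, integer(1), "input_size"),
    feature_dim = vapply(.backbones, `[[`, integer(1), "feature_dim"),
    map_size = vapply(.backbones, `[[`, integer(1), "map_size"),
    constructible = !vapply(.backbones, function(b) is.null(b$cfg), logical(1)),
    row.names = NULL
  )
}

#' Describe a feature-extraction backbone
#'
#' A backbone spec records the architecture name, the pixel size its inputs
#' must have, the embedding dimension `D` of its final feature maps, and
#' whether pretrained weights are requested. `vgg16`, `alexnet` and the
#' CPU-scale `tiny_test` network (two stride-2 conv blocks, `D = 8`,
#' 32-pixel input) can be constructed here; `resnet34`, `densenet` and
#' `mobilenet_v2` are registered for completeness but their non-sequential
#' blocks are not bundled, so [init_backbone()] refuses them.
#'
#' @param name one of `"tiny_test"`, `"vgg16"`, `"alexnet"`, `"resnet34"`,
#'   `"densenet"`, `"mobilenet_v2"`.
#' @param pretrained logical; this offline package has no weight source, so
#'   `TRUE` raises an error. Kept so that a spec written for a pretrained
#'   run fails loudly rather than silently using random weights.
#' @param trainable_depth `"all"` (default; the whole backbone is fine-tuned
#'   during training) or `"head_only"` (backbone frozen).
#' @return An object of class `"backbone_spec"`.
#' @examples
#' backbone_spec("tiny_test")
#' @export
backbone_spec <- function(name = "tiny_test", pretrained = FALSE,
                          trainable_depth = c("all", "head_only")) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.backbones))
    stop_invalid("unknown backbone '", name, "'; see list_backbones()")
  check_flag(pretrained, "pretrained")
  trainable_depth <- match.arg(trainable_depth)
  reg <- .backbones[[name]]
  structure(list(name = name, input_size = reg$input_size,
                 feature_dim = reg$feature_dim, map_size = reg$map_size,
                 pretrained = pretrained, trainable_depth = trainable_depth),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat("Backbone spec:", x$name, "\n")
  cat("  input:", x$input_size, "x", x$input_size, "x 3\n")
  cat("  feature maps: D =", x$feature_dim, ", spatial",
      x$map_size, "x", x$map_size, "\n")
  cat("  pretrained:", x$pretrained,
      " trainable:", x$trainable_depth, "\n")
  invisible(x)
}

#' Instantiate a backbone with randomly initialized weights
#'
#' Builds the layer stack for a constructible architecture and draws
#' He-normal weights under a deterministic seed. There is no pretrained
#' weight source in this offline package, so `spec$pretrained = TRUE` is an
#' error rather than a silent fallback.
#'
#' @param spec a [backbone_spec()] or an architecture name.
#' @param seed integer seed for the weight draw.
#' @return An object of class `"dmil_backbone"`: the spec plus an
#'   initialized layer list.
#' @examples
#' bb <- init_backbone("tiny_test", seed = 1)
#' @export
init_backbone <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- backbone_spec(spec)
  if (!inherits(spec, "backbone_spec")) stop_invalid("not a backbone_spec")
  reg <- .backbones[[spec$name]]
  if (is.null(reg$cfg))
    stop_invalid("backbone '", spec$name, "' requires residual/dense blocks ",
                 "that are not bundled in this offline package; use vgg16, ",
                 "alexnet, tiny_test, or supply a custom layer stack")
  if (isTRUE(spec$pretrained))
    stop_invalid("no pretrained weights are available offline; ",
                 "set pretrained = FALSE for a random initialization")
  set.seed(derive_seed(seed, paste0("backbone_", spec$name)))
  structure(list(spec = spec, layers = nn_init_layers(reg$cfg())),
            class = "dmil_backbone")
}

#' Extract per-instance convolutional feature maps
#'
#' Runs every instance of a bag through the shared-weight backbone. All
#' instances pass through identical parameters, so identical instances give
#' identical maps and the result does not depend on how instances are
#' batched internally. For a VGG16-style backbone on a 32-instance bag of
#' 224x224x3 inputs the result has shape `32 x 512 x 7 x 7`.
#'
#' @param bag a [build_bag()] object, or a plain numeric array of shape
#'   `K x S x S x 3`.
#' @param backbone an initialized [init_backbone()] object (a name or spec
#'   is accepted and initialized with seed 1).
#' @param chunk instances processed per internal batch; only memory, never
#'   values, depends on it. Default adapts to the input size.
#' @return Numeric array of shape `K x D x h x w` (instance, channel, rows,
#'   cols) of class `"instance_maps"`.
#' @seealso [global_average_pool()]
#' @export
extract_instance_features <- function(bag, backbone, chunk = NULL) {
  if (is.character(backbone) || inherits(backbone, "backbone_spec"))
    backbone <- init_backbone(backbone)
  if (!inherits(backbone, "dmil_backbone")) stop_invalid("not a backbone")
  inst <- if (inherits(bag, "tumor_bag")) bag$instances else bag
  if (!is.array(inst) || length(dim(inst)) != 4L || dim(inst)[4] != 3L)
    stop_invalid("bag instances must be a K x S x S x 3 array")
  S <- backbone$spec$input_size
  if (dim(inst)[2] != S || dim(inst)[3] != S)
    stop_invalid("instance size ", dim(inst)[2], "x", dim(inst)[3],
                 " does not match backbone input ", S, "x", S)
  K <- dim(inst)[1]
  x <- aperm(inst, c(2, 3, 4, 1))             # [S, S, 3, K]
  if (is.null(chunk)) chunk <- if (S >= 128L) 2L else K
  pieces <- split(seq_len(K), ceiling(seq_len(K) / chunk))
  maps <- NULL
  for (id in pieces) {
    o <- nn_forward(backbone$layers, x[, , , id, drop = FALSE])$out
    if (is.null(maps)) {
      dm <- dim(o)
      maps <- array(NA_real_, dim = c(dm[1], dm[2], dm[3], K))
    }
    maps[, , , id] <- o
  }
  structure(aperm(maps, c(4, 3, 1, 2)), class = "instance_maps")
}

#' Reduce feature maps to instance embeddings by global average pooling
#'
#' `E[k, d]` is the mean of map `maps[k, d, , ]` over its spatial positions,
#' reducing a `K x D x h x w` tensor to the `K x D` bag of embeddings
#' `H = {h_1, ..., h_K}` that the MIL pooling operators consume.
#'
#' @param maps array `K x D x h x w` from [extract_instance_features()].
#' @return A `K x D` numeric matrix.
#' @examples
#' m <- array(1:16, dim = c(1, 1, 4, 4))
#' global_average_pool(m)  # mean of 1:16
#' @export
global_average_pool <- function(maps) {
  d <- dim(maps)
  if (is.null(d) || length(d) != 4L)
    stop_invalid("'maps' must be a K x D x h x w array")
  if (!all(is.finite(maps))) stop_invalid("'maps' contains non-finite values")
  E <- matrix(rowMeans(matrix(maps, nrow = d[1] * d[2], ncol = d[3] * d[4])),
              nrow = d[1], ncol = d[2])
  E
}

# internal: [h, w, D, N] stack -> N x D embeddings (same reduction, nn layout)
gap_stack <- function(out) {
  d <- dim(out)
  t(matrix(colMeans(matrix(out, nrow = d[1] * d[2])), nrow = d[3], ncol = d[4]))
}

# internal: route dE (N x D) back through global average pooling
gap_backward <- function(dE, h, w) {
  M <- t(dE) / (h * w)                       # D x N
  array(rep(as.vector(M), each = h * w), dim = c(h, w, nrow(M), ncol(M)))
}
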