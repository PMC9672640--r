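# Stratified splitting, supervised training of backbone + pooling + head,
# and bag scoring.

#' Stratified train/validation/test split
#'
#' Splits a labelled manifest into train, validation and test cohorts at
#' the given ratios *within each class*: with `n_c` bags in class `c`,
#' `n_train = round(r_train * n_c)` and `n_val = round(r_val * n_c)`
#' (half-up rounding), and the test cohort receives the remainder.
#' Assignment within a class is random under `seed` but invariant to the
#' row order of the manifest (ids are sorted before permutation). With the
#' study-sized manifest — 301 bags, 163 response / 138 nonresponse, ratios
#' 70:10:20 — this yields cohorts of 211, 30 and 60 bags.
#'
#' @param manifest data.frame with columns `bag_id` and `label` (binary,
#'   no missing values).
#' @param ratios positive length-3 numeric summing to 1:
#'   (train, validation, test).
#' @param seed integer seed.
#' @return Object of class `"split_manifest"`: lists `train`,
#'   `validation`, `test` of bag ids, plus `ratios`, `seed` and a
#'   per-class count table.
#' @export
split_stratified <- function(manifest, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (!is.data.frame(manifest) || !all(c("bag_id", "label") %in% names(manifest)))
    stop_invalid("'manifest' needs columns bag_id and label")
  if (anyNA(manifest$label))
    stop_invalid("every bag must be labelled for a stratified split")
  if (length(ratios) != 3L || any(ratios <= 0))
    stop_invalid("'ratios' must be 3 positive fractions")
  if (abs(sum(ratios) - 1) > 1e-8)
    stop_invalid("'ratios' must sum to 1 (got ", sum(ratios), ")")
  ids <- as.character(manifest$bag_id)
  labs <- manifest$label
  out <- list(train = character(0), validation = character(0),
              test = character(0))
  counts <- NULL
  for (cl in sort(unique(labs))) {
    cids <- sort(ids[labs == cl])
    n_c <- length(cids)
    if (n_c < 3L)
      stop_invalid("class ", cl, " has ", n_c,
                   " bags; need at least one per split")
    n_tr <- as.integer(round_half_up(ratios[1] * n_c))
    n_va <- as.integer(round_half_up(ratios[2] * n_c))
    n_te <- n_c - n_tr - n_va
    if (n_te < 0L)
      stop_invalid("rounded split sizes exceed class size for class ", cl)
    set.seed(derive_seed(seed, paste0("split_class_", cl)))
    perm <- sample(cids)
    out$train <- c(out$train, perm[seq_len(n_tr)])
    out$validation <- c(out$validation,
                        perm[n_tr + seq_len(n_va)])
    if (n_te > 0L)
      out$test <- c(out$test, perm[n_tr + n_va + seq_len(n_te)])
    counts <- rbind(counts, c(class = cl, train = n_tr, validation = n_va,
                              test = n_te))
  }
  structure(list(train = out$train, validation = out$validation,
                 test = out$test, ratios = as.numeric(ratios),
                 seed = as.integer(seed),
                 counts = as.data.frame(counts)),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat("Stratified split", paste(x$ratios * 100, collapse = ":"),
      "(seed", paste0(x$seed, ")\n"))
  cat("  train:", length(x$train), " validation:", length(x$validation),
      " test:", length(x$test), "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Training configuration
#'
#' Defaults are the published training setup: Adam, learning rate 1e-5,
#' mini-batches of 32 bags, 50 epochs, binary cross-entropy between the
#' sigmoid bag score and the bag label. "Batch size 32" is interpreted as
#' 32 bags per optimizer step — the bag is the sample unit in MIL and a
#' bag's instances always travel together. The checkpoint returned after
#' training is the epoch with the best validation AUC, falling back to the
#' last epoch when no validation set is given. Early stopping, weight
#' decay, augmentation and class weighting are deliberately absent.
#'
#' @param learning_rate positive Adam step size.
#' @param epochs number of passes over the training bags (>= 1).
#' @param batch_bags bags per optimizer step (>= 1).
#' @param loss only `"bce"` (binary cross-entropy) is provided.
#' @param optimizer only `"adam"` is provided.
#' @param seed top-level seed governing initialization and shuffling.
#' @param checkpoint `"val_auc"` or `"last"`.
#' @param attention_L attention hidden size (used when pooling is
#'   `"attention"`).
#' @param init_sd scale of the near-zero attention initialization; the
#'   classifier head always starts at exactly zero (all bags score 0.5).
#' @param verbose print a line per epoch.
#' @return Object of class `"dmil_control"`.
#' @export
dmil_control <- function(learning_rate = 1e-5, epochs = 50L, batch_bags = 32L,
                         loss = "bce", optimizer = "adam", seed = 1L,
                         checkpoint = c("val_auc", "last"),
                         attention_L = 128L, init_sd = 1e-3,
                         verbose = FALSE) {
  if (!is.numeric(learning_rate) || learning_rate < 0)
    stop_invalid("'learning_rate' must be non-negative")
  if (!is_count(epochs) || epochs < 1L) stop_invalid("'epochs' must be >= 1")
  if (!is_count(batch_bags) || batch_bags < 1L)
    stop_invalid("'batch_bags' must be >= 1")
  loss <- match.arg(loss, "bce")
  optimizer <- match.arg(optimizer, "adam")
  checkpoint <- match.arg(checkpoint)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_bags = as.integer(batch_bags), loss = loss,
                 optimizer = optimizer, seed = as.integer(seed),
                 checkpoint = checkpoint, attention_L = as.integer(attention_L),
                 init_sd = init_sd, verbose = isTRUE(verbose)),
            class = "dmil_control")
}

# ---- internal model plumbing ----------------------------------------------

bag_matrixify <- function(bags) {
  # returns list(mode = "image"|"embedding", bags = list)
  if (inherits(bags, "tumor_bag") || is.matrix(bags)) bags <- list(bags)
  if (!is.list(bags) || length(bags) == 0L) stop_invalid("no bags supplied")
  if (all(vapply(bags, is.matrix, logical(1))))
    return(list(mode = "embedding", bags = bags))
  if (all(vapply(bags, inherits, logical(1), "tumor_bag")))
    return(list(mode = "image", bags = bags))
  stop_invalid("bags must be all tumor_bag objects or all K x D matrices")
}

bag_ids_of <- function(bags) {
  ids <- names(bags)
  if (is.null(ids)) ids <- rep(NA_character_, length(bags))
  for (i in seq_along(bags)) {
    if ((is.na(ids[i]) || ids[i] == "") && inherits(bags[[i]], "tumor_bag"))
      ids[i] <- bags[[i]]$bag_id
    if (is.na(ids[i]) || ids[i] == "") ids[i] <- sprintf("bag%03d", i)
  }
  make.unique(ids)
}

labels_of <- function(bags, labels) {
  if (is.null(labels)) {
    labels <- vapply(bags, function(b)
      if (inherits(b, "tumor_bag")) as.numeric(b$label) else NA_real_,
      numeric(1))
  }
  as.numeric(labels)
}

# stack image bags into one [S, S, 3, sum K] array
stack_instances <- function(bags) {
  arrs <- lapply(bags, function(b) aperm(b$instances, c(2, 3, 4, 1)))
  Ks <- vapply(bags, function(b) dim(b$instances)[1], integer(1))
  d1 <- dim(arrs[[1]])
  x <- array(0, dim = c(d1[1], d1[2], 3L, sum(Ks)))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[4]
    x[, , , at + seq_len(k)] <- a
    at <- at + k
  }
  list(x = x, Ks = Ks)
}

model_forward <- function(model, bags, mode, train = FALSE) {
  if (mode == "image") {
    st <- stack_instances(bags)
    fw <- nn_forward(model$layers, st$x, train = train)
    E_all <- gap_stack(fw$out)
    ends <- cumsum(st$Ks)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    Es <- lapply(seq_along(bags), function(i) E_all[starts[i]:ends[i], ,
                                                    drop = FALSE])
  } else {
    fw <- NULL
    st <- NULL
    Es <- bags
  }
  pf <- lapply(Es, pool_forward, pooling = model$pooling, pp = model$pool)
  Z <- do.call(rbind, lapply(pf, `[[`, "z"))
  logits <- as.vector(Z %*% model$head$weight + model$head$bias)
  list(logits = logits, Es = Es, pf = pf, Z = Z, fw = fw, st = st)
}

bce_from_logits <- function(l, y) {
  mean(pmax(l, 0) - l * y + log1p(exp(-abs(l))))
}

model_backward <- function(model, fwd, y, mode) {
  nb <- length(y)
  p <- stats::plogis(fwd$logits)
  dlogit <- (p - y) / nb
  grads <- list(
    head.weight = as.vector(crossprod(fwd$Z, dlogit)),
    head.bias = sum(dlogit)
  )
  if (model$pooling == "conv") grads$pool.u <- 0 * model$pool$u
  if (model$pooling == "attention") {
    grads$pool.V <- 0 * model$pool$V
    grads$pool.w <- 0 * model$pool$w
  }
  dEs <- vector("list", nb)
  for (i in seq_len(nb)) {
    dz <- dlogit[i] * model$head$weight
    pb <- pool_backward(dz, fwd$Es[[i]], model$pooling, model$pool,
                        fwd$pf[[i]]$cache)
    dEs[[i]] <- pb$dE
    if (!is.null(pb$dparams)) {
      if (model$pooling == "conv") grads$pool.u <- grads$pool.u + pb$dparams$u
      if (model$pooling == "attention") {
        grads$pool.V <- grads$pool.V + pb$dparams$V
        grads$pool.w <- grads$pool.w + pb$dparams$w
      }
    }
  }
  if (mode == "image" && model$trainable_depth == "all") {
    dE_all <- do.call(rbind, dEs)
    dmaps <- gap_backward(dE_all, dim(fwd$fw$out)[1], dim(fwd$fw$out)[2])
    bb <- nn_backward(model$layers, fwd$fw$caches, dmaps)
    for (i in seq_along(bb$grads)) {
      if (!is.null(bb$grads[[i]])) {
        grads[[paste0("bb", i, ".W")]] <- bb$grads[[i]]$dW
        grads[[paste0("bb", i, ".b")]] <- bb$grads[[i]]$db
      }
    }
  }
  grads
}

model_theta <- function(model) {
  th <- list(head.weight = model$head$weight, head.bias = model$head$bias)
  if (model$pooling == "conv") th$pool.u <- model$pool$u
  if (model$pooling == "attention") {
    th$pool.V <- model$pool$V
    th$pool.w <- model$pool$w
  }
  if (!is.null(model$layers) && model$trainable_depth == "all") {
    for (i in seq_along(model$layers)) {
      if (model$layers[[i]]$type == "conv") {
        th[[paste0("bb", i, ".W")]] <- model$layers[[i]]$W
        th[[paste0("bb", i, ".b")]] <- model$layers[[i]]$b
      }
    }
  }
  th
}

model_set_theta <- function(model, th) {
  model$head$weight <- th$head.weight
  model$head$bias <- th$head.bias
  if (model$pooling == "conv") model$pool$u <- th$pool.u
  if (model$pooling == "attention") {
    model$pool$V <- th$pool.V
    model$pool$w <- th$pool.w
  }
  for (nm in names(th)) {
    if (grepl("^bb[0-9]+\\.", nm)) {
      i <- as.integer(sub("^bb([0-9]+)\\..*$", "\\1", nm))
      fld <- sub("^bb[0-9]+\\.", "", nm)
      model$layers[[i]][[fld]] <- th[[nm]]
    }
  }
  model
}

# ---- the fitting function -------------------------------------------------

#' Fit a deep multiple-instance-learning bag classifier
#'
#' Trains the full stack — shared-weight convolutional backbone, MIL
#' pooling head (max, convolutional, or attention), and sigmoid classifier
#' — on labelled bags by minimizing binary cross-entropy with Adam.
#' Mini-batches are batches of *bags*; the instances of a bag always stay
#' together. With `backbone = NULL` (or when bags are plain `K x D`
#' matrices) the imaging stage is bypassed and the pooling head is trained
#' directly on instance embeddings, which is the fast route for synthetic
#' experiments.
#'
#' Initialization: backbone weights are He-normal draws; the attention
#' parameters start near zero and the classifier head at exactly zero, so
#' every bag initially scores 0.5 and the decision direction is learned
#' from the data rather than inherited from a random draw (see the methods
#' vignette). All randomness derives from `control$seed`; identical inputs
#' and seed give bit-identical histories on the same platform.
#'
#' @param bags list of [build_bag()] objects (image route) or of `K x D`
#'   embedding matrices (embedding route).
#' @param labels numeric 0/1 bag labels (1 = response); taken from the bags
#'   themselves when omitted. Both classes must be present.
#' @param pooling `"attention"` (default), `"max"`, or `"conv"`. Conv
#'   pooling fixes the bag size at construction; max and attention accept
#'   any `K >= 1`.
#' @param backbone a backbone name, [backbone_spec()], or initialized
#'   [init_backbone()]; `NULL` for the embedding route.
#' @param val_bags,val_labels optional validation cohort for the
#'   checkpoint criterion and the per-epoch validation AUC.
#' @param control a [dmil_control()].
#' @return Object of class `"dmil"` with the trained parameters, the
#'   config snapshot, and `history` (per-epoch training loss and
#'   validation AUC). Standard methods: [predict.dmil()], `print`,
#'   `summary`, `coef`, `plot`, `fitted`, `residuals`, `simulate`.
#' @examples
#' co <- generate_embedding_cohort(synthetic_config(
#'   n_bags = 20, n_instances = 8, embed_dim = 4, seed = 7))
#' fit <- dmil(co$bags, co$labels, pooling = "attention", backbone = NULL,
#'             control = dmil_control(epochs = 3, learning_rate = 1e-3))
#' predict(fit, co$bags[1:2])
#' @export
dmil <- function(bags, labels = NULL, pooling = c("attention", "max", "conv"),
                 backbone = "tiny_test", val_bags = NULL, val_labels = NULL,
                 control = dmil_control()) {
  pooling <- match.arg(pooling)
  if (!inherits(control, "dmil_control")) stop_invalid("bad 'control'")
  bm <- bag_matrixify(bags)
  bags <- bm$bags
  mode <- bm$mode
  if (mode == "embedding") backbone <- NULL
  y <- labels_of(bags, labels)
  if (anyNA(y)) stop_invalid("all training bags must be labelled")
  if (length(unique(y)) < 2L)
    stop_invalid("training set contains a single class; need both")
  ids <- bag_ids_of(bags)

  if (mode == "image") {
    if (is.null(backbone))
      stop_invalid("image bags need a backbone; got NULL")
    if (is.character(backbone)) backbone <- backbone_spec(backbone)
    if (inherits(backbone, "backbone_spec")) {
      spec <- backbone
      set.seed(derive_seed(control$seed, "backbone"))
      backbone <- init_backbone(spec, seed = control$seed)
    }
    if (!inherits(backbone, "dmil_backbone")) stop_invalid("bad 'backbone'")
    S <- backbone$spec$input_size
    if (dim(bags[[1]]$instances)[2] != S)
      stop_invalid("bag instance size ", dim(bags[[1]]$instances)[2],
                   " does not match backbone input ", S)
    D <- backbone$spec$feature_dim
    layers <- backbone$layers
    trainable_depth <- backbone$spec$trainable_depth
    spec <- backbone$spec
  } else {
    D <- ncol(bags[[1]])
    layers <- NULL
    trainable_depth <- "all"
    spec <- NULL
  }
  K0 <- if (mode == "image") dim(bags[[1]]$instances)[1] else nrow(bags[[1]])

  set.seed(derive_seed(control$seed, "pool_init"))
  pool <- switch(pooling,
    max = NULL,
    conv = conv_pool_params(K0),
    attention = attention_params(D, L = control$attention_L,
                                 sd = control$init_sd))
  model <- list(layers = layers, pooling = pooling, pool = pool,
                head = list(weight = numeric(D), bias = 0),
                trainable_depth = trainable_depth, spec = spec, mode = mode,
                D = D, K = K0)

  nb <- length(bags)
  n_batches <- ceiling(nb / control$batch_bags)
  adam <- adam_state()
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  best <- list(auc = -Inf, theta = NULL, epoch = NA_integer_)
  has_val <- !is.null(val_bags)
  if (has_val) {
    vb <- bag_matrixify(val_bags)$bags
    vy <- labels_of(vb, val_labels)
  }

  for (epoch in seq_len(control$epochs)) {
    set.seed(derive_seed(control$seed, paste0("shuffle", epoch)))
    ord <- sample.int(nb)
    losses <- numeric(n_batches)
    for (bi in seq_len(n_batches)) {
      take <- ord[((bi - 1L) * control$batch_bags + 1L):
                    min(bi * control$batch_bags, nb)]
      fwd <- model_forward(model, bags[take], mode, train = TRUE)
      losses[bi] <- bce_from_logits(fwd$logits, y[take])
      if (!is.finite(losses[bi]))
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi,
             "; check inputs and learning rate", call. = FALSE)
      grads <- model_backward(model, fwd, y[take], mode)
      theta <- model_theta(model)
      upd <- adam_step(theta, grads[names(theta)], adam,
                       lr = control$learning_rate)
      adam <- upd$state
      model <- model_set_theta(model, upd$params)
    }
    val_auc <- NA_real_
    if (has_val && length(unique(vy[!is.na(vy)])) == 2L) {
      vs <- stats::plogis(model_forward(model, vb, mode)$logits)
      val_auc <- roc_auc(vs, vy)$auc
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_auc = val_auc))
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.6f  val AUC %s", epoch,
                      mean(losses),
                      ifelse(is.na(val_auc), "-", fmt_num(val_auc))))
    if (control$checkpoint == "val_auc" && !is.na(val_auc) &&
        val_auc > best$auc) {
      best <- list(auc = val_auc, theta = model_theta(model), epoch = epoch)
    }
  }
  if (!is.null(best$theta)) model <- model_set_theta(model, best$theta)

  fit <- structure(list(model = model, pooling = pooling, control = control,
                        history = history, n_train = nb,
                        checkpoint_epoch = if (!is.null(best$theta))
                          best$epoch else control$epochs,
                        train_ids = ids, train_labels = y),
                   class = "dmil")
  fit$fitted <- predict(fit, bags)
  fit
}

#' Predict bag-level response probabilities
#'
#' Scores bags with a trained model. Evaluation is deterministic — there
#' are no stochastic layers — so repeated calls give identical scores.
#'
#' @param object a fitted [dmil()] model.
#' @param newdata a list of bags compatible with the model (same instance
#'   size for the image route, same `D` for the embedding route), or a
#'   single bag.
#' @param ... unused.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
predict.dmil <- function(object, newdata, ...) {
  bm <- bag_matrixify(newdata)
  if (bm$mode != object$model$mode)
    stop_invalid("model was fitted on ", object$model$mode,
                 " bags but newdata is ", bm$mode)
  bags <- bm$bags
  if (bm$mode == "image") {
    S <- object$model$spec$input_size
    szs <- vapply(bags, function(b) dim(b$instances)[2], integer(1))
    if (any(szs != S))
      stop_invalid("instance size ", szs[szs != S][1],
                   " incompatible with backbone input ", S)
  } else if (ncol(bags[[1]]) != object$model$D) {
    stop_invalid("embedding dimension ", ncol(bags[[1]]),
                 " does not match model D = ", object$model$D)
  }
  chunk <- max(1L, object$control$batch_bags)
  out <- numeric(length(bags))
  for (id in split(seq_along(bags), ceiling(seq_along(bags) / chunk))) {
    out[id] <- stats::plogis(
      model_forward(object$model, bags[id], bm$mode)$logits)
  }
  names(out) <- bag_ids_of(bags)
  out
}

#' Score bags with a trained model
#'
#' Convenience wrapper around [predict.dmil()] returning a scores table.
#'
#' @param model a fitted [dmil()] object.
#' @param bags list of bags.
#' @return data.frame with columns `bag_id` and `score`.
#' @export
predict_bags <- function(model, bags) {
  p <- predict(model, bags)
  data.frame(bag_id = names(p), score = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Per-instance attention weights of a trained model
#'
#' Exposes which slices the attention head relies on: for each bag, the
#' softmax weights `a_k` of its instances (they sum to 1 per bag). Only
#' defined for attention pooling.
#'
#' @param model a fitted [dmil()] with `pooling = "attention"`.
#' @param bags list of bags.
#' @return data.frame with columns `bag_id`, `instance_index`, `weight`,
#'   ready to write as CSV.
#' @export
attention_weights <- function(model, bags) {
  if (!inherits(model, "dmil") || model$pooling != "attention")
    stop_invalid("attention weights need a model fitted with attention pooling")
  bm <- bag_matrixify(bags)
  ids <- bag_ids_of(bm$bags)
  fwd <- model_forward(model$model, bm$bags, bm$mode)
  do.call(rbind, lapply(seq_along(bm$bags), function(i) {
    a <- fwd$pf[[i]]$cache$a
    data.frame(bag_id = ids[i], instance_index = seq_along(a), weight = a,
               stringsAsFactors = FALSE)
  }))
}

# ---- standard S3 methods --------------------------------------------------

#' @export
print.dmil <- function(x, ...) {
  m <- x$model
  cat("Deep MIL bag classifier\n")
  cat("  route:", if (m$mode == "image")
    paste0("image (backbone ", m$spec$name, ", D = ", m$D, ")")
    else paste0("embedding (D = ", m$D, ")"), "\n")
  cat("  pooling:", x$pooling,
      if (x$pooling == "attention") paste0("(L = ", ncol(m$pool$w) %||%
                                             length(m$pool$w), ")") else "",
      "\n")
  cat("  trained:", x$n_train, "bags,", nrow(x$history), "epochs",
      "| checkpoint epoch", x$checkpoint_epoch, "\n")
  cat("  final training loss:",
      fmt_num(utils::tail(x$history$train_loss, 1), 6), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.dmil <- function(object, ...) {
  h <- object$history
  cat("Deep MIL model summary\n")
  print(object)
  npar <- sum(vapply(model_theta(object$model), length, integer(1)))
  cat("  trainable parameters:", npar, "\n")
  if (any(!is.na(h$val_auc)))
    cat("  best validation AUC:", fmt_num(max(h$val_auc, na.rm = TRUE)),
        "at epoch", h$epoch[which.max(h$val_auc)], "\n")
  cat("  training-loss trajectory (first/last):",
      fmt_num(h$train_loss[1], 6), "->",
      fmt_num(utils::tail(h$train_loss, 1), 6), "\n")
  invisible(object)
}

#' @export
coef.dmil <- function(object, ...) {
  m <- object$model
  out <- list(head = m$head)
  if (object$pooling == "conv") out$conv_kernel <- m$pool$u
  if (object$pooling == "attention") out$attention <- list(V = m$pool$V,
                                                           w = m$pool$w)
  out
}

#' @export
fitted.dmil <- function(object, ...) object$fitted

#' @export
residuals.dmil <- function(object, ...) {
  object$train_labels - object$fitted
}

#' @export
plot.dmil <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, if (any(!is.na(h$val_auc))) 2 else 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Training loss", ...)
  if (any(!is.na(h$val_auc)))
    graphics::plot(h$epoch, h$val_auc, type = "l", xlab = "epoch",
                   ylab = "validation AUC", main = "Validation AUC",
                   ylim = c(0, 1), ...)
  invisible(x)
}

#' Simulate bag labels from a fitted model
#'
#' Draws Bernoulli labels at the model's fitted (training-bag)
#' probabilities — the model's generative view of its own cohort.
#'
#' @param object a fitted [dmil()].
#' @param nsim number of simulated label vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of 0/1 labels.
#' @export
simulate.dmil <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted
  out <- as.data.frame(matrix(stats::rbinom(length(p) * nsim, 1L,
                                            rep(p, nsim)),
                              ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- names(p)
  out
}
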