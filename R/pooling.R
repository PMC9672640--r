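# MIL pooling operators: aggregate the K x D instance-embedding matrix of a
# bag into one D-vector, by columnwise max, by a learned 32x1 convolution
# across instances, or by attention — a learned convex combination
#   z = sum_k a_k h_k,   a_k = softmax_k( w' tanh(V h_k') )
# whose weights sum to 1 so the bag score remains a single prediction.

check_embeddings <- function(E) {
  if (!is.matrix(E) || !is.numeric(E))
    stop_invalid("'E' must be a numeric K x D matrix of instance embeddings")
  if (nrow(E) < 1L) stop_invalid("empty bag: K must be >= 1")
  if (!all(is.finite(E))) stop_invalid("'E' contains non-finite values")
  invisible(E)
}

#' Max pooling across instances
#'
#' The bag representation keeps, for every feature channel, the largest
#' value over the K slices: `z[d] = max_k E[k, d]`. Permutation-invariant
#' and parameter-free; sensitive only to the strongest instance per channel.
#'
#' @param E numeric `K x D` matrix of instance embeddings.
#' @return Numeric length-`D` bag representation.
#' @examples
#' max_pool_bag(rbind(c(1, 5), c(3, 2)))  # 3 5
#' @export
max_pool_bag <- function(E) {
  check_embeddings(E)
  apply(E, 2L, max)
}

#' Parameters for convolutional pooling
#'
#' The convolutional pooling head is a single `K x 1` kernel applied across
#' instances and shared by all D feature channels, with no bias. The
#' default initialization `u = 1/K` starts as plain averaging.
#'
#' @param K bag size the kernel is built for (the standard cuboid gives 32).
#' @param u optional numeric kernel of length `K`.
#' @return Object of class `"conv_pool_params"`.
#' @export
conv_pool_params <- function(K = 32L, u = NULL) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop_invalid("'K' must be a positive count")
  if (is.null(u)) u <- rep(1 / K, K)
  if (length(u) != K || !all(is.finite(u)))
    stop_invalid("'u' must be a finite numeric vector of length K")
  structure(list(u = as.numeric(u), K = K), class = "conv_pool_params")
}

#' Convolutional pooling across instances
#'
#' Applies the learned `K x 1` kernel across the instance axis:
#' `z[d] = sum_k u[k] * E[k, d]`. One kernel is shared across all feature
#' channels and there is no bias term. Because the kernel is indexed by
#' slice position, this pooling is *not* permutation-invariant — reordering
#' slices changes the result.
#'
#' @param E numeric `K x D` embedding matrix.
#' @param params a [conv_pool_params()] whose `K` matches `nrow(E)`.
#' @return Numeric length-`D` bag representation.
#' @export
conv_pool_bag <- function(E, params) {
  check_embeddings(E)
  if (inherits(params, "conv_pool_params")) params <- params$u
  if (length(params) != nrow(E))
    stop_invalid("kernel length ", length(params),
                 " does not match bag size ", nrow(E))
  as.vector(crossprod(E, params))
}

#' Parameters for attention pooling
#'
#' The attention head scores each instance with a two-layer map
#' `s_k = w' tanh(V h_k')` — a hidden layer `V` (L x D, tanh) followed by a
#' linear layer `w` (L) — and normalizes the scores with a softmax. `L` is
#' the attention hidden size (conventional default 128).
#'
#' Initialization is near zero (`sd = 1e-3` by default): the pooling then
#' starts as an almost uniform average and the attention pattern is learned
#' rather than inherited from a random draw, which matters at the very
#' small fine-tuning learning rates used for this model.
#'
#' @param D embedding dimension.
#' @param L attention hidden size.
#' @param sd standard deviation of the normal initialization.
#' @param V,w optional explicit parameter values (`L x D` matrix, length-`L`
#'   vector); when given, `sd` is ignored.
#' @return Object of class `"attention_params"` with elements `V` and `w`.
#' @export
attention_params <- function(D, L = 128L, sd = 1e-3, V = NULL, w = NULL) {
  D <- as.integer(D); L <- as.integer(L)
  if (is.na(L) || L < 1L) stop_invalid("'L' must be a positive count")
  if (is.null(V)) V <- matrix(stats::rnorm(L * D, sd = sd), nrow = L)
  if (is.null(w)) w <- stats::rnorm(L, sd = sd)
  if (!is.matrix(V) || nrow(V) != L || ncol(V) != D || !all(is.finite(V)))
    stop_invalid("'V' must be a finite L x D matrix")
  if (length(w) != L || !all(is.finite(w)))
    stop_invalid("'w' must be a finite vector of length L")
  structure(list(V = V, w = as.numeric(w), L = L, D = D),
            class = "attention_params")
}

# numerically stabilized softmax
softmax_stable <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Attention-based MIL pooling
#'
#' Scores every instance with `s_k = w' tanh(V h_k')`, converts the scores
#' to weights `a = softmax(s)` (computed with max-subtraction so that
#' scores of magnitude up to about 700 per weight difference remain
#' stable), and returns the weighted average `z = sum_k a_k h_k` together
#' with the weights. The weights are strictly positive, sum to 1, and `z`
#' lies in the per-channel convex hull of the instance embeddings. The
#' operation is permutation-equivariant: shuffling instances permutes `a`
#' and leaves `z` unchanged.
#'
#' @param E numeric `K x D` embedding matrix.
#' @param params an [attention_params()] with matching `D`.
#' @return List with `z` (length-`D` bag representation) and `a` (length-`K`
#'   attention weights).
#' @examples
#' E <- matrix(rnorm(6), nrow = 3)
#' p <- attention_params(D = 2, L = 4)
#' r <- attention_pool_bag(E, p)
#' sum(r$a)  # 1
#' @export
attention_pool_bag <- function(E, params) {
  check_embeddings(E)
  if (!inherits(params, "attention_params"))
    stop_invalid("'params' must be attention_params")
  if (ncol(E) != ncol(params$V))
    stop_invalid("embedding dimension ", ncol(E),
                 " does not match attention D = ", ncol(params$V))
  Tm <- tanh(E %*% t(params$V))            # K x L
  s <- as.vector(Tm %*% params$w)          # K
  a <- softmax_stable(s)
  z <- as.vector(crossprod(E, a))
  list(z = z, a = a)
}

#' Classifier head for a bag representation
#'
#' A fully connected layer with sigmoid activation maps the pooled bag
#' representation to a probability in `[0, 1]`:
#' `p = logistic(weight . z + bias)`.
#'
#' @param z numeric length-`D` bag representation.
#' @param head list with `weight` (length `D`) and `bias` (scalar).
#' @return Probability of the positive (response) class.
#' @examples
#' classify_bag(c(1, 2), list(weight = c(0, 0), bias = 0))  # 0.5
#' @export
classify_bag <- function(z, head) {
  if (!all(is.finite(z))) stop_invalid("'z' contains non-finite values")
  if (length(head$weight) != length(z))
    stop_invalid("head dimension ", length(head$weight),
                 " does not match representation length ", length(z))
  stats::plogis(sum(head$weight * z) + head$bias)
}

# ---- forward/backward used by the trainer ---------------------------------

# pooling forward for one bag; returns z and a cache for the backward pass
pool_forward <- function(E, pooling, pp) {
  switch(pooling,
    max = {
      am <- max.col(t(E), ties.method = "first")   # argmax row per channel
      list(z = E[cbind(am, seq_len(ncol(E)))], cache = list(am = am))
    },
    conv = list(z = as.vector(crossprod(E, pp$u)), cache = NULL),
    attention = {
      Tm <- tanh(E %*% t(pp$V))
      s <- as.vector(Tm %*% pp$w)
      a <- softmax_stable(s)
      list(z = as.vector(crossprod(E, a)), cache = list(Tm = Tm, a = a))
    },
    stop_invalid("unknown pooling '", pooling, "'"))
}

# dz -> gradients wrt E and pooling parameters
pool_backward <- function(dz, E, pooling, pp, cache) {
  switch(pooling,
    max = {
      dE <- matrix(0, nrow(E), ncol(E))
      dE[cbind(cache$am, seq_len(ncol(E)))] <- dz
      list(dE = dE, dparams = NULL)
    },
    conv = list(dE = outer(pp$u, dz),
                dparams = list(u = as.vector(E %*% dz))),
    attention = {
      a <- cache$a; Tm <- cache$Tm
      da <- as.vector(E %*% dz)
      ds <- a * (da - sum(a * da))            # softmax Jacobian
      dE <- outer(a, dz)
      dpre <- outer(ds, pp$w) * (1 - Tm^2)    # K x L
      dV <- crossprod(dpre, E)                # L x D
      dw <- as.vector(crossprod(Tm, ds))
      list(dE = dE + dpre %*% pp$V, dparams = list(V = dV, w = dw))
    })
}
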