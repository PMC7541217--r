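#' Architecture of the patch classifier
#'
#' The classifier stacks convolutional clusters, each applying batch
#' normalisation, a SAME-padded convolution, a rectifier, 2x2 max pooling
#' (stride 2, floor truncation) and dropout, in that order, followed by two
#' fully connected layers: the first as wide as the flattened feature map,
#' the second with one neuron per class (true, false). Dropout stays
#' available at prediction time, which is what turns repeated forward
#' passes into Monte-Carlo posterior samples.
#'
#' The default is the full-scale stack: 4 clusters with kernel sides
#' 10/7/5/1 and depths 32/64/128/256, dropout 0.2.
#'
#' @param kernel_sides Integer vector of convolution kernel sides, one per
#'   cluster.
#' @param channel_depths Integer vector of output depths, same length.
#' @param dropout_rate Dropout probability in (0, 1).
#' @param n_outputs Number of classes (2: true, false).
#' @return A `cnn_architecture` list.
#' @export
cnn_architecture <- function(kernel_sides = c(10L, 7L, 5L, 1L),
                             channel_depths = c(32L, 64L, 128L, 256L),
                             dropout_rate = 0.2, n_outputs = 2L) {
  if (length(kernel_sides) != length(channel_depths)) {
    stop("kernel_sides and channel_depths must have equal length",
         call. = FALSE)
  }
  if (dropout_rate <= 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in (0, 1)", call. = FALSE)
  }
  structure(list(kernel_sides = as.integer(kernel_sides),
                 channel_depths = as.integer(channel_depths),
                 n_conv_clusters = length(kernel_sides),
                 dropout_rate = dropout_rate,
                 n_outputs = as.integer(n_outputs)),
            class = "cnn_architecture")
}

#' Desk-scale architecture
#'
#' A reduced three-cluster stack (depths 4, 8 and 16, 3x3 kernels) for small
#' synthetic patches; the full stack stays the default elsewhere.
#'
#' @param ... Overrides passed to [cnn_architecture].
#' @return A `cnn_architecture`.
#' @export
desk_architecture <- function(...) {
  args <- utils::modifyList(list(kernel_sides = c(3L, 3L, 3L),
                                 channel_depths = c(4L, 8L, 16L)), list(...))
  do.call(cnn_architecture, args)
}

#' Training configuration
#'
#' Softmax cross-entropy with an L2 weight-decay penalty, optimised with
#' Adam; weights start from the fan-balanced (Glorot) uniform scheme.
#' Full-scale defaults: learning rate 0.05, weight decay 0.001, Adam
#' beta1 = 0.9 / beta2 = 0.999, batches of 128 patches, 200,000 steps.
#' Desk runs use far fewer steps (see [desk_training_config]).
#'
#' @param learning_rate,weight_decay Positive scalars.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size Patches per step (>= 1).
#' @param max_steps Number of optimisation steps.
#' @param rng_seed Integer seed for batch sampling, dropout and init.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.05, weight_decay = 0.001,
                            beta1 = 0.9, beta2 = 0.999, batch_size = 128L,
                            max_steps = 200000L, rng_seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_steps >= 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

#' @rdname training_config
#' @param ... Overrides passed to [training_config].
#' @export
desk_training_config <- function(...) {
  args <- utils::modifyList(list(learning_rate = 0.005, batch_size = 32L,
                                 max_steps = 2000L), list(...))
  do.call(training_config, args)
}

#' Build an untrained patch classifier
#'
#' Validates that the patch side survives every pooling stage (each cluster
#' halves the map with floor truncation; the error names the first cluster
#' at which the map would collapse below 1x1) and initialises all weights.
#'
#' @param arch A [cnn_architecture].
#' @param patch_side_px Odd patch side in pixels.
#' @param seed Integer seed for the initialiser.
#' @return A `bcnn_model`.
#' @export
build_model <- function(arch, patch_side_px, seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  s <- as.integer(patch_side_px)
  for (i in seq_along(arch$kernel_sides)) {
    s <- s %/% 2L
    if (s < 1L) {
      stop(sprintf(
        "patch side %d collapses below 1x1 at cluster %d; use a larger patch",
        patch_side_px, i), call. = FALSE)
    }
  }
  params <- cpp_cnn_init(as.integer(patch_side_px), unclass(arch),
                         as.integer(seed))
  structure(list(arch = arch, patch_side_px = as.integer(patch_side_px),
                 params = params, trained = FALSE, init_seed = as.integer(seed),
                 loss_trace = numeric(0)),
            class = "bcnn_model")
}

#' @export
print.bcnn_model <- function(x, ...) {
  cat(sprintf(
    "<bcnn_model: %d-px patches, %d clusters (depths %s), %strained>\n",
    x$patch_side_px, x$arch$n_conv_clusters,
    paste(x$arch$channel_depths, collapse = "/"),
    if (x$trained) "" else "un"))
  invisible(x)
}

as_input_array <- function(patches) {
  if (inherits(patches, "patch_batch")) patches <- patch_windows(patches)
  if (is.matrix(patches)) patches <- array(patches, c(dim(patches), 1))
  stopifnot(length(dim(patches)) == 3, dim(patches)[1] == dim(patches)[2])
  patches / 255
}

#' Train the patch classifier
#'
#' @param model A `bcnn_model`.
#' @param patches A labelled `patch_batch` from [build_training_set], or a
#'   `side x side x N` array (then `labels` is required).
#' @param cfg A [training_config].
#' @param labels Integer labels (1 = true class, 0 = false class) when
#'   `patches` is a bare array.
#' @return The trained model, with `$loss_trace` holding the per-step loss
#'   (cross entropy plus the weight-decay penalty).
#' @export
train_model <- function(model, patches, cfg, labels = NULL) {
  stopifnot(inherits(model, "bcnn_model"), inherits(cfg, "training_config"))
  if (inherits(patches, "patch_batch")) {
    labels <- patches$labels
  }
  X <- as_input_array(patches)
  if (is.null(labels) || length(labels) != dim(X)[3]) {
    stop("need one label per patch", call. = FALSE)
  }
  if (length(unique(labels)) < 2 && cfg$max_steps > 0) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (dim(X)[1] != model$patch_side_px) {
    stop(sprintf("model expects %d-px patches, got %d px",
                 model$patch_side_px, dim(X)[1]), call. = FALSE)
  }
  if (cfg$max_steps == 0L) {
    model$trained <- TRUE
    return(model)
  }
  fit <- cpp_cnn_train(model$params, unclass(model$arch), X,
                       as.integer(labels), cfg$max_steps, cfg$batch_size,
                       cfg$learning_rate, cfg$weight_decay, cfg$beta1,
                       cfg$beta2, cfg$rng_seed)
  model$params <- fit$params
  model$loss_trace <- as.numeric(fit$loss_trace)
  if (any(!is.finite(model$loss_trace))) {
    warning("non-finite training loss encountered", call. = FALSE)
  }
  model$trained <- TRUE
  model
}

#' Bayesian prediction by Monte-Carlo dropout
#'
#' Runs `T` stochastic forward passes with dropout active (batch norm uses
#' its trained statistics) and summarises, per patch, the true-class softmax
#' output across passes: `mu` is the mean and `sigma` the sample standard
#' deviation (defined as 0 when `T = 1`).
#'
#' @param model A trained `bcnn_model`.
#' @param patches `patch_batch` or array; large batches are processed in
#'   chunks.
#' @param T Number of stochastic passes (>= 1); 17 passes retain the
#'   accuracy of larger ensembles at a fraction of the cost.
#' @param seed Integer seed for the dropout masks.
#' @param keep_passes Keep the per-pass probability matrix?
#' @param chunk_size Patches per forward chunk.
#' @return Data frame with columns `mu`, `sigma` (+ attribute `"passes"`
#'   when `keep_passes`).
#' @export
predict_bayesian <- function(model, patches, T = 17L, seed = 1L,
                             keep_passes = FALSE, chunk_size = 2048L) {
  stopifnot(inherits(model, "bcnn_model"))
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  n <- if (inherits(patches, "patch_batch")) patches$n else dim(patches)[3]
  mu <- sigma <- numeric(n)
  passes <- if (keep_passes) matrix(NA_real_, n, T) else NULL
  starts <- seq(1L, n, by = chunk_size)
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunk_size - 1L, n)
    Xc <- if (inherits(patches, "patch_batch")) {
      as_input_array(patch_windows(patches, idx))
    } else {
      as_input_array(patches[, , idx, drop = FALSE])
    }
    P <- cpp_cnn_predict(model$params, unclass(model$arch), Xc,
                         TRUE, T, as.integer(seed) + ci * 7919L)
    mu[idx] <- rowMeans(P)
    sigma[idx] <- if (T > 1L) apply(P, 1, stats::sd) else 0
    if (keep_passes) passes[idx, ] <- P
  }
  out <- data.frame(mu = mu, sigma = sigma)
  attr(out, "T") <- T
  if (keep_passes) attr(out, "passes") <- passes
  out
}

#' Deterministic prediction
#'
#' A single forward pass with dropout inactive; the label is the argmax of
#' the softmax, with an exact tie (true-class probability 0.5) resolved to
#' the false class.
#'
#' @param model A trained `bcnn_model`.
#' @param patches `patch_batch` or array.
#' @param chunk_size Patches per forward chunk.
#' @return Data frame with `prob_true` and logical `label`.
#' @export
predict_deterministic <- function(model, patches, chunk_size = 4096L) {
  stopifnot(inherits(model, "bcnn_model"))
  n <- if (inherits(patches, "patch_batch")) patches$n else dim(patches)[3]
  prob <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunk_size - 1L, n)
    Xc <- if (inherits(patches, "patch_batch")) {
      as_input_array(patch_windows(patches, idx))
    } else {
      as_input_array(patches[, , idx, drop = FALSE])
    }
    P <- cpp_cnn_predict_probs(model$params, unclass(model$arch), Xc)
    prob[idx] <- P[, 2]
  }
  data.frame(prob_true = prob, label = prob > 0.5)
}
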