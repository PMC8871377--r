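#' Training configuration for the embedding network
#'
#' Defaults follow the published training recipe for this detector: Adam,
#' mini-batches of 12, learning rate 0.001, 30 epochs, two output classes,
#' features constrained to a hypersphere of radius `alpha = 5`, and a
#' stratified 80/20 train/validation split.
#'
#' @param batch_size mini-batch size M.
#' @param n_classes number of classes C (2: AMD vs NORMAL).
#' @param alpha radius of the feature hypersphere (> 0).
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs (0 returns the initialized model).
#' @param optimizer only `"adam"` is implemented.
#' @param train_frac fraction of images in the training split, in (0, 1).
#' @param seed integer seed driving initialization, the split and batch
#'   shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 12, n_classes = 2, alpha = 5,
                         learning_rate = 0.001, epochs = 30,
                         optimizer = "adam", train_frac = 0.8, seed = 1) {
  assert_positive_int(batch_size, "batch_size")
  if (alpha <= 0) abort("`alpha` must be > 0")
  if (train_frac <= 0 || train_frac >= 1) abort("`train_frac` must lie in (0, 1)")
  if (epochs < 0 || epochs != floor(epochs)) abort("`epochs` must be a non-negative integer")
  if (!identical(optimizer, "adam")) abort('only optimizer = "adam" is implemented')
  structure(list(batch_size = as.integer(batch_size),
                 n_classes = as.integer(n_classes), alpha = alpha,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, train_frac = train_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Backbone specification
#'
#' `tiny_cnn` is the default desk-scale backbone: a small convolutional
#' network (two conv/ReLU/average-pool blocks and a dense layer to a 64-d
#' raw feature) trained here from scratch. `resnet50` names the full-scale
#' configuration; training it requires a deep-learning runtime and is not
#' bundled, so selecting it raises an informative error.
#'
#' @param kind `"tiny_cnn"` or `"resnet50"`.
#' @param pretrained whether a `resnet50` backbone would start from generic
#'   pretrained weights (ignored for `tiny_cnn`).
#' @param input_side side length the backbone downsamples inputs to
#'   (`tiny_cnn` only).
#' @param feature_dim raw feature dimension d (`tiny_cnn` only).
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(kind = c("tiny_cnn", "resnet50"),
                          pretrained = FALSE, input_side = 32,
                          feature_dim = 64) {
  kind <- match.arg(kind)
  structure(list(kind = kind, pretrained = isTRUE(pretrained),
                 input_side = as.integer(input_side),
                 feature_dim = as.integer(feature_dim)),
            class = "backbone_spec")
}

#' Project a raw feature onto the alpha-sphere
#'
#' The L2-Norm + Scale head: `alpha * x / ||x||_2`, so every output has
#' Euclidean norm exactly `alpha`. Applied row-wise when `x` is a matrix.
#'
#' @param x numeric vector, or matrix with one feature per row.
#' @param alpha sphere radius (> 0).
#' @return vector or matrix of the same shape with row norms `alpha`.
#' @export
#' @examples
#' l2_norm_scale(c(3, 4), alpha = 5) # unchanged: already on the 5-sphere
#' l2_norm_scale(c(1, 0, 0), alpha = 5) # c(5, 0, 0)
l2_norm_scale <- function(x, alpha = 5) {
  if (alpha <= 0) abort("`alpha` must be > 0")
  if (is.matrix(x)) {
    norms <- sqrt(rowSums(x^2))
    if (any(norms == 0)) {
      abort("zero feature vector cannot be projected onto the alpha-sphere")
    }
    alpha * x / norms
  } else {
    nrm <- sqrt(sum(x^2))
    if (nrm == 0) {
      abort("zero feature vector cannot be projected onto the alpha-sphere")
    }
    alpha * x / nrm
  }
}

#' L2-constrained softmax loss
#'
#' Mean negative log-probability of the true class under a softmax over the
#' `C` logits `W^T f(x) + b`, where every feature `f(x)` is constrained to
#' the hypersphere of radius `alpha`. The norm constraint is a contract: a
#' feature whose norm deviates from `alpha` beyond `tol` (relative)
#' indicates a missing L2-Norm layer upstream and raises an error.
#'
#' @param features numeric matrix, one feature per row, row norms `alpha`.
#' @param labels integer class ids in `1..C` (one per row).
#' @param W d x C weight matrix of the classification layer.
#' @param b length-C bias vector.
#' @param alpha expected feature norm.
#' @param tol relative norm tolerance.
#' @return the scalar loss (>= 0; `log(C)` at uniform logits).
#' @export
#' @examples
#' f <- l2_norm_scale(matrix(rnorm(8), 4), alpha = 5)
#' l2_softmax_loss(f, c(1, 2, 1, 2), W = matrix(0, 2, 2), b = c(0, 0)) # log(2)
l2_softmax_loss <- function(features, labels, W, b, alpha = 5, tol = 1e-3) {
  features <- as.matrix(features)
  norms <- sqrt(rowSums(features^2))
  if (any(abs(norms - alpha) > tol * alpha)) {
    abort(sprintf(
      "feature norm(s) deviate from alpha = %g beyond tolerance (range %.6g..%.6g): missing L2-Norm layer?",
      alpha, min(norms), max(norms)))
  }
  C <- ncol(W)
  if (any(labels < 1 | labels > C | labels != floor(labels))) {
    abort("`labels` must be integer class ids in 1..C")
  }
  logits <- sweep(features %*% W, 2, b, `+`)
  P <- softmax_rows(logits)
  -mean(log(P[cbind(seq_len(nrow(features)), labels)]))
}

embedding_classes <- c("NORMAL", "AMD")

binary_labels_of <- function(images) {
  labs <- map_chr(images$images, "binary_label")
  match(labs, embedding_classes)
}

# Stratified seeded split: returns indices of the training portion.
stratified_split <- function(y, frac, seed) {
  with_seed(seed, {
    idx <- unlist(lapply(unique(y), function(cl) {
      rows <- which(y == cl)
      sample(rows, round(frac * length(rows)))
    }))
    sort(idx)
  })
}

new_embedding_model <- function(params, spec, config, history,
                                trained_epochs) {
  structure(list(backbone = spec$kind, params = params, alpha = config$alpha,
                 feature_dim = spec$feature_dim,
                 input_side = spec$input_side, classes = embedding_classes,
                 config = config, history = history,
                 trained_epochs = trained_epochs),
            class = "embedding_model")
}

#' Train the embedding network
#'
#' Trains the backbone plus L2-Norm/Scale head and classification layer end
#' to end by minimizing the L2-constrained softmax loss with Adam, on the
#' binary AMD-vs-NORMAL labels. The split into training and validation
#' portions is seeded and stratified by class. After training the model is
#' used as a feature extractor ([extract_features()]): the classification
#' layer is never applied downstream.
#'
#' @param images an `oct_imageset` containing both classes.
#' @param config a [train_config()].
#' @param backbone a [backbone_spec()].
#' @return an `embedding_model` whose `history` tibble records per-epoch
#'   training and validation loss and accuracy.
#' @export
train_embedding <- function(images, config = train_config(),
                            backbone = backbone_spec()) {
  if (backbone$kind == "resnet50") {
    abort(paste("the resnet50 backbone requires a deep-learning runtime;",
                "train it externally and use its exported features, or use",
                'backbone_spec("tiny_cnn")'))
  }
  y <- binary_labels_of(images)
  if (length(unique(y)) < 2) {
    abort("training requires both classes (AMD and NORMAL) present")
  }
  side <- backbone$input_side
  dims <- tiny_cnn_dims(side)
  idx1 <- im2col_idx(side, side, 1L)
  idx2 <- im2col_idx(dims$p1, dims$p1, 8L)
  params <- init_tiny_cnn(side, backbone$feature_dim, config$n_classes,
                          derive_seed(config$seed, 1L))
  history <- tibble(epoch = integer(), train_loss = numeric(),
                    train_acc = numeric(), val_loss = numeric(),
                    val_acc = numeric())
  if (config$epochs == 0) {
    return(new_embedding_model(params, backbone, config, history, 0L))
  }
  tr <- stratified_split(y, config$train_frac, derive_seed(config$seed, 2L))
  va <- setdiff(seq_along(y), tr)
  Xtr <- prep_tensor(images$images[tr], side); ytr <- y[tr]
  Xva <- prep_tensor(images$images[va], side); yva <- y[va]
  state <- adam_init(params)
  eval_split <- function(X, yy) {
    if (length(yy) == 0) return(c(NA_real_, NA_real_))
    fw <- tiny_cnn_raw_features(params, X, idx1, idx2, dims)
    feat <- l2_norm_scale(fw$raw, config$alpha)
    logits <- sweep(feat %*% params$Wc, 2, params$bc, `+`)
    P <- softmax_rows(logits)
    c(-mean(log(P[cbind(seq_along(yy), yy)] + 1e-12)),
      mean(max.col(P, ties.method = "first") == yy))
  }
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 3L, ep),
                     sample.int(length(ytr)))
    losses <- c(); accs <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
      res <- tiny_cnn_batch_grad(params, Xtr[, , bi, drop = FALSE], ytr[bi],
                                 config$alpha, idx1, idx2, dims)
      if (!is.finite(res$loss)) {
        abort(sprintf("non-finite loss at epoch %d: training diverged", ep))
      }
      upd <- adam_step(params, res$grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      losses <- c(losses, res$loss); accs <- c(accs, res$acc)
    }
    ev <- eval_split(Xva, yva)
    history <- bind_rows(history, tibble(
      epoch = ep, train_loss = mean(losses), train_acc = mean(accs),
      val_loss = ev[1], val_acc = ev[2]))
  }
  new_embedding_model(params, backbone, config, history, config$epochs)
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> backbone %s, d = %d, alpha = %g, %d epoch(s) trained\n",
              x$backbone, x$feature_dim, x$alpha, x$trained_epochs))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final epoch: train loss %.4f acc %.3f | val loss %.4f acc %.3f\n",
                last$train_loss, last$train_acc, last$val_loss, last$val_acc))
  }
  invisible(x)
}

#' Tidy the training history of an embedding model
#'
#' @param x an `embedding_model`.
#' @param ... unused.
#' @return the per-epoch history tibble.
#' @method tidy embedding_model
#' @export
tidy.embedding_model <- function(x, ...) x$history

#' Extract alpha-sphere features
#'
#' Runs images through the backbone and the L2-Norm/Scale head; the
#' classification layer is never applied. Every returned row has Euclidean
#' norm `alpha`.
#'
#' @param model an `embedding_model`.
#' @param images an `oct_imageset` (may be empty).
#' @return an `n x d` numeric matrix, one feature per image, in input
#'   order; a 0-row matrix for an empty image set.
#' @export
extract_features <- function(model, images) {
  stopifnot(inherits(model, "embedding_model"))
  n <- length(images$images)
  if (n == 0) return(matrix(numeric(0), nrow = 0, ncol = model$feature_dim))
  side <- model$input_side
  dims <- tiny_cnn_dims(side)
  idx1 <- im2col_idx(side, side, 1L)
  idx2 <- im2col_idx(dims$p1, dims$p1, 8L)
  X <- prep_tensor(images$images, side)
  fw <- tiny_cnn_raw_features(model$params, X, idx1, idx2, dims)
  l2_norm_scale(fw$raw, model$alpha)
}

#' Write a feature matrix as CSV
#'
#' One row per image; feature columns `f1..fd`, last column `id` carrying
#' the image identifier, for interoperability with external tooling.
#'
#' @param features numeric matrix from [extract_features()].
#' @param ids character identifiers, one per row.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, ids, path) {
  df <- as.data.frame(features)
  names(df) <- sprintf("f%d", seq_len(ncol(features)))
  df$id <- ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features_csv()]
#'
#' @param path CSV path.
#' @return list with `features` (matrix) and `ids` (character).
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df$id)
  df$id <- NULL
  list(features = as.matrix(df), ids = ids)
}

#' Save / load an embedding model
#'
#' The model (weights and configuration) is serialized with
#' [base::saveRDS()]; a sidecar JSON records the training configuration and
#' feature dimension for provenance.
#'
#' @param model an `embedding_model`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_embedding <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  meta <- list(backbone = model$backbone, feature_dim = model$feature_dim,
               alpha = model$alpha, input_side = model$input_side,
               trained_epochs = model$trained_epochs,
               config = unclass(model$config))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_embedding
#' @param dir directory written by [save_embedding()].
#' @export
load_embedding <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
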