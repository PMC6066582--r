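#' Stacked sparse autoencoder (SSAE) models
#'
#' An SSAE is an ordered stack of the *encoding* halves of greedily trained
#' sparse autoencoders: autoencoder 1 is trained on the input features,
#' autoencoder l on the hidden activations of the partial stack 1..(l-1);
#' after each greedy stage the decoding half is discarded. An SSAE trained
#' unsupervised on a large healthy-connectome corpus is the transferable
#' "prototype" at the heart of the transfer-learning workflow.
#'
#' @name ssae
NULL

new_ssae <- function(encoders, layer_sizes, hyperparams, provenance, seed) {
  stopifnot(provenance %in% c("offline", "target-pretrained"))
  L <- length(encoders)
  stopifnot(L >= 1, length(layer_sizes) == L + 1)
  for (l in seq_len(L)) {
    W <- encoders[[l]]$W
    stopifnot(nrow(W) == layer_sizes[l + 1], ncol(W) == layer_sizes[l],
              length(encoders[[l]]$b) == layer_sizes[l + 1],
              all(is.finite(W)), all(is.finite(encoders[[l]]$b)))
  }
  structure(list(encoders = encoders, layer_sizes = as.integer(layer_sizes),
                 hyperparams = hyperparams, provenance = provenance,
                 seed = as.integer(seed)),
            class = "ssae")
}

#' Train a stacked sparse autoencoder greedily
#'
#' Trains `length(hp$layer_sizes)` sparse autoencoders layer by layer: each
#' stage trains on the hidden activations produced by the encoders of all
#' previous stages (stage 1 trains on `X` itself), keeps the encoding half
#' and discards the decoding half. Training is unsupervised: the function
#' receives a feature matrix only, so offline learning can never see task
#' labels. Stage l uses seed `hp$seed + l - 1`.
#'
#' @param X sample-by-feature matrix (the training corpus).
#' @param hp a [hyperparams()] object; `hp$layer_sizes` gives the widths.
#' @param provenance `"offline"` (prototype learned on an independent healthy
#'   corpus) or `"target-pretrained"` (conventional pretraining on the target
#'   task's own training data).
#' @return An object of class `"ssae"`.
#' @export
train_ssae <- function(X, hp, provenance = c("offline", "target-pretrained")) {
  provenance <- match.arg(provenance)
  X <- scale_features(as.matrix(X), hp)
  L <- length(hp$layer_sizes)
  encoders <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    hp_l <- hp
    hp_l$seed <- hp$seed + l - 1L
    ae <- train_sparse_ae(A, hp$layer_sizes[l], hp_l)
    encoders[[l]] <- list(W = ae$W1, b = ae$b1)
    A <- ae_encode(ae, A)
    if (any(!is.finite(A)))
      stop("train_ssae: non-finite activations after greedy stage ", l)
  }
  new_ssae(encoders, c(ncol(X), hp$layer_sizes), hp, provenance, hp$seed)
}

#' Extract top-layer SSAE features
#'
#' Composes the sigmoid encoding maps of all layers, turning raw
#' connectivity features into the high-level representation used by the
#' classifier head.
#'
#' @param model an `"ssae"`. @param X matrix whose width equals the model's
#'   input width (or a single feature vector).
#' @return Matrix of top-layer activations (entries in (0, 1)).
#' @export
ssae_extract <- function(model, X) {
  X <- as_row_matrix(X, model$layer_sizes[1], "ssae_extract")
  A <- X
  for (enc in model$encoders)
    A <- sigmoid(sweep(A %*% t(enc$W), 2L, enc$b, "+"))
  A
}

#' Transfer-initialize from an offline prototype
#'
#' Returns an independent copy of an offline-learned SSAE prototype, ready
#' to initialize a transfer-learning classifier. Mutating the copy never
#' affects the prototype. Models that were pretrained on the target task
#' are refused: passing one here indicates a pipeline wiring bug.
#'
#' @param prototype an `"ssae"` with `provenance == "offline"`.
#' @return An `"ssae"` with parameters bit-identical to the prototype.
#' @export
transfer_init <- function(prototype) {
  stopifnot(inherits(prototype, "ssae"))
  if (!identical(prototype$provenance, "offline"))
    stop("transfer_init: prototype must have provenance 'offline', got '",
         prototype$provenance, "' (pipeline wiring bug?)")
  prototype   # R copy-on-modify semantics give an isolated copy
}

#' @export
print.ssae <- function(x, ...) {
  cat("SSAE (", x$provenance, "): ",
      paste(x$layer_sizes, collapse = "-"), "\n", sep = "")
  invisible(x)
}

# ---- portable model container (JSON, full double precision) ----

#' Write / read SSAE and classifier models
#'
#' Models are stored as a portable JSON container holding layer sizes,
#' per-layer weights and biases at full double precision (17 significant
#' digits, bit-exact on round-trip), hyperparameters, provenance tag and
#' creation seed. Classifier models additionally store the softmax
#' coefficients, class mapping, mode and fine-tuning trace.
#'
#' @param model an `"ssae"` or `"dtlnn"` object. @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   reconstructed model.
#' @export
write_model <- function(model, path) {
  obj <- serialize_model(model)
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

serialize_model <- function(model) {
  if (inherits(model, "ssae")) {
    list(type = "ssae",
         layer_sizes = model$layer_sizes,
         encoders = lapply(model$encoders, function(e)
           list(W = e$W, b = e$b)),
         hyperparams = unclass(model$hyperparams),
         provenance = model$provenance,
         seed = model$seed)
  } else if (inherits(model, "dtlnn")) {
    list(type = "dtlnn",
         ssae = serialize_model(model$ssae),
         theta = model$head$theta,
         intercept = model$head$intercept,
         classes = model$classes,
         mode = model$mode,
         fine_tuned = model$fine_tuned,
         training_log = model$training_log)
  } else stop("write_model: unsupported model class")
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  deserialize_model(obj)
}

deserialize_model <- function(obj) {
  if (identical(obj$type, "ssae")) {
    hp <- do.call(hyperparams, obj$hyperparams)
    encoders <- lapply(obj$encoders, function(e)
      list(W = as.matrix(e$W), b = as.numeric(e$b)))
    new_ssae(encoders, obj$layer_sizes, hp, obj$provenance, obj$seed)
  } else if (identical(obj$type, "dtlnn")) {
    ssae <- deserialize_model(obj$ssae)
    head <- softmax_model(as.matrix(obj$theta),
                          if (is.null(obj$intercept)) NULL
                          else as.numeric(obj$intercept))
    new_dtlnn(ssae, head, obj$classes, obj$mode,
              fine_tuned = isTRUE(obj$fine_tuned),
              training_log = obj$training_log)
  } else stop("read_model: unrecognized model container")
}
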