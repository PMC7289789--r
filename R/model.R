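#' Multi-branch classifier configuration
#'
#' One configuration defines a classifier with one convolutional branch per
#' enabled feature block: \code{"S"} (one-hot sequence, 4 channels),
#' \code{"F"} (one-hot dot-bracket structure, 3 channels), \code{"C"} (raw
#' conservation, 1 channel). Every enabled branch runs the same stack of
#' exactly three convolutional layers (ReLU, width-2 max pooling); branch
#' outputs are flattened, concatenated and passed through a dense ReLU layer
#' to a single logistic output.
#'
#' Layer hyperparameters are configuration, not fixed truth: the defaults
#' (filters 32/64/128, kernel 5, pool 2, 64 dense units, Adam at 1e-3) are
#' chosen to train in minutes on a CPU at the 100-bp input length and can be
#' overridden wholesale.
#'
#' @param branches character vector, non-empty subset of
#'   \code{c("S", "F", "C")}.
#' @param filters integer vector of length 3: filters per conv layer.
#' @param kernel odd convolution kernel width (shared across layers).
#' @param pool pooling width after each conv layer.
#' @param dense_units units of the fully connected layer.
#' @param class_weighting balance classes by inverse frequency
#'   (\code{N/(2*N_c)}); \code{FALSE} reproduces the unweighted ("-U")
#'   variants.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss (ignored when
#'   no validation set is supplied).
#' @param input_length model input length L in bp.
#' @param seed RNG seed controlling weight initialization and shuffling.
#' @return A \code{model_config} list.
#' @export
model_config <- function(branches = c("S", "F", "C"),
                         filters = c(32L, 64L, 128L),
                         kernel = 5L, pool = 2L, dense_units = 64L,
                         class_weighting = TRUE, learning_rate = 1e-3,
                         batch_size = 64L, epochs = 30L, patience = 5L,
                         input_length = 100L, seed = 1L) {
  branches <- unique(as.character(branches))
  if (length(branches) == 0L) {
    stop("model_config: branch set must be non-empty", call. = FALSE)
  }
  if (!all(branches %in% c("S", "F", "C"))) {
    stop("model_config: branches must be a subset of S, F, C", call. = FALSE)
  }
  stopifnot(length(filters) == 3L, kernel %% 2L == 1L, kernel >= 1L,
            pool >= 1L, dense_units >= 1L, epochs >= 1L, batch_size >= 1L)
  conv <- lapply(seq_len(3L), function(l) {
    list(filters = as.integer(filters[l]), kernel = as.integer(kernel),
         activation = "relu", pool = as.integer(pool))
  })
  structure(list(branches = branches, conv = conv,
                 dense_units = as.integer(dense_units),
                 class_weighting = isTRUE(class_weighting),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 input_length = as.integer(input_length),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained model from a configuration
#'
#' Initializes the network weights (He-normal, seeded by
#' \code{config$seed}). The model accepts exactly one feature block per
#' enabled branch and produces a scalar probability per example.
#'
#' @param config a \code{model_config}.
#' @return An untrained \code{snc_model}.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  structure(list(config = config, params = nn_init_params(config),
                 history = NULL, trained = FALSE),
            class = "snc_model")
}

#' Inverse-frequency class weights
#'
#' \code{weight_c = N_total / (2 * N_c)}; with weighting disabled both
#' classes get weight 1.
#'
#' @param labels vector of 0/1 labels, both classes present.
#' @param enabled \code{FALSE} returns unit weights (the "-U" variants).
#' @return named numeric vector \code{c("0" = w0, "1" = w1)}.
#' @export
class_weights <- function(labels, enabled = TRUE) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("class_weights: both classes must be present", call. = FALSE)
  }
  if (!enabled) return(c("0" = 1, "1" = 1))
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Train a model on encoded, labelled windows
#'
#' Minimizes (optionally class-weighted) binary cross-entropy with Adam.
#' Training is reproducible: \code{config$seed} fixes initialization and
#' shuffling, so identical inputs in identical order give identical weights.
#' With a validation set, training stops early after
#' \code{config$patience} epochs without validation-loss improvement and the
#' best weights are restored.
#'
#' @param model an \code{snc_model} from \code{\link{build_model}}.
#' @param examples encoded batch (from \code{\link{encode_windows}}) with
#'   0/1 \code{labels}; both classes must be present.
#' @param validation optional encoded batch with labels for early stopping.
#' @param config optional \code{model_config} overriding the model's.
#' @param verbose print per-epoch losses.
#' @return The trained \code{snc_model} with a \code{history} data.frame
#'   (epoch, train_loss, val_loss).
#' @export
train_model <- function(model, examples, validation = NULL, config = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "snc_model"))
  config <- config %||NULL% model$config
  y <- as.numeric(examples$labels)
  if (length(y) == 0L || anyNA(y)) {
    stop("train_model: examples must carry 0/1 labels", call. = FALSE)
  }
  cw <- class_weights(y, enabled = config$class_weighting)
  wts <- unname(cw[as.character(y)])
  set.seed(config$seed)
  params <- nn_init_params(config)
  state <- adam_init(params)
  n <- length(y)
  inputs <- examples[c("S", "F", "C")]
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; best_params <- params; stale <- 0L
  val_y <- if (!is.null(validation)) as.numeric(validation$labels)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (b0 in seq.int(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      bin <- subset_inputs(inputs, config$branches, idx)
      fwd <- nn_forward(params, config, bin, keep_cache = TRUE)
      loss <- bce_loss(fwd$p, y[idx], wts[idx])
      epoch_loss <- epoch_loss + loss * length(idx)
      grads <- nn_backward(params, config, bin, fwd, y[idx], wts[idx])
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    train_loss <- epoch_loss / n
    val_loss <- NA_real_
    if (!is.null(validation)) {
      vp <- nn_predict_batched(params, config, validation)
      vw <- unname(cw[as.character(val_y)])
      val_loss <- bce_loss(vp, val_y, vw)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose) {
      snc_log("epoch %d: train %.4f val %s", epoch, train_loss,
              ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)))
    }
    if (!is.null(validation)) {
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_params <- params; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  }
  if (!is.null(validation)) params <- best_params
  model$config <- config
  model$params <- params
  model$history <- history
  model$trained <- TRUE
  model
}

`%||NULL%` <- function(a, b) if (is.null(a)) b else a

nn_predict_batched <- function(params, config, batch, chunk = 8192L,
                               use_compiled = TRUE) {
  for (br in config$branches) {
    X <- batch[[br]]
    if (is.null(X) || length(dim(X)) != 3L ||
        dim(X)[2] != config$input_length ||
        dim(X)[3] != branch_channels[[br]]) {
      stop(sprintf("shape error: branch %s expects (N, %d, %d) input",
                   br, config$input_length, branch_channels[[br]]),
           call. = FALSE)
    }
  }
  n <- dim(batch[[config$branches[1]]])[1]
  if (n == 0L) return(numeric(0))
  if (use_compiled) {
    conv_w <- lapply(stats::setNames(nm = config$branches), function(br)
      lapply(seq_along(config$conv), function(l) params[[pname(br, l, "W")]]))
    conv_b <- lapply(stats::setNames(nm = config$branches), function(br)
      lapply(seq_along(config$conv), function(l) params[[pname(br, l, "b")]]))
    out <- numeric(n)
    for (b0 in seq.int(1L, n, by = chunk)) {
      idx <- b0:min(b0 + chunk - 1L, n)
      bin <- subset_inputs(batch, config$branches, idx)
      out[idx] <- .nn_forward_scores(bin, conv_w, conv_b, params$dense_W,
                                     params$dense_b, drop(params$out_W),
                                     params$out_b, config$branches,
                                     config$conv[[1]]$pool)
    }
    return(out)
  }
  out <- numeric(n)
  for (b0 in seq.int(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    bin <- subset_inputs(batch, config$branches, idx)
    out[idx] <- nn_forward(params, config, bin)$p
  }
  out
}

#' Score encoded windows with a trained model
#'
#' @param model a trained \code{snc_model}.
#' @param windows encoded batch from \code{\link{encode_windows}} (or any
#'   list holding the branch arrays the model needs).
#' @return numeric vector of probabilities in [0, 1], one per window, order
#'   preserved; deterministic given weights and input.
#' @export
predict_scores <- function(model, windows) {
  stopifnot(inherits(model, "snc_model"))
  if (!isTRUE(model$trained)) {
    stop("predict_scores: model is untrained", call. = FALSE)
  }
  nn_predict_batched(model$params, model$config, windows)
}

#' @export
predict.snc_model <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

MODEL_FORMAT <- "sncscan-model-1"

#' Save / load a trained model
#'
#' A single-file archive embedding the configuration, weights and training
#' history. Round-trips preserve predictions bit-for-bit.
#'
#' @param model a trained \code{snc_model}.
#' @param path file path.
#' @return \code{save_model}: \code{path} invisibly; \code{load_model}: the
#'   \code{snc_model}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "snc_model"))
  saveRDS(list(format = MODEL_FORMAT, config = model$config,
               params = model$params, history = model$history,
               trained = model$trained), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("load_model: cannot read model file ", path, " (", conditionMessage(e),
         ")", call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    stop("load_model: ", path, " is not a ", MODEL_FORMAT, " archive",
         call. = FALSE)
  }
  structure(list(config = obj$config, params = obj$params,
                 history = obj$history, trained = obj$trained),
            class = "snc_model")
}

#' Read only the configuration from a model archive
#' @param path model file path.
#' @return the embedded \code{model_config}.
#' @export
read_model_config <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("read_model_config: cannot read ", path, call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    stop("read_model_config: ", path, " is not a ", MODEL_FORMAT, " archive",
         call. = FALSE)
  }
  obj$config
}

#' Write training history as TSV
#' @param model trained model.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_history <- function(model, path) {
  utils::write.table(model$history, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
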