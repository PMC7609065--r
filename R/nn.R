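#' Architecture specification for the per-frame classifier
#'
#' Describes the sequence model: an initial 1-D convolution, `n_res_blocks`
#' pre-activation residual blocks (batch norm, ReLU, convolution twice,
#' additive skip with a 1x1 projection where the filter count grows,
#' followed by stride-1 max pooling), a final batch norm + ReLU, a
#' bidirectional LSTM with dropout on its outputs, and a per-frame dense
#' softmax over the six classes. The filter count starts at `base_filters`
#' (2^5 = 32 in the full recipe) and doubles every `grow_every` blocks while
#' the kernel size starts at `kernel_start` and shrinks by `kernel_step`
#' at the same cadence (never below 4). Output length always equals input
#' length: the model labels every frame.
#'
#' The full-scale recipe (`n_res_blocks = 16`) is expensive to train on a
#' laptop CPU; the defaults here are a reduced model of the same family
#' suitable for desk-scale experiments. All sizes are configurable.
#'
#' @param n_channels 3 for ALEX (DD, DA, AA), 2 for non-ALEX.
#' @param n_classes Number of output classes (6).
#' @param n_res_blocks Number of residual blocks.
#' @param base_filters Filters in the first block group.
#' @param grow_every Double the filters / shrink the kernel every this many
#'   blocks.
#' @param kernel_start Kernel size of the initial convolution and first
#'   block group.
#' @param kernel_step Kernel reduction per block group.
#' @param lstm_units Hidden units per LSTM direction.
#' @param dropout Dropout rate on the LSTM outputs (training only).
#' @param pool Width of the stride-1 max pooling after each block.
#' @return An object of class `nn_spec`.
#' @export
nn_spec <- function(n_channels = 3L, n_classes = 6L, n_res_blocks = 4L,
                    base_filters = 32L, grow_every = 4L, kernel_start = 12L,
                    kernel_step = 4L, lstm_units = 32L, dropout = 0.2,
                    pool = 2L) {
  if (!n_channels %in% c(2L, 3L)) stop("n_channels must be 2 or 3")
  stopifnot(n_res_blocks >= 1L, base_filters >= 1L, lstm_units >= 1L,
            dropout >= 0, dropout < 1)
  stage <- (seq_len(n_res_blocks) - 1L) %/% grow_every
  filters <- as.integer(base_filters * 2^stage)
  kernels <- pmax(4L, as.integer(kernel_start - kernel_step * stage))
  structure(list(
    n_channels = as.integer(n_channels), n_classes = as.integer(n_classes),
    n_res_blocks = as.integer(n_res_blocks),
    base_filters = as.integer(base_filters),
    grow_every = as.integer(grow_every),
    kernel_start = as.integer(kernel_start),
    kernel_step = as.integer(kernel_step),
    filters = filters, kernels = kernels,
    lstm_units = as.integer(lstm_units), dropout = dropout,
    pool = as.integer(pool)
  ), class = "nn_spec")
}

#' The full-scale architecture recipe
#'
#' Sixteen residual blocks, 32 base filters doubling every 4th block
#' (32, 64, 128, 256), kernel sizes 16 shrinking by 4 every 4th block
#' (16, 12, 8, 4), 16 bidirectional LSTM units. Training this on ~150,000
#' traces takes CPU-hours; it is provided for full reproductions.
#'
#' @inheritParams nn_spec
#' @return An `nn_spec`.
#' @export
nn_spec_full <- function(n_channels = 3L) {
  nn_spec(n_channels = n_channels, n_res_blocks = 16L, base_filters = 32L,
          grow_every = 4L, kernel_start = 16L, kernel_step = 4L,
          lstm_units = 16L, dropout = 0.4, pool = 2L)
}

#' @export
print.nn_spec <- function(x, ...) {
  cat(sprintf("sequence classifier spec: %d input channel(s) -> %d classes\n",
              x$n_channels, x$n_classes))
  cat(sprintf("  %d residual block(s); filters: %s; kernels: %s\n",
              x$n_res_blocks, paste(x$filters, collapse = ","),
              paste(x$kernels, collapse = ",")))
  cat(sprintf("  biLSTM %d units, dropout %.2f, pool %d\n",
              x$lstm_units, x$dropout, x$pool))
  invisible(x)
}

# He (variance-scaling) initialization for convolutions, small uniform for
# recurrent weights; LSTM forget-gate bias starts at 1.
init_nn_params <- function(spec) {
  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  p <- list()
  k0 <- spec$kernels[1]
  f0 <- spec$filters[1]
  p$conv0_W <- he(k0 * spec$n_channels, f0, k0 * spec$n_channels)
  p$conv0_b <- numeric(f0)
  cin <- f0
  for (i in seq_len(spec$n_res_blocks)) {
    pre <- paste0("b", i - 1L, "_")
    f <- spec$filters[i]
    k <- spec$kernels[i]
    p[[paste0(pre, "bn1_g")]] <- rep(1, cin)
    p[[paste0(pre, "bn1_b")]] <- numeric(cin)
    p[[paste0(pre, "cA_W")]] <- he(k * cin, f, k * cin)
    p[[paste0(pre, "cA_b")]] <- numeric(f)
    p[[paste0(pre, "bn2_g")]] <- rep(1, f)
    p[[paste0(pre, "bn2_b")]] <- numeric(f)
    p[[paste0(pre, "cB_W")]] <- he(k * f, f, k * f)
    p[[paste0(pre, "cB_b")]] <- numeric(f)
    if (cin != f) {
      p[[paste0(pre, "proj_W")]] <- he(cin, f, cin)
      p[[paste0(pre, "proj_b")]] <- numeric(f)
    }
    cin <- f
  }
  p$fbn_g <- rep(1, cin)
  p$fbn_b <- numeric(cin)
  H <- spec$lstm_units
  for (dir in c("lstm_f_", "lstm_b_")) {
    p[[paste0(dir, "Wx")]] <- glorot(cin, 4L * H)
    p[[paste0(dir, "Wh")]] <- glorot(H, 4L * H)
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget gate bias
    p[[paste0(dir, "b")]] <- b
  }
  p$dense_W <- glorot(2L * H, spec$n_classes)
  p$dense_b <- numeric(spec$n_classes)
  p
}

init_run_stats <- function(spec) {
  rs <- list()
  cin <- spec$filters[1]
  for (i in seq_len(spec$n_res_blocks)) {
    pre <- paste0("b", i - 1L, "_")
    f <- spec$filters[i]
    rs[[paste0(pre, "bn1_m")]] <- numeric(cin)
    rs[[paste0(pre, "bn1_v")]] <- rep(1, cin)
    rs[[paste0(pre, "bn2_m")]] <- numeric(f)
    rs[[paste0(pre, "bn2_v")]] <- rep(1, f)
    cin <- f
  }
  rs$fbn_m <- numeric(cin)
  rs$fbn_v <- rep(1, cin)
  rs
}

#' Training configuration
#'
#' Mirrors the published optimization recipe: minibatches of 32 with the
#' Adam optimizer at learning rate 0.001, the rate divided by 10 after two
#' consecutive epochs without validation-loss improvement, early stopping
#' after five such epochs, an 80/20 train/validation split by trace, and
#' label smoothing 0.05.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay_factor Division factor on plateau.
#' @param lr_patience Epochs without improvement before decaying.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param epochs Maximum epochs.
#' @param train_fraction Fraction of traces used for training (rest for
#'   validation).
#' @param label_smoothing Smoothing strength for the targets.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 0.001,
                         lr_decay_factor = 10, lr_patience = 2L,
                         early_stop_patience = 5L, epochs = 20L,
                         train_fraction = 0.8, label_smoothing = 0.05) {
  stopifnot(train_fraction > 0, train_fraction < 1, batch_size >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 epochs = as.integer(epochs),
                 train_fraction = train_fraction,
                 label_smoothing = label_smoothing),
            class = "train_config")
}

#' Convert a labelled dataset to training arrays
#'
#' Normalizes every trace to its global maximum and stacks channels and
#' smoothed labels into the dense arrays consumed by the trainer.
#'
#' @param dataset A [generate_dataset()] result with stored traces.
#' @param label_smoothing Smoothing strength.
#' @return List with `x` (frames x channels x traces), `y` (frames x 6 x
#'   traces) and `hard` (frames x traces integer matrix of true classes).
#' @export
training_arrays <- function(dataset, label_smoothing = 0.05) {
  stopifnot(inherits(dataset, "fret_dataset"), !is.null(dataset$traces))
  trs <- dataset$traces
  n <- length(trs)
  stopifnot(n > 0)
  t0 <- trs[[1]]$trace$n_frames
  nc <- if (is.null(trs[[1]]$trace$aa)) 2L else 3L
  x <- array(0, dim = c(t0, nc, n))
  y <- array(0, dim = c(t0, 6L, n))
  hard <- matrix(0L, t0, n)
  for (i in seq_len(n)) {
    tr <- normalize_trace(trs[[i]]$trace)
    x[, 1, i] <- tr$dd
    x[, 2, i] <- tr$da
    if (nc == 3L) x[, 3, i] <- tr$aa
    y[, , i] <- smooth_labels(trs[[i]]$labels, eps = label_smoothing)
    hard[, i] <- as.integer(trs[[i]]$labels)
  }
  list(x = x, y = y, hard = hard)
}

#' Train the per-frame six-class sequence classifier
#'
#' Minimizes the cross-entropy between per-frame softmax outputs and the
#' label-smoothed ground truth with Adam, honoring the learning-rate
#' plateau schedule and early stopping of [train_config()]. Input traces
#' are expected normalized (see [training_arrays()], which is applied
#' automatically when a dataset is given).
#'
#' @param data A [generate_dataset()] result (with traces) or a list with
#'   arrays `x` and `y` as produced by [training_arrays()].
#' @param spec An [nn_spec()].
#' @param config A [train_config()].
#' @param seed Integer seed for weight initialization, the train/validation
#'   split, batch shuffling and dropout.
#' @param verbose Print per-epoch progress?
#' @return An object of class `fret_nn` with elements `params`, `run_stats`,
#'   `spec`, `history` (per-epoch train/validation loss and learning rate)
#'   and `classes`.
#' @export
train_classifier <- function(data, spec = nn_spec(), config = train_config(),
                             seed = 1L, verbose = TRUE) {
  if (inherits(data, "fret_dataset")) {
    data <- training_arrays(data, label_smoothing = config$label_smoothing)
  }
  x <- data$x
  y <- data$y
  if (length(dim(x)) != 3L) stop("x must be a 3-d array")
  n <- dim(x)[3]
  if (n < 2L) stop("need at least 2 traces to train")
  if (dim(x)[2] != spec$n_channels) {
    stop("channel mismatch: data has ", dim(x)[2], " channels, spec wants ",
         spec$n_channels)
  }
  dominant <- apply(y, c(1, 3), which.max)
  if (length(unique(as.vector(dominant))) < 2L) {
    warning("degenerate training set: all frames carry a single class")
  }
  set.seed(seed)
  params <- init_nn_params(spec)
  rstats <- init_run_stats(spec)
  cspec <- spec_for_cpp(spec)

  idx <- sample.int(n)
  n_train <- max(1L, floor(config$train_fraction * n))
  tr_idx <- idx[seq_len(n_train)]
  va_idx <- idx[-seq_len(n_train)]
  if (length(va_idx) == 0L) va_idx <- tr_idx[1]

  # Adam state
  m <- lapply(params, function(w) w * 0)
  v <- lapply(params, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L

  best_val <- Inf
  best_params <- params
  best_rstats <- rstats
  bad_epochs <- 0L
  history <- data.frame()

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    nb <- ceiling(length(ord) / config$batch_size)
    tr_loss <- 0
    for (b in seq_len(nb)) {
      bi <- ord[((b - 1L) * config$batch_size + 1L):
                  min(b * config$batch_size, length(ord))]
      xb <- x[, , bi, drop = FALSE]
      yb <- y[, , bi, drop = FALSE]
      out <- .nn_core_cpp(params, rstats, cspec, xb, yb,
                          training = TRUE, want_grad = TRUE)
      rstats <- out$run_stats
      g <- out$grads
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(params)) {
        gi <- g[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gi
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gi^2
        params[[nm]] <- params[[nm]] -
          lr * corr * m[[nm]] / (sqrt(v[[nm]]) + eps)
      }
      tr_loss <- tr_loss + out$loss * length(bi)
    }
    tr_loss <- tr_loss / length(ord)

    val_loss <- nn_eval_loss(params, rstats, cspec, x, y, va_idx,
                             config$batch_size)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tr_loss,
                                val_loss = val_loss, lr = lr))
    if (verbose) {
      message(sprintf("epoch %2d: train %.4f  val %.4f  (lr %g)",
                      epoch, tr_loss, val_loss, lr))
    }
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss
      best_params <- params
      best_rstats <- rstats
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs %% config$lr_patience == 0L) {
        lr <- lr / config$lr_decay_factor
      }
      if (bad_epochs >= config$early_stop_patience) break
    }
  }

  structure(list(params = best_params, run_stats = best_rstats, spec = spec,
                 history = history, classes = FRET_CLASSES, seed = seed),
            class = "fret_nn")
}

spec_for_cpp <- function(spec) {
  list(filters = spec$filters, kernels = spec$kernels, pool = spec$pool,
       lstm_units = spec$lstm_units, n_classes = spec$n_classes,
       dropout = spec$dropout)
}

nn_eval_loss <- function(params, rstats, cspec, x, y, idx, batch_size) {
  total <- 0
  nb <- ceiling(length(idx) / batch_size)
  for (b in seq_len(nb)) {
    bi <- idx[((b - 1L) * batch_size + 1L):min(b * batch_size, length(idx))]
    out <- .nn_core_cpp(params, rstats, cspec, x[, , bi, drop = FALSE],
                        y[, , bi, drop = FALSE],
                        training = FALSE, want_grad = FALSE)
    total <- total + out$loss * length(bi)
  }
  total / length(idx)
}

#' @export
print.fret_nn <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("trained per-frame classifier: %d parameters, %d channel(s)\n",
              np, x$spec$n_channels))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epoch(s); final val loss %.4f\n", last$epoch,
                min(x$history$val_loss)))
  }
  invisible(x)
}

#' Per-frame class probabilities for traces
#'
#' Runs the trained classifier on one or more traces. Each trace is
#' normalized to its global maximum first; every prediction is independent
#' of any other trace in the batch.
#'
#' @param object A trained `fret_nn`.
#' @param newdata A [fret_trace()], a list of them, or a 3-d array
#'   (frames x channels x traces) of already-normalized input.
#' @param ... Unused.
#' @return For a single trace, a (frames x 6) matrix with columns
#'   [fret_classes()]; otherwise a list of such matrices.
#' @export
predict.fret_nn <- function(object, newdata, ...) {
  single <- inherits(newdata, "fret_trace")
  if (single) newdata <- list(newdata)
  if (is.list(newdata)) {
    nc <- object$spec$n_channels
    tlen <- newdata[[1]]$n_frames
    x <- array(0, dim = c(tlen, nc, length(newdata)))
    for (i in seq_along(newdata)) {
      tr <- newdata[[i]]
      if (!inherits(tr, "fret_trace")) stop("newdata must contain traces")
      have <- if (is.null(tr$aa)) 2L else 3L
      if (have != nc) {
        stop(sprintf("channel mismatch: trace has %d channels, model expects %d",
                     have, nc))
      }
      if (tr$n_frames != tlen) stop("all traces must have equal length")
      tr <- normalize_trace(tr)
      x[, 1, i] <- tr$dd
      x[, 2, i] <- tr$da
      if (nc == 3L) x[, 3, i] <- tr$aa
    }
  } else {
    x <- newdata
    if (length(dim(x)) != 3L || dim(x)[2] != object$spec$n_channels) {
      stop("array input must be frames x channels x traces with matching channels")
    }
  }
  probs <- nn_predict_array(object, x)
  if (single) probs[[1]] else probs
}

nn_predict_array <- function(object, x, batch_size = 64L) {
  cspec <- spec_for_cpp(object$spec)
  n <- dim(x)[3]
  out <- vector("list", n)
  nb <- ceiling(n / batch_size)
  for (b in seq_len(nb)) {
    bi <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    res <- .nn_core_cpp(object$params, object$run_stats, cspec,
                        x[, , bi, drop = FALSE], NULL,
                        training = FALSE, want_grad = FALSE)
    for (j in seq_along(bi)) {
      pm <- res$probs[, , j]
      colnames(pm) <- FRET_CLASSES
      out[[bi[j]]] <- pm
    }
  }
  out
}

#' Save / load a trained classifier
#'
#' The model bundle (architecture spec + weights + batch-norm statistics)
#' is written as a single RDS file together with a digest of the spec;
#' loading re-validates the digest.
#'
#' @param model A `fret_nn`.
#' @param path File path.
#' @return `load_model()` returns the `fret_nn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fret_nn"))
  bundle <- list(model = unclass(model),
                 spec_digest = spec_digest(model$spec),
                 format_version = 1L)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- readRDS(path)
  model <- structure(bundle$model, class = "fret_nn")
  if (!identical(spec_digest(model$spec), bundle$spec_digest)) {
    stop("model bundle is corrupt: architecture digest mismatch")
  }
  model
}

spec_digest <- function(spec) {
  paste(unlist(spec[c("n_channels", "n_classes", "filters", "kernels",
                      "lstm_units", "pool")]), collapse = "-")
}
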