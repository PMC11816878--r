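# LSTM binary classifier over selected feature vectors.
#
# Gate equations (x_t input chunk, h hidden state, c memory cell):
#   f = sigmoid(W_f x + U_f h + b_f)     forget gate
#   i = sigmoid(W_i x + U_i h + b_i)     input gate
#   o = sigmoid(W_o x + U_o h + b_o)     output gate
#   g = tanh  (W_c x + U_c h + b_c)      candidate memory
#   c' = f * c + i * g
#   h' = o * tanh(c')                    (default output rule)
# A `paper_literal` flag switches the output rule to h' = tanh(c') + o,
# the literal printed variant (unbounded h; kept for transparency, not used
# in training). Flat feature vectors are presented as a sequence of
# fixed-length chunks, zero-padded at the end.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize LSTM cell parameters
#'
#' Uniform draws in `[-r, r]` with `r = 1 / sqrt(max(input_size,
#' hidden_size))`, seeded.
#'
#' @param input_size Chunk length fed per time step.
#' @param hidden_size Hidden/memory dimension.
#' @param seed RNG seed.
#' @return List of class `"lstm_params"` with matrices `W_f, W_i, W_o, W_c`
#'   (hidden x input), `U_f, U_i, U_o, U_c` (hidden x hidden), biases
#'   `b_f, b_i, b_o, b_c`, and `hidden_size`, `input_size`.
#' @export
lstm_init_params <- function(input_size, hidden_size, seed = NULL) {
  check_number(input_size, "input_size", lower = 1)
  check_number(hidden_size, "hidden_size", lower = 1)
  r <- 1 / sqrt(max(input_size, hidden_size))
  with_seed(seed, {
    mk <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
    structure(list(
      W_f = mk(hidden_size, input_size), U_f = mk(hidden_size, hidden_size),
      b_f = stats::runif(hidden_size, -r, r),
      W_i = mk(hidden_size, input_size), U_i = mk(hidden_size, hidden_size),
      b_i = stats::runif(hidden_size, -r, r),
      W_o = mk(hidden_size, input_size), U_o = mk(hidden_size, hidden_size),
      b_o = stats::runif(hidden_size, -r, r),
      W_c = mk(hidden_size, input_size), U_c = mk(hidden_size, hidden_size),
      b_c = stats::runif(hidden_size, -r, r),
      hidden_size = as.integer(hidden_size),
      input_size = as.integer(input_size)), class = "lstm_params")
  })
}

#' One LSTM cell step
#'
#' @param x Input vector of length `input_size` (or a batch matrix,
#'   n x input_size).
#' @param state List with `h` and `c` (vectors of length `hidden_size`, or
#'   n x hidden matrices for a batch); `NULL` starts from zeros.
#' @param params An [lstm_init_params()] (or compatible list).
#' @param paper_literal Use the literal printed output rule
#'   `h' = tanh(c') + o` instead of `h' = o * tanh(c')` (default FALSE).
#' @return List with updated `h`, `c`, and `gates` (list `f, i, o, g`).
#' @export
lstm_cell_forward <- function(x, state = NULL, params, paper_literal = FALSE) {
  batch <- is.matrix(x)
  X <- if (batch) x else matrix(x, 1L)
  if (ncol(X) != params$input_size) {
    stop_arg("input length %d does not match input_size %d",
             ncol(X), params$input_size)
  }
  hs <- params$hidden_size
  if (is.null(state)) {
    H <- matrix(0, nrow(X), hs); C <- matrix(0, nrow(X), hs)
  } else {
    H <- if (is.matrix(state$h)) state$h else matrix(state$h, 1L)
    C <- if (is.matrix(state$c)) state$c else matrix(state$c, 1L)
    if (ncol(H) != hs || ncol(C) != hs) stop_arg("state dims do not match hidden_size")
  }
  lin <- function(W, U, b) {
    sweep(X %*% t(W) + H %*% t(U), 2, b, "+")
  }
  f <- sigmoid(lin(params$W_f, params$U_f, params$b_f))
  i <- sigmoid(lin(params$W_i, params$U_i, params$b_i))
  o <- sigmoid(lin(params$W_o, params$U_o, params$b_o))
  g <- tanh(lin(params$W_c, params$U_c, params$b_c))
  C2 <- f * C + i * g
  H2 <- if (paper_literal) tanh(C2) + o else o * tanh(C2)
  if (!batch) {
    list(h = drop(H2), c = drop(C2),
         gates = list(f = drop(f), i = drop(i), o = drop(o), g = drop(g)))
  } else {
    list(h = H2, c = C2, gates = list(f = f, i = i, o = o, g = g))
  }
}

#' Run an LSTM over an input sequence
#'
#' Left fold of [lstm_cell_forward()]; a length-1 sequence equals a single
#' cell call.
#'
#' @param sequence Non-empty list of input vectors (or batch matrices).
#' @param params LSTM parameters.
#' @param state Initial state (`NULL` = zeros).
#' @param paper_literal Passed through to the cell.
#' @return Final state list (`h`, `c`, `gates` of the last step).
#' @export
sequence_forward <- function(sequence, params, state = NULL,
                             paper_literal = FALSE) {
  if (length(sequence) == 0L) stop_arg("`sequence` must be non-empty")
  for (x in sequence) {
    state <- lstm_cell_forward(x, state, params, paper_literal = paper_literal)
  }
  state
}

#' LSTM classifier configuration
#'
#' @param hidden_size Hidden dimension (default 16).
#' @param chunk_len How many features are presented per time step; the
#'   feature vector is zero-padded to a multiple of it (default 8, so a
#'   fused 40-feature vector becomes 5 time steps).
#' @param epochs Gradient-descent epochs (default 300).
#' @param lr Learning rate on the batch-mean loss (default 1).
#' @param batch_size Mini-batch size; `NULL` (default) trains full-batch.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return List of class `"classifier_config"`.
#' @export
classifier_config <- function(hidden_size = 16L, chunk_len = 8L,
                              epochs = 300L, lr = 1, batch_size = NULL,
                              seed = 1L) {
  check_number(hidden_size, "hidden_size", lower = 1)
  check_number(chunk_len, "chunk_len", lower = 1)
  check_number(epochs, "epochs", lower = 1)
  check_number(lr, "lr")
  if (lr <= 0) stop_arg("`lr` must be positive")
  if (!is.null(batch_size)) check_number(batch_size, "batch_size", lower = 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 chunk_len = as.integer(chunk_len),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 seed = seed),
            class = "classifier_config")
}

# Chunk an n x p feature matrix into a list of S = ceil(p / L) batch
# matrices of width L (zero-padded).
chunk_sequence <- function(x, chunk_len) {
  p <- ncol(x)
  steps <- ceiling(p / chunk_len)
  padded <- steps * chunk_len
  if (padded > p) x <- cbind(x, matrix(0, nrow(x), padded - p))
  lapply(seq_len(steps), function(s) {
    x[, ((s - 1L) * chunk_len + 1L):(s * chunk_len), drop = FALSE]
  })
}

# Forward pass over a chunked batch, keeping per-step caches for BPTT.
lstm_forward_cached <- function(xs, params) {
  n <- nrow(xs[[1]]); hs <- params$hidden_size
  H <- matrix(0, n, hs); C <- matrix(0, n, hs)
  cache <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    prev_h <- H; prev_c <- C
    st <- lstm_cell_forward(xs[[t]], list(h = H, c = C), params)
    H <- st$h; C <- st$c
    cache[[t]] <- list(x = xs[[t]], prev_h = prev_h, prev_c = prev_c,
                       f = st$gates$f, i = st$gates$i, o = st$gates$o,
                       g = st$gates$g, c = C)
  }
  list(h = H, cache = cache)
}

# Backpropagation through time for the BCE loss; returns gradients for every
# parameter. dH_last is the loss gradient w.r.t. the final hidden state.
lstm_backward <- function(cache, params, dH_last) {
  hs <- params$hidden_size
  zero_like <- function(m) matrix(0, nrow(m), ncol(m))
  G <- list(W_f = zero_like(params$W_f), U_f = zero_like(params$U_f),
            b_f = numeric(hs),
            W_i = zero_like(params$W_i), U_i = zero_like(params$U_i),
            b_i = numeric(hs),
            W_o = zero_like(params$W_o), U_o = zero_like(params$U_o),
            b_o = numeric(hs),
            W_c = zero_like(params$W_c), U_c = zero_like(params$U_c),
            b_c = numeric(hs))
  dH <- dH_last
  dC <- matrix(0, nrow(dH), ncol(dH))
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    tc <- tanh(cc$c)
    dO <- dH * tc
    dC <- dC + dH * cc$o * (1 - tc^2)
    dF <- dC * cc$prev_c
    dI <- dC * cc$g
    dG <- dC * cc$i
    da_f <- dF * cc$f * (1 - cc$f)
    da_i <- dI * cc$i * (1 - cc$i)
    da_o <- dO * cc$o * (1 - cc$o)
    da_g <- dG * (1 - cc$g^2)
    G$W_f <- G$W_f + t(da_f) %*% cc$x; G$U_f <- G$U_f + t(da_f) %*% cc$prev_h
    G$b_f <- G$b_f + colSums(da_f)
    G$W_i <- G$W_i + t(da_i) %*% cc$x; G$U_i <- G$U_i + t(da_i) %*% cc$prev_h
    G$b_i <- G$b_i + colSums(da_i)
    G$W_o <- G$W_o + t(da_o) %*% cc$x; G$U_o <- G$U_o + t(da_o) %*% cc$prev_h
    G$b_o <- G$b_o + colSums(da_o)
    G$W_c <- G$W_c + t(da_g) %*% cc$x; G$U_c <- G$U_c + t(da_g) %*% cc$prev_h
    G$b_c <- G$b_c + colSums(da_g)
    dH <- da_f %*% params$U_f + da_i %*% params$U_i +
      da_o %*% params$U_o + da_g %*% params$U_c
    dC <- dC * cc$f
  }
  G
}

#' Train the LSTM classifier
#'
#' Plain (mini-batch) gradient descent on the binary cross-entropy of an
#' affine-plus-sigmoid read-out of the final hidden state; the default is
#' full-batch. Deterministic under the config seed. Features should be
#' standardized (constant columns trigger a warning but training proceeds).
#'
#' @param x Numeric matrix (samples x selected features), standardized.
#' @param y Binary labels (0/1), both classes present.
#' @param config A [classifier_config()].
#' @return Model of class `"lstm_classifier"` with the cell parameters,
#'   read-out weights, `loss_history`, and the training configuration.
#' @export
train_classifier <- function(x, y, config = classifier_config()) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop_arg("both classes must be present")
  if (nrow(x) != length(y)) stop_arg("`x` rows must match `y` length")
  sds <- apply(x, 2, stats::sd)
  if (any(!is.finite(sds) | sds == 0)) {
    warning("constant feature column(s) in training input", call. = FALSE)
  }
  n <- nrow(x); hs <- config$hidden_size
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  params <- lstm_init_params(config$chunk_len, hs, seed = config$seed)
  ro <- with_seed(derive_seed(config$seed, 7L), {
    list(w = stats::runif(hs, -1 / sqrt(hs), 1 / sqrt(hs)), b = 0)
  })
  eps <- 1e-12
  loss_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- if (bs < n) {
      with_seed(derive_seed(config$seed, 100L + ep), sample.int(n))
    } else {
      seq_len(n)
    }
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = bs)) {
      rows <- ord[start:min(start + bs - 1L, n)]
      xs <- chunk_sequence(x[rows, , drop = FALSE], config$chunk_len)
      yb <- y[rows]
      fw <- lstm_forward_cached(xs, params)
      p <- sigmoid(drop(fw$h %*% ro$w) + ro$b)
      batch_losses <- c(batch_losses,
                        -mean(yb * log(p + eps) + (1 - yb) * log(1 - p + eps)))
      dz <- (p - yb) / length(rows)
      dw <- drop(t(fw$h) %*% dz)
      db <- sum(dz)
      G <- lstm_backward(fw$cache, params, outer(dz, ro$w))
      lr <- config$lr
      for (nm in names(G)) params[[nm]] <- params[[nm]] - lr * G[[nm]]
      ro$w <- ro$w - lr * dw
      ro$b <- ro$b - lr * db
    }
    loss_history[ep] <- mean(batch_losses)
  }
  structure(list(params = params, readout = ro, config = config,
                 loss_history = loss_history,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "lstm_classifier")
}

#' Predict with a trained LSTM classifier
#'
#' @param object An [train_classifier()] model.
#' @param newdata Matrix or vector of features matching the training columns.
#' @param ... Unused.
#' @return Data frame with `probability` (in `[0, 1]`) and `label`
#'   (probability >= 0.5 maps to 1, the documented tie rule).
#' @export
predict.lstm_classifier <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (!is.null(object$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$feature_names)) {
    stop_arg("feature columns do not match the training mask")
  }
  if (!is.null(object$n_features) && ncol(x) != object$n_features) {
    stop_arg("feature count %d does not match the %d used in training",
             ncol(x), object$n_features)
  }
  xs <- chunk_sequence(x, object$config$chunk_len)
  fw <- lstm_forward_cached(xs, object$params)
  p <- sigmoid(drop(fw$h %*% object$readout$w) + object$readout$b)
  data.frame(probability = p, label = as.integer(p >= 0.5))
}

#' Serialize a trained classifier to a flat text file
#'
#' Versioned JSON with every weight written out, so models survive as plain
#' text and reload bit-identically.
#'
#' @param model An `lstm_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(model, path) {
  pl <- model$params
  obj <- list(
    format = "texhawk-lstm", version = 1L,
    hidden_size = pl$hidden_size, input_size = pl$input_size,
    chunk_len = model$config$chunk_len,
    n_features = model$n_features,
    feature_names = model$feature_names,
    weights = lapply(pl[c("W_f", "U_f", "b_f", "W_i", "U_i", "b_i",
                          "W_o", "U_o", "b_o", "W_c", "U_c", "b_c")],
                     function(m) if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
                     else list(dim = length(m), data = as.numeric(m))),
    readout = list(w = model$readout$w, b = model$readout$b)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized classifier
#'
#' @param path File written by [save_classifier()].
#' @return An `lstm_classifier` usable with [predict.lstm_classifier()].
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "texhawk-lstm")) stop_arg("unrecognized model file")
  wts <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2]) else w$data
  })
  params <- c(wts, list(hidden_size = as.integer(obj$hidden_size),
                        input_size = as.integer(obj$input_size)))
  class(params) <- "lstm_params"
  cfg <- classifier_config(hidden_size = obj$hidden_size,
                           chunk_len = obj$chunk_len)
  fn <- obj$feature_names
  if (length(fn) == 0L) fn <- NULL
  structure(list(params = params,
                 readout = list(w = obj$readout$w, b = obj$readout$b),
                 config = cfg, loss_history = numeric(0),
                 n_features = as.integer(obj$n_features),
                 feature_names = fn),
            class = "lstm_classifier")
}
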