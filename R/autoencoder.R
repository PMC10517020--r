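# Denoising autoencoders: a single-hidden-layer (bottleneck) MLP trained
# with the Adam optimizer and mean-squared-error loss on corrupted inputs
# against clean targets. Implemented directly with matrix algebra so runs
# are deterministic, single-threaded and dependency-free.

#' Autoencoder architecture and training specification
#'
#' The default early-integration shape compresses the 1600 concatenated
#' selected biological features to a 160-dimensional bottleneck; the
#' late-integration shapes are 500 -> 50 -> 500 (mRNA, methylation) and
#' 300 -> 30 -> 300 (miRNA, lncRNA). Corruption is applied to the model
#' input only; the reconstruction target is always the clean matrix, and
#' corruption is resampled fresh each epoch.
#'
#' @param input_dim width of the input matrix.
#' @param bottleneck_dim embedding width (must be < `input_dim`).
#' @param activation hidden-layer activation: `"relu"`, `"tanh"` or
#'   `"sigmoid"` (output layer is linear; inputs are z-scored and
#'   unbounded).
#' @param noise_type `"none"` (basic autoencoder), `"zeros"` (random
#'   entries replaced by zero) or `"gaussian"` (additive zero-centered
#'   noise).
#' @param noise_level zeroed fraction (grid 0.2/0.3/0.4) or Gaussian SD
#'   (grid 0.5/1.0/1.5); ignored for `"none"`.
#' @param learning_rate Adam learning rate.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param batch_size minibatch size.
#' @param seed RNG seed for initialization, shuffling and corruption.
#' @return an `encoder_spec`.
#' @export
encoder_spec <- function(input_dim, bottleneck_dim,
                         activation = c("sigmoid", "relu", "tanh"),
                         noise_type = c("zeros", "none", "gaussian"),
                         noise_level = 0.3,
                         learning_rate = 0.001, max_epochs = 100,
                         patience = 5, batch_size = 32, seed = 1L) {
  activation <- match.arg(activation)
  noise_type <- match.arg(noise_type)
  if (bottleneck_dim >= input_dim) stopf("bottleneck_dim must be smaller than input_dim")
  if (noise_type == "zeros" && !is_fraction(noise_level)) {
    stopf("zeros noise_level must be a fraction in [0,1]")
  }
  if (noise_type == "gaussian" && (!is.numeric(noise_level) || noise_level < 0)) {
    stopf("gaussian noise_level must be a non-negative SD")
  }
  if (noise_type == "none") noise_level <- 0
  structure(list(input_dim = as.integer(input_dim),
                 bottleneck_dim = as.integer(bottleneck_dim),
                 activation = activation, noise_type = noise_type,
                 noise_level = noise_level, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "encoder_spec")
}

#' Replace random matrix entries with zeros
#'
#' Each entry is independently set to 0 with probability `fraction`; the
#' input object is left untouched (corruption is applied to a copy).
#'
#' @param matrix numeric matrix.
#' @param fraction corruption probability per entry.
#' @param seed RNG seed (`NULL` to use the current stream).
#' @return the corrupted copy.
#' @export
corrupt_zeros <- function(matrix, fraction, seed = NULL) {
  stopifnot(is_fraction(fraction))
  if (fraction == 0) return(matrix)
  with_seed(seed, {
    matrix[runif(length(matrix)) < fraction] <- 0
    matrix
  })
}

#' Add zero-centered Gaussian noise to a matrix
#'
#' @param matrix numeric matrix.
#' @param sd noise standard deviation.
#' @param seed RNG seed (`NULL` to use the current stream).
#' @return the corrupted copy.
#' @export
corrupt_gaussian <- function(matrix, sd, seed = NULL) {
  stopifnot(is.numeric(sd), sd >= 0)
  if (sd == 0) return(matrix)
  with_seed(seed, matrix + matrix(stats::rnorm(length(matrix), 0, sd),
                                  nrow(matrix), ncol(matrix)))
}

activation_fns <- list(
  relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
  tanh = list(f = tanh, df = function(z, a) 1 - a^2),
  sigmoid = list(f = stats::plogis, df = function(z, a) a * (1 - a)))

corrupt_input <- function(X, spec) {
  switch(spec$noise_type,
         none = X,
         zeros = corrupt_zeros(X, spec$noise_level),
         gaussian = corrupt_gaussian(X, spec$noise_level))
}

#' Train a (denoising) autoencoder
#'
#' Minimizes the mean squared error between the decoder output and the
#' clean input, feeding corrupted input forward. Training stops at
#' `max_epochs` or when the validation loss fails to improve for
#' `patience` consecutive epochs, restoring the best-validation weights.
#' Deterministic given `spec$seed`.
#'
#' @param spec an [encoder_spec()].
#' @param train clean training matrix (patients x `input_dim`).
#' @param validation clean validation matrix; if `NULL`, 10% of the
#'   training rows (at least 2) are held out internally.
#' @return object of class `trained_encoder` with `spec`, `weights`,
#'   `training_history` (per-epoch train/validation loss) and
#'   `stopped_epoch`.
#' @export
train_autoencoder <- function(spec, train, validation = NULL) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (ncol(train) != spec$input_dim) {
    stopf("input_dim is %d but the training matrix has %d columns",
          spec$input_dim, ncol(train))
  }
  with_seed(spec$seed, {
    if (is.null(validation)) {
      n_val <- max(2L, round(0.10 * nrow(train)))
      vidx <- sample.int(nrow(train), n_val)
      validation <- train[vidx, , drop = FALSE]
      train <- train[-vidx, , drop = FALSE]
    }
    if (nrow(validation) == 0) stopf("validation matrix is empty")
    train_autoencoder_impl(spec, train, validation)
  })
}

train_autoencoder_impl <- function(spec, X, V) {
  d <- spec$input_dim
  h <- spec$bottleneck_dim
  act <- activation_fns[[spec$activation]]
  glorot <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  W <- list(W1 = glorot(d, h), b1 = numeric(h), W2 = glorot(h, d), b2 = numeric(d))
  adam <- lapply(W, function(p) list(m = p * 0, v = p * 0))
  lr <- spec$learning_rate; b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  t_step <- 0

  forward <- function(Xin, W) {
    Z <- sweep(Xin %*% W$W1, 2, W$b1, "+")
    H <- act$f(Z)
    Y <- sweep(H %*% W$W2, 2, W$b2, "+")
    list(Z = Z, H = H, Y = Y)
  }
  mse <- function(Y, X) mean((Y - X)^2)

  n <- nrow(X)
  best_val <- Inf
  best_W <- W
  best_epoch <- 0L
  bad <- 0L
  hist_train <- hist_val <- numeric(0)
  stopped <- spec$max_epochs
  for (epoch in seq_len(spec$max_epochs)) {
    Xc <- corrupt_input(X, spec)
    perm <- sample.int(n)
    ep_loss <- 0
    n_batch <- 0L
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- perm[start:min(start + spec$batch_size - 1, n)]
      xb <- Xc[idx, , drop = FALSE]
      tb <- X[idx, , drop = FALSE]
      fw <- forward(xb, W)
      B <- length(idx)
      dY <- 2 * (fw$Y - tb) / (B * d)
      dH <- dY %*% t(W$W2)
      dZ <- dH * act$df(fw$Z, fw$H)
      grads <- list(W1 = crossprod(xb, dZ), b1 = colSums(dZ),
                    W2 = crossprod(fw$H, dY), b2 = colSums(dY))
      t_step <- t_step + 1
      for (p in names(W)) {
        g <- grads[[p]]
        adam[[p]]$m <- b1m * adam[[p]]$m + (1 - b1m) * g
        adam[[p]]$v <- b2m * adam[[p]]$v + (1 - b2m) * g^2
        mhat <- adam[[p]]$m / (1 - b1m^t_step)
        vhat <- adam[[p]]$v / (1 - b2m^t_step)
        W[[p]] <- W[[p]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + mse(fw$Y, tb)
      n_batch <- n_batch + 1L
    }
    train_loss <- ep_loss / n_batch
    val_loss <- mse(forward(V, W)$Y, V)
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      stopf("NaN/Inf loss at epoch %d: check input scaling or lower the learning rate", epoch)
    }
    hist_train <- c(hist_train, train_loss)
    hist_val <- c(hist_val, val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_W <- W
      best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= spec$patience) {stopped <- epoch; break}
    }
  }
  structure(list(spec = spec, weights = best_W,
                 training_history = data.frame(epoch = seq_along(hist_train),
                                               train_loss = hist_train,
                                               val_loss = hist_val),
                 stopped_epoch = as.integer(stopped),
                 best_epoch = best_epoch),
            class = "trained_encoder")
}

#' @export
print.trained_encoder <- function(x, ...) {
  cat(sprintf("trained %s autoencoder %d -> %d (%s), stopped at epoch %d (best %d)\n",
              x$spec$noise_type, x$spec$input_dim, x$spec$bottleneck_dim,
              x$spec$activation, x$stopped_epoch, x$best_epoch))
  invisible(x)
}

#' Encode a matrix through the bottleneck
#'
#' Clean (uncorrupted) forward pass through the encoder half; returns the
#' patients x `bottleneck_dim` embedding.
#'
#' @param model a `trained_encoder`.
#' @param matrix matrix with `input_dim` columns.
#' @return embedding matrix.
#' @export
encode <- function(model, matrix) {
  stopifnot(inherits(model, "trained_encoder"))
  if (ncol(matrix) != model$spec$input_dim) {
    stopf("matrix width %d does not match input_dim %d",
          ncol(matrix), model$spec$input_dim)
  }
  act <- activation_fns[[model$spec$activation]]
  emb <- act$f(sweep(matrix %*% model$weights$W1, 2, model$weights$b1, "+"))
  colnames(emb) <- sprintf("ae%03d", seq_len(ncol(emb)))
  rownames(emb) <- rownames(matrix)
  emb
}

#' Reconstruct a matrix through the full autoencoder
#' @param model a `trained_encoder`.
#' @param matrix matrix with `input_dim` columns.
#' @return reconstruction with the input's shape.
#' @export
reconstruct <- function(model, matrix) {
  emb <- encode(model, matrix)
  sweep(emb %*% model$weights$W2, 2, model$weights$b2, "+")
}

#' The default autoencoder hyperparameter grid
#'
#' Basic (noise-free), denoising-zeros (fractions 0.2/0.3/0.4) and
#' denoising-Gaussian (SDs 0.5/1.0/1.5) models, each crossed with the ReLU,
#' tanh and sigmoid activations: 21 configurations.
#'
#' @return data.frame with columns `noise_type`, `noise_level`,
#'   `activation`.
#' @export
default_encoder_grid <- function() {
  rbind(
    expand.grid(noise_type = "none", noise_level = 0,
                activation = c("relu", "tanh", "sigmoid"),
                stringsAsFactors = FALSE),
    expand.grid(noise_type = "zeros", noise_level = c(0.2, 0.3, 0.4),
                activation = c("relu", "tanh", "sigmoid"),
                stringsAsFactors = FALSE),
    expand.grid(noise_type = "gaussian", noise_level = c(0.5, 1.0, 1.5),
                activation = c("relu", "tanh", "sigmoid"),
                stringsAsFactors = FALSE))
}
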