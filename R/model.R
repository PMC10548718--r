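#' Channel architecture configuration
#'
#' Each channel is a stack of fully connected layers with rectifier
#' activations and dropout after every layer; it maps a k-dimensional
#' entity embedding to the shared latent space whose dimension is the
#' last layer width.
#'
#' @param input_dim Embedding dimension k fed to the channel
#'   (default 1024).
#' @param layer_widths Dense layer widths (default `c(512, 256, 128, 64)`).
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.2).
#' @return list of class `channel_config`.
#' @export
channel_config <- function(input_dim = 1024L,
                           layer_widths = c(512L, 256L, 128L, 64L),
                           dropout_rate = 0.2) {
  if (any(layer_widths <= 0L)) stop("layer widths must be strictly positive")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout must be in [0,1)")
  if (input_dim <= 0L) stop("input_dim must be positive")
  structure(
    list(input_dim = as.integer(input_dim),
         layer_widths = as.integer(layer_widths),
         activation = "relu", dropout_rate = dropout_rate),
    class = "channel_config"
  )
}

#' Siamese model configuration
#'
#' The model has a drug channel f and a disease channel g (see
#' [channel_config()]), merged by the elementwise absolute difference of
#' their outputs, followed by a dense rectifier layer of `head_width`
#' units and a single sigmoid unit producing the association probability.
#' In `heterogeneous` mode the two channels have independent weights
#' (drugs and diseases are different kinds of object); in `homogeneous`
#' mode they share one parameter set. A symmetrized Kullback-Leibler
#' penalty between the two channels' (exponentially normalized) outputs
#' pulls the drug and disease latent distributions together; its weight
#' is `kl_weight` and it can be restricted to positive pairs.
#'
#' @param channel A [channel_config()].
#' @param head_width Width of the merge head's hidden layer (default 32).
#' @param weight_mode `"heterogeneous"` or `"homogeneous"`.
#' @param kl_weight Non-negative weight of the channel-divergence penalty
#'   (default 0.1).
#' @param kl_scope `"all_pairs"` or `"positive_only"`.
#' @return list of class `model_config`.
#' @export
model_config <- function(channel = channel_config(), head_width = 32L,
                         weight_mode = c("heterogeneous", "homogeneous"),
                         kl_weight = 0.1,
                         kl_scope = c("all_pairs", "positive_only")) {
  weight_mode <- match.arg(weight_mode)
  kl_scope <- match.arg(kl_scope)
  stopifnot(inherits(channel, "channel_config"))
  if (head_width <= 0L) stop("head_width must be positive")
  if (kl_weight < 0) stop("kl_weight must be >= 0")
  structure(
    list(channel = channel, head_width = as.integer(head_width),
         weight_mode = weight_mode, kl_weight = kl_weight,
         kl_scope = kl_scope),
    class = "model_config"
  )
}

#' Training configuration
#'
#' Adam optimization of the composite loss (binary cross-entropy plus the
#' weighted channel divergence), monitored on validation accuracy with
#' early stopping, learning-rate reduction on plateau, and best-weights
#' restoration.
#'
#' @param learning_rate Initial Adam step size (default 5e-5).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Maximum training epochs (default 200).
#' @param early_stop_patience Epochs without validation-accuracy
#'   improvement before stopping (default 20).
#' @param lr_reduce_factor Multiplier applied to the learning rate on
#'   plateau (default 0.5).
#' @param lr_reduce_patience Plateau length triggering the reduction
#'   (default 10).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-5, batch_size = 32L,
                         max_epochs = 200L, early_stop_patience = 20L,
                         lr_reduce_factor = 0.5, lr_reduce_patience = 10L,
                         seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (early_stop_patience < 1L || lr_reduce_patience < 1L) {
    stop("patiences must be >= 1")
  }
  structure(
    list(learning_rate = learning_rate, optimizer = "adam",
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         lr_reduce_factor = lr_reduce_factor,
         lr_reduce_patience = as.integer(lr_reduce_patience),
         monitor = "val_accuracy", seed = as.integer(seed)),
    class = "train_config"
  )
}

# one dense layer parameter pair, Glorot-uniform init
.init_dense <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = rep(0, n_out))
}

.init_channel <- function(cfg) {
  dims <- c(cfg$input_dim, cfg$layer_widths)
  lapply(seq_len(length(dims) - 1L),
         function(l) .init_dense(dims[l], dims[l + 1L]))
}

#' Initialize a siamese model
#'
#' Builds the parameter tensors for both channels and the merge head with
#' seeded Glorot-uniform initialization. In homogeneous mode a single
#' channel parameter set is stored and used for both inputs.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return list of class `siamese_model`.
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  h <- utils::tail(config$channel$layer_widths, 1L)
  withr::with_seed(seed, {
    f <- .init_channel(config$channel)
    g <- if (config$weight_mode == "heterogeneous") {
      .init_channel(config$channel)
    } else {
      NULL  # shared with f
    }
    head <- list(
      h1 = .init_dense(h, config$head_width),
      out = .init_dense(config$head_width, 1L)
    )
  })
  structure(list(f = f, g = g, head = head, config = config),
            class = "siamese_model")
}

#' Count trainable parameters
#'
#' Sums `n_in * n_out + n_out` over every dense layer actually stored
#' (a shared homogeneous channel is counted once).
#'
#' @param model A `siamese_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "siamese_model"))
  one <- function(layer) length(layer$W) + length(layer$b)
  n <- sum(vapply(model$f, one, numeric(1))) +
    one(model$head$h1) + one(model$head$out)
  if (!is.null(model$g)) {
    n <- n + sum(vapply(model$g, one, numeric(1)))
  }
  as.integer(n)
}

#' @export
print.siamese_model <- function(x, ...) {
  cat(sprintf("<siamese_model %s> channels %s -> %s, head %d, %d parameters\n",
              x$config$weight_mode, x$config$channel$input_dim,
              paste(x$config$channel$layer_widths, collapse = "-"),
              x$config$head_width, count_params(x)))
  invisible(x)
}

#' Binary cross-entropy loss
#'
#' `L = -[y log(yhat) + (1 - y) log(1 - yhat)]`, elementwise. Predicted
#' probabilities must lie strictly inside (0, 1); inside that interval
#' they are additionally clamped to `[eps, 1 - eps]` before the logarithm
#' to keep the loss finite in floating point.
#'
#' @param y Labels in {0, 1}.
#' @param yhat Predicted probabilities in (0, 1).
#' @param eps Clamping constant (default 1e-7).
#' @return Numeric vector of losses (non-negative).
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  if (any(yhat <= 0 | yhat >= 1)) {
    stop("predicted probabilities must lie strictly in (0, 1)")
  }
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# softmax over rows of a matrix (or a single vector)
.softmax_rows <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  z <- m - apply(m, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Symmetrized channel divergence
#'
#' Converts each channel output to a probability vector by exponential
#' normalization (softmax) and returns the symmetrized Kullback-Leibler
#' divergence `0.5 * (KL(P||Q) + KL(Q||P))`. The value is non-negative
#' and zero exactly when the normalized vectors coincide.
#'
#' @param eps_r,eps_p Channel output vectors (or matrices, one row per
#'   pair).
#' @return Numeric scalar (or per-row vector) divergence.
#' @export
channel_kl <- function(eps_r, eps_p) {
  p <- .softmax_rows(eps_r)
  q <- .softmax_rows(eps_p)
  v <- 0.5 * rowSums((p - q) * (log(p) - log(q)))
  if (is.null(dim(eps_r))) v[[1L]] else v
}
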