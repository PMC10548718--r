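# Internal feed-forward machinery for the siamese model: dense/ReLU/dropout
# channels, absolute-difference merge, sigmoid head, manual backprop and
# Adam. Everything runs on base matrix algebra; minibatches keep the work
# BLAS-bound.

.affine <- function(X, layer) sweep(X %*% layer$W, 2L, layer$b, "+")

.dropout_mask <- function(n, m, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(n * m) >= rate) / (1 - rate), n, m)
}

# forward through one channel, keeping caches for backprop
.channel_forward <- function(layers, X, rate, training) {
  caches <- vector("list", length(layers))
  A <- X
  for (l in seq_along(layers)) {
    Z <- .affine(A, layers[[l]])
    R <- pmax(Z, 0)
    mask <- if (training) .dropout_mask(nrow(R), ncol(R), rate) else NULL
    out <- if (is.null(mask)) R else R * mask
    caches[[l]] <- list(A_prev = A, Z = Z, mask = mask)
    A <- out
  }
  list(out = A, caches = caches)
}

.channel_backward <- function(layers, caches, dA) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    cc <- caches[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dZ <- dA * (cc$Z > 0)
    grads[[l]] <- list(W = crossprod(cc$A_prev, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

# row-wise softmax with stable log
.softmax_log <- function(m) {
  z <- m - apply(m, 1L, max)
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  list(p = exp(logp), logp = logp)
}

# gradient of 0.5*sum((p-q)*(logp-logq)) wrt the pre-softmax rows
.kl_grads <- function(eps_r, eps_p) {
  sr <- .softmax_log(eps_r)
  sq <- .softmax_log(eps_p)
  p <- pmax(sr$p, 1e-12)
  q <- pmax(sq$p, 1e-12)
  dl <- sr$logp - sq$logp
  gp <- 0.5 * (dl + 1 - q / p)
  gq <- 0.5 * (-dl + 1 - p / q)
  dr <- p * (gp - rowSums(p * gp))
  dp <- q * (gq - rowSums(q * gq))
  kl <- 0.5 * rowSums((p - q) * dl)
  list(d_eps_r = dr, d_eps_p = dp, kl = kl)
}

# full forward pass; model$g NULL means shared (homogeneous) channel
.model_forward <- function(model, Xr, Xp, training = FALSE) {
  cfg <- model$config
  rate <- cfg$channel$dropout_rate
  g_layers <- if (is.null(model$g)) model$f else model$g
  fr <- .channel_forward(model$f, Xr, rate, training)
  gp <- .channel_forward(g_layers, Xp, rate, training)
  eps_h <- abs(fr$out - gp$out)
  Z1 <- .affine(eps_h, model$head$h1)
  R1 <- pmax(Z1, 0)
  mask1 <- if (training) .dropout_mask(nrow(R1), ncol(R1), rate) else NULL
  H1 <- if (is.null(mask1)) R1 else R1 * mask1
  Z2 <- .affine(H1, model$head$out)
  prob <- 1 / (1 + exp(-Z2))
  list(prob = as.numeric(prob), eps_r = fr$out, eps_p = gp$out,
       fr = fr, gp = gp, eps_h = eps_h, Z1 = Z1, mask1 = mask1, H1 = H1)
}

#' Forward pass of the siamese model
#'
#' Projects the drug and disease embedding vectors through their
#' channels, merges them by the elementwise absolute difference
#' `eps_h = |eps_r - eps_p|`, and maps the result to an association
#' probability in (0, 1). Dropout is active only when `training = TRUE`.
#'
#' @param model A `siamese_model`.
#' @param drug_vec,disease_vec Numeric vectors of length `input_dim`
#'   (or matrices with one row per pair).
#' @param training Logical; enables dropout.
#' @return list with `prob`, `eps_r`, `eps_p`.
#' @export
siamese_forward <- function(model, drug_vec, disease_vec, training = FALSE) {
  stopifnot(inherits(model, "siamese_model"))
  k <- model$config$channel$input_dim
  if (is.null(dim(drug_vec))) drug_vec <- matrix(drug_vec, nrow = 1L)
  if (is.null(dim(disease_vec))) disease_vec <- matrix(disease_vec, nrow = 1L)
  if (ncol(drug_vec) != k || ncol(disease_vec) != k) {
    stop("input vectors must have length ", k, " (channel input_dim)")
  }
  fw <- .model_forward(model, drug_vec, disease_vec, training = training)
  list(prob = fw$prob, eps_r = fw$eps_r, eps_p = fw$eps_p)
}

#' Composite loss of the siamese model on a batch
#'
#' Mean binary cross-entropy plus `kl_weight` times the mean symmetrized
#' channel divergence (over all pairs or positive pairs only, per the
#' model config). Evaluated in inference mode (no dropout).
#'
#' @param model A `siamese_model`.
#' @param xr,xp Input matrices (one row per pair).
#' @param y Labels in {0, 1}.
#' @param kl_weight Optional override of the config's `kl_weight`.
#' @return Scalar loss.
#' @export
siamese_loss <- function(model, xr, xp, y, kl_weight = NULL) {
  lam <- if (is.null(kl_weight)) model$config$kl_weight else kl_weight
  fw <- .model_forward(model, xr, xp, training = FALSE)
  base <- mean(bce_loss(y, pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)))
  if (lam == 0) return(base)
  kl <- channel_kl(fw$eps_r, fw$eps_p)
  scope <- if (model$config$kl_scope == "positive_only") y == 1L else
    rep(TRUE, length(y))
  kl_term <- if (any(scope)) mean(kl[scope]) else 0
  base + lam * kl_term
}

# backward pass for one training batch; returns nested grads matching
# list(f=..., g=..., head=...)
.model_backward <- function(model, fw, y) {
  cfg <- model$config
  n <- length(y)
  dZ2 <- matrix((fw$prob - y) / n, ncol = 1L)
  gout <- list(W = crossprod(fw$H1, dZ2), b = colSums(dZ2))
  dH1 <- tcrossprod(dZ2, model$head$out$W)
  if (!is.null(fw$mask1)) dH1 <- dH1 * fw$mask1
  dZ1 <- dH1 * (fw$Z1 > 0)
  gh1 <- list(W = crossprod(fw$eps_h, dZ1), b = colSums(dZ1))
  d_eps_h <- tcrossprod(dZ1, model$head$h1$W)
  s <- sign(fw$eps_r - fw$eps_p)
  d_eps_r <- d_eps_h * s
  d_eps_p <- -d_eps_h * s
  if (cfg$kl_weight > 0) {
    kg <- .kl_grads(fw$eps_r, fw$eps_p)
    scope <- if (cfg$kl_scope == "positive_only") as.numeric(y == 1L) else 1
    scale <- cfg$kl_weight / n
    d_eps_r <- d_eps_r + scale * kg$d_eps_r * scope
    d_eps_p <- d_eps_p + scale * kg$d_eps_p * scope
  }
  bf <- .channel_backward(model$f, fw$fr$caches, d_eps_r)
  g_layers <- if (is.null(model$g)) model$f else model$g
  bg <- .channel_backward(g_layers, fw$gp$caches, d_eps_p)
  if (is.null(model$g)) {
    # shared channel accumulates gradients from both passes
    f_grads <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                      bf$grads, bg$grads, SIMPLIFY = FALSE)
    list(f = f_grads, g = NULL, head = list(h1 = gh1, out = gout))
  } else {
    list(f = bf$grads, g = bg$grads, head = list(h1 = gh1, out = gout))
  }
}

# --- recursive Adam over nested parameter lists -------------------------

.zeros_like <- function(x) {
  if (is.list(x)) lapply(x, .zeros_like) else x * 0
}

.adam_apply <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  if (is.list(p)) {
    out <- list(p = p, m = m, v = v)
    for (nm in seq_along(p)) {
      if (is.null(p[[nm]])) next
      r <- .adam_apply(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t,
                       beta1, beta2, eps)
      out$p[[nm]] <- r$p
      out$m[[nm]] <- r$m
      out$v[[nm]] <- r$v
    }
    return(out)
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

.split_xy <- function(block, k) {
  list(xr = block$x[, seq_len(k), drop = FALSE],
       xp = block$x[, k + seq_len(k), drop = FALSE],
       y = block$y)
}

#' Train the siamese model
#'
#' Minimizes the mean binary cross-entropy plus the weighted channel
#' divergence with Adam, monitoring validation accuracy: early stopping
#' after `early_stop_patience` epochs without improvement,
#' learning-rate halving (factor `lr_reduce_factor`) after
#' `lr_reduce_patience` flat epochs, and restoration of the
#' best-validation weights at the end.
#'
#' @param model A `siamese_model` from [init_model()].
#' @param train_block,val_block `feature_block`s (concatenated
#'   drug||disease rows plus labels); the training block must contain
#'   both classes.
#' @param tc A [train_config()].
#' @param threshold Decision threshold used for the accuracy monitor.
#' @return list with `model` (best weights) and `history` (data.frame
#'   epoch, train_loss, val_loss, train_acc, val_acc, lr).
#' @export
train_siamese <- function(model, train_block, val_block,
                          tc = train_config(), threshold = 0.5) {
  stopifnot(inherits(model, "siamese_model"), inherits(tc, "train_config"))
  if (nrow(train_block$x) == 0L || nrow(val_block$x) == 0L) {
    stop("training and validation blocks must be non-empty")
  }
  if (length(unique(train_block$y)) < 2L) {
    stop("training block must contain both classes")
  }
  k <- model$config$channel$input_dim
  tr <- .split_xy(train_block, k)
  va <- .split_xy(val_block, k)
  params <- list(f = model$f, g = model$g, head = model$head)
  m_state <- .zeros_like(params)
  v_state <- .zeros_like(params)
  lr <- tc$learning_rate
  best_acc <- -Inf
  best_params <- params
  es_wait <- 0L
  lr_wait <- 0L
  t_step <- 0L
  hist <- vector("list", tc$max_epochs)
  n <- nrow(tr$xr)

  acc_of <- function(prob, y) mean((prob > threshold) == (y == 1L))
  eval_model <- function() {
    mdl <- model
    mdl$f <- params$f
    mdl$g <- params$g
    mdl$head <- params$head
    mdl
  }

  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tc$batch_size)
      ep_loss <- 0
      ep_n <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + tc$batch_size - 1L, n)]
        mdl <- eval_model()
        fw <- .model_forward(mdl, tr$xr[idx, , drop = FALSE],
                             tr$xp[idx, , drop = FALSE], training = TRUE)
        yb <- tr$y[idx]
        p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
        loss_b <- mean(bce_loss(yb, p))
        if (model$config$kl_weight > 0) {
          klv <- channel_kl(fw$eps_r, fw$eps_p)
          scope <- if (model$config$kl_scope == "positive_only") {
            yb == 1L
          } else {
            rep(TRUE, length(yb))
          }
          if (any(scope)) {
            loss_b <- loss_b + model$config$kl_weight * mean(klv[scope])
          }
        }
        grads <- .model_backward(mdl, fw, yb)
        t_step <- t_step + 1L
        upd <- .adam_apply(params, grads, m_state, v_state, lr, t_step)
        params <- upd$p
        m_state <- upd$m
        v_state <- upd$v
        ep_loss <- ep_loss + loss_b * length(idx)
        ep_n <- ep_n + length(idx)
      }
      mdl <- eval_model()
      tr_fw <- .model_forward(mdl, tr$xr, tr$xp, training = FALSE)
      va_fw <- .model_forward(mdl, va$xr, va$xp, training = FALSE)
      val_loss <- siamese_loss(mdl, va$xr, va$xp, va$y)
      val_acc <- acc_of(va_fw$prob, va$y)
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / ep_n, val_loss = val_loss,
        train_acc = acc_of(tr_fw$prob, tr$y), val_acc = val_acc, lr = lr
      )
      if (val_acc > best_acc + 1e-12) {
        best_acc <- val_acc
        best_params <- params
        es_wait <- 0L
        lr_wait <- 0L
      } else {
        es_wait <- es_wait + 1L
        lr_wait <- lr_wait + 1L
        if (lr_wait >= tc$lr_reduce_patience) {
          lr <- lr * tc$lr_reduce_factor
          lr_wait <- 0L
        }
        if (es_wait >= tc$early_stop_patience) break
      }
    }
  })
  model$f <- best_params$f
  model$g <- best_params$g
  model$head <- best_params$head
  list(model = model, history = do.call(rbind, hist[!vapply(hist, is.null,
                                                            logical(1))]))
}

#' Score drug-disease pairs with a trained model
#'
#' Looks up the embedding of every pair, runs the model in inference
#' mode and applies the strict decision rule: predicted label 1 iff the
#' probability exceeds the threshold.
#'
#' @param model A trained `siamese_model`.
#' @param pairs A `pair_set` (or data.frame with `drug`, `disease`).
#' @param table An `embedding_table`.
#' @param threshold Decision threshold (default 0.5; ties go to 0).
#' @return data.frame with `drug`, `disease`, `prob`, `label`, in input
#'   order.
#' @export
predict_pairs <- function(model, pairs, table, threshold = 0.5) {
  if (nrow(pairs) == 0L) {
    return(data.frame(drug = character(), disease = character(),
                      prob = numeric(), label = integer()))
  }
  fake_labels <- if ("label" %in% names(pairs)) pairs$label else
    rep(0L, nrow(pairs))
  block <- pairs_to_features(
    data.frame(drug = pairs$drug, disease = pairs$disease,
               label = fake_labels, stringsAsFactors = FALSE),
    table
  )
  k <- model$config$channel$input_dim
  sp <- .split_xy(block, k)
  fw <- .model_forward(model, sp$xr, sp$xp, training = FALSE)
  data.frame(
    drug = pairs$drug, disease = pairs$disease, prob = fw$prob,
    label = as.integer(fw$prob > threshold), stringsAsFactors = FALSE
  )
}
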