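# independent layer-summation oracle for parameter counts
param_oracle <- function(input_dim, widths, head_width, shared) {
  dense <- function(i, o) i * o + o
  dims <- c(input_dim, widths)
  channel <- sum(mapply(dense, dims[-length(dims)], dims[-1]))
  head <- dense(widths[length(widths)], head_width) + dense(head_width, 1)
  (if (shared) 1 else 2) * channel + head
}

test_that("parameter counts match the layer-summation oracle", {
  hetero <- init_model(model_config(), seed = 1)
  expect_equal(count_params(hetero),
               param_oracle(1024, c(512, 256, 128, 64), 32, FALSE))
  expect_equal(count_params(hetero), 1396673L)

  homo <- init_model(model_config(weight_mode = "homogeneous"), seed = 1)
  expect_equal(count_params(homo),
               param_oracle(1024, c(512, 256, 128, 64), 32, TRUE))
  expect_equal(count_params(homo), 699393L)

  small <- init_model(model_config(channel_config(10, c(7, 5)),
                                   head_width = 3), seed = 1)
  expect_equal(count_params(small), param_oracle(10, c(7, 5), 3, FALSE))
})

test_that("initialization is seeded and configs are validated", {
  cfg <- model_config(channel_config(16, c(8, 4)), head_width = 4)
  m1 <- init_model(cfg, seed = 5)
  m2 <- init_model(cfg, seed = 5)
  x <- withr::with_seed(1, matrix(rnorm(32), 2, 16))
  f1 <- siamese_forward(m1, x, x + 1)
  f2 <- siamese_forward(m2, x, x + 1)
  expect_identical(f1$prob, f2$prob)
  expect_error(channel_config(16, c(8, 0)), "positive")
  expect_error(channel_config(16, c(8), dropout_rate = 1), "dropout")
  expect_error(model_config(channel_config(4, 2), head_width = 0),
               "head_width")
})

test_that("forward merge is symmetric and bounded", {
  cfg <- model_config(channel_config(12, c(6, 4)), head_width = 3)
  m <- init_model(cfg, seed = 2)
  xr <- withr::with_seed(3, matrix(rnorm(5 * 12), 5, 12))
  xp <- withr::with_seed(4, matrix(rnorm(5 * 12), 5, 12))
  fw <- siamese_forward(m, xr, xp)
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # |a-b| = |b-a|: swapping channel outputs leaves the merge unchanged
  expect_equal(abs(fw$eps_r - fw$eps_p), abs(fw$eps_p - fw$eps_r))
  expect_error(siamese_forward(m, xr[, 1:5], xp), "length")
})

test_that("homogeneous channels collapse identical inputs to zero difference", {
  homo <- init_model(model_config(channel_config(10, c(8, 6)),
                                  head_width = 4,
                                  weight_mode = "homogeneous"), seed = 3)
  x <- withr::with_seed(5, matrix(rnorm(40), 4, 10))
  fw <- siamese_forward(homo, x, x)
  expect_equal(max(abs(fw$eps_r - fw$eps_p)), 0)
  hetero <- init_model(model_config(channel_config(10, c(8, 6)),
                                    head_width = 4), seed = 3)
  fw2 <- siamese_forward(hetero, x, x)
  expect_gt(max(abs(fw2$eps_r - fw2$eps_p)), 0)
})

test_that("binary cross-entropy matches its closed forms", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 0.5), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(1, 1 - 1e-9), 1e-6)
  expect_true(all(bce_loss(c(0, 1, 1), c(0.2, 0.7, 0.01)) >= 0))
  expect_error(bce_loss(1, 1), "strictly")
  expect_error(bce_loss(0, 0), "strictly")
})

test_that("channel divergence is a symmetrized non-negative score", {
  a <- c(0.3, -1, 2, 0.5)
  b <- c(1, 0.2, -0.4, 0)
  expect_equal(channel_kl(a, a), 0)
  expect_gte(channel_kl(a, b), 0)
  expect_equal(channel_kl(a, b), channel_kl(b, a))
  set.seed(11)
  for (i in 1:20) {
    u <- rnorm(6)
    v <- rnorm(6)
    expect_gte(channel_kl(u, v), -1e-12)
  }
  # shift invariance of the softmax normalization
  expect_equal(channel_kl(a + 5, b), channel_kl(a, b))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(channel_config(4, c(3), dropout_rate = 0),
                      head_width = 2, kl_weight = 0.3)
  m <- init_model(cfg, seed = 7)
  xr <- withr::with_seed(8, matrix(rnorm(3 * 4), 3, 4))
  xp <- withr::with_seed(9, matrix(rnorm(3 * 4), 3, 4))
  y <- c(1L, 0L, 1L)

  fw <- siamdr:::.model_forward(m, xr, xp, training = FALSE)
  grads <- siamdr:::.model_backward(m, fw, y)

  loss_at <- function(model) siamese_loss(model, xr, xp, y)
  h <- 1e-6
  check <- function(getter, setter, gmat, label) {
    g_num <- gmat
    for (i in seq_along(gmat)) {
      mp <- setter(m, getter(m) + h * (seq_along(gmat) == i))
      mm <- setter(m, getter(m) - h * (seq_along(gmat) == i))
      g_num[i] <- (loss_at(mp) - loss_at(mm)) / (2 * h)
    }
    expect_equal(as.numeric(gmat), as.numeric(g_num), tolerance = 1e-4,
                 label = label)
  }
  check(function(m) m$f[[1]]$W,
        function(m, v) { m$f[[1]]$W <- matrix(v, 4, 3); m },
        grads$f[[1]]$W, "drug channel W1")
  check(function(m) m$g[[1]]$W,
        function(m, v) { m$g[[1]]$W <- matrix(v, 4, 3); m },
        grads$g[[1]]$W, "disease channel W1")
  check(function(m) m$head$h1$W,
        function(m, v) { m$head$h1$W <- matrix(v, 3, 2); m },
        grads$head$h1$W, "head W")
  check(function(m) m$head$out$b,
        function(m, v) { m$head$out$b <- v; m },
        grads$head$out$b, "output bias")
})

test_that("total loss is affine in the divergence weight", {
  cfg0 <- model_config(channel_config(8, c(6, 4), dropout_rate = 0),
                       head_width = 3, kl_weight = 0)
  m <- init_model(cfg0, seed = 4)
  xr <- withr::with_seed(6, matrix(rnorm(10 * 8), 10, 8))
  xp <- withr::with_seed(7, matrix(rnorm(10 * 8), 10, 8))
  y <- rep(c(1L, 0L), 5)
  l0 <- siamese_loss(m, xr, xp, y, kl_weight = 0)
  l01 <- siamese_loss(m, xr, xp, y, kl_weight = 0.1)
  l1 <- siamese_loss(m, xr, xp, y, kl_weight = 1)
  kl_term <- l1 - l0
  expect_equal(l01, l0 + 0.1 * kl_term, tolerance = 1e-10)
  # lambda = 0 recovers the plain cross-entropy
  fw <- siamese_forward(m, xr, xp)
  expect_equal(l0, mean(bce_loss(y, fw$prob)), tolerance = 1e-10)
})

test_that("training fits a linearly separable fixture to perfect accuracy", {
  blk <- make_separable_fixture(n = 200, dim = 16, margin = 2, seed = 1)
  cfg <- model_config(channel_config(16, c(16, 8)), head_width = 8,
                      kl_weight = 0.1)
  tc <- train_config(learning_rate = 2e-3, max_epochs = 150,
                     early_stop_patience = 30, lr_reduce_patience = 15,
                     seed = 2)
  fit <- train_siamese(init_model(cfg, seed = 2), blk, blk, tc)
  expect_true(max(fit$history$train_acc) == 1)
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_acc", "lr") %in%
                    names(fit$history)))
})

test_that("early stopping halts before the epoch budget", {
  blk <- make_separable_fixture(n = 60, dim = 8, margin = 2, seed = 3)
  cfg <- model_config(channel_config(8, c(6)), head_width = 4)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 500,
                     early_stop_patience = 2, lr_reduce_patience = 2,
                     seed = 3)
  fit <- train_siamese(init_model(cfg, seed = 3), blk, blk, tc)
  expect_lt(nrow(fit$history), 500)
  expect_error(
    train_siamese(init_model(cfg, seed = 1),
                  structure(list(x = blk$x[blk$y == 1, ],
                                 y = blk$y[blk$y == 1], pairs = NULL),
                            class = "feature_block"),
                  blk, tc),
    "both classes"
  )
})

test_that("prediction applies the strict probability threshold", {
  toks <- c("drug:a", "drug:b", "disease:p")
  tab <- stub_table(toks, dim = 6)
  m <- init_model(model_config(channel_config(6, c(4)), head_width = 3),
                  seed = 1)
  pairs <- data.frame(drug = c("a", "b"), disease = "p")
  pr <- predict_pairs(m, pairs, tab)
  expect_equal(pr$label, as.integer(pr$prob > 0.5))
  # at a threshold equal to the probability itself the call is negative
  pr_tie <- predict_pairs(m, pairs[1, ], tab, threshold = pr$prob[1])
  expect_equal(pr_tie$label, 0L)
  expect_identical(pr, predict_pairs(m, pairs, tab))
  expect_equal(nrow(predict_pairs(m, pairs[0, ], tab)), 0L)
})
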