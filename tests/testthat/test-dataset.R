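test_that("positive set filters by status and deduplicates", {
  assoc <- data.frame(
    drug_id = c("r1", "r1", "r1", "r2"),
    disease_id = c("p1", "p2", "p1", "p1"),
    status = c("approved", "withdrawn", "approved", "approved")
  )
  pos <- build_positive_set(assoc, "approved")
  expect_equal(nrow(pos), 2L)
  expect_true(all(paste(pos$drug, pos$disease) %in%
                    c("r1 p1", "r2 p1")))
  expect_equal(nrow(build_positive_set(assoc[0, ], "approved")), 0L)
})

test_that("adverse-reaction negatives exclude positives and non-diseases", {
  sidefx <- data.frame(drug_id = c("r1", "r1", "r2"),
                       term_id = c("p2", "sX", "p2"))
  neg <- build_negative_set(sidefx, diseases = c("p1", "p2"))
  expect_equal(nrow(neg), 2L)  # sX is not a disease
  neg2 <- build_negative_set(sidefx, c("p1", "p2"),
                             positives = data.frame(drug = "r1",
                                                    disease = "p2"))
  expect_equal(paste(neg2$drug, neg2$disease), "r2 p2")
})

test_that("pair_set enforces disjointness and records provenance", {
  pos <- data.frame(drug = c("r1", "r2"), disease = c("p1", "p2"))
  neg <- data.frame(drug = c("r1", "r3"), disease = c("p1", "p3"))
  ps <- pair_set(pos, neg)
  expect_equal(sum(ps$label == 1L), 2L)
  expect_equal(sum(ps$label == 0L), 1L)  # (r1,p1) dropped from negatives
  prov <- attr(ps, "provenance")
  expect_equal(unname(prov["n_total"]),
               unname(prov["n_positive"] + prov["n_negative"]))
})

test_that("a 748-positive set yields a 74+74 test split at 10 percent", {
  pos <- data.frame(drug = sprintf("r%03d", rep(1:44, length.out = 748)),
                    disease = sprintf("p%04d", 1:748))
  neg <- data.frame(drug = sprintf("r%03d", rep(1:44, length.out = 900)),
                    disease = sprintf("q%04d", 1:900))
  ps <- pair_set(pos, neg)
  sp <- split_test(ps, fraction = 0.1, seed = 5)
  expect_equal(sum(sp$test$label == 1L), 74L)
  expect_equal(sum(sp$test$label == 0L), 74L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(ps))
  # conservation and disjointness
  key <- function(d) paste(d$drug, d$disease)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(ps))
})

test_that("split_test floors, is seeded, and checks negative supply", {
  pos <- data.frame(drug = sprintf("r%d", 1:10),
                    disease = sprintf("p%d", 1:10))
  neg <- data.frame(drug = sprintf("r%d", 1:3),
                    disease = sprintf("q%d", 1:3))
  ps <- pair_set(pos, neg)
  sp <- split_test(ps, 0.1, seed = 2)
  expect_equal(sum(sp$test$label == 1L), 1L)
  expect_equal(sum(sp$test$label == 0L), 1L)
  expect_identical(split_test(ps, 0.1, seed = 2)$test, sp$test)
  # 5 test positives would need 5 negatives; only 3 exist
  expect_error(split_test(ps, 0.5, seed = 2), "insufficient negatives")
})

test_that("pairs_to_features concatenates embeddings in pair order", {
  toks <- c("drug:r1", "drug:r2", "drug:r3",
            "disease:p1", "disease:p2")
  tab <- stub_table(toks, dim = 8)
  pairs <- data.frame(drug = c("r2", "r1", "r3"),
                      disease = c("p1", "p2", "p1"),
                      label = c(1L, 0L, 1L))
  blk <- pairs_to_features(pairs, tab)
  expect_equal(dim(blk$x), c(3L, 16L))
  expect_equal(blk$y, c(1L, 0L, 1L))
  expect_equal(blk$x[1, ],
               unname(c(tab$vectors["drug:r2", ],
                        tab$vectors["disease:p1", ])))
  empty <- pairs_to_features(pairs[0, ], tab)
  expect_equal(nrow(empty$x), 0L)
  pairs$drug[2] <- "missing"
  expect_error(pairs_to_features(pairs, tab), "out-of-vocabulary")
})

make_imbalanced_block <- function(n_pos = 20L, n_neg = 100L, dim = 6L,
                                  seed = 4L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_pos * dim, mean = 2), n_pos, dim),
               matrix(rnorm(n_neg * dim), n_neg, dim))
  })
  structure(list(x = x, y = c(rep(1L, n_pos), rep(0L, n_neg)),
                 pairs = NULL), class = "feature_block")
}

test_that("rebalancing strategies hit their target class counts", {
  blk <- make_imbalanced_block()
  counts <- function(b) c(pos = sum(b$y == 1L), neg = sum(b$y == 0L))

  expect_identical(rebalance(blk, "IMB"), blk)
  expect_equal(unname(counts(rebalance(blk, "RUS", seed = 1))), c(20L, 20L))
  expect_equal(unname(counts(rebalance(blk, "ROS", seed = 1))),
               c(100L, 100L))
  expect_equal(unname(counts(rebalance(blk, "OSMOTE", seed = 1))),
               c(100L, 100L))
  soru <- rebalance(blk, "SORU", smote_ratio = 0.9, seed = 1)
  expect_equal(unname(counts(soru)), c(90L, 90L))
})

test_that("rebalance validates its input", {
  blk <- make_imbalanced_block()
  one_class <- structure(list(x = blk$x[blk$y == 0L, ],
                              y = blk$y[blk$y == 0L], pairs = NULL),
                         class = "feature_block")
  expect_error(rebalance(one_class, "RUS"), "both classes")
  tiny <- make_imbalanced_block(n_pos = 4L, n_neg = 30L)
  expect_error(rebalance(tiny, "OSMOTE", k_neighbors = 5L), "k_neighbors")
})

test_that("SMOTE rows lie on minority-neighbour segments", {
  blk <- make_imbalanced_block(n_pos = 12L, n_neg = 40L, dim = 4L)
  k <- 5L
  out <- rebalance(blk, "OSMOTE", k_neighbors = k, seed = 9)
  x_min <- blk$x[blk$y == 1L, ]
  synth_rows <- out$x[-seq_len(nrow(blk$x)), , drop = FALSE]
  expect_equal(nrow(synth_rows), 40L - 12L)

  d <- as.matrix(dist(x_min))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  on_segment <- function(z) {
    for (i in seq_len(nrow(x_min))) {
      for (j in nn[i, ]) {
        a <- x_min[i, ]
        b <- x_min[j, ]
        dir <- b - a
        tt <- (z - a)[which.max(abs(dir))] / dir[which.max(abs(dir))]
        if (is.finite(tt) && tt >= -1e-8 && tt <= 1 + 1e-8 &&
            max(abs(z - (a + tt * dir))) < 1e-8) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  expect_true(all(apply(synth_rows, 1L, on_segment)))
})

test_that("pair sets round-trip through TSV", {
  ps <- pair_set(data.frame(drug = "r1", disease = "p1"),
                 data.frame(drug = "r2", disease = "p2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(ps, path)
  back <- read.delim(path)
  expect_equal(back$label, c(1L, 0L))
})
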