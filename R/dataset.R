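#' Build the positive drug-disease pair set
#'
#' Filters an association table to a given status (e.g. regulatory
#' approval) and deduplicates, yielding the set of known therapeutic
#' pairs.
#'
#' @param associations data.frame with columns `drug_id`, `disease_id`,
#'   `status`.
#' @param status_filter Status value retained (default `"approved"`).
#' @return data.frame with columns `drug`, `disease`, one row per pair.
#' @export
build_positive_set <- function(associations, status_filter = "approved") {
  stopifnot(all(c("drug_id", "disease_id", "status") %in%
                  names(associations)))
  keep <- associations$status == status_filter
  unique(data.frame(
    drug = associations$drug_id[keep],
    disease = associations$disease_id[keep],
    stringsAsFactors = FALSE
  ))
}

#' Build the adverse-reaction negative pair set
#'
#' A drug-disease pair is a presumed negative when the disease appears
#' among the drug's recorded side effects (side-effect terms and disease
#' identifiers share a normalized vocabulary) and the pair is not a known
#' positive: a drug that causes a condition as an adverse reaction is
#' taken not to treat it.
#'
#' @param side_effects data.frame with columns `drug_id`, `term_id`
#'   (terms normalized to the disease identifier space).
#' @param diseases Character vector of disease identifiers in the graph.
#' @param positives Positive pair data.frame from [build_positive_set()].
#' @return data.frame with columns `drug`, `disease`.
#' @export
build_negative_set <- function(side_effects, diseases, positives = NULL) {
  stopifnot(all(c("drug_id", "term_id") %in% names(side_effects)))
  hit <- side_effects$term_id %in% diseases
  neg <- unique(data.frame(
    drug = side_effects$drug_id[hit],
    disease = side_effects$term_id[hit],
    stringsAsFactors = FALSE
  ))
  if (!is.null(positives) && nrow(positives) && nrow(neg)) {
    neg <- neg[!(paste(neg$drug, neg$disease) %in%
                   paste(positives$drug, positives$disease)), , drop = FALSE]
  }
  rownames(neg) <- NULL
  neg
}

#' Assemble a labelled pair set
#'
#' Combines positive and negative pairs into one labelled table.
#' Disjointness is enforced: any negative also present among the
#' positives is dropped.
#'
#' @param positives,negatives Pair data.frames (`drug`, `disease`).
#' @return data.frame of class `pair_set` with columns `drug`, `disease`,
#'   `label` (1/0) and `role` (initially `"train"`); attribute
#'   `provenance` records the set sizes.
#' @export
pair_set <- function(positives, negatives) {
  if (nrow(negatives)) {
    negatives <- negatives[!(paste(negatives$drug, negatives$disease) %in%
                               paste(positives$drug, positives$disease)), ,
                           drop = FALSE]
  }
  ps <- rbind(
    data.frame(drug = positives$drug, disease = positives$disease,
               label = 1L, role = "train", stringsAsFactors = FALSE),
    data.frame(drug = negatives$drug, disease = negatives$disease,
               label = 0L, role = "train", stringsAsFactors = FALSE)
  )
  rownames(ps) <- NULL
  attr(ps, "provenance") <- c(
    n_positive = nrow(positives), n_negative = nrow(negatives),
    n_total = nrow(positives) + nrow(negatives)
  )
  class(ps) <- c("pair_set", class(ps))
  ps
}

#' Extract a fixed, class-balanced test split
#'
#' Samples `floor(fraction * n_positive)` positives uniformly at random
#' (seeded) plus an equal number of negatives; everything else stays in
#' the training set. No pair appears on both sides.
#'
#' @param pairs A `pair_set`.
#' @param fraction Fraction of positives to hold out (default 0.1).
#' @param seed Integer seed.
#' @return list with `train` and `test` pair sets (roles updated).
#' @export
split_test <- function(pairs, fraction = 0.1, seed = 1L) {
  stopifnot(inherits(pairs, "pair_set"), fraction > 0, fraction < 1)
  pos <- which(pairs$label == 1L)
  neg <- which(pairs$label == 0L)
  n_test <- floor(fraction * length(pos))
  if (n_test < 1L) stop("positive set too small for the requested fraction")
  if (length(neg) < n_test) {
    stop("insufficient negatives: need ", n_test, ", have ", length(neg))
  }
  picks <- withr::with_seed(seed, {
    list(pos = sample(pos, n_test), neg = sample(neg, n_test))
  })
  test_idx <- sort(c(picks$pos, picks$neg))
  test <- pairs[test_idx, , drop = FALSE]
  train <- pairs[-test_idx, , drop = FALSE]
  test$role <- "test"
  rownames(test) <- rownames(train) <- NULL
  prov <- attr(pairs, "provenance")
  for (nm in c("train", "test")) {
    x <- get(nm)
    attr(x, "provenance") <- prov
    class(x) <- c("pair_set", "data.frame")
    assign(nm, x)
  }
  list(train = train, test = test)
}

#' Join drug and disease embeddings into per-pair feature rows
#'
#' Row i is the concatenation of the drug vector and the disease vector
#' of pair i (length `2 * vector_size`); label order is preserved.
#'
#' @param pairs A `pair_set` (or data.frame with `drug`, `disease`,
#'   `label`).
#' @param table An `embedding_table` covering every pair's tokens.
#' @return list of class `feature_block` with `x` (matrix), `y` (integer
#'   labels) and `pairs` (the input rows).
#' @export
pairs_to_features <- function(pairs, table) {
  stopifnot(inherits(table, "embedding_table"))
  k <- ncol(table$vectors)
  if (nrow(pairs) == 0L) {
    return(structure(
      list(x = matrix(numeric(0), 0L, 2L * k), y = integer(0), pairs = pairs),
      class = "feature_block"
    ))
  }
  dtok <- .ns("drug", pairs$drug)
  ptok <- .ns("disease", pairs$disease)
  di <- match(dtok, rownames(table$vectors))
  pi <- match(ptok, rownames(table$vectors))
  bad <- which(is.na(di) | is.na(pi))
  if (length(bad)) {
    stop("pair(s) with out-of-vocabulary tokens: ",
         paste(utils::head(sprintf("(%s, %s)", pairs$drug[bad],
                                   pairs$disease[bad]), 5L), collapse = "; "))
  }
  x <- cbind(table$vectors[di, , drop = FALSE],
             table$vectors[pi, , drop = FALSE])
  rownames(x) <- NULL
  structure(
    list(x = x, y = as.integer(pairs$label), pairs = pairs),
    class = "feature_block"
  )
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %d rows x %d features (%d pos / %d neg)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

# SMOTE interpolation: each synthetic row sits on the segment between a
# random minority row and one of its k nearest minority neighbours.
.smote_rows <- function(x_min, n_new, k_neighbors) {
  n <- nrow(x_min)
  if (n <= k_neighbors) {
    stop("SMOTE needs minority count > k_neighbors (",
         n, " <= ", k_neighbors, "); reduce k_neighbors")
  }
  d <- as.matrix(stats::dist(x_min))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]))
  base <- sample.int(n, n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
  gap <- stats::runif(n_new)
  x_min[base, , drop = FALSE] +
    gap * (x_min[pick, , drop = FALSE] - x_min[base, , drop = FALSE])
}

#' Rebalance a training feature block
#'
#' Five strategies for the positive/negative imbalance of the training
#' data:
#' * `IMB` — leave the block unchanged;
#' * `RUS` — randomly undersample the majority class to parity;
#' * `ROS` — randomly duplicate minority rows to parity;
#' * `OSMOTE` — grow the minority to parity with SMOTE interpolation;
#' * `SORU` — SMOTE the minority up to `smote_ratio` times the majority
#'   count, then randomly undersample the majority down to the new
#'   minority count.
#'
#' Resampling operates on the joint concatenated feature space; labels
#' stay aligned. Only training data should ever be rebalanced.
#'
#' @param block A `feature_block`.
#' @param strategy One of `"IMB"`, `"RUS"`, `"ROS"`, `"OSMOTE"`, `"SORU"`.
#' @param smote_ratio Target minority/majority ratio for `SORU`
#'   (default 0.9).
#' @param k_neighbors SMOTE neighbourhood size (default 5).
#' @param seed Integer seed.
#' @return A `feature_block`; synthetic SMOTE rows carry no pair identity,
#'   so `pairs` is dropped for resampled blocks.
#' @export
rebalance <- function(block, strategy = c("IMB", "RUS", "ROS", "OSMOTE",
                                          "SORU"),
                      smote_ratio = 0.9, k_neighbors = 5L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(block, "feature_block"))
  n1 <- sum(block$y == 1L)
  n0 <- sum(block$y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("rebalancing requires both classes present")
  }
  if (strategy == "IMB") {
    return(block)
  }
  min_lab <- if (n1 <= n0) 1L else 0L
  maj_lab <- 1L - min_lab
  i_min <- which(block$y == min_lab)
  i_maj <- which(block$y == maj_lab)

  withr::with_seed(seed, {
    if (strategy == "RUS") {
      keep <- sort(c(i_min, sample(i_maj, length(i_min))))
      x <- block$x[keep, , drop = FALSE]
      y <- block$y[keep]
    } else if (strategy == "ROS") {
      extra <- sample(i_min, length(i_maj) - length(i_min), replace = TRUE)
      idx <- c(seq_len(nrow(block$x)), extra)
      x <- block$x[idx, , drop = FALSE]
      y <- block$y[idx]
    } else if (strategy == "OSMOTE") {
      new_x <- .smote_rows(block$x[i_min, , drop = FALSE],
                           length(i_maj) - length(i_min), k_neighbors)
      x <- rbind(block$x, new_x)
      y <- c(block$y, rep(min_lab, nrow(new_x)))
    } else {  # SORU
      target_min <- floor(smote_ratio * length(i_maj))
      n_new <- max(0L, target_min - length(i_min))
      if (n_new > 0L) {
        new_x <- .smote_rows(block$x[i_min, , drop = FALSE], n_new,
                             k_neighbors)
        x <- rbind(block$x, new_x)
        y <- c(block$y, rep(min_lab, nrow(new_x)))
      } else {
        target_min <- length(i_min)
        x <- block$x
        y <- block$y
      }
      i_maj2 <- which(y == maj_lab)
      keep <- sort(c(which(y == min_lab), sample(i_maj2, target_min)))
      x <- x[keep, , drop = FALSE]
      y <- y[keep]
    }
  })
  rownames(x) <- NULL
  structure(list(x = x, y = as.integer(y), pairs = NULL),
            class = "feature_block")
}

#' Write a labelled pair set as TSV
#'
#' @param pairs A `pair_set`.
#' @param path Destination (columns `drug_id`, `disease_id`, `label`,
#'   `role`).
#' @return Invisibly, the path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(
    data.frame(drug_id = pairs$drug, disease_id = pairs$disease,
               label = pairs$label, role = pairs$role),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
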