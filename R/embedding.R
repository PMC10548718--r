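#' Serialize a knowledge graph as triplet sentences
#'
#' Every triplet becomes one three-token sentence `head relation tail`
#' (namespaced entity ids plus the relation name). Sentence order is a
#' seeded permutation of the triplet set so that downstream stochastic
#' training sees a reproducible stream.
#'
#' @param kg A `ddkg` object.
#' @param seed Integer seed controlling the shuffle.
#' @return A character matrix of class `kg_corpus` with one row per
#'   sentence and three columns.
#' @export
triplets_to_corpus <- function(kg, seed = 1L) {
  stopifnot(inherits(kg, "ddkg"))
  if (nrow(kg$triplets) == 0L) {
    stop("cannot build a corpus from an empty graph")
  }
  ord <- withr::with_seed(seed, sample.int(nrow(kg$triplets)))
  m <- as.matrix(kg$triplets[ord, c("head", "relation", "tail")])
  dimnames(m) <- NULL
  class(m) <- c("kg_corpus", class(m))
  m
}

#' Write a corpus as plain text, one sentence per line
#'
#' @param corpus A `kg_corpus` matrix.
#' @param path Destination file; tokens are space-separated.
#' @return Invisibly, the path.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(apply(corpus, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Configuration for CBOW embedding training
#'
#' The training objective is continuous bag-of-words with negative
#' sampling: each token is predicted from the mean of its in-window
#' context vectors. Sentences are three tokens long, so the default
#' window of 2 always covers the whole sentence.
#'
#' @param vector_size Embedding dimension (the production-scale default is
#'   1024; tests use 16-64).
#' @param window Context window half-width.
#' @param epochs Passes over the corpus.
#' @param min_count Minimum corpus frequency for a token to be embedded.
#' @param negative Number of negative samples per prediction.
#' @param alpha,min_alpha Initial and final learning rate (linear decay).
#' @param seed Integer seed; training is single-threaded and reproducible.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(vector_size = 1024L, window = 2L, epochs = 50L,
                             min_count = 1L, negative = 5L, alpha = 0.025,
                             min_alpha = 1e-4, seed = 1L) {
  if (vector_size < 1L) stop("vector_size must be a positive integer")
  if (min_count < 1L) stop("min_count must be >= 1")
  if (window < 1L) stop("window must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(
    list(
      vector_size = as.integer(vector_size), window = as.integer(window),
      epochs = as.integer(epochs), min_count = as.integer(min_count),
      negative = as.integer(negative), alpha = alpha, min_alpha = min_alpha,
      seed = as.integer(seed), training_mode = "cbow"
    ),
    class = "embedding_config"
  )
}

#' Train CBOW embeddings on a triplet-sentence corpus
#'
#' Learns one vector per token (entities and relation names jointly) with
#' a continuous bag-of-words objective and negative sampling drawn from
#' the unigram distribution raised to the 3/4 power. With a fixed seed the
#' result is bit-reproducible.
#'
#' @param corpus A `kg_corpus` matrix from [triplets_to_corpus()].
#' @param config An [embedding_config()].
#' @return A list of class `embedding_table` with `vectors` (matrix, one
#'   row per token) and `config`.
#' @export
train_cbow <- function(corpus, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  if (is.null(dim(corpus)) || nrow(corpus) == 0L) {
    stop("corpus must be non-empty")
  }
  toks <- as.character(t(corpus))
  counts <- table(toks)
  # deterministic vocab order: frequency desc, then token name
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  freq <- as.numeric(counts)[ord]
  keep <- freq >= config$min_count
  vocab <- vocab[keep]
  freq <- freq[keep]
  if (length(vocab) == 0L) {
    stop("no token reaches min_count = ", config$min_count)
  }
  idx <- match(toks, vocab)  # NA for dropped tokens
  sent <- matrix(idx, ncol = 3L, byrow = TRUE)
  kept <- t(sent)
  kept_list <- split(kept[!is.na(kept)], rep(seq_len(nrow(sent)),
                                             each = 3L)[!is.na(kept)])
  lens <- vapply(kept_list, length, integer(1))
  kept_list <- kept_list[lens >= 2L]  # need at least one context token
  flat <- unlist(kept_list, use.names = FALSE) - 1L
  offsets <- c(0L, cumsum(vapply(kept_list, length, integer(1))))
  if (length(flat) == 0L) {
    stop("corpus has no sentence with >= 2 in-vocabulary tokens")
  }
  cdf <- cumsum(freq^0.75)
  cdf <- cdf / cdf[length(cdf)]
  vec <- cpp_cbow_train(
    as.integer(flat), as.integer(offsets), length(vocab),
    config$vector_size, config$window, config$epochs, config$negative,
    config$alpha, config$min_alpha, as.numeric(cdf), config$seed
  )
  rownames(vec) <- vocab
  structure(list(vectors = vec, config = config), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dims\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Look up the embedding vector of a token
#'
#' @param table An `embedding_table`.
#' @param token Token (namespaced entity id or relation name).
#' @return Numeric vector of length `vector_size`.
#' @export
embedding_lookup <- function(table, token) {
  stopifnot(inherits(table, "embedding_table"), length(token) == 1L)
  i <- match(token, rownames(table$vectors))
  if (is.na(i)) {
    stop("token not in embedding vocabulary: '", token, "'")
  }
  table$vectors[i, ]
}

#' Write an embedding table in word2vec text format
#'
#' First line is `vocab_size dim`, then one `token v1 ... vd` line per
#' token.
#'
#' @param table An `embedding_table`.
#' @param path Destination file.
#' @return Invisibly, the path.
#' @export
write_word2vec <- function(table, path) {
  v <- table$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(v), ncol(v)), con)
  writeLines(
    paste(rownames(v),
          apply(v, 1L, function(r) paste(formatC(r, format = "g", digits = 8),
                                         collapse = " "))),
    con
  )
  invisible(path)
}

#' Read an embedding table from word2vec text format
#'
#' @param path File written by [write_word2vec()] or any word2vec-style
#'   text embedding file.
#' @return An `embedding_table` (with a minimal config recording the
#'   dimension).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  toks <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(vec) <- toks
  structure(
    list(vectors = vec,
         config = embedding_config(vector_size = hdr[2L])),
    class = "embedding_table"
  )
}
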