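#' Repeated cross-validation of the siamese scorer
#'
#' The fixed held-out test split is evaluated under every (fold, repeat)
#' run: for each repeat the training pairs are partitioned into `folds`
#' label-stratified subsets; each fold in turn serves as the validation
#' monitor while the remaining folds — after rebalancing — train a fresh
#' model, which is then scored on the fixed test set. Rebalancing never
#' touches validation or test rows.
#'
#' @param pairs A `pair_set` whose `role` column already marks the fixed
#'   `test` rows (see [split_test()]); all other rows are cross-validated.
#' @param table An `embedding_table` trained on the leakage-cleaned graph,
#'   or a function taking the validation-fold pairs and returning a fresh
#'   `embedding_table` (strict per-fold re-embedding).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats with fresh fold assignments
#'   (default 4).
#' @param strategy Imbalance strategy for the training folds (see
#'   [rebalance()]).
#' @param seed Base seed; per-repeat and per-fold seeds derive from it.
#' @param threshold Decision threshold.
#' @param smote_ratio,k_neighbors Passed to [rebalance()].
#' @return list of class `cv_report` with `runs` (data.frame: repeat,
#'   fold, and one column per metric), `summary` (mean and sample
#'   standard deviation per metric over all runs) and `ensemble` (a
#'   `metric_report` on the test set for the average of all runs'
#'   predicted probabilities — the stable headline score).
#' @export
cross_validate <- function(pairs, table, model_cfg = model_config(),
                           train_cfg = train_config(), folds = 5L,
                           repeats = 4L, strategy = "SORU", seed = 1L,
                           threshold = 0.5, smote_ratio = 0.9,
                           k_neighbors = 5L) {
  stopifnot(inherits(pairs, "pair_set"))
  if (folds < 2L) stop("folds must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  test <- pairs[pairs$role == "test", , drop = FALSE]
  work <- pairs[pairs$role != "test", , drop = FALSE]
  if (nrow(test) == 0L) stop("pair set has no fixed test split")
  table_for <- if (is.function(table)) table else function(va) table

  runs <- list()
  probs <- list()
  test_y <- NULL
  for (rep_i in seq_len(repeats)) {
    rep_seed <- seed + 1000L * rep_i
    fold_of <- withr::with_seed(rep_seed, {
      f <- integer(nrow(work))
      for (lab in c(0L, 1L)) {
        idx <- which(work$label == lab)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      f
    })
    for (fold_i in seq_len(folds)) {
      va <- work[fold_of == fold_i, , drop = FALSE]
      tr <- work[fold_of != fold_i, , drop = FALSE]
      va$role <- "validation"
      tab <- table_for(va)
      test_block <- pairs_to_features(test, tab)
      tr_block <- rebalance(
        pairs_to_features(tr, tab), strategy,
        smote_ratio = smote_ratio, k_neighbors = k_neighbors,
        seed = rep_seed + fold_i
      )
      va_block <- pairs_to_features(va, tab)
      tc <- train_cfg
      tc$seed <- rep_seed + fold_i
      model <- init_model(model_cfg, seed = rep_seed + fold_i)
      fit <- train_siamese(model, tr_block, va_block, tc,
                           threshold = threshold)
      k <- model_cfg$channel$input_dim
      sp <- .split_xy(test_block, k)
      fw <- .model_forward(fit$model, sp$xr, sp$xp, training = FALSE)
      mr <- metrics(test_block$y, fw$prob, threshold = threshold)
      probs[[length(probs) + 1L]] <- fw$prob
      test_y <- test_block$y
      runs[[length(runs) + 1L]] <- data.frame(
        rep = rep_i, fold = fold_i, acc = mr$acc, auc_roc = mr$auc_roc,
        auc_pr = mr$auc_pr, brier = mr$brier, mcc = mr$mcc, f1 = mr$f1,
        n = mr$n
      )
    }
  }
  runs <- do.call(rbind, runs)
  ensemble <- metrics(test_y, Reduce(`+`, probs) / length(probs),
                      threshold = threshold)
  metric_cols <- c("acc", "auc_roc", "auc_pr", "brier", "mcc", "f1")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(runs[metric_cols], mean, numeric(1)),
    sd = vapply(runs[metric_cols], function(v) {
      if (length(v) > 1L) stats::sd(v) else 0
    }, numeric(1)),
    row.names = NULL
  )
  structure(list(runs = runs, summary = summary, ensemble = ensemble,
                 folds = folds, repeats = repeats),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds x %d repeats on fixed test set\n",
              x$folds, x$repeats))
  print(x$summary, digits = 4)
  cat("ensemble: ")
  print(x$ensemble)
  invisible(x)
}

#' Rank candidate drugs for a query disease
#'
#' Scores every candidate drug against the disease and returns the top
#' of the list sorted by decreasing probability; exact ties are broken
#' by drug identifier so the ranking is stable across runs.
#'
#' @param model A trained `siamese_model`.
#' @param table An `embedding_table`.
#' @param disease Disease identifier (local id).
#' @param drugs Character vector of candidate drug identifiers.
#' @param top_n Number of entries to return (default 10).
#' @return data.frame `rank`, `drug`, `prob`.
#' @export
rank_drugs <- function(model, table, disease, drugs, top_n = 10L) {
  stopifnot(length(disease) == 1L, length(drugs) >= 1L)
  if (!(.ns("disease", disease) %in% rownames(table$vectors))) {
    stop("disease not in embedding vocabulary: '", disease, "'")
  }
  preds <- predict_pairs(
    model,
    data.frame(drug = drugs, disease = disease, stringsAsFactors = FALSE),
    table
  )
  ord <- order(-preds$prob, preds$drug)
  top <- utils::head(preds[ord, , drop = FALSE], top_n)
  data.frame(rank = seq_len(nrow(top)), drug = top$drug, prob = top$prob,
             stringsAsFactors = FALSE)
}

#' Write a cross-validation report as CSV
#'
#' @param report A `cv_report`.
#' @param path Destination file (long format: repeat, fold, metrics).
#' @return Invisibly, the path.
#' @export
write_cv_report <- function(report, path) {
  utils::write.csv(report$runs, path, row.names = FALSE)
  invisible(path)
}
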