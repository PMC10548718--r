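#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings: input tables (in-memory data.frames or
#' TSV paths), graph version, embedding, model and training
#' configurations, the imbalance strategy, split and cross-validation
#' layout, and a base seed from which each stage's seed is derived
#' deterministically.
#'
#' @param nodes,edges,associations,side_effects Input tables (data.frames)
#'   or paths to TSV files in the package dialects.
#' @param version Graph version tag (see [version_relations()]).
#' @param embedding An [embedding_config()].
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param strategy Imbalance strategy (see [rebalance()]).
#' @param test_fraction Fraction of positives held out (default 0.1).
#' @param folds,repeats Cross-validation layout (defaults 5 and 4).
#' @param status_filter Association status defining positives.
#' @param threshold Decision threshold.
#' @param per_fold_embedding Logical; retrain the embedding inside every
#'   cross-validation run with that run's validation fold also removed
#'   from the graph (stricter leakage control, much slower). Default
#'   FALSE: the embedding is trained once on the graph cleaned of the
#'   fixed test pairs.
#' @param seed Base seed.
#' @param out_dir Optional run directory for artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(nodes, edges, associations, side_effects,
                            version = "V1",
                            embedding = embedding_config(),
                            model = model_config(),
                            train = train_config(),
                            strategy = "SORU", test_fraction = 0.1,
                            folds = 5L, repeats = 4L,
                            status_filter = "approved", threshold = 0.5,
                            per_fold_embedding = FALSE, seed = 1L,
                            out_dir = NULL) {
  structure(
    list(nodes = nodes, edges = edges, associations = associations,
         side_effects = side_effects, version = version,
         embedding = embedding, model = model, train = train,
         strategy = strategy, test_fraction = test_fraction,
         folds = as.integer(folds), repeats = as.integer(repeats),
         status_filter = status_filter, threshold = threshold,
         per_fold_embedding = per_fold_embedding,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

.load_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    utils::read.delim(x, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    x
  }
}

#' Run the full association-prediction pipeline
#'
#' Stages: build the typed graph at the configured version, derive
#' drug-domain edges, assemble positive (status-filtered) and negative
#' (adverse-reaction) pair sets, extract the fixed class-balanced test
#' split, remove the test pairs' treatment and side-effect edges from
#' the graph, embed the cleaned graph with CBOW, then run repeated
#' cross-validation of the siamese model (training folds rebalanced,
#' metrics on the fixed test set). With `out_dir` set, the run directory
#' receives `kg.tsv`, `emb.w2v`, `pairs.tsv`, `report.csv`,
#' `config.json` and a `model/` checkpoint of a final model trained on
#' the first fold layout.
#'
#' @param config A [pipeline_config()].
#' @return list of class `pipeline_result` with `cv` (a `cv_report`),
#'   `kg`, `table` (embedding), `pairs` (labelled pair set with roles)
#'   and `test_metrics` (mean test-set metrics across runs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  nodes <- .load_table(config$nodes)
  edges <- .load_table(config$edges)
  assoc <- .load_table(config$associations)
  sidefx <- .load_table(config$side_effects)

  kg <- build_kg(nodes, edges, version = config$version)
  kg <- derive_drug_domain_edges(kg)

  diseases <- .local_id(names(kg$nodes)[kg$nodes == "disease"])
  positives <- build_positive_set(assoc, config$status_filter)
  negatives <- build_negative_set(sidefx, diseases, positives)
  if (nrow(negatives) == 0L) {
    stop("dataset stage: adverse-reaction rule produced no negatives")
  }
  ps <- pair_set(positives, negatives)
  sp <- split_test(ps, fraction = config$test_fraction,
                   seed = config$seed + 11L)

  kg_clean <- remove_treatment_edges(kg, sp$test)
  corpus <- triplets_to_corpus(kg_clean, seed = config$seed + 23L)
  emb_cfg <- config$embedding
  emb_cfg$seed <- config$seed + 37L
  table <- train_cbow(corpus, emb_cfg)

  all_pairs <- rbind(sp$train, sp$test)
  class(all_pairs) <- c("pair_set", "data.frame")
  cv_table <- if (isTRUE(config$per_fold_embedding)) {
    function(va) {
      kg_fold <- remove_treatment_edges(kg_clean, va)
      train_cbow(triplets_to_corpus(kg_fold, seed = config$seed + 23L),
                 emb_cfg)
    }
  } else {
    table
  }
  cv <- cross_validate(
    all_pairs, cv_table, model_cfg = config$model, train_cfg = config$train,
    folds = config$folds, repeats = config$repeats,
    strategy = config$strategy, seed = config$seed + 53L,
    threshold = config$threshold
  )
  test_metrics <- stats::setNames(cv$summary$mean, cv$summary$metric)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_kg(kg_clean, file.path(config$out_dir, "kg.tsv"),
             file.path(config$out_dir, "kg_nodes.tsv"))
    write_word2vec(table, file.path(config$out_dir, "emb.w2v"))
    write_pairs(all_pairs, file.path(config$out_dir, "pairs.tsv"))
    write_cv_report(cv, file.path(config$out_dir, "report.csv"))
    echo <- config
    for (nm in c("nodes", "edges", "associations", "side_effects")) {
      if (!is.character(echo[[nm]])) echo[[nm]] <- "<in-memory table>"
    }
    jsonlite::write_json(unclass(echo),
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    .write_checkpoint(all_pairs, table, config)
  }

  structure(
    list(cv = cv, kg = kg_clean, table = table, pairs = all_pairs,
         test_metrics = test_metrics, config = config),
    class = "pipeline_result"
  )
}

# train one model on the first-fold layout and store config + weights
.write_checkpoint <- function(all_pairs, table, config) {
  dir <- file.path(config$out_dir, "model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  work <- all_pairs[all_pairs$role != "test", , drop = FALSE]
  n_val <- max(2L, floor(nrow(work) / max(2L, config$folds)))
  idx <- withr::with_seed(config$seed + 71L,
                          sample.int(nrow(work), n_val))
  va <- work[idx, , drop = FALSE]
  tr <- work[-idx, , drop = FALSE]
  tr_block <- rebalance(pairs_to_features(tr, table), config$strategy,
                        seed = config$seed + 72L)
  fit <- train_siamese(init_model(config$model, seed = config$seed + 73L),
                       tr_block, pairs_to_features(va, table),
                       config$train, threshold = config$threshold)
  jsonlite::write_json(unclass(config$model), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  saveRDS(fit$model, file.path(dir, "weights.rds"))
  utils::write.csv(fit$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$kg)
  print(x$cv)
  invisible(x)
}

#' Run an ablation grid over graph versions, weight modes and strategies
#'
#' Repeats the pipeline for every combination of the supplied axes and
#' stacks the per-cell summaries into one long table.
#'
#' @param config Base [pipeline_config()].
#' @param versions Character vector of graph versions.
#' @param modes Character vector of weight modes.
#' @param strategies Character vector of imbalance strategies.
#' @return data.frame with columns `version`, `weight_mode`, `strategy`,
#'   `metric`, `mean`, `sd`.
#' @export
run_ablation_grid <- function(config, versions = "V1",
                              modes = "heterogeneous",
                              strategies = "SORU") {
  if (!length(versions) || !length(modes) || !length(strategies)) {
    stop("every grid axis must be non-empty")
  }
  out <- list()
  for (v in versions) {
    for (m in modes) {
      for (s in strategies) {
        cfg <- config
        cfg$version <- v
        cfg$model$weight_mode <- m
        cfg$strategy <- s
        cfg$out_dir <- NULL
        res <- tryCatch(run_pipeline(cfg), error = function(e) {
          stop("ablation cell (", v, ", ", m, ", ", s, ") failed: ",
               conditionMessage(e))
        })
        sm <- res$cv$summary
        out[[length(out) + 1L]] <- data.frame(
          version = v, weight_mode = m, strategy = s,
          metric = sm$metric, mean = sm$mean, sd = sm$sd,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Desk-scale pipeline configuration for a synthetic benchmark
#'
#' Convenience constructor bundling the method settings used throughout
#' the package's synthetic-benchmark experiments: 48-dimensional CBOW
#' embeddings trained for 300 epochs (the triplet corpus at this graph
#' size is three orders of magnitude smaller than a production corpus,
#' so more passes replace more sentences), channel widths 64-32 with a
#' 16-unit head, Adam at 1e-3, up to 100 epochs with early stopping,
#' 5 folds x 1 repeat.
#'
#' @param synth Output of [generate_synthetic()].
#' @param seed Base seed for the pipeline.
#' @param version Graph version tag.
#' @param strategy Imbalance strategy.
#' @param weight_mode Channel weight mode.
#' @param folds,repeats Cross-validation layout.
#' @param ... Further arguments passed to [pipeline_config()].
#' @return A [pipeline_config()].
#' @export
synthetic_pipeline_config <- function(synth, seed = 1L, version = "V1",
                                      strategy = "SORU",
                                      weight_mode = "heterogeneous",
                                      folds = 5L, repeats = 1L, ...) {
  pipeline_config(
    synth$nodes, synth$edges, synth$associations, synth$side_effects,
    version = version,
    embedding = embedding_config(vector_size = 48L, epochs = 300L),
    model = model_config(
      channel = channel_config(input_dim = 48L, layer_widths = c(64L, 32L)),
      head_width = 16L, weight_mode = weight_mode
    ),
    train = train_config(learning_rate = 1e-3, max_epochs = 100L,
                         early_stop_patience = 20L,
                         lr_reduce_patience = 10L),
    strategy = strategy, folds = folds, repeats = repeats, seed = seed, ...
  )
}
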