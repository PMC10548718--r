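# Shared in-code fixtures: a hand-written toy graph covering most
# relation types, and small synthetic configurations for fast tests.

toy_tables <- function() {
  nodes <- data.frame(
    node_id = c("r1", "c1", "c2", "t1", "d1", "s1", "a1",
                "p1", "g1", "cl1", "ty1", "se1"),
    node_type = c("drug", "chemical_substructure", "chemical_substructure",
                  "target_protein", "protein_domain", "side_effect",
                  "atc_code", "disease", "gene", "disease_class",
                  "disease_type", "semantic_type"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    head_id = c("r1", "r1", "r1", "r1", "t1", "r1", "r1",
                "p1", "p1", "p1", "p1", "g1", "r1"),
    relation = c("has_chemical_substructure", "has_chemical_substructure",
                 "has_target", "has_domain", "has_domain_target",
                 "has_side_effect", "has_ATC_code",
                 "has_gene", "has_class", "has_type", "has_semantic_type",
                 "has_encoded", "has_treatment"),
    tail_id = c("c1", "c2", "t1", "d1", "d1", "s1", "a1",
                "g1", "cl1", "ty1", "se1", "t1", "p1"),
    stringsAsFactors = FALSE
  )
  list(nodes = nodes, edges = edges)
}

small_synth_config <- function(seed = 1L) {
  synthetic_config(
    n_drugs = 24L, n_diseases = 10L, n_clusters = 3L,
    vocab = list(chemical_substructure = 18L, target_protein = 12L,
                 protein_domain = 9L, side_effect = 16L, atc_code = 6L,
                 gene = 12L, disease_class = 4L, disease_type = 4L,
                 semantic_type = 4L),
    seed = seed
  )
}

# tiny deterministic embedding table without any training
stub_table <- function(tokens, dim = 8L, seed = 1L) {
  v <- withr::with_seed(seed,
                        matrix(stats::rnorm(length(tokens) * dim),
                               length(tokens), dim))
  rownames(v) <- tokens
  structure(list(vectors = v, config = embedding_config(vector_size = dim)),
            class = "embedding_table")
}

# a fast pipeline configuration for plumbing tests (not for accuracy)
quick_pipeline_config <- function(synth, seed = 1L, ...) {
  pipeline_config(
    synth$nodes, synth$edges, synth$associations, synth$side_effects,
    embedding = embedding_config(vector_size = 16L, epochs = 40L),
    model = model_config(channel = channel_config(16L, c(16L, 8L)),
                         head_width = 8L),
    train = train_config(learning_rate = 1e-3, max_epochs = 8L,
                         early_stop_patience = 4L, lr_reduce_patience = 3L),
    folds = 2L, repeats = 1L, test_fraction = 0.15, seed = seed, ...
  )
}
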